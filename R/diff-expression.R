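#' Two-group pooled-variance t-test
#'
#' Thin, strictly-validated wrapper used by the per-transcript screens.
#' Degenerate inputs follow explicit conventions: identical groups with
#' zero variance give `t = 0, p = 1`; zero pooled variance with unequal
#' means is an error.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @param var_equal Pooled-variance test (default); set `FALSE` for Welch.
#' @return A one-row tibble with `t`, `df`, `p`.
#' @export
two_group_ttest <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) abort("each group needs >= 2 values.")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(tibble(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    abort("degenerate variance: groups are constant but differ in mean.")
  }
  ht <- t.test(x, y, var.equal = var_equal)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Empirical-Bayes moderated t-statistics
#'
#' Shrinks per-gene sample variances toward a common prior before
#' testing: the posterior variance is
#' `s2_post = (d0 * s0_sq + d * s2) / (d0 + d)` with residual degrees of
#' freedom `d`, and the moderated statistic
#' `t = delta / sqrt(s2_post * (1/n1 + 1/n2))` is referred to a
#' t-distribution on `d0 + d` degrees of freedom.  `d0 = 0` recovers the
#' ordinary pooled t-test exactly; `d0 = Inf` tests every gene against the
#' common variance `s0_sq`.
#'
#' When `d0`/`s0_sq` are not supplied they are estimated from the
#' distribution of `log(s2)` by method of moments: for scaled-chi-square
#' sampling, `var(log s2)` exceeds `trigamma(d/2)` by `trigamma(d0/2)`,
#' which is inverted by Newton iteration.
#'
#' @param delta Per-gene difference of group means (log2 scale).
#' @param s2 Per-gene pooled sample variances (>= 0).
#' @param n1,n2 Group sizes.
#' @param d0,s0_sq Optional prior degrees of freedom (>= 0, `Inf` allowed)
#'   and prior variance (> 0); both estimated when `NULL`.
#' @return A tibble with per-gene `t`, `df`, `p`, `s2_post`, plus the
#'   hyperparameters used as attributes `"d0"` and `"s0_sq"`.
#' @export
moderated_ttest <- function(delta, s2, n1, n2, d0 = NULL, s0_sq = NULL) {
  if (length(delta) != length(s2)) abort("`delta` and `s2` lengths differ.")
  if (any(s2 < 0)) abort("variances must be >= 0.")
  d <- n1 + n2 - 2
  if (d < 1) abort("need n1 + n2 >= 3.")
  if (is.null(d0) || is.null(s0_sq)) {
    est <- fit_variance_prior(s2, d)
    d0 <- d0 %||% est$d0
    s0_sq <- s0_sq %||% est$s0_sq
  }
  if (d0 < 0) abort("`d0` must be >= 0.")
  if (!is.finite(s0_sq) || s0_sq <= 0) abort("`s0_sq` must be positive.")
  if (d0 == 0 && all(s2 == 0)) {
    abort("all genes have zero variance and d0 = 0: nothing to test against.")
  }
  s2_post <- if (is.infinite(d0)) {
    rep(s0_sq, length(s2))
  } else {
    (d0 * s0_sq + d * s2) / (d0 + d)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t <- delta / se
  df <- d0 + d
  p <- if (is.infinite(df)) 2 * pnorm(-abs(t)) else 2 * pt(-abs(t), df)
  out <- tibble(t = t, df = df, p = p, s2_post = s2_post)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

# Method-of-moments fit of the scaled-chi-square variance prior from
# log sample variances; zero variances are excluded from the fit.
fit_variance_prior <- function(s2, d) {
  s2 <- s2[s2 > 0]
  if (length(s2) < 2) abort("need >= 2 positive variances to fit the prior.")
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  excess <- var(e) - trigamma(d / 2)
  if (excess <= 0) {
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0_sq <- exp(mean(e) - log(d0 / 2) + digamma(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Solve trigamma(x) = y by Newton iteration on 1/trigamma (monotone,
# nearly linear), as is standard for this fit.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (same order), controlling the FDR.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation test
#'
#' Tests whether `selected` over-represents `category` within `universe`:
#' `p = P(X >= overlap)` for `X ~ Hypergeometric(N = |universe|,
#' K = |category|, n = |selected|)`.
#'
#' @param selected,category,universe Character vectors of identifiers;
#'   `selected` and `category` must be subsets of `universe`.
#' @return A one-row tibble with `overlap`, `expected`, `p`.
#' @export
hypergeometric_enrichment <- function(selected, category, universe) {
  selected <- unique(selected); category <- unique(category)
  universe <- unique(universe)
  if (length(setdiff(selected, universe)) > 0 ||
      length(setdiff(category, universe)) > 0) {
    abort("`selected` and `category` must be subsets of `universe`.")
  }
  N <- length(universe); K <- length(category); n <- length(selected)
  k <- length(intersect(selected, category))
  tibble(
    overlap = k,
    expected = n * K / N,
    p = phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  )
}

#' @rdname hypergeometric_enrichment
#' @param sets Named list of gene sets (e.g. from [read_gmt()]); sets are
#'   intersected with the universe before testing.
#' @return `enrich_gene_sets()`: a tibble with one row per set
#'   (`set`, `set_size`, `overlap`, `expected`, `p`, `p_adj`).
#' @export
enrich_gene_sets <- function(selected, sets, universe) {
  res <- purrr::imap(sets, function(members, nm) {
    cat_in <- intersect(members, universe)
    if (length(cat_in) == 0) return(NULL)
    row <- hypergeometric_enrichment(selected, cat_in, universe)
    dplyr::bind_cols(tibble(set = nm, set_size = length(cat_in)), row)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) > 0) out$p_adj <- bh_adjust(out$p)
  dplyr::arrange(out, .data$p)
}

#' Call differentially expressed transcripts against normal controls
#'
#' Per transcript, cases are compared to normal controls on the log2
#' fold-change matrix (shift-invariant, so identical to testing the raw
#' log2 values).  The reported average fold change is the ratio of
#' geometric means (difference of log2 group means, exponentiated), and a
#' transcript is called `up` when `fc > fc_cut` with BH-adjusted
#' `p < alpha`, `down` when `fc < 1/fc_cut` with `p_adj < alpha`, and
#' `none` otherwise.
#'
#' @param fc Wide log2 fold-change tibble from
#'   [log2_fold_change_vs_normal()] (raw log2 values work equally).
#' @param annotation Cohort annotation.
#' @param case_groups Disease groups forming the case arm; default all
#'   non-normal groups present.  Restrict to a single subtype for
#'   subtype-specific calls.
#' @param method `"ttest"` (pooled two-group t) or `"moderated"`
#'   (empirical-Bayes moderated t).
#' @param fc_cut Linear fold-change threshold (default 4).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param d0,s0_sq Optional explicit moderation hyperparameters.
#' @return A tibble with one row per transcript: `transcript_id`,
#'   `mean_log2fc`, `fc`, `t`, `df`, `p_raw`, `p_adj`, `call`.
#' @export
call_differential <- function(fc, annotation,
                              case_groups = NULL,
                              method = c("ttest", "moderated"),
                              fc_cut = 4, alpha = 0.05,
                              d0 = NULL, s0_sq = NULL) {
  method <- match.arg(method)
  assert_expr_tbl(fc)
  annotation <- validate_annotation(annotation)
  if (fc_cut <= 1) abort("`fc_cut` must exceed 1.")
  present <- sample_ids(fc)
  normals <- intersect(annotation$sample_id[annotation$group == "normal"], present)
  case_groups <- case_groups %||%
    setdiff(unique(annotation$group), "normal")
  cases <- intersect(
    annotation$sample_id[annotation$group %in% case_groups], present
  )
  if (length(normals) < 2 || length(cases) < 2) {
    abort("need >= 2 samples per arm.")
  }
  m <- expr_matrix(fc)
  n1 <- length(cases); n2 <- length(normals)
  mu1 <- rowMeans(m[, cases, drop = FALSE])
  mu2 <- rowMeans(m[, normals, drop = FALSE])
  delta <- mu1 - mu2
  v1 <- row_vars(m[, cases, drop = FALSE])
  v2 <- row_vars(m[, normals, drop = FALSE])
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)

  if (method == "ttest") {
    d <- n1 + n2 - 2
    se <- sqrt(s2 * (1 / n1 + 1 / n2))
    degen <- s2 == 0
    if (any(degen & delta != 0)) {
      abort(sprintf(
        "degenerate variance with unequal means for transcript(s): %s",
        paste(head(rownames(m)[degen & delta != 0], 5), collapse = ", ")
      ))
    }
    t <- ifelse(degen, 0, delta / se)
    p <- ifelse(degen, 1, 2 * pt(-abs(t), d))
    stats <- tibble(t = t, df = d, p = p)
  } else {
    stats <- moderated_ttest(delta, s2, n1, n2, d0 = d0, s0_sq = s0_sq)
  }

  p_adj <- bh_adjust(stats$p)
  fc_lin <- 2^delta
  call <- dplyr::case_when(
    fc_lin > fc_cut & p_adj < alpha ~ "up",
    fc_lin < 1 / fc_cut & p_adj < alpha ~ "down",
    .default = "none"
  )
  tibble(
    transcript_id = rownames(m),
    mean_log2fc = delta, fc = fc_lin,
    t = stats$t, df = stats$df,
    p_raw = stats$p, p_adj = p_adj,
    call = call
  )
}
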