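#' Correlation between two sample-level quantities
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param method `"pearson"` or `"spearman"` (mid-rank ties, asymptotic
#'   two-sided p).
#' @return A one-row tibble `method`, `r`, `p`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need >= 3 paired finite observations.")
  if (sd(x) == 0 || sd(y) == 0) abort("correlation undefined for a constant vector.")
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  tibble(method = method, r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Ordinary least-squares fit with explicit sample exclusion
#'
#' Exclusion is only ever by user-listed sample ids (no automatic outlier
#' detection); excluded ids are recorded in the result.  A constant
#' response gives `r_squared = 0` by convention.
#'
#' @param x Predictor values.
#' @param y Response values.
#' @param ids Optional sample ids aligned with `x`/`y` (required when
#'   `exclude` is used).
#' @param exclude Sample ids to drop before fitting.
#' @return A one-row tibble `slope`, `intercept`, `r_squared`, `p_value`
#'   (two-sided slope test), `n`, `excluded` (list column).
#' @export
linear_fit <- function(x, y, ids = NULL, exclude = NULL) {
  if (length(x) != length(y)) abort("`x` and `y` lengths differ.")
  if (!is.null(exclude)) {
    if (is.null(ids)) abort("`exclude` needs `ids` to identify samples.")
    keep <- !(ids %in% exclude)
    x <- x[keep]; y <- y[keep]
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need >= 3 points after exclusion.")
  if (sd(x) == 0) abort("degenerate predictor: all x equal.")
  fit <- lm(y ~ x)
  if (sd(y) == 0) {
    return(tibble(slope = 0, intercept = y[1], r_squared = 0, p_value = 1,
                  n = length(x), excluded = list(exclude %||% character(0))))
  }
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate here
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    n = length(x),
    excluded = list(exclude %||% character(0))
  )
}

#' Principal-component summary of the differential transcripts
#'
#' Treats samples as observations over the (gene-centered) fold-change
#' profiles of the supplied transcripts, computes the fraction of total
#' variance carried by the first principal component, and regresses the
#' PC1 sample scores on the log2 leukocyte index.  When most expression
#' variation stems from leukocyte infiltration, PC1 dominates and aligns
#' with the index.
#'
#' @param fc Wide log2 fold-change tibble restricted to the transcripts
#'   of interest (e.g. all differentially expressed ones).
#' @param index Per-sample index tibble or named vector.
#' @return A list of class `myo_pca`: `pc1_variance_fraction`, `fit` (the
#'   [linear_fit()] of PC1 scores on log2 index), and `scores`
#'   (tibble `sample_id`, `pc1`, `log2_index`).
#' @export
pc1_analysis <- function(fc, index) {
  assert_expr_tbl(fc)
  m <- expr_matrix(fc)
  if (nrow(m) < 2 || ncol(m) < 3) abort("need >= 2 transcripts and >= 3 samples.")
  v <- index_vector(index, colnames(m))
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (sum(ev) == 0) abort("degenerate matrix: no variance.")
  scores <- tibble(
    sample_id = colnames(m),
    pc1 = unname(pc$x[, 1]),
    log2_index = unname(log2(v))
  )
  fit <- if (sd(scores$log2_index) > 0) {
    linear_fit(scores$log2_index, scores$pc1, ids = scores$sample_id)
  }  # a constant index leaves nothing to regress on
  structure(
    list(
      pc1_variance_fraction = ev[1] / sum(ev),
      fit = fit,
      scores = scores
    ),
    class = "myo_pca"
  )
}

#' @export
print.myo_pca <- function(x, ...) {
  cat(sprintf("PC1 carries %.1f%% of the variance; PC1 ~ log2 index R^2 = %.2f\n",
              100 * x$pc1_variance_fraction, x$fit$r_squared))
  invisible(x)
}

#' Concordance of the leukocyte index with the H&E inflammation grade
#'
#' Regresses the log2 index (response) on the ordinal 0-4 histology grade
#' treated numerically; the log2 scale makes a unit of grade comparable
#' to a doubling of the index.
#'
#' @param index Per-sample index tibble (`sample_id`, `index`) or named
#'   vector.
#' @param annotation Cohort annotation with an `he_grade` column.
#' @param exclude Optional sample ids to drop.
#' @return A [linear_fit()] row.
#' @export
he_concordance <- function(index, annotation, exclude = NULL) {
  annotation <- validate_annotation(annotation)
  if (!"he_grade" %in% names(annotation)) abort("annotation lacks `he_grade`.")
  ann <- annotation[!is.na(annotation$he_grade), ]
  v <- index_vector(index, ann$sample_id)
  if (length(unique(ann$he_grade)) < 2) abort("all H&E grades are equal.")
  linear_fit(as.numeric(ann$he_grade), log2(v),
             ids = ann$sample_id, exclude = exclude)
}

#' Screen for anti-correlated mRNA:miRNA pairs
#'
#' Computes the correlation of every mRNA x miRNA pair across the shared
#' samples and returns pairs at or below `r_cut`, with BH-adjusted
#' p-values computed over all tested pairs.  P-values use the asymptotic
#' t approximation `t = r * sqrt((n-2)/(1-r^2))` (mid-ranks first for
#' Spearman), matching `cor.test(..., exact = FALSE)`.
#'
#' @param mrna_fc,mirna_fc Wide log2 fold-change tibbles for the two
#'   platforms.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param r_cut Correlation ceiling for reporting (default -0.5); pairs
#'   must be at or below it, so positively correlated pairs are excluded
#'   by construction.
#' @return A tibble `mrna_id`, `mirna_id`, `r`, `p`, `p_adj`, strongest
#'   anti-correlation first.
#' @export
anticorrelation_screen <- function(mrna_fc, mirna_fc,
                                   method = c("spearman", "pearson"),
                                   r_cut = -0.5) {
  method <- match.arg(method)
  assert_expr_tbl(mrna_fc); assert_expr_tbl(mirna_fc)
  shared <- intersect(sample_ids(mrna_fc), sample_ids(mirna_fc))
  if (length(shared) < 3) abort("need >= 3 shared samples between matrices.")
  A <- expr_matrix(mrna_fc)[, shared, drop = FALSE]
  B <- expr_matrix(mirna_fc)[, shared, drop = FALSE]
  if (method == "spearman") {
    A <- t(apply(A, 1, rank))
    B <- t(apply(B, 1, rank))
  }
  R <- suppressWarnings(cor(t(A), t(B)))
  n <- length(shared)
  tstat <- R * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
  P <- 2 * pt(-abs(tstat), n - 2)
  out <- tibble(
    mrna_id = rep(rownames(R), times = ncol(R)),
    mirna_id = rep(colnames(R), each = nrow(R)),
    r = as.vector(R),
    p = as.vector(P)
  )
  out$p_adj <- bh_adjust(out$p)
  out |>
    dplyr::filter(is.finite(.data$r), .data$r <= r_cut) |>
    dplyr::arrange(.data$r)
}
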