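#' Adjust an expression matrix by the leukocyte index
#'
#' The deconvolution step: transcriptional change attributable purely to
#' leukocyte infiltration is removed so that what remains reflects
#' tissue-intrinsic regulation.  In `divide` mode (primary) each sample's
#' column is divided by its index — `adjusted[g, s] = values[g, s] -
#' log2(index_s)` — which exactly nulls a transcript whose fold change
#' equals the infiltration ratio (the invasion-model fingerprint of a
#' leukocyte-specific gene).  `residual` mode instead regresses each
#' gene's log2 values on the log2 index across samples and keeps
#' intercept plus residual, removing only the gene's own linear
#' index-dependence.
#'
#' @param expr Wide log2 expression or fold-change tibble.
#' @param index Per-sample index: tibble(`sample_id`, `index`) from
#'   [leukocyte_index()] or a named positive numeric vector covering all
#'   samples of `expr`.
#' @param mode `"divide"` (default) or `"residual"`.
#' @return The adjusted tibble (same shape and ids), with attributes
#'   `"mode"` and `"index"` (the named vector used).  `divide` mode is
#'   lossless: adding `log2(index)` back restores the input exactly.
#' @export
adjust_matrix <- function(expr, index, mode = c("divide", "residual")) {
  mode <- match.arg(mode)
  assert_expr_tbl(expr)
  m <- expr_matrix(expr)
  v <- index_vector(index, colnames(m))
  li <- log2(v)
  if (mode == "divide") {
    adj <- sweep(m, 2, li)
  } else {
    lic <- li - mean(li)
    denom <- sum(lic^2)
    if (denom == 0) abort("residual mode needs a non-constant index.")
    slope <- (m %*% lic) / denom          # per-gene OLS slope on log2 index
    adj <- m - slope %*% rbind(li)
  }
  out <- expr_tibble(adj)
  attr(out, "platform") <- attr(expr, "platform")
  attr(out, "mode") <- mode
  attr(out, "index") <- v
  out
}

#' Re-assess over-expression after index adjustment
#'
#' Re-runs the differential-expression call on the adjusted matrix and
#' reports which originally up-called transcripts remain over-expressed —
#' the transcripts whose up-regulation is not accounted for by leukocyte
#' infiltration — together with the surviving fraction.  Down-calls on
#' adjusted data are returned too but flagged for cautious
#' interpretation: division by the index mechanically deepens the
#' apparent down-regulation of muscle-intrinsic transcripts.
#'
#' @param adj Adjusted log2 fold-change tibble from [adjust_matrix()].
#' @param annotation Cohort annotation (same cohort as the original call).
#' @param de_original [call_differential()] result on the unadjusted
#'   matrix.
#' @param case_groups,method,fc_cut,alpha Passed to [call_differential()]
#'   for the re-assessment (same thresholds re-applied by default).
#' @return An object of class `myo_reassessment`: `de_adjusted` (full
#'   adjusted-call table), `survivors` (originally-up transcripts still
#'   up, with original and adjusted statistics), `n_up_original`,
#'   `n_surviving`, `surviving_fraction`, and `caution_down` (transcripts
#'   newly called down on adjusted data).
#' @export
reassess_overexpression <- function(adj, annotation, de_original,
                                    case_groups = NULL,
                                    method = c("ttest", "moderated"),
                                    fc_cut = 4, alpha = 0.05) {
  method <- match.arg(method)
  de_adj <- call_differential(adj, annotation, case_groups = case_groups,
                              method = method, fc_cut = fc_cut, alpha = alpha)
  up0 <- de_original$transcript_id[de_original$call == "up"]
  if (!all(up0 %in% de_adj$transcript_id)) {
    abort("adjusted matrix does not cover all originally up-called transcripts.")
  }
  adj_up <- de_adj$transcript_id[de_adj$call == "up"]
  surviving <- intersect(up0, adj_up)
  survivors <- de_original |>
    dplyr::filter(.data$transcript_id %in% surviving) |>
    dplyr::select("transcript_id", orig_log2fc = "mean_log2fc",
                  orig_p_adj = "p_adj") |>
    dplyr::left_join(
      de_adj |>
        dplyr::select("transcript_id", adj_log2fc = "mean_log2fc",
                      adj_p_adj = "p_adj"),
      by = "transcript_id"
    )
  structure(
    list(
      de_adjusted = de_adj,
      survivors = survivors,
      n_up_original = length(up0),
      n_surviving = length(surviving),
      surviving_fraction = if (length(up0) > 0) length(surviving) / length(up0) else NA_real_,
      caution_down = de_adj$transcript_id[de_adj$call == "down"]
    ),
    class = "myo_reassessment"
  )
}

#' @export
print.myo_reassessment <- function(x, ...) {
  cat(sprintf(
    "%d of %d originally over-expressed transcripts (%.1f%%) remain over-expressed after index adjustment\n",
    x$n_surviving, x$n_up_original, 100 * x$surviving_fraction
  ))
  invisible(x)
}

#' @rdname reassess_overexpression
#' @param x A `myo_reassessment`.
#' @param ... Unused.
#' @export
glance.myo_reassessment <- function(x, ...) {
  tibble(
    n_up_original = x$n_up_original,
    n_surviving = x$n_surviving,
    surviving_fraction = x$surviving_fraction,
    n_caution_down = length(x$caution_down)
  )
}
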