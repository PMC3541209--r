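# ggplot2 views of the main result types.  These return plot objects and
# never print; all numbers shown come from the tables they are given.

#' Consensus-matrix heatmap
#'
#' Genes are ordered by cluster (then by robustness within cluster) so
#' coherent modules appear as blocks along the diagonal.
#'
#' @param object A `myo_consensus`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.myo_consensus <- function(object, ...) {
  ord <- tidy(object) |>
    dplyr::arrange(.data$cluster, dplyr::desc(.data$robustness)) |>
    dplyr::pull("transcript_id")
  M <- object$consensus[ord, ord]
  df <- tibble(
    a = factor(rep(ord, times = length(ord)), levels = ord),
    b = factor(rep(ord, each = length(ord)), levels = rev(ord)),
    consensus = as.vector(M)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, fill = .data$consensus)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "consensus",
                  title = sprintf("Merged consensus matrix (k = %d)", object$k)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Leukocyte index versus H&E inflammation grade
#'
#' @param index Per-sample index tibble from [leukocyte_index()].
#' @param annotation Cohort annotation with `he_grade`.
#' @return A ggplot object (points jittered horizontally, OLS line).
#' @export
plot_index_grade <- function(index, annotation) {
  df <- dplyr::inner_join(index, annotation, by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$he_grade, .data$log2_index)) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$group),
                         width = 0.08, height = 0, size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "grey30", linewidth = 0.5) +
    ggplot2::labs(x = "H&E inflammation grade (0-4)",
                  y = "log2 leukocyte index", colour = "group") +
    ggplot2::theme_classic()
}

#' Signature-score heatmap across samples
#'
#' @param scores Long score tibble from [score_signatures()].
#' @param annotation Cohort annotation (orders samples by group).
#' @param cap Upper display cap on the log2 score (default 4).
#' @return A ggplot object.
#' @export
plot_signature_heatmap <- function(scores, annotation, cap = 4) {
  ann <- validate_annotation(annotation) |>
    dplyr::arrange(factor(.data$group, c("normal", "nm", "dm", "pm", "ibm")))
  df <- scores |>
    dplyr::mutate(
      sample_id = factor(.data$sample_id, levels = ann$sample_id),
      display = pmin(pmax(.data$score_log2, 0), cap)
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_id, .data$signature,
                                   fill = .data$display)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(colours = c("blue", "cyan", "yellow", "red"),
                                  limits = c(0, cap)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Index recovery against simulated ground truth
#'
#' @param index Per-sample index tibble.
#' @param cohort The `myo_cohort` that produced it.
#' @return A ggplot object of log2 index versus log2 true ratio with the
#'   identity line.
#' @export
plot_index_recovery <- function(index, cohort) {
  df <- dplyr::inner_join(index, cohort$truth$samples, by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(log2(.data$ratio), .data$log2_index,
                                   colour = .data$group)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "log2 true infiltration ratio",
                  y = "log2 leukocyte index", colour = "group") +
    ggplot2::theme_classic()
}
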