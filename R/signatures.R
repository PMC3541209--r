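#' Define gene signatures from eligible consensus clusters
#'
#' A cluster is signature-eligible when it has at least
#' `min_robust_members` robust members (membership robustness at or above
#' the configured cutoff); each eligible cluster yields one signature
#' whose membership is exactly its robust members.  Signatures are named
#' by cluster letter (A, B, ...) unless an annotation map is supplied
#' (e.g. `c("3" = "type1_ifn")`).
#'
#' @param cc A `myo_consensus` result.
#' @param annotations Optional named character vector mapping cluster id
#'   (as character) to a signature name.
#' @param min_members Eligibility threshold; defaults to the value in the
#'   consensus config.
#' @return A tibble `signature`, `cluster`, `transcript_id` (one row per
#'   robust member).
#' @export
define_signatures <- function(cc, annotations = NULL,
                              min_members = cc$config$min_robust_members) {
  stopifnot(inherits(cc, "myo_consensus"))
  eligible <- cc$robust_members[lengths(cc$robust_members) >= min_members]
  if (length(eligible) == 0) {
    abort("no signature-eligible cluster (need >= min_members robust members).")
  }
  cluster_ids <- names(eligible)
  nm <- LETTERS[seq_along(eligible)]
  if (!is.null(annotations)) {
    hit <- cluster_ids %in% names(annotations)
    nm[hit] <- unname(annotations[cluster_ids[hit]])
  }
  purrr::map2_dfr(nm, seq_along(eligible), function(name, i) {
    tibble(
      signature = name,
      cluster = as.integer(cluster_ids[i]),
      transcript_id = eligible[[i]]
    )
  })
}

#' Score one signature across samples
#'
#' A signature's score in a sample is the median of the linear fold
#' changes (versus normal controls) of its member genes; for even member
#' counts the mean of the two central values is used.  Scores for
#' normal-control samples therefore center near 1 (log2 near 0).
#'
#' @param members Character vector of member transcript ids.
#' @param fc Wide log2 fold-change tibble containing all members.
#' @return A tibble `sample_id`, `score_fc`, `score_log2`.
#' @export
score_signature <- function(members, fc) {
  m <- expr_matrix(fc)
  missing <- setdiff(members, rownames(m))
  if (length(missing) > 0) {
    abort(paste0("signature member(s) absent from fold-change matrix: ",
                 paste(missing, collapse = ", ")))
  }
  lin <- 2^m[members, , drop = FALSE]
  score <- apply(lin, 2, median)
  tibble(sample_id = colnames(m), score_fc = unname(score),
         score_log2 = log2(unname(score)))
}

#' Score every signature across samples
#'
#' @param signatures Signature membership tibble from
#'   [define_signatures()] (or [signatures_from_truth()]).
#' @param fc Wide log2 fold-change tibble.
#' @return A long tibble `signature`, `sample_id`, `score_fc`,
#'   `score_log2`.
#' @export
score_signatures <- function(signatures, fc) {
  signatures |>
    dplyr::group_by(.data$signature) |>
    dplyr::group_modify(~ score_signature(.x$transcript_id, fc)) |>
    dplyr::ungroup()
}

#' Designate the per-sample leukocyte infiltration index
#'
#' The index is the score of one designated leukocyte signature: under
#' the invasion model the median fold change of leukocyte-specific genes
#' estimates each sample's leukocyte-fraction ratio relative to normal
#' muscle.  Explicit designation by signature name is the primary path;
#' `"auto"` picks the signature with the most robust members (the largest
#' coherent leukocyte cluster), which requires `signatures`.
#'
#' @param scores Long score tibble from [score_signatures()].
#' @param designation A signature name, or `"auto"`.
#' @param signatures Membership tibble (needed for `"auto"`).
#' @return A tibble `sample_id`, `index`, `log2_index`; the designated
#'   signature name is attached as attribute `"signature"`.
#' @export
leukocyte_index <- function(scores, designation = "auto", signatures = NULL) {
  if (identical(designation, "auto")) {
    if (is.null(signatures)) {
      abort("auto designation needs the signature membership tibble.")
    }
    sizes <- dplyr::count(signatures, .data$signature)
    designation <- sizes$signature[which.max(sizes$n)]
  }
  if (!designation %in% scores$signature) {
    abort(sprintf("designated signature `%s` not present in scores.", designation))
  }
  out <- scores |>
    dplyr::filter(.data$signature == designation) |>
    dplyr::transmute(sample_id = .data$sample_id, index = .data$score_fc,
                     log2_index = .data$score_log2)
  attr(out, "signature") <- designation
  out
}
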