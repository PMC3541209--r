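#' Run the full infiltration-analysis pipeline
#'
#' Sequences the stages end to end: obtain a cohort (simulate, or read
#' expression + annotation from files), compute fold changes versus
#' normal controls, call differential expression, select the most
#' variable up-regulated genes, consensus-cluster them, define and score
#' signatures, designate the leukocyte index, adjust the matrix by the
#' index and re-assess over-expression, then run the association
#' analyses (PC1, H&E concordance when grades are present,
#' signature-index correlations, and the mRNA:miRNA anti-correlation
#' screen when a miRNA matrix is available).  If no transcript is called
#' up-regulated the pipeline stops gracefully after the DE stage.
#'
#' @param config A configuration list, or the path to a YAML file holding
#'   one.  Recognized entries:
#'   \describe{
#'     \item{`seed`}{integer; drives the simulation and the consensus
#'       bootstrap (required when simulating).}
#'     \item{`simulate`}{list of [mixture_config()] arguments (mutually
#'       exclusive with `input`).}
#'     \item{`input`}{list with paths `mrna`, `annotation`, optional
#'       `mirna`.}
#'     \item{`de`}{list: `method` ("ttest"/"moderated"), `fc_cut` (4),
#'       `alpha` (0.05), optional `case_groups` (subtypes forming the
#'       case arm; default all non-normal).}
#'     \item{`consensus`}{list of [consensus_config()] arguments.}
#'     \item{`signature`}{list: `designation` ("auto" or a name),
#'       `annotations` (cluster -> name map).}
#'     \item{`adjust`}{list: `mode` ("divide"/"residual").}
#'     \item{`associations`}{list: `r_cut` for the anti-correlation
#'       screen (-0.5).}
#'   }
#' @param out_dir Optional output directory; when given, every stage
#'   table is written as TSV and the run summary as
#'   `run_summary.json` — identical config and seed give byte-identical
#'   summaries.
#' @return An object of class `myo_run` holding every stage result and a
#'   `summary` list (also serialized as the JSON summary).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  has_sim <- !is.null(config$simulate) || is.null(config$input)
  if (!is.null(config$simulate) && !is.null(config$input)) {
    abort("supply exactly one of `simulate` and `input`.")
  }
  seed <- config$seed %||% config$simulate$seed
  if (has_sim && is.null(seed)) abort("a seed is required when simulating.")
  seed <- as.integer(seed %||% 0L)

  de_cfg <- config$de %||% list()
  de_method <- de_cfg$method %||% "ttest"
  case_groups <- de_cfg$case_groups
  fc_cut <- de_cfg$fc_cut %||% 4
  alpha <- de_cfg$alpha %||% 0.05
  adj_mode <- (config$adjust %||% list())$mode %||% "divide"
  r_cut <- (config$associations %||% list())$r_cut %||% -0.5

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    message(sprintf("[myoinfil] %-12s done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  # -- data ------------------------------------------------------------
  cohort <- NULL
  if (has_sim) {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- sim_args$seed %||% seed
    if (!is.null(sim_args$ratio_ranges)) {
      sim_args$ratio_ranges <- lapply(sim_args$ratio_ranges, as.numeric)
    }
    for (nm in c("group_sizes", "gene_blocks", "mirna_blocks")) {
      if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
    }
    cohort <- stage("simulate", simulate_cohort(do.call(mixture_config, sim_args)))
    mrna <- cohort$mrna; mirna <- cohort$mirna
    annotation <- cohort$annotation
  } else {
    mrna <- stage("read", read_expression_matrix(config$input$mrna, "mrna"))
    annotation <- read_annotation(config$input$annotation)
    mirna <- if (!is.null(config$input$mirna)) {
      read_expression_matrix(config$input$mirna, "mirna")
    }
  }

  # -- fold change + differential expression ---------------------------
  fc <- stage("fold_change", log2_fold_change_vs_normal(mrna, annotation))
  mirna_fc <- if (!is.null(mirna) && ncol(mirna) > 1) {
    log2_fold_change_vs_normal(mirna, annotation)
  }
  de <- stage("de", call_differential(fc, annotation, case_groups = case_groups,
                                      method = de_method,
                                      fc_cut = fc_cut, alpha = alpha))
  de_counts <- list(
    n_tested = nrow(de),
    n_up = sum(de$call == "up"),
    n_down = sum(de$call == "down")
  )

  summary <- list(
    seed = seed,
    stages = c("data", "fold_change", "de"),
    de = de_counts
  )
  run <- list(cohort = cohort, annotation = annotation,
              fc = fc, mirna_fc = mirna_fc, de = de)

  if (de_counts$n_up == 0) {
    summary$stopped_after <- "de"
    run$summary <- summary
    run <- structure(run, class = "myo_run")
    if (!is.null(out_dir)) write_run(run, out_dir)
    return(run)
  }

  # -- clustering, signatures, index -----------------------------------
  cc_args <- config$consensus %||% list()
  cc_args$seed <- cc_args$seed %||% (seed + 1L)
  ccfg <- do.call(consensus_config, cc_args)
  selected <- stage("select",
                    select_top_variable(fc, de, n = ccfg$top_n_variable))
  cc <- stage("consensus", run_consensus(fc, ccfg, genes = selected))
  sig_cfg <- config$signature %||% list()
  annotations <- sig_cfg$annotations
  if (!is.null(annotations)) annotations <- unlist(annotations)
  signatures <- stage("signatures", define_signatures(cc, annotations))
  scores <- score_signatures(signatures, fc)
  index <- leukocyte_index(scores, sig_cfg$designation %||% "auto", signatures)

  # -- adjustment ------------------------------------------------------
  adjusted <- stage("adjust", adjust_matrix(fc, index, mode = adj_mode))
  reassessment <- reassess_overexpression(adjusted, annotation, de,
                                          case_groups = case_groups,
                                          method = de_method,
                                          fc_cut = fc_cut, alpha = alpha)

  # -- associations ----------------------------------------------------
  assoc <- stage("associate", {
    de_ids <- de$transcript_id[de$call != "none"]
    pca <- pc1_analysis(dplyr::filter(fc, .data$transcript_id %in% de_ids), index)
    he <- NULL
    if ("he_grade" %in% names(annotation) &&
        sum(!is.na(annotation$he_grade)) >= 3 &&
        length(unique(stats::na.omit(annotation$he_grade))) > 1) {
      he <- he_concordance(index, annotation)
    }
    sig_cor <- scores |>
      dplyr::group_by(.data$signature) |>
      dplyr::group_modify(function(d, key) {
        v <- index_vector(index, d$sample_id)
        correlate(d$score_log2, log2(v), method = "spearman")
      }) |>
      dplyr::ungroup()
    anti <- if (!is.null(mirna_fc)) {
      anticorrelation_screen(fc, mirna_fc, r_cut = r_cut)
    }
    list(pca = pca, he = he, signature_index_cor = sig_cor, anticorrelation = anti)
  })

  summary$stages <- c(summary$stages, "select", "consensus", "signatures",
                      "adjust", "associate")
  summary$consensus <- list(
    k = cc$k,
    n_clustered = length(cc$gene_ids),
    n_eligible = glance(cc)$n_eligible
  )
  summary$signatures <- purrr::map(
    split(signatures$transcript_id, signatures$signature), length
  )
  summary$index_signature <- attr(index, "signature")
  summary$adjustment <- list(
    mode = adj_mode,
    n_up_original = reassessment$n_up_original,
    n_surviving = reassessment$n_surviving,
    surviving_fraction = reassessment$surviving_fraction
  )
  summary$associations <- list(
    pc1_variance_fraction = assoc$pca$pc1_variance_fraction,
    pc1_index_r2 = assoc$pca$fit$r_squared,
    he_grade_r2 = if (!is.null(assoc$he)) assoc$he$r_squared,
    n_anticorrelated_pairs = if (!is.null(assoc$anticorrelation)) {
      nrow(assoc$anticorrelation)
    }
  )

  run <- c(run, list(
    selected = selected, consensus = cc, signatures = signatures,
    scores = scores, index = index, adjusted = adjusted,
    reassessment = reassessment, associations = assoc
  ))
  run$summary <- summary
  run <- structure(run, class = "myo_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  tables <- list(fold_change = run$fc, de_table = run$de)
  if (!is.null(run$mirna_fc)) tables$mirna_fold_change <- run$mirna_fc
  if (!is.null(run$consensus)) {
    tables$cluster_membership <- tidy(run$consensus)
    tables$consensus_matrix <- expr_tibble(run$consensus$consensus, id = "gene_id")
    tables$signature_members <- run$signatures
    tables$signature_scores <- run$scores
    tables$leukocyte_index <- run$index
    tables$adjusted_matrix <- run$adjusted
    tables$adjustment_survivors <- run$reassessment$survivors
    tables$signature_index_correlation <- run$associations$signature_index_cor
    if (!is.null(run$associations$anticorrelation)) {
      tables$anticorrelation_pairs <- run$associations$anticorrelation
    }
  }
  tables$run_summary <- run$summary
  write_tables(tables, out_dir)
}

#' @export
print.myo_run <- function(x, ...) {
  s <- x$summary
  cat("myoinfil pipeline run\n")
  cat(sprintf("  DE: %d up / %d down of %d tested\n",
              s$de$n_up, s$de$n_down, s$de$n_tested))
  if (!is.null(s$stopped_after)) {
    cat(sprintf("  stopped after stage `%s`\n", s$stopped_after))
    return(invisible(x))
  }
  cat(sprintf("  consensus: k = %d, %d eligible signature cluster(s)\n",
              s$consensus$k, s$consensus$n_eligible))
  cat(sprintf("  index signature: %s\n", s$index_signature))
  cat(sprintf("  surviving over-expression after adjustment: %d/%d (%.1f%%)\n",
              s$adjustment$n_surviving, s$adjustment$n_up_original,
              100 * s$adjustment$surviving_fraction))
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `myo_run`.
#' @param ... Unused.
#' @export
glance.myo_run <- function(x, ...) {
  s <- x$summary
  tibble(
    n_tested = s$de$n_tested,
    n_up = s$de$n_up,
    n_down = s$de$n_down,
    k = s$consensus$k %||% NA_integer_,
    n_signatures = length(s$signatures),
    surviving_fraction = s$adjustment$surviving_fraction %||% NA_real_,
    pc1_variance_fraction = s$associations$pc1_variance_fraction %||% NA_real_,
    he_grade_r2 = s$associations$he_grade_r2 %||% NA_real_
  )
}
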