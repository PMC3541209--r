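#' Expected bulk signal under the invasion model
#'
#' The invasion model is the special case of a linear cell-type mixture in
#' which one compartment (here, leukocytes) changes its proportion between
#' conditions.  A tissue at baseline contains a leukocyte fraction `p0`;
#' in an "invaded" sample that fraction is scaled by the infiltration
#' ratio `r`.  For a transcript expressed at linear level `x_leu` in
#' leukocytes and `x_mus` in muscle:
#'
#' * baseline bulk  = `p0 * x_leu + (1 - p0) * x_mus`
#' * invaded bulk   = `r * p0 * x_leu + (1 - r * p0) * x_mus`
#'
#' and the bulk fold change is their ratio.  A leukocyte-specific
#' transcript (`x_mus = 0`) therefore has fold change exactly `r`: the
#' coherent overexpression of such transcripts reads out the change in
#' leukocyte fraction, which is what the leukocyte index exploits.
#'
#' @param x_leu,x_mus Non-negative linear expression levels in the
#'   leukocyte and muscle compartments (vectorized).
#' @param p0 Baseline leukocyte fraction, in (0, 1).
#' @param r Infiltration ratio; `r * p0` must stay below 1.
#' @return A tibble with columns `baseline`, `invaded`, `fold_change`.
#' @export
#' @examples
#' mixture_expectation(x_leu = 50, x_mus = 0, p0 = 0.05, r = 5)  # FC = 5
mixture_expectation <- function(x_leu, x_mus, p0, r) {
  if (any(p0 <= 0 | p0 >= 1)) abort("`p0` must lie strictly inside (0, 1).")
  if (any(x_leu < 0) || any(x_mus < 0)) abort("compartment levels must be >= 0.")
  if (any(r * p0 >= 1)) {
    abort("impossible composition: `r * p0` must be < 1.")
  }
  baseline <- p0 * x_leu + (1 - p0) * x_mus
  invaded <- r * p0 * x_leu + (1 - r * p0) * x_mus
  if (any(baseline <= 0)) abort("baseline bulk level must be positive.")
  tibble(baseline = baseline, invaded = invaded, fold_change = invaded / baseline)
}

#' Configuration for the synthetic mixture cohort
#'
#' Defaults emulate a 36-biopsy myositis study design: 5 normal controls,
#' 5 necrotizing myopathy (nm), 8 dermatomyositis (dm), 8 polymyositis
#' (pm) and 10 inclusion body myositis (ibm) samples, a 5% baseline
#' leukocyte fraction, and subtype-specific infiltration-ratio ranges
#' rising from ~1 in controls to up to 16 in ibm.  Transcripts come in
#' compartment-labelled blocks: five leukocyte gene classes (an
#' interferon-stimulated module, immunoglobulin-like and MHC-class-I-like
#' modules, and two generic leukocyte modules), muscle-specific genes,
#' housekeeping genes expressed equally in both compartments, and a small
#' muscle-intrinsic ISG block that can be induced in flagged samples
#' independently of infiltration.
#'
#' @param group_sizes Named counts per disease group.
#' @param p0 Baseline leukocyte fraction.
#' @param ratio_ranges Named list of `c(lo, hi)` uniform ranges for the
#'   per-sample infiltration ratio, by group.
#' @param gene_blocks Named mRNA transcript counts per class.
#' @param mirna_blocks Named miRNA transcript counts per class.
#' @param intrinsic_fold Muscle-compartment induction factor applied to
#'   `intrinsic_isg` (and, when `ifn_muscle_frac > 0`, `ifn_like`) genes
#'   in induced samples.
#' @param ifn_muscle_frac Fraction of an `ifn_like` gene's baseline bulk
#'   signal contributed by the muscle compartment (0 = strictly
#'   leukocyte-specific ISGs; > 0 lets muscle-intrinsic interferon
#'   activation raise the ISG signature without infiltration).
#' @param module_sd Log2 SD of the per-sample activity of the four
#'   modulated leukocyte modules (ifn/ig/mhc1/generic II) in disease
#'   samples, modelling subtype-specific infiltrate composition; normal
#'   controls carry the reference resident population (activity 0), and
#'   the first generic leukocyte module is pan-leukocyte and tracks total
#'   infiltration exactly.
#' @param noise_sd Log2 SD of i.i.d. measurement noise.
#' @param grade_sd Log2-scale SD of the noise in the simulated ordinal
#'   H&E inflammation grade.
#' @param n_pfa_dm Number of dm samples flagged with perifascicular
#'   atrophy (drawn at random among dm samples).
#' @param induction_scope `"pfa"` (default): intrinsic induction applies
#'   to PFA-flagged samples; `"all_cases"`: to every non-normal sample;
#'   `"none"`: disabled.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A validated `mixture_config` list.
#' @export
mixture_config <- function(group_sizes = c(normal = 5, nm = 5, dm = 8, pm = 8, ibm = 10),
                           p0 = 0.05,
                           ratio_ranges = list(
                             normal = c(0.8, 1.2), nm = c(1, 2), dm = c(1, 8),
                             pm = c(2, 12), ibm = c(4, 16)
                           ),
                           gene_blocks = c(
                             ifn_like = 40, ig_like = 30, mhc1_like = 30,
                             immune_generic_1 = 60, immune_generic_2 = 30,
                             muscle_specific = 60, housekeeping = 140,
                             intrinsic_isg = 10
                           ),
                           mirna_blocks = c(leukocyte_mirna = 8, muscle_mirna = 8),
                           intrinsic_fold = 8,
                           ifn_muscle_frac = 0,
                           module_sd = 0.5,
                           noise_sd = 0.3,
                           grade_sd = 0.4,
                           n_pfa_dm = 4,
                           induction_scope = c("pfa", "all_cases", "none"),
                           seed = 1L) {
  induction_scope <- match.arg(induction_scope)
  cfg <- list(
    group_sizes = group_sizes, p0 = p0, ratio_ranges = ratio_ranges,
    gene_blocks = gene_blocks, mirna_blocks = mirna_blocks,
    intrinsic_fold = intrinsic_fold, ifn_muscle_frac = ifn_muscle_frac,
    module_sd = module_sd, noise_sd = noise_sd, grade_sd = grade_sd,
    n_pfa_dm = n_pfa_dm, induction_scope = induction_scope,
    seed = as.integer(seed)
  )
  validate_mixture_config(cfg)
}

validate_mixture_config <- function(cfg) {
  groups <- names(cfg$group_sizes)
  if (is.null(groups) || !all(groups %in% c("normal", "nm", "dm", "pm", "ibm"))) {
    abort("group_sizes must be named with normal/nm/dm/pm/ibm.")
  }
  if (any(cfg$group_sizes < 0)) abort("group sizes must be >= 0.")
  if (cfg$p0 <= 0 || cfg$p0 >= 1) abort("p0 must lie in (0, 1).")
  for (g in groups[cfg$group_sizes > 0]) {
    rng <- cfg$ratio_ranges[[g]]
    if (is.null(rng) || length(rng) != 2 || rng[1] > rng[2] || rng[1] <= 0) {
      abort(sprintf("ratio_ranges$%s must be a valid c(lo, hi) with lo > 0.", g))
    }
    if (max(rng) * cfg$p0 >= 1) {
      abort(sprintf("ratio_ranges$%s allows r * p0 >= 1 (impossible mixture).", g))
    }
  }
  if (any(cfg$gene_blocks < 0) || any(cfg$mirna_blocks < 0)) {
    abort("block counts must be >= 0.")
  }
  if (cfg$noise_sd < 0 || cfg$module_sd < 0 || cfg$grade_sd < 0) {
    abort("noise SDs must be >= 0.")
  }
  if (cfg$intrinsic_fold <= 0) abort("intrinsic_fold must be positive.")
  if (cfg$ifn_muscle_frac < 0 || cfg$ifn_muscle_frac >= 1) {
    abort("ifn_muscle_frac must lie in [0, 1).")
  }
  if (is.na(cfg$seed)) abort("a seed is required to simulate.")
  structure(cfg, class = "mixture_config")
}

# Gene classes whose leukocyte-compartment activity varies between samples
# (distinct leukocyte subpopulations / pathway programs); immune_generic_1
# is pan-leukocyte and left unmodulated so it reads out total infiltration.
MODULATED_CLASSES <- c("ifn_like", "ig_like", "mhc1_like", "immune_generic_2")
LEUKOCYTE_CLASSES <- c(MODULATED_CLASSES, "immune_generic_1")

#' Simulate a mixture cohort with known infiltration ground truth
#'
#' Draws per-sample infiltration ratios uniformly within each group's
#' range, builds every transcript's bulk linear signal from
#' [mixture_expectation()] (with per-sample leukocyte-module activity for
#' the modulated classes and muscle-compartment induction of intrinsic
#' ISGs in induced samples), takes log2, and adds i.i.d. Gaussian noise in
#' log2 space.  The ordinal H&E grade is emitted as
#' `clip(round(log2(r) + N(0, grade_sd)), 0, 4)`.  All randomness derives
#' from `config$seed`, so identical configs give bitwise-identical cohorts.
#'
#' @param config A [mixture_config()].
#' @return A list of class `myo_cohort` with elements `mrna` and `mirna`
#'   (wide log2 expression tibbles), `annotation` (sample table with
#'   group, he_grade, pfa), and `truth` (list with per-sample `samples`
#'   tibble carrying the true ratio and leukocyte fraction, per-transcript
#'   `transcripts` tibble carrying class labels and compartment profiles,
#'   and the `config`).
#' @export
simulate_cohort <- function(config = mixture_config()) {
  cfg <- validate_mixture_config(unclass(config))
  withr::with_seed(cfg$seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg) {
  gs <- cfg$group_sizes[cfg$group_sizes > 0]
  groups <- rep(names(gs), gs)
  n <- length(groups)
  samples <- tibble(
    sample_id = sprintf("S%02d", seq_len(n)),
    group = groups
  )
  lo <- vapply(cfg$ratio_ranges[groups], `[[`, numeric(1), 1)
  hi <- vapply(cfg$ratio_ranges[groups], `[[`, numeric(1), 2)
  samples$ratio <- runif(n, lo, hi)
  samples$leukocyte_fraction <- samples$ratio * cfg$p0

  dm_idx <- which(samples$group == "dm")
  pfa_idx <- if (length(dm_idx) > 0 && cfg$n_pfa_dm > 0) {
    sample(dm_idx, min(cfg$n_pfa_dm, length(dm_idx)))
  } else integer(0)
  samples$pfa <- seq_len(n) %in% pfa_idx
  samples$induced <- switch(cfg$induction_scope,
    pfa = samples$pfa,
    all_cases = samples$group != "normal",
    none = rep(FALSE, n)
  )

  transcripts <- make_transcripts(cfg)
  mrna_tr <- transcripts[transcripts$platform == "mrna", ]
  mirna_tr <- transcripts[transcripts$platform == "mirna", ]

  # per-sample log2 activity of the modulated leukocyte modules; drawn for
  # disease samples only — the small resident leukocyte population of
  # normal muscle is taken as the reference composition, so subtype-driven
  # infiltrate programs (B-cell rich vs cytotoxic etc.) vary across cases
  # without perturbing the normal-control reference
  act <- matrix(0, nrow = length(MODULATED_CLASSES), ncol = n,
                dimnames = list(MODULATED_CLASSES, samples$sample_id))
  case <- samples$group != "normal"
  if (cfg$module_sd > 0 && any(case)) {
    act[, case] <- rnorm(length(MODULATED_CLASSES) * sum(case), 0, cfg$module_sd)
  }

  mrna <- simulate_platform(mrna_tr, samples, act, cfg)
  mirna <- simulate_platform(mirna_tr, samples, act, cfg)

  grade_noise <- rnorm(n, 0, cfg$grade_sd)
  he_grade <- pmin(4, pmax(0, round(log2(samples$ratio) + grade_noise)))

  annotation <- tibble(
    sample_id = samples$sample_id,
    group = samples$group,
    he_grade = as.integer(he_grade),
    pfa = samples$pfa,
    muscle_site = NA_character_
  )

  structure(
    list(
      mrna = mrna, mirna = mirna, annotation = annotation,
      truth = list(samples = samples, transcripts = transcripts,
                   config = structure(cfg, class = "mixture_config"))
    ),
    class = "myo_cohort"
  )
}

make_transcripts <- function(cfg) {
  blocks <- dplyr::bind_rows(
    tibble(class = rep(names(cfg$gene_blocks), cfg$gene_blocks), platform = "mrna"),
    tibble(class = rep(names(cfg$mirna_blocks), cfg$mirna_blocks), platform = "mirna")
  )
  prefix <- c(
    ifn_like = "ISG", ig_like = "IG", mhc1_like = "MHC1",
    immune_generic_1 = "LEU1", immune_generic_2 = "LEU2",
    muscle_specific = "MUS", housekeeping = "HK", intrinsic_isg = "INT",
    leukocyte_mirna = "MIR-LEU", muscle_mirna = "MIR-MUS"
  )
  blocks <- blocks |>
    dplyr::group_by(.data$class) |>
    dplyr::mutate(transcript_id = sprintf("%s_%03d", prefix[.data$class[1]],
                                          dplyr::row_number())) |>
    dplyr::ungroup()

  base <- 2^runif(nrow(blocks), 4, 9)  # linear abundance in the expressing compartment
  leu_expressed <- blocks$class %in% c(LEUKOCYTE_CLASSES, "leukocyte_mirna")
  mus_expressed <- blocks$class %in% c("muscle_specific", "intrinsic_isg", "muscle_mirna")
  blocks$x_leukocyte <- ifelse(leu_expressed | blocks$class == "housekeeping", base, 0)
  blocks$x_muscle <- ifelse(mus_expressed | blocks$class == "housekeeping", base, 0)

  # optional muscle-compartment floor for ISGs: muscle contributes
  # ifn_muscle_frac of the baseline bulk signal of an ifn_like gene
  if (cfg$ifn_muscle_frac > 0) {
    isg <- blocks$class == "ifn_like"
    phi <- cfg$ifn_muscle_frac
    blocks$x_muscle[isg] <-
      phi * cfg$p0 * blocks$x_leukocyte[isg] / ((1 - cfg$p0) * (1 - phi))
  }
  blocks[, c("transcript_id", "platform", "class", "x_leukocyte", "x_muscle")]
}

simulate_platform <- function(transcripts, samples, act, cfg) {
  g <- nrow(transcripts)
  n <- nrow(samples)
  if (g == 0) {
    return(structure(tibble(transcript_id = character(0)), platform = "empty"))
  }
  # log2 module activity per transcript x sample (0 for unmodulated classes)
  amod <- matrix(0, g, n)
  mod_rows <- transcripts$class %in% MODULATED_CLASSES
  if (any(mod_rows)) {
    amod[mod_rows, ] <- act[transcripts$class[mod_rows], , drop = FALSE]
  }
  induced_cls <- transcripts$class %in% c("intrinsic_isg", "ifn_like")
  fold <- matrix(1, g, n)
  fold[induced_cls, samples$induced] <- cfg$intrinsic_fold

  p <- matrix(rep(samples$leukocyte_fraction, each = g), g, n)
  bulk <- p * transcripts$x_leukocyte * 2^amod +
    (1 - p) * transcripts$x_muscle * fold
  if (any(bulk <= 0)) abort("degenerate transcript with zero bulk signal.")
  vals <- log2(bulk)
  if (cfg$noise_sd > 0) vals <- vals + rnorm(g * n, 0, cfg$noise_sd)
  dimnames(vals) <- list(transcripts$transcript_id, samples$sample_id)
  out <- expr_tibble(vals)
  attr(out, "platform") <- if (transcripts$platform[1] == "mrna") "mrna" else "mirna"
  out
}

#' Truth-defined signature membership for a simulated cohort
#'
#' Bypasses clustering and declares one signature per leukocyte gene
#' class, using the simulator's class labels as membership.  Useful for
#' testing scoring and index exactness independently of the clustering
#' stage (with zero noise all leukocyte profiles are perfectly correlated
#' and a data-driven partition of them is arbitrary).
#'
#' @param cohort A `myo_cohort`.
#' @param classes Gene classes to expose as signatures (default: the five
#'   leukocyte classes).
#' @return A tibble with columns `signature`, `cluster` (NA), and
#'   `transcript_id`, as produced by [define_signatures()].
#' @export
signatures_from_truth <- function(cohort, classes = LEUKOCYTE_CLASSES) {
  tr <- cohort$truth$transcripts
  out <- tr |>
    dplyr::filter(.data$platform == "mrna", .data$class %in% classes) |>
    dplyr::transmute(signature = .data$class, cluster = NA_integer_,
                     transcript_id = .data$transcript_id)
  if (nrow(out) == 0) abort("no transcripts in the requested classes.")
  out
}

#' Map consensus clusters to simulator gene classes
#'
#' Labels each cluster of a consensus result with the majority true class
#' of its robust members — the evaluation-side bridge between data-driven
#' clusters and planted modules.
#'
#' @param cc A `myo_consensus` result.
#' @param cohort The `myo_cohort` the clustering was run on.
#' @return A tibble with columns `cluster`, `class` (majority truth
#'   class), and `purity` (fraction of robust members from that class).
#' @export
cluster_class_map <- function(cc, cohort) {
  stopifnot(inherits(cc, "myo_consensus"))
  truth <- cohort$truth$transcripts[, c("transcript_id", "class")]
  tidy(cc) |>
    dplyr::filter(.data$robust) |>
    dplyr::left_join(truth, by = "transcript_id") |>
    dplyr::count(.data$cluster, .data$class) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      class = .data$class[which.max(.data$n)],
      purity = max(.data$n) / sum(.data$n),
      .groups = "drop"
    )
}
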