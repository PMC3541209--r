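# Shared fixtures, all generated in code.  Heavy objects (full pipeline
# runs) are computed once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

quiet_pipeline <- function(config) {
  suppressMessages(run_pipeline(config))
}

# The default study-design cohort run end to end.
default_run <- function() {
  cached("default_run", quiet_pipeline(list(seed = 101)))
}

# Zero measurement noise, zero module-activity variation, normal controls
# pinned at exactly baseline composition: the configuration under which
# the invasion model's fold-change identities hold exactly.
noiseless_config <- function(seed = 105, ...) {
  mixture_config(
    noise_sd = 0, module_sd = 0,
    ratio_ranges = list(
      normal = c(1, 1), nm = c(1, 2), dm = c(1, 8),
      pm = c(2, 12), ibm = c(4, 16)
    ),
    seed = seed, ...
  )
}

# All infiltration ratios pinned at 1: a null cohort with measurement
# noise and module-activity variation but no group signal.
null_config <- function(seed = 106) {
  mixture_config(
    ratio_ranges = list(
      normal = c(1, 1), nm = c(1, 1), dm = c(1, 1),
      pm = c(1, 1), ibm = c(1, 1)
    ),
    intrinsic_fold = 1, seed = seed
  )
}

leukocyte_classes <- c("ifn_like", "ig_like", "mhc1_like",
                       "immune_generic_1", "immune_generic_2")

truth_classes <- function(cohort) {
  tr <- cohort$truth$transcripts
  stats::setNames(tr$class, tr$transcript_id)
}

# Planted-module fold-change matrix built directly: `per` genes around
# each of `nblock` module profiles, plus iid log2 noise.
make_block_fc <- function(nblock, per, n_samples = 20, noise = 0.3,
                          seed = 11) {
  withr::with_seed(seed, {
    profiles <- matrix(stats::rnorm(nblock * n_samples, sd = 1.5),
                       nblock, n_samples)
    m <- profiles[rep(seq_len(nblock), each = per), , drop = FALSE] +
      matrix(stats::rnorm(nblock * per * n_samples, sd = noise),
             nblock * per, n_samples)
    rownames(m) <- sprintf("B%d_G%02d", rep(seq_len(nblock), each = per),
                           rep(seq_len(per), nblock))
    colnames(m) <- sprintf("S%02d", seq_len(n_samples))
    out <- tibble::as_tibble(as.data.frame(m))
    dplyr::bind_cols(tibble::tibble(transcript_id = rownames(m)), out)
  })
}

block_labels <- function(fc) sub("_G\\d+$", "", fc$transcript_id)
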