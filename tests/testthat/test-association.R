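test_that("correlations match their definitions, including mid-rank ties", {
  expect_equal(correlate(1:6, c(2, 5, 7, 8, 11, 30), "spearman")$r, 1)
  expect_equal(correlate(1:5, -(1:5), "pearson")$r, -1)

  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 4)
  got <- correlate(x, y, "spearman")
  # oracle: mid-ranks then the Pearson product-moment formula
  rx <- rank(x); ry <- rank(y)
  r_manual <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(got$r, r_manual)

  expect_error(correlate(rep(1, 5), 1:5), "constant")
  expect_error(correlate(1:2, 1:2), ">= 3")
})

test_that("linear fits agree with the closed-form normal equations", {
  x <- c(0.5, 1.2, 2.0, 3.1, 4.4)
  y <- c(1.1, 2.0, 2.6, 4.2, 5.0)
  fit <- linear_fit(x, y)
  slope_manual <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept_manual <- mean(y) - slope_manual * mean(x)
  resid <- y - intercept_manual - slope_manual * x
  r2_manual <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  expect_equal(fit$slope, slope_manual)
  expect_equal(fit$intercept, intercept_manual)
  expect_equal(fit$r_squared, r2_manual)

  ident <- linear_fit(x, x)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)
  expect_equal(ident$r_squared, 1)

  flat <- linear_fit(x, rep(2, 5))
  expect_equal(flat$r_squared, 0)

  ex <- linear_fit(c(x, 10), c(y, -50), ids = c(letters[1:5], "out"),
                   exclude = "out")
  expect_equal(ex$slope, fit$slope)
  expect_identical(ex$excluded[[1]], "out")
  expect_error(linear_fit(rep(1, 4), 1:4), "degenerate predictor")
})

test_that("PC1 variance fraction behaves on constructed spectra", {
  # rank-1 matrix: a single direction carries all the variance
  u <- c(1, 2, 3); v <- c(0.5, -1, 2, 1.5)
  m1 <- u %*% t(v)
  rownames(m1) <- paste0("g", 1:3); colnames(m1) <- paste0("s", 1:4)
  idx <- stats::setNames(rep(1, 4), colnames(m1))
  p1 <- pc1_analysis(myoinfil:::expr_tibble(m1), idx)
  expect_equal(p1$pc1_variance_fraction, 1)

  # two orthogonal equal-variance directions split the spectrum evenly
  m2 <- rbind(g1 = c(1, -1, 1, -1), g2 = c(1, 1, -1, -1))
  colnames(m2) <- paste0("s", 1:4)
  p2 <- pc1_analysis(myoinfil:::expr_tibble(m2), idx)
  expect_equal(p2$pc1_variance_fraction, 0.5)
})

test_that("infiltration dominates the principal component of the DE genes", {
  run <- default_run()
  pca <- run$associations$pca
  expect_gte(pca$pc1_variance_fraction, 0.6)
  expect_gte(pca$fit$r_squared, 0.85)
})

test_that("H&E concordance is high for real grades and gone after permutation", {
  run <- default_run()
  he <- run$associations$he
  expect_gte(he$r_squared, 0.7)

  ann_perm <- run$annotation
  ann_perm$he_grade <- withr::with_seed(8, sample(ann_perm$he_grade))
  he_perm <- he_concordance(run$index, ann_perm)
  expect_lt(he_perm$r_squared, 0.2)

  # constructed identity: grades equal to the log2 index
  idx <- tibble::tibble(sample_id = paste0("x", 1:5), index = 2^(0:4))
  ann <- tibble::tibble(sample_id = paste0("x", 1:5), group = "pm",
                        he_grade = 0:4)
  fit <- he_concordance(idx, ann)
  expect_equal(fit$slope, 1)
  expect_equal(fit$r_squared, 1)
  expect_error(he_concordance(idx, dplyr::mutate(ann, he_grade = 2L)), "equal")
})

test_that("the anti-correlation screen filters by sign and adjusts p-values", {
  run <- default_run()
  anti <- run$associations$anticorrelation
  expect_true(all(anti$r <= -0.5))
  expect_true(all(anti$p_adj >= anti$p))
  # leukocyte mRNA x muscle miRNA pairs are the expected strong hits
  expect_true(any(grepl("MIR-MUS", anti$mirna_id)))
  mus_mrna_hits <- anti[grepl("^MUS_", anti$mrna_id), ]
  expect_true(all(grepl("MIR-LEU", mus_mrna_hits$mirna_id)))

  # a pair equal to itself correlates at +1 and is excluded by the sign filter
  self <- anticorrelation_screen(run$fc[1:5, ], run$fc[1:5, ], r_cut = -0.5)
  expect_false(any(self$mrna_id == self$mirna_id))
  none <- anticorrelation_screen(run$fc[1:5, ], run$mirna_fc, r_cut = -1)
  expect_equal(nrow(none), 0)
})

test_that("excluding intrinsically induced samples sharpens the IFN-index fit", {
  run <- cached("fig4_run", quiet_pipeline(list(
    seed = 103,
    simulate = list(
      ratio_ranges = list(normal = c(0.8, 1.2), nm = c(1, 2), dm = c(1, 2),
                          pm = c(2, 12), ibm = c(4, 16)),
      n_pfa_dm = 8, ifn_muscle_frac = 0.3
    ),
    de = list(case_groups = c("pm", "ibm"))
  )))
  map <- cluster_class_map(run$consensus, run$cohort)
  sig_of <- function(class) {
    cl <- map$cluster[map$class == class]
    unique(run$signatures$signature[run$signatures$cluster == cl])
  }
  idx <- leukocyte_index(run$scores, sig_of("immune_generic_1"))
  sc <- run$scores[run$scores$signature == sig_of("ifn_like"), ]
  d <- dplyr::inner_join(sc, idx, by = "sample_id") |>
    dplyr::inner_join(run$annotation, by = "sample_id")
  fit_all <- linear_fit(d$log2_index, d$score_log2, ids = d$sample_id)
  fit_ex <- linear_fit(d$log2_index, d$score_log2, ids = d$sample_id,
                       exclude = d$sample_id[d$pfa])
  expect_gt(fit_ex$r_squared, fit_all$r_squared)
})
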