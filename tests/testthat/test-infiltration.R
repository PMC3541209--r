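test_that("adjustment by a unit index is the identity and division is lossless", {
  run <- default_run()
  fc <- run$fc
  ones <- stats::setNames(rep(1, length(myoinfil:::sample_ids(fc))),
                          myoinfil:::sample_ids(fc))
  adj <- adjust_matrix(fc, ones)
  expect_equal(myoinfil:::expr_matrix(adj), myoinfil:::expr_matrix(fc))

  adj2 <- adjust_matrix(fc, run$index)
  v <- attr(adj2, "index")
  restored <- sweep(myoinfil:::expr_matrix(adj2), 2, log2(v), `+`)
  expect_equal(restored, myoinfil:::expr_matrix(fc))

  bad <- ones; bad[1] <- -2
  expect_error(adjust_matrix(fc, bad), "positive")
})

test_that("dividing by the true ratio nulls leukocyte-specific genes exactly", {
  co <- simulate_cohort(noiseless_config())
  fc <- log2_fold_change_vs_normal(co$mrna, co$annotation)
  truth <- co$truth$samples
  idx <- tibble::tibble(sample_id = truth$sample_id, index = truth$ratio)
  adj <- adjust_matrix(fc, idx)
  m <- myoinfil:::expr_matrix(adj)
  cls <- truth_classes(co)
  leu <- names(cls)[cls %in% leukocyte_classes]
  expect_equal(max(abs(m[leu, ])), 0, tolerance = 1e-10)
  # muscle-specific genes shift further down by log2(index)
  mus <- names(cls)[cls == "muscle_specific"]
  fc_m <- myoinfil:::expr_matrix(fc)
  cases <- truth$sample_id[truth$ratio > 1]
  expect_true(all(m[mus, cases] < fc_m[mus, cases]))
})

test_that("muscle-intrinsic induction is untouched by adjustment at r = 1", {
  cfg <- mixture_config(
    noise_sd = 0, module_sd = 0,
    ratio_ranges = list(normal = c(1, 1), nm = c(1, 1), dm = c(1, 1),
                        pm = c(1, 1), ibm = c(1, 1)),
    induction_scope = "all_cases", intrinsic_fold = 8, seed = 7
  )
  co <- simulate_cohort(cfg)
  fc <- log2_fold_change_vs_normal(co$mrna, co$annotation)
  idx <- tibble::tibble(sample_id = co$truth$samples$sample_id,
                        index = co$truth$samples$ratio)
  adj <- adjust_matrix(fc, idx)
  cls <- truth_classes(co)
  intr <- names(cls)[cls == "intrinsic_isg"]
  cases <- co$annotation$sample_id[co$annotation$group != "normal"]
  m <- 2^myoinfil:::expr_matrix(adj)
  expect_equal(unname(m[intr, cases]),
               matrix(8, length(intr), length(cases)), tolerance = 1e-10)
})

test_that("residual mode removes each gene's linear index dependence", {
  withr::local_seed(3)
  li <- runif(12, 0, 3)
  m <- rbind(
    dep = 1 + 2 * li + rnorm(12, 0, 0.01),
    indep = rnorm(12)
  )
  colnames(m) <- sprintf("s%02d", 1:12)
  idx <- stats::setNames(2^li, colnames(m))
  adj <- adjust_matrix(myoinfil:::expr_tibble(m), idx, mode = "residual")
  a <- myoinfil:::expr_matrix(adj)
  expect_lt(abs(cor(a["dep", ], li)), 0.15)
  # intercept + residual keeps the gene's own level
  expect_equal(mean(a["dep", ]) + 2 * mean(li), mean(m["dep", ]), tolerance = 0.05)
  expect_error(
    adjust_matrix(myoinfil:::expr_tibble(m),
                  stats::setNames(rep(2, 12), colnames(m)), mode = "residual"),
    "non-constant"
  )
})

test_that("re-assessment with a unit index preserves the original up set", {
  run <- default_run()
  ones <- stats::setNames(rep(1, length(myoinfil:::sample_ids(run$fc))),
                          myoinfil:::sample_ids(run$fc))
  adj <- adjust_matrix(run$fc, ones)
  re <- reassess_overexpression(adj, run$annotation, run$de)
  up0 <- run$de$transcript_id[run$de$call == "up"]
  expect_setequal(re$survivors$transcript_id, up0)
  expect_equal(re$surviving_fraction, 1)
})

test_that("pure-invasion over-expression is almost entirely explained away", {
  run <- default_run()  # default cohort: induction only in 4 PFA-DM samples
  expect_lte(run$reassessment$surviving_fraction, 0.1)
  g <- glance(run$reassessment)
  expect_equal(g$n_up_original, sum(run$de$call == "up"))
  # index division mechanically depresses tissue-resident transcripts;
  # those down-calls are flagged for caution rather than silently reported
  cls <- truth_classes(run$cohort)
  down_classes <- unique(cls[run$reassessment$caution_down])
  expect_true("muscle_specific" %in% down_classes)
  expect_true(all(down_classes %in%
                    c("muscle_specific", "housekeeping", "intrinsic_isg")))
})

test_that("recomputing the index on the adjusted matrix returns to unity", {
  run <- default_run()
  adj_scores <- score_signatures(run$signatures, run$adjusted)
  idx2 <- leukocyte_index(adj_scores, attr(run$index, "signature"))
  expect_lte(max(abs(idx2$log2_index)), 0.1)
})

test_that("intrinsically dysregulated genes survive adjustment and are recovered", {
  run <- cached("intrinsic_run", quiet_pipeline(list(
    seed = 102,
    simulate = list(induction_scope = "all_cases", intrinsic_fold = 64)
  )))
  frac <- run$reassessment$surviving_fraction
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.10)
  cls <- truth_classes(run$cohort)
  surv_cls <- cls[run$reassessment$survivors$transcript_id]
  expect_gte(mean(surv_cls == "intrinsic_isg"), 0.9)
})
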