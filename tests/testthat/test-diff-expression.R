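test_that("two-group t-test matches the pooled-variance formula", {
  expect_equal(two_group_ttest(c(1, 2, 3), c(1, 2, 3)),
               tibble::tibble(t = 0, df = 4, p = 1))

  x <- c(4, 5, 6); y <- c(1, 2, 3)
  got <- two_group_ttest(x, y)
  # independent recomputation from first principles
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  t_manual <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(got$t, t_manual)
  expect_equal(got$df, 4)
  expect_equal(got$p, 2 * pt(-abs(t_manual), 4))
  expect_equal(got$t, 3.674, tolerance = 1e-3)
  expect_equal(got$p, 0.0213, tolerance = 1e-2)

  expect_error(two_group_ttest(c(0, 0), c(1, 1)), "degenerate variance")
  expect_error(two_group_ttest(1, c(1, 2)), ">= 2")
})

test_that("moderated t reduces to the ordinary t at d0 = 0 and to the prior at d0 = Inf", {
  withr::local_seed(7)
  n1 <- 6; n2 <- 4
  gmat <- matrix(rnorm(20 * (n1 + n2)), nrow = 20)
  delta <- rowMeans(gmat[, 1:n1]) - rowMeans(gmat[, n1 + 1:n2])
  v1 <- apply(gmat[, 1:n1], 1, var); v2 <- apply(gmat[, n1 + 1:n2], 1, var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)

  plain <- vapply(seq_len(20), function(g) {
    two_group_ttest(gmat[g, 1:n1], gmat[g, n1 + 1:n2])$t
  }, numeric(1))
  mod0 <- moderated_ttest(delta, s2, n1, n2, d0 = 0, s0_sq = 1)
  expect_equal(mod0$t, plain, tolerance = 1e-10)
  expect_equal(mod0$df, rep(n1 + n2 - 2, 20))

  modInf <- moderated_ttest(delta, s2, n1, n2, d0 = Inf, s0_sq = 2)
  expect_equal(modInf$s2_post, rep(2, 20))
  expect_equal(modInf$t, delta / sqrt(2 * (1 / n1 + 1 / n2)))
})

test_that("posterior variances follow the shrinkage formula by hand", {
  s2 <- c(0.5, 1, 2, 4, 10)
  d <- 8; d0 <- 4; s0 <- 1
  mod <- moderated_ttest(rep(1, 5), s2, n1 = 5, n2 = 5, d0 = d0, s0_sq = s0)
  expect_equal(mod$s2_post, (d0 * s0 + d * s2) / (d0 + d))
  expect_equal(mod$df, rep(d0 + d, 5))
})

test_that("the method-of-moments variance prior agrees with limma", {
  withr::local_seed(13)
  d <- 10
  s2 <- 1.4 * rchisq(300, df = d) / d * exp(rnorm(300, 0, 0.4))
  est <- myoinfil:::fit_variance_prior(s2, d)
  ref <- limma::fitFDist(s2, df1 = d)
  expect_equal(est$s0_sq, ref$scale, tolerance = 1e-6)
  expect_equal(est$d0, ref$df2, tolerance = 1e-6)
  sq <- limma::squeezeVar(s2, df = d)
  mod <- moderated_ttest(rep(0, 300), s2, n1 = 6, n2 = 6)
  expect_equal(mod$s2_post, sq$var.post, tolerance = 1e-6)
})

test_that("BH adjustment equals the brute-force step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # independent oracle: adj(i) = min_{j >= i} p_(j) * m / j, clipped at 1
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p)
    adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
    out <- numeric(m); out[o] <- adj
    out
  }
  withr::local_seed(31)
  for (len in c(1, 2, 3, 5, 8, 12)) {
    for (rep in 1:20) {
      p <- round(runif(len), 3)
      expect_equal(bh_adjust(p), bh_oracle(p))
    }
  }
})

test_that("hypergeometric p equals exhaustive enumeration over draws", {
  # universe 10, category 4, selected 5 with overlap 4 -> 6/252
  uni <- letters[1:10]; cat4 <- letters[1:4]; sel <- letters[1:5]
  got <- hypergeometric_enrichment(sel, cat4, uni)
  expect_equal(got$overlap, 4)
  expect_equal(got$p, 6 / 252)

  # full enumeration oracle for small universes
  enum_p <- function(n_sel, category, universe, k_obs) {
    draws <- utils::combn(universe, n_sel)
    mean(apply(draws, 2, function(d) length(intersect(d, category)) >= k_obs))
  }
  withr::local_seed(17)
  for (rep in 1:10) {
    N <- sample(6:15, 1)
    universe <- sample(letters, N)
    category <- sample(universe, sample(1:(N - 1), 1))
    selected <- sample(universe, sample(1:(N - 1), 1))
    got <- hypergeometric_enrichment(selected, category, universe)
    expect_equal(
      got$p, enum_p(length(selected), category, universe, got$overlap)
    )
  }

  expect_equal(hypergeometric_enrichment(character(0), cat4, uni)$p, 1)
  expect_equal(hypergeometric_enrichment(sel, uni, uni)$p, 1)
  expect_error(hypergeometric_enrichment(c("zz"), cat4, uni), "subset")
})

test_that("differential calls apply both the fold-change and FDR thresholds", {
  # two tight genes, one over 4-fold and one just under
  withr::local_seed(23)
  n <- 6
  vals <- rbind(
    big   = c(rnorm(n, 0, 0.05), rnorm(n, log2(5), 0.05)),
    small = c(rnorm(n, 0, 0.05), rnorm(n, log2(3.9), 0.05)),
    flat  = rnorm(2 * n, 0, 0.05)
  )
  colnames(vals) <- sprintf("s%02d", 1:(2 * n))
  ann <- tibble::tibble(sample_id = colnames(vals),
                        group = rep(c("normal", "pm"), each = n))
  fc <- log2_fold_change_vs_normal(myoinfil:::expr_tibble(vals), ann)
  de <- call_differential(fc, ann)
  expect_identical(de$call[de$transcript_id == "big"], "up")
  expect_identical(de$call[de$transcript_id == "small"], "none")
  expect_lt(de$p_adj[de$transcript_id == "small"], 0.05)  # significant but under FC cut
  expect_identical(de$call[de$transcript_id == "flat"], "none")
  expect_equal(de$fc, 2^de$mean_log2fc)
})

test_that("simulated truth is recovered: leukocyte genes up, others not", {
  run <- default_run()
  cls <- truth_classes(run$cohort)
  de <- run$de
  up <- de$transcript_id[de$call == "up"]
  leu <- names(cls)[cls %in% leukocyte_classes]
  expect_gt(length(intersect(up, leu)) / length(leu), 0.9)
  expect_length(intersect(up, names(cls)[cls %in% c("muscle_specific", "housekeeping")]), 0)
})

test_that("moderated and ordinary calls agree on strong effects", {
  run <- default_run()
  de_t <- run$de
  de_m <- call_differential(run$fc, run$annotation, method = "moderated")
  strong <- de_t$transcript_id[de_t$fc > 8 & de_t$p_adj < 1e-4]
  expect_true(all(de_m$call[de_m$transcript_id %in% strong] == "up"))
})
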