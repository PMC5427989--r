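# QC filter and longitudinal-stability identification.

test_that("zero-fraction filter excludes at >= threshold and is idempotent", {
  m <- matrix(1, 3, 100)
  m[1, 1:20] <- 0                 # exactly 20% zeros -> excluded
  m[2, 1:19] <- 0                 # 19% zeros -> retained
  rownames(m) <- c("chr1_0", "chr1_250", "chr1_500")
  f <- zero_fraction_filter(m, max_zero_fraction = 0.20)
  expect_identical(rownames(f$matrix), c("chr1_250", "chr1_500"))
  expect_equal(f$report$n_removed, 1)
  expect_equal(f$report$retained_pct, 200 / 3)
  # idempotent
  f2 <- zero_fraction_filter(f$matrix, max_zero_fraction = 0.20)
  expect_identical(f2$matrix, f$matrix)
  # all-positive matrix untouched
  g <- zero_fraction_filter(matrix(runif(50) + 1, 5, 10))
  expect_equal(g$report$retained_pct, 100)
  expect_error(zero_fraction_filter(matrix(0, 0, 0)), "empty")
})

test_that("retained fraction under binomial zero inflation matches the tail oracle", {
  sim <- simulate_cohort(sim_config(n_mz_pairs = 100, n_dz_pairs = 0,
                                    n_singletons = 0, n_bins = 8000,
                                    zero_inflation = 0.25,
                                    causal_bin_effects = NULL, seed = 17))
  f <- zero_fraction_filter(sim$matrix[, 1:200], max_zero_fraction = 0.20)
  # bin retained iff Binomial(200, 0.25) zeros < 40
  expected <- stats::pbinom(39, 200, 0.25)
  mc_se <- sqrt(expected * (1 - expected) / 8000)
  expect_lt(abs(f$report$n_retained / 8000 - expected), 4 * mc_se)
})

test_that("repeat correlation reproduces the t-transform p and flags lsBINs", {
  # an exact copy is perfectly stable
  m <- matrix(rnorm(500), 10, 50, dimnames = list(paste0("chr1_", (0:9) * 250), NULL))
  r <- repeat_correlation(m, m)
  expect_true(all(r$is_lsbin))
  expect_equal(r$r_repeat, rep(1, 10))

  # r = 0.12 at n = 292 sits just inside the 0.05 boundary (t = 2.06, 290 df)
  v <- vectors_with_correlation(292, 0.12, seed = 2)
  rr <- repeat_correlation(rbind(v$x), rbind(v$y))
  expect_equal(rr$r_repeat, 0.12, tolerance = 1e-12)
  expect_lt(abs(rr$p_repeat - 0.040), 1e-3)
  expect_true(rr$is_lsbin)
  # dual route: cor.test as the independent oracle
  ct <- cor.test(v$x, v$y)
  expect_equal(rr$p_repeat, ct$p.value, tolerance = 1e-12)

  # zero-variance bin: undefined correlation, not an lsBIN
  m2 <- m; m2[3, ] <- 5
  rz <- repeat_correlation(m2, m)
  expect_true(is.na(rz$r_repeat[3]) && !rz$is_lsbin[3])

  expect_error(repeat_correlation(m[, 1:2], m[, 1:2]), "at least 3")
})

test_that("pure-noise bins are flagged at the nominal rate with uniform p", {
  set.seed(9)
  n <- 60
  v1 <- matrix(rnorm(40000 * n), 40000, n)
  v2 <- matrix(rnorm(40000 * n), 40000, n)
  r <- repeat_correlation(v1, v2)
  # ~5% significant overall, ~2.5% after the r > 0 requirement
  expect_lt(abs(mean(r$p_repeat < 0.05) - 0.05),
            4 * sqrt(0.05 * 0.95 / 40000))
  expect_lt(abs(mean(r$is_lsbin) - 0.025),
            4 * sqrt(0.025 * 0.975 / 40000))
  ks <- suppressWarnings(ks.test(r$p_repeat, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("twin correlations: identical members give 1, shuffled pairing gives ~0", {
  sim <- small_sim(seed = 3)
  ch <- sim$cohort[sim$cohort$visit == 1, ]
  # duplicate member 1 onto member 2 within each pair -> r_mz = r_dz = 1
  m <- sim$matrix[, ch$sample_id]
  for (f in unique(ch$family_id)) {
    ids <- ch$sample_id[ch$family_id == f]
    if (length(ids) == 2) m[, ids[2]] <- m[, ids[1]]
  }
  tw <- twin_correlations(m, ch)
  expect_equal(tw$r_mz, rep(1, nrow(tw)), tolerance = 1e-12)
  expect_equal(tw$r_dz, rep(1, nrow(tw)), tolerance = 1e-12)
  # re-match pair members across families -> exchangeable -> r ~ 0
  ch_shuf <- ch
  set.seed(1)
  mz2 <- ch$sample_id[ch$zygosity == "MZ"]
  ch_shuf$family_id[ch_shuf$sample_id %in% mz2] <-
    sample(ch$family_id[ch$zygosity == "MZ"])
  tw0 <- suppressWarnings(twin_correlations(sim$matrix[, ch$sample_id], ch_shuf))
  expect_lt(abs(mean(tw0$r_mz)), 0.1)
})

test_that("stability dependence is positive when heritability tracks stability", {
  # construct bins whose r_mz/r_dz grow with r_repeat
  set.seed(12)
  n <- 200
  r_rep <- runif(n, 0.1, 0.9)
  stab <- data.frame(bin = paste0("b", 1:n), r_repeat = r_rep)
  # r_dz grows sublinearly so the MZ/DZ ratio itself increases with r_rep
  twin <- data.frame(bin = stab$bin,
                     r_mz = 0.6 * r_rep + rnorm(n, 0, 0.03), n_mz = 100,
                     r_dz = 0.25 * sqrt(r_rep) + rnorm(n, 0, 0.03), n_dz = 100)
  dep <- stability_dependence(twin, stab)
  expect_true(all(dep$cor > 0))
  expect_true(all(dep$p < 0.0001))
  expect_true(all(is.finite(dep$cor)))
  # constant stability -> undefined
  stab0 <- stab; stab0$r_repeat <- 0.5
  expect_error(stability_dependence(twin, stab0), "constant")
})

test_that("no dependence appears when heritability is constant across stability", {
  set.seed(13)
  n <- 400
  stab <- data.frame(bin = paste0("b", 1:n), r_repeat = runif(n, 0.1, 0.9))
  twin <- data.frame(bin = stab$bin,
                     r_mz = 0.4 + rnorm(n, 0, 0.05), n_mz = 100,
                     r_dz = 0.2 + rnorm(n, 0, 0.05), n_dz = 100)
  dep <- stability_dependence(twin, stab)
  expect_lt(max(abs(dep$cor)), 4 / sqrt(n))
})
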