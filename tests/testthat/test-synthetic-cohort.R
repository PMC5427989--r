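# The generator is first-class analysis code: its twin correlation
# structure, longitudinal stability, zero inflation and liability model are
# what the downstream estimators assume, so each is verified against its
# closed-form expectation.

test_that("cohort structure and determinism", {
  sim <- small_sim(seed = 5)
  v1 <- sim$cohort[sim$cohort$visit == 1, ]
  expect_equal(nrow(v1), 2 * 60 + 2 * 30 + 6)
  expect_equal(as.vector(table(v1$zygosity)[c("MZ", "DZ", "SGL")]),
               c(120L, 60L, 6L))
  # singletons carry a recorded cotwin status despite missing cotwin data
  expect_true(all(v1$cotwin_cwp[v1$zygosity == "SGL"] %in% c(0L, 1L)))
  # one column per sample-visit, bins in rows
  expect_identical(colnames(sim$matrix), sim$cohort$sample_id)
  expect_equal(nrow(sim$matrix), 120)
  # twins share age
  ages <- tapply(v1$age, v1$family_id, function(a) diff(range(a)))
  expect_true(all(ages[table(v1$family_id) == 2] == 0))
  sim2 <- small_sim(seed = 5)
  expect_identical(sim, sim2)
  expect_false(identical(sim$matrix, small_sim(seed = 6)$matrix))
})

test_that("zero inflation and prevalence match their configured rates", {
  sim <- simulate_cohort(sim_config(n_mz_pairs = 300, n_dz_pairs = 150,
                                    n_singletons = 0, n_bins = 200,
                                    zero_inflation = 0.10, seed = 8))
  zf <- rowMeans(sim$matrix == 0)
  n_entries <- length(sim$matrix)
  expect_lt(abs(mean(zf) - 0.10), 4 * sqrt(0.1 * 0.9 / n_entries) + 1e-3)
  v1 <- sim$cohort[sim$cohort$visit == 1, ]
  expect_lt(abs(mean(v1$cwp) - 0.18), 4 * sqrt(0.18 * 0.82 / nrow(v1)))
})

test_that("test-retest correlation equals its target for stable bins and ~0 otherwise", {
  sim <- simulate_cohort(sim_config(n_mz_pairs = 250, n_dz_pairs = 100,
                                    n_singletons = 0, n_bins = 400,
                                    frac_stable_bins = 0.5,
                                    test_retest_r = 0.45,
                                    zero_inflation = 0, repeat_fraction = 1,
                                    causal_bin_effects = NULL, seed = 21))
  ch <- sim$cohort
  s1 <- ch$sample_id[ch$visit == 1][match(ch$individual_id[ch$visit == 2],
                                          ch$individual_id[ch$visit == 1])]
  s2 <- ch$sample_id[ch$visit == 2]
  r <- repeat_correlation(sim$matrix[, s1], sim$matrix[, s2])$r_repeat
  stable <- sim$truth$stable_bin_flags
  expect_lt(abs(mean(r[stable]) - 0.45),
            3 * sd(r[stable]) / sqrt(sum(stable)))
  expect_lt(abs(mean(r[!stable])),
            3 * sd(r[!stable]) / sqrt(sum(!stable)))
})

test_that("twin correlations follow the ACE closed form", {
  # a2 = 0.6, c2 = 0: E[r_MZ] = 0.6, E[r_DZ] = 0.3
  sim <- simulate_cohort(sim_config(n_mz_pairs = 1200, n_dz_pairs = 1200,
                                    n_singletons = 0, n_bins = 60,
                                    frac_stable_bins = 1, bin_h2 = 0.6,
                                    bin_c2 = 0, test_retest_r = 0.6,
                                    zero_inflation = 0, repeat_fraction = 0,
                                    causal_bin_effects = NULL, seed = 31))
  tw <- twin_correlations(sim$matrix, sim$cohort, seed = 1)
  expect_lt(abs(mean(tw$r_mz) - 0.6), 3 * sd(tw$r_mz) / sqrt(nrow(tw)))
  expect_lt(abs(mean(tw$r_dz) - 0.3), 3 * sd(tw$r_dz) / sqrt(nrow(tw)))
})

test_that("no familial liability component gives equal MZ and DZ concordance", {
  sim <- simulate_cohort(sim_config(n_mz_pairs = 1500, n_dz_pairs = 1500,
                                    n_singletons = 0, n_bins = 1,
                                    liability_h2 = 0, causal_bin_effects = NULL,
                                    beta_age = 0, beta_bmi = 0, seed = 44))
  v1 <- sim$cohort[sim$cohort$visit == 1, ]
  conc <- function(zyg) {
    f <- split(v1$cwp[v1$zygosity == zyg], v1$family_id[v1$zygosity == zyg])
    both <- vapply(f, sum, 0) == 2
    any1 <- vapply(f, sum, 0) >= 1
    sum(both) / sum(any1)        # casewise-style concordance
  }
  expect_lt(abs(conc("MZ") - conc("DZ")), 0.06)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(bin_h2 = 0.7, bin_c2 = 0.4), "bin_h2")
  expect_error(sim_config(test_retest_r = 0.1, bin_h2 = 0.15, bin_c2 = 0.05),
               "test_retest_r")
  expect_error(sim_config(prevalence = 0), "prevalence")
  expect_error(sim_config(liability_h2 = 0.9,
                          causal_bin_effects = data.frame(bin = 1:4,
                                                          gamma = 0.2)),
               "variance shares")
  expect_error(sim_config(n_bins = 2, frac_stable_bins = 1,
                          causal_bin_effects = data.frame(bin = 1:3,
                                                          gamma = 0.05)),
               "causal")
})
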