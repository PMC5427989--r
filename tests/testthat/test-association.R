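# Discovery, age adjustment, replication and Fisher combination.

test_that("paired discovery t matches its closed form and t.test", {
  pairs <- data.frame(family_id = c("F1", "F2", "F3"),
                      affected = c("a1", "a2", "a3"),
                      unaffected = c("u1", "u2", "u3"))
  m <- matrix(0, 2, 6, dimnames = list(c("chr1_0", "chr1_250"),
                                       c("a1", "a2", "a3", "u1", "u2", "u3")))
  m[1, ] <- c(1, 2, 3, 0, 0, 0)       # differences {1, 2, 3}
  m[2, ] <- c(5, 6, 7, 5, 6, 7)       # identical within pair
  d <- discover_discordant(m, pairs)
  expect_equal(d$t_disc[1], 2 / (1 / sqrt(3)), tolerance = 1e-12)   # 3.464
  expect_equal(d$p_disc[1], t.test(c(1, 2, 3))$p.value, tolerance = 1e-12)
  expect_equal(d$p_disc[1], 0.0742, tolerance = 1e-3)
  expect_equal(d$t_disc[2], 0)
  expect_equal(d$p_disc[2], 1)
  expect_equal(d$sign[1], 1)
})

test_that("paired t is invariant to within-pair-constant shifts", {
  set.seed(4)
  pairs <- data.frame(family_id = paste0("F", 1:10),
                      affected = paste0("a", 1:10),
                      unaffected = paste0("u", 1:10))
  m <- matrix(rnorm(200), 10, 20,
              dimnames = list(NULL, c(paste0("a", 1:10), paste0("u", 1:10))))
  shift <- rnorm(10)              # family effect, same for both members
  m2 <- m + rep(c(shift, shift), each = nrow(m))
  expect_equal(discover_discordant(m, pairs)$t_disc,
               discover_discordant(m2, pairs)$t_disc, tolerance = 1e-10)
})

test_that("age adjustment gives residuals orthogonal to age and age^2", {
  set.seed(5)
  age <- runif(80, 20, 80)
  m <- rbind(lin = 2 + 0.1 * age,
             quad = 1 + 0.05 * age - 0.001 * age^2 + rnorm(80, 0, 0.2),
             noise = rnorm(80))
  adj <- adjust_age(m, age)
  expect_equal(unname(adj["lin", ]), rep(0, 80), tolerance = 1e-10)
  for (b in rownames(m)) {
    expect_lt(abs(sum(adj[b, ] * age)), 1e-8)
    expect_lt(abs(sum(adj[b, ] * age^2)), 1e-7)
  }
  # OLS oracle recovers the quadratic coefficients within 2 SE
  fit <- lm(m["quad", ] ~ age + I(age^2))
  expect_lt(abs(coef(fit)[2] - 0.05), 2 * summary(fit)$coefficients[2, 2])
  expect_error(adjust_age(m, rep(50, 80)), "constant")
})

test_that("Welch replication matches its closed form", {
  cohort <- toy_cohort(cwp = c(1, 1, 1, 0, 0, 0),
                       zygosity = rep("MZ", 6))
  m <- matrix(c(0, 1, 2, 3, 4, 5), 1,
              dimnames = list("chr1_0", cohort$sample_id))
  r <- replicate_ewas(m, cohort)
  expect_equal(r$t_rep, -3.674, tolerance = 1e-3)
  ot <- t.test(c(0, 1, 2), c(3, 4, 5))
  expect_equal(r$t_rep, unname(ot$statistic), tolerance = 1e-12)
  expect_equal(r$p_rep, ot$p.value, tolerance = 1e-12)
  expect_equal(r$p_rep, 0.0213, tolerance = 1e-3)
  # identical distributions -> t = 0, p = 1
  m0 <- matrix(rep(c(1, 2, 3), 2), 1, dimnames = list("chr1_0", cohort$sample_id))
  r0 <- replicate_ewas(m0, cohort)
  expect_equal(r0$t_rep, 0)
  expect_equal(r0$p_rep, 1)
})

test_that("Fisher combination follows the chi-square(4) closed form and gate", {
  # arithmetic at the boundary pair (0.05, 0.05); the strict p < 0.05 gate
  # itself excludes the boundary, so disable it for the closed-form check
  f <- fisher_combine(0.05, 0.05, 1, 1, gate = FALSE)
  expect_equal(f$chi2_fisher, -4 * log(0.05), tolerance = 1e-12)   # 11.98
  expect_equal(f$p_fisher, pchisq(-4 * log(0.05), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(abs(f$p_fisher - 0.0175), 1e-3)
  fg <- fisher_combine(0.049, 0.049, 1, 1)
  expect_true(fg$combined)
  expect_equal(fg$chi2_fisher, -2 * (log(0.049) + log(0.049)), tolerance = 1e-12)
  # non-significant inputs fail the gate; ungated they combine to chi2 = 0
  f1 <- fisher_combine(1, 1, 1, 1)
  expect_false(f1$combined)
  f1u <- fisher_combine(1, 1, 1, 1, gate = FALSE)
  expect_equal(f1u$chi2_fisher, 0)
  expect_equal(f1u$p_fisher, 1)
  # opposite directions are never combined, however significant
  f2 <- fisher_combine(0.01, 0.01, 1, -1)
  expect_false(f2$combined)
  expect_true(is.na(f2$p_fisher))
  expect_error(fisher_combine(0, 0.5, 1, 1), "0, 1")
})

test_that("Fisher combination is symmetric and monotone", {
  ps <- c(0.001, 0.01, 0.04)
  for (p1 in ps) for (p2 in ps) {
    expect_equal(fisher_combine(p1, p2, 1, 1)$p_fisher,
                 fisher_combine(p2, p1, 1, 1)$p_fisher, tolerance = 1e-14)
  }
  pf <- sapply(ps, function(p) fisher_combine(p, 0.04, 1, 1)$p_fisher)
  expect_true(all(diff(pf) > 0))   # smaller input p -> smaller combined p
})

test_that("two-stage EWAS keeps discovery and replication disjoint and ranks causal bins high", {
  sim <- simulate_cohort(sim_config(
    n_bins = 400,
    causal_bin_effects = data.frame(bin = 1:4, gamma = 0.15), seed = 19))
  ch <- sim$cohort
  v1 <- ch[ch$visit == 1, ]
  lsmat <- sim$matrix[, v1$sample_id]
  ewas <- run_ewas(lsmat, ch, n_pairs = 50, seed = 7)
  disc <- attr(ewas, "discovery_samples")
  expect_length(disc, 100)
  # type-I scale: nominal rates near 5% across mostly-null bins
  expect_lt(abs(mean(ewas$p_disc < 0.05, na.rm = TRUE) - 0.05), 0.03)
  # causal bins enriched relative to null bins on the (ungated) combined
  # evidence: the 50-pair discovery stage alone has modest power, so the
  # enrichment is tested on the joint evidence ranking
  causal <- ewas$bin %in% rownames(sim$matrix)[sim$truth$causal_bin_ids]
  chi2_all <- -2 * (log(ewas$p_disc) + log(ewas$p_rep))
  wt <- wilcox.test(chi2_all[causal], chi2_all[!causal],
                    alternative = "greater")
  expect_lt(wt$p.value, 0.01)
  # every causal bin replicates in the large sample with a concordant sign
  expect_true(all(ewas$p_rep[causal] < 0.05))
})

test_that("rank_top sorts, truncates and breaks ties deterministically", {
  rec <- data.frame(bin = c("chr1_500", "chr1_0", "chr1_250"),
                    combined = TRUE,
                    chi2_fisher = c(10, 10, 12),
                    p_fisher = c(0.04, 0.04, 0.02))
  t1 <- rank_top(rec, k = 10)
  expect_equal(t1$bin, c("chr1_250", "chr1_0", "chr1_500"))  # tie by bin id
  expect_equal(nrow(rank_top(rec, k = 2)), 2)
  expect_identical(rank_top(rec, k = 10), rank_top(rec[c(2, 3, 1), ], k = 10))
})
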