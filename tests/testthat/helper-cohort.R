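# Shared fixtures: all data is generated in code at test time.

small_sim <- function(seed = 1L, ...) {
  simulate_cohort(sim_config(n_mz_pairs = 60L, n_dz_pairs = 30L,
                             n_singletons = 6L, n_bins = 120L,
                             seed = seed, ...))
}

# a pair of vectors with an exactly prescribed sample correlation r
vectors_with_correlation <- function(n, r, seed = 1L) {
  set.seed(seed)
  x <- rnorm(n)
  y0 <- rnorm(n)
  x_c <- scale(x)[, 1]
  # residualize y0 against x, then mix to the exact target correlation
  e <- scale(resid(lm(y0 ~ x)))[, 1]
  y <- r * x_c + sqrt(1 - r^2) * e
  list(x = x_c, y = y)
}

# minimal hand-built cohort table (one visit, pairs listed consecutively)
toy_cohort <- function(cwp, zygosity, age = NULL, bmi = NULL) {
  n <- length(cwp)
  data.frame(sample_id = sprintf("S%03d_v1", seq_len(n)),
             individual_id = sprintf("S%03d", seq_len(n)),
             family_id = sprintf("F%03d", rep(seq_len(n / 2), each = 2)),
             zygosity = zygosity,
             cwp = cwp,
             age = age %||% rep(50, n),
             bmi = bmi %||% rep(25, n),
             smoking = NA_character_,
             neut = NA_real_, eos = NA_real_, mono = NA_real_,
             lymph = NA_real_,
             visit = 1L,
             visit_year = 2000,
             cotwin_cwp = cwp[ifelse(seq_len(n) %% 2 == 1,
                                     seq_len(n) + 1, seq_len(n) - 1)],
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
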