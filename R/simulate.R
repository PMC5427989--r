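# Synthetic twin-cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: per-bin
# ACE variance components with additive-genetic correlation 1 in MZ and 0.5 in
# DZ pairs, longitudinal test-retest correlation for stable bins, zero
# inflation of bin values, and a liability-threshold disease model with age,
# BMI and per-bin methylation effects on the probit scale.

#' Simulation configuration for a synthetic twin cohort
#'
#' Defaults describe a TwinsUK-like female cohort: 565 MZ pairs, 244 DZ pairs
#' and 90 singletons (1708 individuals with methylation data), ages uniform on
#' 17-82, BMI normal(25.6, 4.5), chronic widespread pain prevalence 0.18,
#' liability heritability 0.636, four causal bins jointly explaining 6% of
#' liability variance, and a 17% repeat-visit fraction with gaps of at least
#' three years (mean 7, SD 1.2).
#'
#' @param n_mz_pairs,n_dz_pairs,n_singletons Cohort structure counts.
#'   Singletons are generated as pair members whose cotwin's affection status
#'   is recorded (`cotwin_cwp`) but whose methylation is dropped.
#' @param n_bins Number of 500 bp bins on the 250 bp-step grid.
#' @param frac_stable_bins Fraction of bins that are longitudinally stable;
#'   stable bins occupy the first `round(frac_stable_bins * n_bins)` grid
#'   positions so that causal-bin indices are interpretable.
#' @param bin_h2,bin_c2 Additive-genetic and shared-environment shares of
#'   stable-bin variance (`a^2`, `c^2` of the ACE model).
#' @param test_retest_r Expected test-retest correlation of stable bins
#'   across repeat visits; must be at least `bin_h2 + bin_c2` (the heritable
#'   and family-shared components persist across visits by construction).
#'   Unstable bins have test-retest correlation 0.
#' @param zero_inflation Probability that any matrix entry is set to exactly 0.
#' @param causal_bin_effects Data frame with columns `bin` (index into the
#'   stable bins) and `gamma` (liability effect per SD of methylation), or
#'   `NULL` for no epigenetic effects.
#' @param liability_h2 Additive-genetic fraction of liability variance.
#' @param beta_age,beta_bmi Liability effects per SD of age and BMI.
#' @param prevalence Population prevalence of the binary trait in (0, 1).
#' @param repeat_fraction Fraction of individuals measured at a second visit.
#' @param repeat_gap_years Minimum gap between visits in years (>= 3).
#' @param age_range,bmi_mean,bmi_sd Covariate distributions.
#' @param smoking_known_frac,smoking_current,smoking_ex Smoking availability
#'   and composition among individuals with known smoking status (defaults:
#'   1307 of 1708 known; 99 current and 489 ex-smokers of the 1307).
#' @param wbc_frac Fraction of individuals with white-blood-cell counts.
#' @param seed Integer seed; the generator uses one private RNG stream and
#'   leaves the global RNG state untouched.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_mz_pairs = 565L, n_dz_pairs = 244L, n_singletons = 90L,
                       n_bins = 1000L,
                       frac_stable_bins = 0.10,
                       bin_h2 = 0.15, bin_c2 = 0.05,
                       test_retest_r = 0.30,
                       zero_inflation = 0.05,
                       causal_bin_effects = data.frame(bin = 1:4,
                                                       gamma = sqrt(0.015)),
                       liability_h2 = 0.636,
                       beta_age = 0.15, beta_bmi = 0.15,
                       prevalence = 0.18,
                       repeat_fraction = 292 / 1708,
                       repeat_gap_years = 3.4,
                       age_range = c(17, 82),
                       bmi_mean = 25.6, bmi_sd = 4.5,
                       smoking_known_frac = 1307 / 1708,
                       smoking_current = 99 / 1307,
                       smoking_ex = 489 / 1307,
                       wbc_frac = 441 / 1708,
                       seed = 1L) {
  cfg <- list(n_mz_pairs = as.integer(n_mz_pairs),
              n_dz_pairs = as.integer(n_dz_pairs),
              n_singletons = as.integer(n_singletons),
              n_bins = as.integer(n_bins),
              frac_stable_bins = frac_stable_bins,
              bin_h2 = bin_h2, bin_c2 = bin_c2,
              test_retest_r = test_retest_r,
              zero_inflation = zero_inflation,
              causal_bin_effects = causal_bin_effects,
              liability_h2 = liability_h2,
              beta_age = beta_age, beta_bmi = beta_bmi,
              prevalence = prevalence,
              repeat_fraction = repeat_fraction,
              repeat_gap_years = repeat_gap_years,
              age_range = age_range, bmi_mean = bmi_mean, bmi_sd = bmi_sd,
              smoking_known_frac = smoking_known_frac,
              smoking_current = smoking_current, smoking_ex = smoking_ex,
              wbc_frac = wbc_frac,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @keywords internal
#' @noRd
validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_mz_pairs >= 0, cfg$n_dz_pairs >= 0, cfg$n_singletons >= 0,
            cfg$n_bins >= 1)
  if (cfg$bin_h2 < 0 || cfg$bin_c2 < 0 || cfg$bin_h2 + cfg$bin_c2 > 1)
    stop("invalid bin variance shares: need bin_h2 + bin_c2 <= 1", call. = FALSE)
  if (cfg$test_retest_r < cfg$bin_h2 + cfg$bin_c2 || cfg$test_retest_r > 1)
    stop("test_retest_r must lie in [bin_h2 + bin_c2, 1]", call. = FALSE)
  if (cfg$zero_inflation < 0 || cfg$zero_inflation >= 1)
    stop("zero_inflation must be in [0, 1)", call. = FALSE)
  if (cfg$prevalence <= 0 || cfg$prevalence >= 1)
    stop("prevalence must be in (0, 1)", call. = FALSE)
  if (cfg$repeat_gap_years < 3)
    stop("repeat_gap_years must be at least 3", call. = FALSE)
  gsq <- 0
  if (!is.null(cfg$causal_bin_effects)) {
    ce <- cfg$causal_bin_effects
    stopifnot(is.data.frame(ce), all(c("bin", "gamma") %in% names(ce)))
    n_stable <- round(cfg$frac_stable_bins * cfg$n_bins)
    if (nrow(ce) > cfg$n_bins)
      stop("more causal bins than bins", call. = FALSE)
    if (any(ce$bin < 1) || any(ce$bin > n_stable) || anyDuplicated(ce$bin))
      stop("causal bin indices must be distinct indices of stable bins ",
           "(1..", n_stable, ")", call. = FALSE)
    gsq <- sum(ce$gamma^2)
  }
  tot <- cfg$liability_h2 + gsq + cfg$beta_age^2 + cfg$beta_bmi^2
  if (cfg$liability_h2 < 0 || tot > 1)
    stop("liability variance shares exceed 1 ",
         "(h2 + sum(gamma^2) + beta_age^2 + beta_bmi^2 = ",
         signif(tot, 4), ")", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Twin-cohort simulation configuration\n")
  cat(sprintf("  %d MZ pairs, %d DZ pairs, %d singletons (%d individuals)\n",
              x$n_mz_pairs, x$n_dz_pairs, x$n_singletons,
              2L * (x$n_mz_pairs + x$n_dz_pairs) + x$n_singletons))
  cat(sprintf("  %d bins (%.0f%% stable; a2=%.2f c2=%.2f, test-retest r=%.2f)\n",
              x$n_bins, 100 * x$frac_stable_bins, x$bin_h2, x$bin_c2,
              x$test_retest_r))
  ng <- if (is.null(x$causal_bin_effects)) 0L else nrow(x$causal_bin_effects)
  cat(sprintf("  liability: h2=%.3f, %d causal bins, prevalence=%.2f\n",
              x$liability_h2, ng, x$prevalence))
  invisible(x)
}

# draw correlated additive-genetic components: matrix bins x individuals where
# pair members share the family component fully (MZ) or half (DZ)
#' @keywords internal
#' @noRd
.sim_additive <- function(n_bins, fam_of, mz_fam) {
  n_ind <- length(fam_of)
  n_fam <- max(fam_of)
  A_fam <- matrix(stats::rnorm(n_bins * n_fam), n_bins, n_fam)
  A_ind <- matrix(stats::rnorm(n_bins * n_ind), n_bins, n_ind)
  A <- matrix(0, n_bins, n_ind)
  is_mz_member <- mz_fam[fam_of]
  A[, is_mz_member] <- A_fam[, fam_of[is_mz_member], drop = FALSE]
  dz <- !is_mz_member
  A[, dz] <- sqrt(0.5) * A_fam[, fam_of[dz], drop = FALSE] +
    sqrt(0.5) * A_ind[, dz, drop = FALSE]
  A
}

#' Simulate a twin cohort with bin-level methylation
#'
#' Generates (1) a bins-by-samples methylation matrix whose stable bins carry
#' ACE twin structure and a prescribed test-retest correlation across repeat
#' visits, (2) a cohort table with twin structure, covariates and
#' liability-threshold affection status, and (3) a ground-truth record for
#' parameter-recovery tests.  Identical `config` (including its `seed`) gives
#' byte-identical output.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `twin_cohort` with elements `matrix` (bins x
#'   samples, one column per sample-visit), `bins` (BED-style bin grid),
#'   `cohort` (one row per sample-visit) and `truth`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_mz_pairs = 30, n_dz_pairs = 15,
#'                                   n_singletons = 5, n_bins = 50, seed = 7))
#' dim(sim$matrix)
#' table(sim$cohort$zygosity[sim$cohort$visit == 1])
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  # private RNG stream: save/restore any global state
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(config$seed)

  n_mz <- config$n_mz_pairs; n_dz <- config$n_dz_pairs; n_sgl <- config$n_singletons
  n_fam <- n_mz + n_dz + n_sgl
  # every family is generated as a pair; singleton cotwins are dropped from
  # the methylation matrix but keep a recorded affection status
  fam_of <- rep(seq_len(n_fam), each = 2L)
  n_all <- 2L * n_fam
  fam_zyg <- c(rep("MZ", n_mz), rep("DZ", n_dz),
               rep(c("MZ", "DZ"), length.out = n_sgl))   # latent, for singletons
  mz_fam <- fam_zyg == "MZ"
  sgl_fam <- seq_len(n_fam) > n_mz + n_dz
  member <- rep(c(1L, 2L), times = n_fam)
  dropped <- sgl_fam[fam_of] & member == 2L              # cotwins without data

  n_bins <- config$n_bins
  n_stable <- round(config$frac_stable_bins * n_bins)
  stable <- seq_len(n_bins) <= n_stable

  # --- covariates ----------------------------------------------------------
  age_fam <- stats::runif(n_fam, config$age_range[1], config$age_range[2])
  age <- age_fam[fam_of]                                  # twins share age
  bmi <- stats::rnorm(n_all, config$bmi_mean, config$bmi_sd)
  smoking <- rep(NA_character_, n_all)
  known <- stats::runif(n_all) < config$smoking_known_frac
  u <- stats::runif(n_all)
  smoking[known] <- ifelse(u[known] < config$smoking_current, "current",
                    ifelse(u[known] < config$smoking_current + config$smoking_ex,
                           "ex", "never"))
  has_wbc <- stats::runif(n_all) < config$wbc_frac
  wbc <- cbind(neut = stats::rnorm(n_all, 4.0, 1.3),
               eos = stats::rnorm(n_all, 0.20, 0.12),
               mono = stats::rnorm(n_all, 0.50, 0.16),
               lymph = stats::rnorm(n_all, 1.90, 0.55))
  wbc <- pmax(wbc, 0.01)
  wbc[!has_wbc, ] <- NA_real_

  # --- visit-1 methylation -------------------------------------------------
  mu <- stats::runif(n_bins, 2, 8)
  a <- sqrt(config$bin_h2); cc <- sqrt(config$bin_c2)
  p_pers <- sqrt(config$test_retest_r - config$bin_h2 - config$bin_c2)
  t_trans <- sqrt(1 - config$test_retest_r)
  M <- matrix(stats::rnorm(n_bins * n_all), n_bins, n_all)   # transient/noise
  persistent <- matrix(0, n_bins, n_all)
  if (n_stable > 0) {
    A <- .sim_additive(n_stable, fam_of, mz_fam)
    C <- matrix(stats::rnorm(n_stable * n_fam), n_stable, n_fam)[, fam_of,
                                                                 drop = FALSE]
    P <- matrix(stats::rnorm(n_stable * n_all), n_stable, n_all)
    persistent[stable, ] <- a * A + cc * C + p_pers * P
    M[stable, ] <- persistent[stable, , drop = FALSE] +
      t_trans * M[stable, , drop = FALSE]
  }
  meth1 <- mu + M

  # --- zero inflation (before liability: the trait depends on the observed,
  # zero-inflated methylation values) ---------------------------------------
  if (config$zero_inflation > 0)
    meth1[matrix(stats::runif(length(meth1)), n_bins) < config$zero_inflation] <- 0

  # --- liability and affection status --------------------------------------
  gsq <- 0
  liab_meth <- 0
  if (!is.null(config$causal_bin_effects) && nrow(config$causal_bin_effects)) {
    ce <- config$causal_bin_effects
    gsq <- sum(ce$gamma^2)
    Z <- row_standardize(meth1[ce$bin, , drop = FALSE])
    liab_meth <- as.numeric(crossprod(Z, ce$gamma))
  }
  A_L <- as.numeric(.sim_additive(1L, fam_of, mz_fam))
  e_var <- 1 - config$liability_h2 - gsq - config$beta_age^2 - config$beta_bmi^2
  liab <- config$beta_age * as.numeric(scale(age)) +
    config$beta_bmi * as.numeric(scale(bmi)) +
    liab_meth +
    sqrt(config$liability_h2) * A_L +
    sqrt(e_var) * stats::rnorm(n_all)
  threshold <- stats::qnorm(1 - config$prevalence)
  cwp <- as.integer(liab > threshold)
  cotwin_idx <- ifelse(member == 1L, seq_len(n_all) + 1L, seq_len(n_all) - 1L)
  cotwin_cwp <- cwp[cotwin_idx]

  # --- repeat visits -------------------------------------------------------
  kept <- which(!dropped)
  n_kept <- length(kept)
  n_rep <- round(config$repeat_fraction * n_kept)
  rep_ids <- sort(sample(kept, n_rep))
  # gap ~ N(7, 1.2) truncated below at repeat_gap_years
  lo <- stats::pnorm((config$repeat_gap_years - 7) / 1.2)
  gap <- 7 + 1.2 * stats::qnorm(stats::runif(n_rep, lo, 1))
  meth2 <- NULL
  if (n_rep > 0) {
    M2 <- matrix(stats::rnorm(n_bins * n_rep), n_bins, n_rep)
    M2[stable, ] <- persistent[stable, rep_ids, drop = FALSE] +
      t_trans * M2[stable, , drop = FALSE]
    meth2 <- mu + M2
    if (config$zero_inflation > 0)
      meth2[matrix(stats::runif(length(meth2)), n_bins) < config$zero_inflation] <- 0
  }

  # --- assemble outputs ----------------------------------------------------
  bins <- data.frame(chrom = "chr1",
                     start = (seq_len(n_bins) - 1L) * 250L,
                     end = (seq_len(n_bins) - 1L) * 250L + 500L,
                     stringsAsFactors = FALSE)
  bin_id <- paste(bins$chrom, bins$start, sep = "_")
  ind_id <- sprintf("I%04d", seq_len(n_all))
  zyg_out <- ifelse(sgl_fam[fam_of], "SGL", fam_zyg[fam_of])
  year1 <- 1996 + stats::runif(n_all, 0, 4)

  c1 <- data.frame(sample_id = paste0(ind_id[kept], "_v1"),
                   individual_id = ind_id[kept],
                   family_id = sprintf("F%04d", fam_of[kept]),
                   zygosity = zyg_out[kept],
                   cwp = cwp[kept],
                   age = age[kept],
                   bmi = bmi[kept],
                   smoking = smoking[kept],
                   neut = wbc[kept, "neut"], eos = wbc[kept, "eos"],
                   mono = wbc[kept, "mono"], lymph = wbc[kept, "lymph"],
                   visit = 1L,
                   visit_year = year1[kept],
                   cotwin_cwp = cotwin_cwp[kept],
                   stringsAsFactors = FALSE)
  cohort <- c1
  mat <- meth1[, kept, drop = FALSE]
  colnames(mat) <- c1$sample_id
  if (n_rep > 0) {
    c2 <- c1[match(rep_ids, kept), ]
    c2$sample_id <- paste0(ind_id[rep_ids], "_v2")
    c2$visit <- 2L
    c2$age <- c2$age + gap
    c2$visit_year <- c2$visit_year + gap
    cohort <- rbind(c1, c2)
    colnames(meth2) <- c2$sample_id
    mat <- cbind(mat, meth2)
  }
  rownames(mat) <- bin_id
  rownames(cohort) <- NULL

  truth <- list(stable_bin_flags = stable,
                causal_bin_ids = if (is.null(config$causal_bin_effects)) integer(0)
                                 else config$causal_bin_effects$bin,
                true_h2 = config$liability_h2,
                true_bin_effects = if (is.null(config$causal_bin_effects)) numeric(0)
                                   else config$causal_bin_effects$gamma,
                liability_threshold = threshold)

  structure(list(matrix = mat, bins = bins, cohort = cohort, truth = truth,
                 config = config),
            class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  n1 <- sum(x$cohort$visit == 1)
  cat(sprintf("Twin cohort: %d individuals (%d samples incl. repeats), %d bins\n",
              n1, nrow(x$cohort), nrow(x$matrix)))
  cat(sprintf("  affected: %d (%.1f%%); repeat visits: %d\n",
              sum(x$cohort$cwp[x$cohort$visit == 1]),
              100 * mean(x$cohort$cwp[x$cohort$visit == 1]),
              sum(x$cohort$visit == 2)))
  invisible(x)
}
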