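# Maximum-likelihood liability-threshold variance decomposition for twin
# data.  A binary trait is modelled as a latent liability
#   L_i = beta' x_i + gamma' z_i + A_i + E_i,    case iff L_i > tau,
# with additive-genetic component A (Var = a2, correlation 1 within MZ and
# 0.5 within DZ pairs), unique environment E (Var = 1 - a2 - sum(gamma^2)),
# covariates x (standardized age/BMI) and standardized bin methylation z
# treated as fixed liability covariates, each bin contributing gamma_j^2 to
# liability variance.  Pairs contribute bivariate-normal orthant
# probabilities for their status combination; singletons contribute
# univariate tail terms.  This is an AE decomposition: no shared-environment
# C component is fitted, since the reported components are additive-genetic
# (AGF), epigenetic (EGF) and residual (RES).

# negative log-likelihood; theta = c(tau, beta, gamma, [a2 unless fixed])
#' @keywords internal
#' @noRd
.liability_nll <- function(theta, dat, fix_a2 = NULL) {
  nb <- dat$n_beta; ng <- dat$n_gamma
  tau <- theta[1]
  beta <- if (nb) theta[1 + seq_len(nb)] else numeric(0)
  gamma <- if (ng) theta[1 + nb + seq_len(ng)] else numeric(0)
  a2 <- fix_a2 %||% theta[length(theta)]
  s2 <- 1 - sum(gamma^2)             # residual (A + E) variance
  if (s2 < 1e-4 || a2 > 0.999 * s2 || a2 < 0) return(1e10)
  s <- sqrt(s2)
  mean_lin <- rep(0, dat$n)
  if (nb) mean_lin <- mean_lin + drop(dat$X %*% beta)
  if (ng) mean_lin <- mean_lin + drop(dat$Z %*% gamma)
  u <- (tau - mean_lin) / s          # standardized threshold per individual
  ll <- 0
  for (zyg in c("mz", "dz")) {
    pr <- dat$pairs[[zyg]]
    if (is.null(pr)) next
    rho <- (if (zyg == "mz") 1 else 0.5) * a2 / s2
    P <- bvn_orthants(u[pr$i1], u[pr$i2], rho)
    pk <- P[cbind(seq_along(pr$i1), pr$combo)]
    ll <- ll + sum(log(pmax(pk, 1e-300)))
  }
  if (length(dat$singles)) {
    us <- u[dat$singles]
    cs <- dat$single_cwp
    ll <- ll + sum(log(pmax(ifelse(cs == 1, stats::pnorm(-us),
                                   stats::pnorm(us)), 1e-300)))
  }
  -ll
}

# index structures for the likelihood: pairs by zygosity, singletons,
# covariate and methylation design matrices
#' @keywords internal
#' @noRd
.liability_data <- function(cohort, covariates, meth) {
  v1 <- cohort[cohort$visit == 1, ]
  stopifnot(all(v1$cwp %in% c(0, 1)))
  X <- NULL
  if (length(covariates)) {
    stopifnot(all(covariates %in% names(v1)))
    X <- scale(as.matrix(v1[, covariates, drop = FALSE]))
  }
  Z <- NULL
  if (!is.null(meth)) {
    stopifnot(all(v1$sample_id %in% colnames(meth)))
    Z <- t(row_standardize(meth[, v1$sample_id, drop = FALSE]))
  }
  pair_idx <- function(zyg) {
    rows <- which(v1$zygosity == zyg)
    fams <- split(rows, v1$family_id[rows])
    fams <- fams[lengths(fams) == 2L]
    if (!length(fams)) return(NULL)
    i1 <- vapply(fams, `[`, 0L, 1L); i2 <- vapply(fams, `[`, 0L, 2L)
    # orthant column: 1 = both affected, 2 = first only, 3 = second only, 4 = neither
    combo <- ifelse(v1$cwp[i1] == 1 & v1$cwp[i2] == 1, 1L,
             ifelse(v1$cwp[i1] == 1, 2L,
             ifelse(v1$cwp[i2] == 1, 3L, 4L)))
    list(i1 = unname(i1), i2 = unname(i2), combo = unname(combo))
  }
  mz <- pair_idx("MZ"); dz <- pair_idx("DZ")
  paired <- c(mz$i1, mz$i2, dz$i1, dz$i2)
  singles <- setdiff(seq_len(nrow(v1)), paired)
  list(n = nrow(v1), X = X, Z = Z,
       n_beta = if (is.null(X)) 0L else ncol(X),
       n_gamma = if (is.null(Z)) 0L else ncol(Z),
       beta_names = covariates,
       gamma_names = if (is.null(Z)) character(0) else colnames(Z),
       pairs = list(mz = mz, dz = dz),
       singles = singles, single_cwp = v1$cwp[singles],
       n_mz = length(mz$i1 %||% integer(0)),
       n_dz = length(dz$i1 %||% integer(0)),
       prev = mean(v1$cwp))
}

#' Fit the liability-threshold variance decomposition
#'
#' Maximizes the twin-pair likelihood over threshold, covariate effects,
#' per-bin methylation effects and the additive-genetic liability fraction
#' `a2` (narrow-sense heritability of liability), using bounded quasi-Newton
#' from several starting values of `a2`; the best log-likelihood wins, ties
#' resolved towards the smaller `a2`.  Standard errors come from the
#' observed information (numerical Hessian) at the optimum.
#'
#' @param cohort Cohort table (visit-1 rows are used).
#' @param covariates Cohort columns entering the liability mean (standardized
#'   internally); default age and BMI.
#' @param meth Optional bins-by-samples methylation matrix for the epigenetic
#'   bin set (standardized per bin internally).
#' @param fix_a2 Fix `a2` at a value instead of estimating it (e.g. 0 for the
#'   reduced model of the likelihood-ratio test).
#' @param starts Starting values for `a2`.
#' @param min_pairs Warn when fewer complete pairs than this per zygosity.
#' @return A `liability_fit` with elements `a2`, `se_a2`, `tau`, `beta`,
#'   `gamma`, `fractions` (`AGF`, per-bin `EGF`, `RES`; they sum to 1),
#'   `loglik`, `converged`, `boundary`, pair counts.
#' @export
fit_liability <- function(cohort, covariates = c("age", "bmi"), meth = NULL,
                          fix_a2 = NULL, starts = c(0.1, 0.4, 0.7),
                          min_pairs = 20L) {
  dat <- .liability_data(cohort, covariates, meth)
  if (dat$n_mz < min_pairs || dat$n_dz < min_pairs)
    warning("fewer than ", min_pairs, " complete pairs in a zygosity group (",
            dat$n_mz, " MZ, ", dat$n_dz, " DZ)")
  nb <- dat$n_beta; ng <- dat$n_gamma
  free_a2 <- is.null(fix_a2)
  tau0 <- stats::qnorm(1 - max(min(dat$prev, 0.99), 0.01))
  base <- c(tau0, rep(0, nb + ng))
  lower <- c(-5, rep(-3, nb), rep(-0.9, ng))
  upper <- c(5, rep(3, nb), rep(0.9, ng))
  if (free_a2) { lower <- c(lower, 0); upper <- c(upper, 0.98) }
  if (!free_a2) starts <- starts[1]
  best <- NULL
  for (a2_start in starts) {
    th0 <- if (free_a2) c(base, a2_start) else base
    fit <- try(stats::optim(th0, .liability_nll, dat = dat, fix_a2 = fix_a2,
                            method = "L-BFGS-B", lower = lower, upper = upper,
                            control = list(maxit = 300)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    take <- is.null(best) || fit$value < best$value - 1e-9 ||
      (abs(fit$value - best$value) <= 1e-9 && free_a2 &&
         fit$par[length(fit$par)] < best$par[length(best$par)])
    if (take) best <- fit
  }
  if (is.null(best))
    stop("liability fit failed to converge from all starts", call. = FALSE)
  th <- best$par
  a2 <- if (free_a2) th[length(th)] else fix_a2
  gamma <- if (ng) th[1 + nb + seq_len(ng)] else numeric(0)
  names(gamma) <- dat$gamma_names
  beta <- if (nb) th[1 + seq_len(nb)] else numeric(0)
  names(beta) <- dat$beta_names
  boundary <- free_a2 && (a2 <= 1e-6 || a2 >= 0.98 - 1e-6)

  se <- rep(NA_real_, length(th))
  H <- try(stats::optimHess(th, .liability_nll, dat = dat, fix_a2 = fix_a2),
           silent = TRUE)
  if (!inherits(H, "try-error")) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error")) {
      d <- diag(V)
      se <- ifelse(d > 0, sqrt(pmax(d, 0)), NA_real_)
    }
  }
  se_gamma <- if (ng) se[1 + nb + seq_len(ng)] else numeric(0)
  names(se_gamma) <- dat$gamma_names
  se_beta <- if (nb) se[1 + seq_len(nb)] else numeric(0)
  names(se_beta) <- dat$beta_names

  egf <- gamma^2
  fractions <- list(AGF = a2, EGF = as.list(egf),
                    RES = 1 - a2 - sum(egf))
  structure(list(a2 = a2,
                 se_a2 = if (free_a2) se[length(th)] else NA_real_,
                 tau = th[1], se_tau = se[1],
                 beta = beta, se_beta = se_beta,
                 gamma = gamma, se_gamma = se_gamma,
                 fractions = fractions,
                 loglik = -best$value,
                 converged = best$convergence == 0,
                 boundary = boundary,
                 n_mz_pairs = dat$n_mz, n_dz_pairs = dat$n_dz,
                 n_singletons = length(dat$singles),
                 fixed_a2 = !free_a2),
            class = "liability_fit")
}

#' @export
print.liability_fit <- function(x, ...) {
  cat("Liability-threshold variance decomposition\n")
  cat(sprintf("  a2 (liability heritability): %.3f%s%s\n", x$a2,
              if (is.finite(x$se_a2)) sprintf(" +/- %.3f", x$se_a2) else "",
              if (x$boundary) " [boundary]" else ""))
  if (length(x$gamma))
    cat(sprintf("  epigenetic fractions: %s (total %.3f)\n",
                paste(sprintf("%s=%.4f", names(x$gamma), x$gamma^2),
                      collapse = ", "),
                sum(x$gamma^2)))
  cat(sprintf("  residual: %.3f; logLik = %.2f (%d MZ, %d DZ pairs, %d singletons)\n",
              x$fractions$RES, x$loglik, x$n_mz_pairs, x$n_dz_pairs,
              x$n_singletons))
  invisible(x)
}

#' Likelihood-ratio test for an additive-genetic component
#'
#' Tests `a2 > 0` by comparing the full fit with a reduced fit constrained
#' to `a2 = 0`.  Because the null value lies on the parameter boundary the
#' reference distribution is the mixture `1/2 chi2_0 + 1/2 chi2_1`, so
#' `p = P(chi2_1 >= Lambda) / 2` for positive statistics and 1 otherwise.
#'
#' @param full Unconstrained [fit_liability()] result.
#' @param reduced Nested fit with `fix_a2 = 0` on the same data.
#' @return List with `stat` (Lambda, clamped at 0) and `p`.
#' @export
lrt_vad <- function(full, reduced) {
  stat <- 2 * (full$loglik - reduced$loglik)
  if (stat < -1e-6)
    stop("full-model likelihood below reduced-model likelihood; ",
         "optimization failure", call. = FALSE)
  stat <- max(stat, 0)
  p <- if (stat > 0) stats::pchisq(stat, df = 1, lower.tail = FALSE) / 2 else 1
  list(stat = stat, p = p)
}

#' Variance-component summary of a liability fit
#'
#' Tabulates the additive-genetic (AGF), per-bin epigenetic (EGF) and
#' residual (RES) fractions of liability variance with delta-method SEs
#' (`EGF_j = gamma_j^2`, so `se = 2 |gamma_j| se_gamma_j`).
#'
#' @param fit A converged [fit_liability()] result.
#' @return `data.frame` with `component`, `fraction`, `se`; fractions sum
#'   to 1.
#' @export
variance_report <- function(fit) {
  stopifnot(inherits(fit, "liability_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  egf <- fit$gamma^2
  se_egf <- 2 * abs(fit$gamma) * fit$se_gamma
  res_se <- sqrt(sum(c(fit$se_a2, se_egf)^2, na.rm = TRUE))
  data.frame(component = c("AGF", if (length(egf)) paste0("EGF_", names(egf)),
                           "RES"),
             fraction = c(fit$a2, unname(egf), fit$fractions$RES),
             se = c(fit$se_a2, unname(se_egf), res_se),
             row.names = NULL, stringsAsFactors = FALSE)
}
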