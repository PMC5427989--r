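# Per-bin and joint logistic models of affection status on methylation with
# covariates, and one-way-ANOVA variance-explained estimates for top bins.
#
# Familial dependence between twins is absorbed by including the cotwin's
# affection status as a covariate; no cluster-robust variance is applied by
# default (an optional sandwich-style flag is deliberately not provided --
# the study design treats the cotwin covariate as the adjustment).

# assemble the complete-case model frame for a logistic fit
#' @keywords internal
#' @noRd
.logistic_frame <- function(bin_values, cohort, covariates, standardize = TRUE) {
  allowed <- c("age", "bmi", "cotwin_status", "smoking", "wbc4")
  bad <- setdiff(covariates, allowed)
  if (length(bad))
    stop("unknown covariate(s): ", paste(bad, collapse = ", "), call. = FALSE)
  df <- data.frame(cwp = cohort$cwp)
  if (!is.null(bin_values)) {
    bv <- as.matrix(bin_values)
    if (any(apply(bv, 2L, stats::sd) == 0))
      stop("constant methylation predictor", call. = FALSE)
    if (standardize) bv <- scale(bv)     # per-SD coefficients
    colnames(bv) <- colnames(bin_values) %||%
      paste0("meth", seq_len(ncol(bv)))
    df <- cbind(df, bv)
  }
  if ("age" %in% covariates) df$age <- cohort$age
  if ("bmi" %in% covariates) df$bmi <- cohort$bmi
  if ("cotwin_status" %in% covariates) df$cotwin_status <- cohort$cotwin_cwp
  if ("smoking" %in% covariates)
    df$smoking_ever <- ifelse(is.na(cohort$smoking), NA,
                              as.integer(cohort$smoking %in% c("current", "ex")))
  if ("wbc4" %in% covariates) {
    df$neut <- cohort$neut; df$eos <- cohort$eos
    df$mono <- cohort$mono; df$lymph <- cohort$lymph
  }
  df[stats::complete.cases(df), , drop = FALSE]
}

# fit + package a logistic model; shared by per-bin and joint entry points
#' @keywords internal
#' @noRd
.fit_logistic <- function(df) {
  if (length(unique(df$cwp)) < 2)
    stop("outcome has a single class", call. = FALSE)
  const <- vapply(df[-1], function(x) stats::sd(x) == 0, TRUE)
  if (any(const))
    stop("constant predictor(s): ", paste(names(df[-1])[const], collapse = ", "),
         call. = FALSE)
  npar <- ncol(df)
  if (nrow(df) < 10 * npar)
    warning("fewer than 10 complete cases per parameter (n = ", nrow(df), ")")
  X <- stats::model.matrix(cwp ~ ., df)
  if (qr(X)$rank < ncol(X))
    stop("collinear predictors in logistic model", call. = FALSE)
  fit <- suppressWarnings(stats::glm(cwp ~ ., family = stats::binomial(), data = df))
  sm <- summary(fit)$coefficients
  eps <- 1e-8
  separated <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps) ||
    any(abs(stats::coef(fit)) > 15)
  out <- list(terms = data.frame(term = rownames(sm),
                                 estimate = sm[, 1], se = sm[, 2],
                                 z = sm[, 3], p = sm[, 4],
                                 row.names = NULL, stringsAsFactors = FALSE),
              n = nrow(df),
              converged = fit$converged && !separated,
              separated = separated,
              loglik = as.numeric(stats::logLik(fit)))
  class(out) <- "logistic_fit"
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic model of affection status (n = %d, logLik = %.2f%s)\n",
              x$n, x$loglik,
              if (!x$converged) ", NOT converged" else ""))
  print(x$terms, digits = 3)
  invisible(x)
}

#' Logistic regression of affection status on one bin plus covariates
#'
#' Maximum-likelihood logistic fit of CWP (0/1) on standardized bin
#' methylation and the requested covariates, complete cases only (smoking
#' and WBC counts are available for subsets of the cohort, so `n` varies by
#' covariate set and is reported per model).  Perfect separation is flagged
#' as non-converged rather than silently reported.
#'
#' @param bin_values Methylation values, one per cohort row (visit-1 rows).
#' @param cohort Cohort table restricted to visit-1 samples.
#' @param covariates Subset of `age`, `bmi`, `cotwin_status`, `smoking`
#'   (coded ever/never), `wbc4` (the four white-cell counts).
#' @param standardize Standardize methylation before entry (default), so the
#'   coefficient is log-odds per SD; set `FALSE` for per-unit coefficients.
#' @return A `logistic_fit`: per-term estimates (log-odds per SD of
#'   methylation), SEs, Wald z and p, `n`, `converged`, `loglik`.
#' @export
logistic_cwp <- function(bin_values, cohort,
                         covariates = c("age", "bmi", "cotwin_status"),
                         standardize = TRUE) {
  stopifnot(length(bin_values) == nrow(cohort))
  bv <- matrix(bin_values, ncol = 1, dimnames = list(NULL, "meth"))
  .fit_logistic(.logistic_frame(bv, cohort, covariates, standardize))
}

#' Joint logistic model of several top bins
#'
#' One model containing all listed bins (standardized) plus the covariates;
#' every bin term is retained regardless of significance.  Duplicated or
#' collinear bins raise an error.
#'
#' @param mat Bins-by-samples matrix.
#' @param bin_ids Bin ids (rownames of `mat`), typically the top <= 4.
#' @param cohort Cohort table restricted to visit-1 samples, aligned with the
#'   columns of `mat` via `sample_id`.
#' @param covariates As in [logistic_cwp()].
#' @return A `logistic_fit`.
#' @export
joint_logistic <- function(mat, bin_ids, cohort,
                           covariates = c("age", "bmi", "cotwin_status")) {
  if (anyDuplicated(bin_ids))
    stop("duplicated bin ids in joint model", call. = FALSE)
  stopifnot(all(bin_ids %in% rownames(mat)),
            all(cohort$sample_id %in% colnames(mat)))
  bv <- t(mat[bin_ids, cohort$sample_id, drop = FALSE])
  .fit_logistic(.logistic_frame(bv, cohort, covariates))
}

#' Proportion of methylation variance attributable to affection status
#'
#' One-way ANOVA eta-squared: `SS_between / SS_total` of methylation grouped
#' by affection status, in `[0, 1]`.
#'
#' @param values Methylation values.
#' @param status Binary affection status (0/1), same length.
#' @return Scalar eta-squared.
#' @export
anova_variance_explained <- function(values, status) {
  stopifnot(length(values) == length(status))
  ok <- stats::complete.cases(values, status)
  values <- values[ok]; status <- factor(status[ok])
  if (nlevels(status) < 2) stop("need both affection groups", call. = FALSE)
  if (stats::var(values) == 0)
    stop("zero total variance; eta-squared undefined", call. = FALSE)
  ss <- summary(stats::aov(values ~ status))[[1]][["Sum Sq"]]
  ss[1] / sum(ss)
}
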