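# Internal row-wise statistics used across the pipeline. Matrices are
# bins-in-rows, samples-in-columns throughout the package.

#' @keywords internal
#' @noRd
row_pearson <- function(X, Y) {
  stopifnot(identical(dim(X), dim(Y)))
  n <- ncol(X)
  cx <- X - rowMeans(X)
  cy <- Y - rowMeans(Y)
  sxy <- rowSums(cx * cy)
  sxx <- rowSums(cx * cx)
  syy <- rowSums(cy * cy)
  r <- sxy / sqrt(sxx * syy)
  r[sxx == 0 | syy == 0] <- NA_real_
  r
}

# two-sided p for a Pearson correlation via the t transform on n-2 df
#' @keywords internal
#' @noRd
pearson_p <- function(r, n) {
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
}

# per-row paired t from a matrix of within-pair differences (rows = bins,
# columns = pairs)
#' @keywords internal
#' @noRd
row_t_paired <- function(D) {
  k <- ncol(D)
  m <- rowMeans(D)
  s <- sqrt(rowSums((D - m)^2) / (k - 1))
  t <- m / (s / sqrt(k))
  # identical pair members: no difference at all -> t = 0, p = 1;
  # constant non-zero difference: statistic undefined
  t[s == 0 & m == 0] <- 0
  t[s == 0 & m != 0] <- NA_real_
  p <- 2 * stats::pt(abs(t), df = k - 1, lower.tail = FALSE)
  list(t = t, p = p, df = k - 1)
}

# per-row Welch two-sample t (rows = bins); X, Y have the two groups' samples
#' @keywords internal
#' @noRd
row_t_welch <- function(X, Y) {
  nx <- ncol(X)
  ny <- ncol(Y)
  mx <- rowMeans(X)
  my <- rowMeans(Y)
  vx <- rowSums((X - mx)^2) / (nx - 1)
  vy <- rowSums((Y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  bad <- se2 == 0
  t[bad] <- NA_real_
  p <- 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
  list(t = t, p = p, df = df)
}

# z-score columns-of-samples per row; zero-variance rows left centred
#' @keywords internal
#' @noRd
row_standardize <- function(X) {
  m <- rowMeans(X)
  s <- apply(X, 1L, stats::sd)
  s[s == 0] <- 1
  (X - m) / s
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
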