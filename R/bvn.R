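# Bivariate standard-normal orthant probabilities.
#
# The liability likelihood for a twin pair needs P(X > h, Y > k) for a
# bivariate standard normal with correlation rho, evaluated for hundreds of
# pairs per likelihood call, so the implementation is vectorized over (h, k)
# with a single quadrature rule shared by all pairs.  It uses the tetrachoric
# (Plackett) reduction
#   P(X > h, Y > k; rho) = Phi(-h) Phi(-k) + (1/2pi) *
#       int_0^{asin(rho)} exp(-(h^2 + k^2 - 2 h k sin t) / (2 cos^2 t)) dt
# integrated by Gauss-Legendre.  The sine substitution keeps the integrand
# smooth over the whole admissible range of rho; node count is chosen so the
# absolute error stays below 1e-10 for |rho| <= 0.99 (checked against a
# one-dimensional conditional-CDF oracle in the tests).

# Golub-Welsch Gauss-Legendre nodes/weights on [-1, 1]
#' @keywords internal
#' @noRd
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

.bvn_gl <- gauss_legendre(96)

#' Upper-orthant probability of a bivariate standard normal
#'
#' Computes `P(X > h, Y > k)` for `(X, Y)` bivariate standard normal with
#' correlation `rho`, vectorized over `h` and `k`.
#'
#' @param h,k Numeric vectors of thresholds (recycled to common length).
#' @param rho Scalar correlation in `(-1, 1)`.
#' @return Numeric vector of probabilities.
#' @examples
#' bvn_upper(0, 0, 0.5)     # 1/4 + asin(0.5)/(2*pi)
#' @export
bvn_upper <- function(h, k, rho) {
  stopifnot(length(rho) == 1L, is.finite(rho), abs(rho) < 1)
  n <- max(length(h), length(k))
  h <- rep_len(as.numeric(h), n)
  k <- rep_len(as.numeric(k), n)
  base <- stats::pnorm(-h) * stats::pnorm(-k)
  if (rho == 0) {
    return(base)
  }
  upper <- asin(rho)
  theta <- upper * (.bvn_gl$nodes + 1) / 2
  w <- .bvn_gl$weights * upper / 2
  hk <- h * k
  hk2 <- h^2 + k^2
  acc <- numeric(n)
  for (j in seq_along(theta)) {
    st <- sin(theta[j])
    c2 <- cos(theta[j])^2
    acc <- acc + w[j] * exp(-(hk2 - 2 * st * hk) / (2 * c2))
  }
  p <- base + acc / (2 * pi)
  pmin(pmax(p, 0), 1)
}

#' Status-combination probabilities for a twin pair
#'
#' Probabilities of the four affected/unaffected combinations of a twin pair
#' under the liability-threshold model: both liabilities exceed (or not) their
#' thresholds `t1`, `t2` with liability correlation `rho`.
#'
#' @param t1,t2 Threshold vectors on the standard-normal scale (one element
#'   per pair member; recycled).
#' @param rho Scalar liability correlation.
#' @return Matrix with columns `p11` (both affected), `p10`, `p01`, `p00`;
#'   rows sum to 1.
#' @export
bvn_orthants <- function(t1, t2, rho) {
  p11 <- bvn_upper(t1, t2, rho)
  p1 <- stats::pnorm(-t1)   # P(member 1 affected)
  p2 <- stats::pnorm(-t2)
  p10 <- pmax(p1 - p11, 0)
  p01 <- pmax(p2 - p11, 0)
  p00 <- pmax(1 - p1 - p2 + p11, 0)
  cbind(p11 = p11, p10 = p10, p01 = p01, p00 = p00)
}
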