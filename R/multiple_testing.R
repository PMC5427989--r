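# Multiple-testing correction for correlated bins: the effective number of
# independent tests from eigenvalues of the inter-bin correlation matrix
# (Li & Ji-style counting), the resulting epigenome-wide threshold, and
# false-discovery-rate control valid under dependency.

#' Effective number of independent tests from bin correlations
#'
#' Overlapping and neighbouring bins are strongly correlated, so the raw bin
#' count overstates the number of independent tests.  Each eigenvalue
#' `lambda` of the bin correlation matrix contributes
#' `f(lambda) = 1(lambda >= 1) + (lambda - floor(lambda))` to the effective
#' count; an eigenvalue of 1 (independent bin) counts fully, a large
#' eigenvalue absorbing many correlated bins counts once plus its fractional
#' remainder.  For tractability at epigenome scale the matrix is processed in
#' contiguous coordinate blocks that never span chromosomes (long-range
#' inter-chromosome methylation correlation is treated as negligible), and
#' block contributions are summed.
#'
#' @param mat Bins-by-samples matrix over the tested bins, ordered by genomic
#'   coordinate (rownames `chrom_start`).
#' @param block_size Maximum bins per eigendecomposition block (default 5000).
#' @param alpha Per-study significance level (default 0.05).
#' @param chrom Optional chromosome per bin; parsed from rownames when `NULL`.
#' @return List of class `meff_result`: `block_meff`, `total_meff`, `alpha`,
#'   `threshold` (`alpha / total_meff`), `block_size`, `n_bins`,
#'   `n_dropped` (zero-variance bins).
#' @export
effective_tests <- function(mat, block_size = 5000L, alpha = 0.05,
                            chrom = NULL) {
  if (!is.matrix(mat) || nrow(mat) < 2)
    stop("need at least 2 bins", call. = FALSE)
  sds <- apply(mat, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance bin(s) dropped from Meff")
    mat <- mat[sds > 0, , drop = FALSE]
    if (nrow(mat) < 2) stop("fewer than 2 variable bins", call. = FALSE)
  }
  if (is.null(chrom))
    chrom <- sub("_[0-9]+$", "", rownames(mat) %||% rep("chr", nrow(mat)))
  idx <- seq_len(nrow(mat))
  blocks <- unlist(lapply(split(idx, factor(chrom, unique(chrom))),
                          function(ii) split(ii, ceiling(seq_along(ii) / block_size))),
                   recursive = FALSE)
  block_meff <- vapply(blocks, function(ii) {
    if (length(ii) == 1L) return(1)
    lam <- eigen(stats::cor(t(mat[ii, , drop = FALSE])),
                 symmetric = TRUE, only.values = TRUE)$values
    # clamp numerical dust and snap to integers so the fractional-part rule
    # is stable at exact eigenvalue multiplicities (e.g. rank-1 blocks)
    lam <- round(pmax(abs(lam), 0), 9)
    min(sum((lam >= 1) + (lam - floor(lam))), length(ii))
  }, numeric(1))
  total <- min(sum(block_meff), nrow(mat))
  structure(list(block_meff = unname(block_meff), total_meff = total,
                 alpha = alpha, threshold = alpha / total,
                 block_size = block_size, n_bins = nrow(mat),
                 n_dropped = sum(sds == 0)),
            class = "meff_result")
}

#' @export
print.meff_result <- function(x, ...) {
  cat(sprintf("Effective number of tests: %.1f of %d bins (%d block(s))\n",
              x$total_meff, x$n_bins, length(x$block_meff)))
  cat(sprintf("  per-test threshold at alpha = %g: %.4g\n",
              x$alpha, x$threshold))
  invisible(x)
}

#' Epigenome-wide per-test significance level
#'
#' @param meff A `meff_result` or a numeric effective test count.
#' @param alpha Study-wide level; defaults to the level stored in `meff`
#'   (0.05 for a numeric `meff`).
#' @return `alpha / total_meff`.
#' @export
genomewide_threshold <- function(meff, alpha = NULL) {
  if (inherits(meff, "meff_result")) {
    alpha <- alpha %||% meff$alpha
    meff <- meff$total_meff
  }
  alpha <- alpha %||% 0.05
  stopifnot(meff >= 1)
  alpha / meff
}

#' False discovery rate under dependency (Benjamini-Yekutieli)
#'
#' Step-up adjustment `q_(i) = min_{j >= i} p_(j) * m * c(m) / j` with
#' `c(m) = sum_{k=1..m} 1/k`, valid under arbitrary dependence between
#' tests; output order matches input order.
#'
#' @param p P-values in (0, 1].
#' @return Adjusted q-values, capped at 1.
#' @export
fdr_dependency <- function(p) {
  if (any(!is.na(p) & (p <= 0 | p > 1)))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BY")
}
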