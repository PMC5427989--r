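# Bin-level QC and longitudinal stability.
#
# The analysis restricts itself to bins that (1) are non-zero in most
# individuals and (2) are longitudinally stable within individuals measured
# years apart ("lsBINs"), on the rationale that a chronic condition should
# associate with persistent, not transient, methylation differences.

#' Exclude bins with too many zero values
#'
#' Removes every bin whose fraction of exactly-zero entries is at least
#' `max_zero_fraction` (default: bins with zeros in >= 20% of individuals are
#' excluded).
#'
#' @param mat Bins-by-samples methylation matrix.
#' @param max_zero_fraction Exclusion threshold on the per-bin zero fraction.
#' @return List with `matrix` (retained bins) and `report`
#'   (`n_input`, `n_removed`, `n_retained`, `retained_pct`).
#' @export
zero_fraction_filter <- function(mat, max_zero_fraction = 0.20) {
  if (!is.matrix(mat) || nrow(mat) == 0 || ncol(mat) == 0)
    stop("empty methylation matrix", call. = FALSE)
  zf <- rowMeans(mat == 0)
  keep <- zf < max_zero_fraction
  list(matrix = mat[keep, , drop = FALSE],
       report = list(n_input = nrow(mat),
                     n_removed = sum(!keep),
                     n_retained = sum(keep),
                     retained_pct = retained_percent(nrow(mat), sum(keep))))
}

#' Percentage retained by a filtering step
#'
#' @param n_input,n_retained Counts before and after the filter.
#' @return `100 * n_retained / n_input`.
#' @export
retained_percent <- function(n_input, n_retained) {
  stopifnot(n_input > 0, n_retained >= 0, n_retained <= n_input)
  100 * n_retained / n_input
}

#' Per-bin test-retest correlation and lsBIN flags
#'
#' Pearson correlation of each bin between two visits of the same
#' individuals, with a two-sided p-value from the t transform
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`.  A bin is a longitudinally stable
#' bin (lsBIN) when `p < p_threshold` and `r > 0`.
#'
#' @param visit1,visit2 Bins-by-individuals matrices with columns paired by
#'   position (same individual in the same column of both).
#' @param gap_years Optional per-individual gap between the visits in years;
#'   individuals with gap below `min_gap_years` are dropped.
#' @param min_gap_years Minimum admissible gap (default 3 years).
#' @param p_threshold Significance level of the stability test.
#' @return `data.frame` with `bin`, `r_repeat`, `p_repeat`, `n_repeat`,
#'   `is_lsbin`.  Zero-variance bins get `NA` correlation and are not lsBINs.
#' @export
repeat_correlation <- function(visit1, visit2, gap_years = NULL,
                               min_gap_years = 3.0, p_threshold = 0.05) {
  stopifnot(identical(dim(visit1), dim(visit2)))
  if (!is.null(gap_years)) {
    stopifnot(length(gap_years) == ncol(visit1))
    use <- gap_years >= min_gap_years
    visit1 <- visit1[, use, drop = FALSE]
    visit2 <- visit2[, use, drop = FALSE]
  }
  n <- ncol(visit1)
  if (n < 3) stop("need at least 3 repeat-measured individuals", call. = FALSE)
  r <- row_pearson(visit1, visit2)
  p <- pearson_p(r, n)
  data.frame(bin = rownames(visit1) %||% seq_len(nrow(visit1)),
             r_repeat = r, p_repeat = p, n_repeat = n,
             is_lsbin = !is.na(r) & p < p_threshold & r > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

# split a cohort's visit-1 samples into twin-pair column index pairs
#' @keywords internal
#' @noRd
.twin_pairs <- function(cohort, zyg) {
  v1 <- cohort[cohort$visit == 1 & cohort$zygosity == zyg, ]
  fams <- split(v1$sample_id, v1$family_id)
  fams <- fams[lengths(fams) == 2L]
  if (!length(fams)) return(NULL)
  do.call(rbind, fams)
}

#' Per-bin twin correlations (MZ and DZ separately)
#'
#' Pearson correlation of each bin across complete MZ pairs and across
#' complete DZ pairs, computed on visit-1 samples.  Which member of a pair is
#' "twin 1" is randomized once per call (seeded), since the labelling is
#' arbitrary and a fixed ordering could introduce artifacts.
#'
#' @param mat Bins-by-samples matrix (columns named by `sample_id`).
#' @param cohort Cohort table.
#' @param bins Optional bin ids to restrict to (e.g. the lsBIN set).
#' @param seed Seed for the member-ordering randomization.
#' @return `data.frame` with `bin`, `r_mz`, `n_mz`, `r_dz`, `n_dz`.
#' @export
twin_correlations <- function(mat, cohort, bins = NULL, seed = 1L) {
  if (!is.null(bins)) mat <- mat[rownames(mat) %in% bins, , drop = FALSE]
  prs <- list(MZ = .twin_pairs(cohort, "MZ"), DZ = .twin_pairs(cohort, "DZ"))
  if (any(vapply(prs, function(p) is.null(p) || nrow(p) < 3, TRUE)))
    stop("need at least 3 complete pairs per zygosity group", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  res <- lapply(prs, function(p) {
    flip <- stats::runif(nrow(p)) < 0.5
    first <- ifelse(flip, p[, 2], p[, 1])
    second <- ifelse(flip, p[, 1], p[, 2])
    list(r = row_pearson(mat[, first, drop = FALSE],
                         mat[, second, drop = FALSE]),
         n = nrow(p))
  })
  data.frame(bin = rownames(mat) %||% seq_len(nrow(mat)),
             r_mz = res$MZ$r, n_mz = res$MZ$n,
             r_dz = res$DZ$r, n_dz = res$DZ$n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Dependence of twin correlations on longitudinal stability
#'
#' Correlates per-bin twin correlations (`r_mz`, `r_dz`) and their ratio
#' `r_mz / r_dz` with the test-retest correlation `r_repeat` across bins.  A
#' positive dependence indicates that more longitudinally stable bins are
#' more heritable.  The ratio is only computed for bins with
#' `r_dz >= ratio_min_rdz` to avoid division blow-up.
#'
#' @param twin Result of [twin_correlations()].
#' @param stability Result of [repeat_correlation()] on the same bins.
#' @param ratio_min_rdz Minimum `r_dz` for the ratio (default 0.05).
#' @return `data.frame` with one row per relation (`mz`, `dz`, `ratio`):
#'   correlation with `r_repeat`, p-value, number of bins used; plus an
#'   attribute `n_ratio_excluded`.
#' @export
stability_dependence <- function(twin, stability, ratio_min_rdz = 0.05) {
  m <- merge(twin, stability[, c("bin", "r_repeat")], by = "bin")
  if (nrow(m) < 3) stop("need at least 3 aligned bins", call. = FALSE)
  if (stats::sd(m$r_repeat, na.rm = TRUE) == 0)
    stop("r_repeat constant across bins; dependence undefined", call. = FALSE)
  one <- function(y, x) {
    ok <- is.finite(y) & is.finite(x)
    r <- stats::cor(y[ok], x[ok])
    c(cor = r, p = pearson_p(r, sum(ok)), n = sum(ok))
  }
  ratio_ok <- is.finite(m$r_dz) & m$r_dz >= ratio_min_rdz
  ratio <- ifelse(ratio_ok, m$r_mz / m$r_dz, NA_real_)
  out <- rbind(mz = one(m$r_mz, m$r_repeat),
               dz = one(m$r_dz, m$r_repeat),
               ratio = one(ratio, m$r_repeat))
  out <- data.frame(relation = rownames(out), out, row.names = NULL)
  attr(out, "n_ratio_excluded") <- sum(!ratio_ok)
  out
}
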