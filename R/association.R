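# Two-stage EWAS: discovery in disease-discordant MZ twin pairs (paired t
# test; genetic and shared-environment effects cancel within pair), then
# replication in the remaining sample (Welch t on age-adjusted values), then
# Fisher combination restricted to bins that are nominally significant in
# both stages with the same direction of effect.

#' Select disease-discordant MZ pairs for discovery
#'
#' Picks up to `n_pairs` MZ pairs whose members differ in affection status,
#' deterministically for a given seed.
#'
#' @param cohort Cohort table.
#' @param n_pairs Number of discovery pairs (default 50).
#' @param seed Seed for the (deterministic) pair selection.
#' @return `data.frame` with `family_id`, `affected`, `unaffected`
#'   (sample ids of visit-1 samples).
#' @export
select_discordant_pairs <- function(cohort, n_pairs = 50L, seed = 1L) {
  v1 <- cohort[cohort$visit == 1 & cohort$zygosity == "MZ", ]
  sp <- split(v1, v1$family_id)
  disc <- Filter(function(f) nrow(f) == 2 && sum(f$cwp) == 1, sp)
  if (length(disc) < 2)
    stop("fewer than 2 CWP-discordant MZ pairs", call. = FALSE)
  pairs <- data.frame(
    family_id = vapply(disc, function(f) f$family_id[1], ""),
    affected = vapply(disc, function(f) f$sample_id[f$cwp == 1], ""),
    unaffected = vapply(disc, function(f) f$sample_id[f$cwp == 0], ""),
    row.names = NULL, stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$family_id), ]
  if (nrow(pairs) > n_pairs) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    pairs <- pairs[sort(sample(nrow(pairs), n_pairs)), ]
  }
  rownames(pairs) <- NULL
  pairs
}

#' Discovery: paired t test in discordant MZ pairs
#'
#' For each bin, tests the within-pair difference (affected minus unaffected)
#' against zero.  Positive t means higher methylation in the affected twin.
#'
#' @param mat Bins-by-samples matrix.
#' @param pairs Result of [select_discordant_pairs()].
#' @return `data.frame` with `bin`, `t_disc`, `p_disc`, `n_disc_pairs`,
#'   `sign` (sign of `t_disc`; `NA` for zero-variance differences).
#' @export
discover_discordant <- function(mat, pairs) {
  if (nrow(pairs) < 2) stop("need at least 2 discordant pairs", call. = FALSE)
  D <- mat[, pairs$affected, drop = FALSE] - mat[, pairs$unaffected, drop = FALSE]
  tt <- row_t_paired(D)
  data.frame(bin = rownames(mat) %||% seq_len(nrow(mat)),
             t_disc = tt$t, p_disc = tt$p, n_disc_pairs = nrow(pairs),
             sign = sign(tt$t),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Adjust methylation for age and age squared
#'
#' Replaces each bin's values by the residuals of an ordinary least-squares
#' fit on intercept, age and age^2 (the methylation-age relationship is
#' nonlinear).  Residuals are orthogonal to both regressors.
#'
#' @param mat Bins-by-samples matrix.
#' @param age Age per column of `mat`.
#' @return Adjusted matrix of the same shape.
#' @export
adjust_age <- function(mat, age) {
  stopifnot(length(age) == ncol(mat), !anyNA(age))
  if (stats::sd(age) == 0)
    stop("age constant across samples; adjustment is collinear", call. = FALSE)
  X <- cbind(1, age, age^2)
  qx <- qr(X)
  if (qx$rank < 3L)
    stop("age design matrix is rank-deficient", call. = FALSE)
  coefs <- t(qr.coef(qx, t(mat)))          # bins x 3
  res <- mat - coefs %*% t(X)
  dimnames(res) <- dimnames(mat)
  res
}

#' Replication: Welch t test, affected vs unaffected
#'
#' Two-sample (unequal-variance) t test of adjusted methylation between
#' affected and unaffected individuals of the replication sample.  Positive t
#' means higher methylation in the affected group, matching the discovery
#' sign convention.
#'
#' @param mat Bins-by-samples matrix (typically age-adjusted).
#' @param cohort Cohort table.
#' @param exclude_samples Sample ids to leave out (the discovery
#'   individuals); replication and discovery sets must be disjoint.
#' @return `data.frame` with `bin`, `t_rep`, `p_rep`, `n_rep`, `sign_rep`.
#' @export
replicate_ewas <- function(mat, cohort, exclude_samples = character(0)) {
  v1 <- cohort[cohort$visit == 1 & !(cohort$sample_id %in% exclude_samples), ]
  aff <- v1$sample_id[v1$cwp == 1]
  una <- v1$sample_id[v1$cwp == 0]
  if (length(aff) < 2 || length(una) < 2)
    stop("replication needs >= 2 samples per affection group", call. = FALSE)
  tt <- row_t_welch(mat[, aff, drop = FALSE], mat[, una, drop = FALSE])
  data.frame(bin = rownames(mat) %||% seq_len(nrow(mat)),
             t_rep = tt$t, p_rep = tt$p, n_rep = length(aff) + length(una),
             sign_rep = sign(tt$t),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Direction-concordant Fisher combination of two p-values
#'
#' Combines discovery and replication p-values by Fisher's method,
#' `chi2 = -2 (log p1 + log p2)` on 4 degrees of freedom, restricted to bins
#' that are nominally significant (`p < p_gate`) in both stages with the same
#' direction of effect.  Bins failing the gate keep their component
#' statistics but get `NA` combined fields.
#'
#' @param p_disc,p_rep P-value vectors in (0, 1].
#' @param sign_disc,sign_rep Direction of effect per stage (+1/-1).
#' @param p_gate Nominal-significance gate (default 0.05).
#' @param gate If `FALSE`, combine every bin regardless of significance or
#'   direction (diagnostic mode).
#' @return `data.frame` with `direction_concordant`, `combined`,
#'   `chi2_fisher`, `p_fisher`.
#' @export
fisher_combine <- function(p_disc, p_rep, sign_disc, sign_rep,
                           p_gate = 0.05, gate = TRUE) {
  ok <- stats::complete.cases(p_disc, p_rep)
  if (any(p_disc[ok] <= 0 | p_disc[ok] > 1 | p_rep[ok] <= 0 | p_rep[ok] > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  concord <- sign_disc == sign_rep & sign_disc != 0
  combined <- if (gate) ok & concord & p_disc < p_gate & p_rep < p_gate
              else ok
  chi2 <- ifelse(combined, -2 * (log(p_disc) + log(p_rep)), NA_real_)
  pf <- stats::pchisq(chi2, df = 4, lower.tail = FALSE)
  data.frame(direction_concordant = concord, combined = combined,
             chi2_fisher = chi2, p_fisher = pf,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the two-stage EWAS over a bin set
#'
#' Convenience wrapper: selects discovery pairs, runs the paired t discovery,
#' age-adjusts the replication sample, runs the Welch replication, and
#' combines by the direction-gated Fisher method.
#'
#' @param mat Bins-by-samples matrix (restricted to lsBINs by the caller).
#' @param cohort Cohort table.
#' @param n_pairs Number of discovery pairs.
#' @param p_gate Nominal-significance gate for the combination.
#' @param seed Seed for discovery-pair selection.
#' @return `data.frame` of per-bin association records; attributes
#'   `n_combined_gated` and `n_combined_concordant_only` carry the gated and
#'   direction-only counts.
#' @export
run_ewas <- function(mat, cohort, n_pairs = 50L, p_gate = 0.05, seed = 1L) {
  pairs <- select_discordant_pairs(cohort, n_pairs = n_pairs, seed = seed)
  disc_samples <- c(pairs$affected, pairs$unaffected)
  disc_ind <- cohort$individual_id[match(disc_samples, cohort$sample_id)]
  disc <- discover_discordant(mat, pairs)
  rep_cohort <- cohort[!(cohort$individual_id %in% disc_ind), ]
  rep_v1 <- rep_cohort[rep_cohort$visit == 1, ]
  stopifnot(length(intersect(rep_v1$sample_id, disc_samples)) == 0)
  adj <- adjust_age(mat[, rep_v1$sample_id, drop = FALSE], rep_v1$age)
  repl <- replicate_ewas(adj, rep_v1)
  comb <- fisher_combine(disc$p_disc, repl$p_rep, disc$sign, repl$sign_rep,
                         p_gate = p_gate)
  out <- cbind(disc, repl[, c("t_rep", "p_rep", "n_rep", "sign_rep")], comb)
  attr(out, "n_combined_gated") <- sum(out$combined, na.rm = TRUE)
  attr(out, "n_combined_concordant_only") <-
    sum(out$direction_concordant, na.rm = TRUE)
  attr(out, "discovery_samples") <- disc_samples
  out
}

#' Top-ranked combined association records
#'
#' Sorts combined records by ascending Fisher p-value, breaking ties by
#' larger `chi2_fisher`, then by bin id, and returns the top `k`.
#'
#' @param records [run_ewas()]-style `data.frame`.
#' @param k Number of records to return (default 24).
#' @return Sorted `data.frame` of at most `k` combined records.
#' @export
rank_top <- function(records, k = 24L) {
  comb <- records[!is.na(records$p_fisher) & records$combined, , drop = FALSE]
  if (nrow(comb) == 0) return(comb)
  ord <- order(comb$p_fisher, -abs(comb$chi2_fisher), comb$bin)
  out <- comb[ord, , drop = FALSE][seq_len(min(k, nrow(comb))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
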