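# End-to-end orchestration: QC -> stability -> twin correlations ->
# discovery -> replication -> Fisher combination -> multiple-testing
# correction -> top-k -> logistic models -> liability decomposition.
# Every stage writes a plain-text artifact (TSV/JSON) plus a stage summary
# with input/output counts; identical config + seed gives byte-identical
# artifacts.

#' Pipeline configuration
#'
#' @param bins_path,matrix_path,cohort_path Input files (BED3, TSV matrix,
#'   cohort CSV; see [write_cohort_inputs()] for the formats).
#' @param out_dir Output directory for stage artifacts.
#' @param zero_fraction Bin-exclusion threshold on the zero fraction.
#' @param lsbin_p Significance level of the longitudinal-stability test.
#' @param nominal_p Nominal gate for discovery/replication combination.
#' @param alpha Study-wide significance level for the effective-tests
#'   threshold.
#' @param n_discovery_pairs Discordant MZ pairs used for discovery.
#' @param meff_block_size Block size of the effective-tests
#'   eigendecomposition.
#' @param top_k Number of top combined bins to report.
#' @param n_model_bins Top bins entering the logistic and liability models.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(bins_path, matrix_path, cohort_path,
                            out_dir = "twinewas_run",
                            zero_fraction = 0.20, lsbin_p = 0.05,
                            nominal_p = 0.05, alpha = 0.05,
                            n_discovery_pairs = 50L,
                            meff_block_size = 500L,
                            top_k = 24L, n_model_bins = 4L, seed = 1L) {
  stopifnot(zero_fraction > 0, zero_fraction < 1,
            lsbin_p > 0, lsbin_p < 1, nominal_p > 0, nominal_p < 1,
            alpha > 0, alpha < 1)
  structure(list(bins_path = bins_path, matrix_path = matrix_path,
                 cohort_path = cohort_path, out_dir = out_dir,
                 zero_fraction = zero_fraction, lsbin_p = lsbin_p,
                 nominal_p = nominal_p, alpha = alpha,
                 n_discovery_pairs = as.integer(n_discovery_pairs),
                 meff_block_size = as.integer(meff_block_size),
                 top_k = as.integer(top_k),
                 n_model_bins = as.integer(n_model_bins),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @keywords internal
#' @noRd
.fwrite_tsv <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 10))  # stable text output
  data.table::fwrite(df, path, sep = "\t", na = "NA")
}

#' Run the full analysis pipeline
#'
#' Executes all stages on the configured inputs and writes per-stage
#' artifacts under `config$out_dir`: `stability.tsv`, `twincorr.tsv`,
#' `ewas.tsv`, `top_bins.tsv`, `meff.json`, `models.tsv`, `liability.json`
#' and `stage_summary.json`.  Any stage error aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   artifact directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "read_inputs"
  res <- try({
    inp <- read_bin_matrix(config$bins_path, config$matrix_path)
    cohort <- read_cohort_csv(config$cohort_path)
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    summary_log <- list()
    v1 <- cohort[cohort$visit == 1, ]

    stage <- "qc"
    qc <- zero_fraction_filter(inp$matrix[, v1$sample_id, drop = FALSE],
                               max_zero_fraction = config$zero_fraction)
    mat <- inp$matrix[rownames(qc$matrix), , drop = FALSE]
    summary_log$qc <- qc$report

    stage <- "stability"
    rep_ind <- cohort$individual_id[cohort$visit == 2]
    s1 <- cohort$sample_id[cohort$visit == 1][
      match(rep_ind, cohort$individual_id[cohort$visit == 1])]
    s2 <- cohort$sample_id[cohort$visit == 2][
      match(rep_ind, cohort$individual_id[cohort$visit == 2])]
    gap <- cohort$visit_year[match(s2, cohort$sample_id)] -
      cohort$visit_year[match(s1, cohort$sample_id)]
    stab <- repeat_correlation(mat[, s1, drop = FALSE], mat[, s2, drop = FALSE],
                               gap_years = gap, p_threshold = config$lsbin_p)
    .fwrite_tsv(stab, file.path(config$out_dir, "stability.tsv"))
    lsbins <- stab$bin[stab$is_lsbin]
    summary_log$stability <- list(n_input = nrow(stab),
                                  n_lsbin = length(lsbins),
                                  n_repeat_individuals = length(rep_ind))

    stage <- "twincorr"
    twin <- twin_correlations(mat[lsbins, , drop = FALSE], cohort,
                              seed = config$seed + 1L)
    .fwrite_tsv(twin, file.path(config$out_dir, "twincorr.tsv"))
    summary_log$twincorr <- list(n_bins = nrow(twin),
                                 n_mz = twin$n_mz[1], n_dz = twin$n_dz[1],
                                 mean_r_mz = mean(twin$r_mz, na.rm = TRUE),
                                 mean_r_dz = mean(twin$r_dz, na.rm = TRUE))

    stage <- "ewas"
    lsmat <- mat[lsbins, v1$sample_id, drop = FALSE]
    ewas <- run_ewas(lsmat, cohort, n_pairs = config$n_discovery_pairs,
                     p_gate = config$nominal_p, seed = config$seed + 2L)
    summary_log$ewas <- list(
      n_bins = nrow(ewas),
      n_disc_nominal = sum(ewas$p_disc < config$nominal_p, na.rm = TRUE),
      n_rep_nominal = sum(ewas$p_rep < config$nominal_p, na.rm = TRUE),
      n_combined_gated = attr(ewas, "n_combined_gated"),
      n_concordant = attr(ewas, "n_combined_concordant_only"))

    stage <- "correct"
    meff <- effective_tests(lsmat, block_size = config$meff_block_size,
                            alpha = config$alpha)
    ewas$q_fisher <- NA_real_
    comb <- which(ewas$combined)
    if (length(comb))
      ewas$q_fisher[comb] <- fdr_dependency(ewas$p_fisher[comb])
    .fwrite_tsv(ewas, file.path(config$out_dir, "ewas.tsv"))
    jsonlite::write_json(
      list(alpha = config$alpha, block_size = config$meff_block_size,
           n_bins = meff$n_bins, meff_total = meff$total_meff,
           threshold = meff$threshold, block_meff = meff$block_meff),
      file.path(config$out_dir, "meff.json"), auto_unbox = TRUE, digits = NA)
    summary_log$correct <- list(meff_total = meff$total_meff,
                                threshold = meff$threshold)

    stage <- "rank"
    top <- rank_top(ewas, k = config$top_k)
    .fwrite_tsv(top, file.path(config$out_dir, "top_bins.tsv"))
    summary_log$rank <- list(n_top = nrow(top))

    stage <- "models"
    model_bins <- utils::head(top$bin, config$n_model_bins)
    models <- NULL
    if (length(model_bins) >= 1) {
      per_bin <- lapply(model_bins, function(b) {
        f <- logistic_cwp(lsmat[b, v1$sample_id], v1)
        cbind(model = b, f$terms, n = f$n, converged = f$converged)
      })
      models <- do.call(rbind, per_bin)
      if (length(model_bins) >= 2) {
        jf <- joint_logistic(lsmat, model_bins, v1)
        models <- rbind(models, cbind(model = "joint", jf$terms, n = jf$n,
                                      converged = jf$converged))
      }
      eta2 <- vapply(model_bins, function(b)
        anova_variance_explained(lsmat[b, v1$sample_id], v1$cwp), numeric(1))
      summary_log$models <- list(n_bins = length(model_bins),
                                 eta2_pct = as.list(100 * eta2))
      .fwrite_tsv(models, file.path(config$out_dir, "models.tsv"))
    } else summary_log$models <- list(n_bins = 0L)

    stage <- "liability"
    liab <- NULL
    if (length(model_bins) >= 1) {
      meth_top <- lsmat[model_bins, , drop = FALSE]
      full <- fit_liability(cohort, meth = meth_top)
      reduced <- fit_liability(cohort, meth = meth_top, fix_a2 = 0)
      lrt <- lrt_vad(full, reduced)
      liab <- list(full = full, reduced = reduced, lrt = lrt,
                   report = variance_report(full))
      jsonlite::write_json(
        list(a2 = full$a2, se_a2 = full$se_a2,
             beta = as.list(full$beta), gamma = as.list(full$gamma),
             fractions = list(AGF = full$fractions$AGF,
                              EGF = full$fractions$EGF,
                              RES = full$fractions$RES),
             loglik = full$loglik,
             lrt = list(stat = lrt$stat, p = lrt$p)),
        file.path(config$out_dir, "liability.json"),
        auto_unbox = TRUE, digits = NA)
      summary_log$liability <- list(a2 = full$a2, lrt_p = lrt$p)
    }

    jsonlite::write_json(summary_log,
                         file.path(config$out_dir, "stage_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    list(out_dir = config$out_dir, summary = summary_log, stability = stab,
         twin = twin, ewas = ewas, meff = meff, top = top, models = models,
         liability = liab)
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop("pipeline stage '", stage, "' failed: ",
         attr(res, "condition")$message, call. = FALSE)
  invisible(res)
}
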