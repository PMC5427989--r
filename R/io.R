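# Plain-text pipeline I/O: BED3 bin definitions, TSV methylation matrix
# (bins in rows, one column per sample-visit), cohort CSV, JSON reports.

#' Read a BED3 bin-definition file
#'
#' Bins are 0-based half-open intervals. Under `strict = TRUE` the grid is
#' validated as 500 bp bins on a 250 bp step (`end - start == 500`,
#' `start %% 250 == 0`); a 1-based file (starts not divisible by 250) is
#' rejected with a coordinate-convention hint.
#'
#' @param path BED3 file path.
#' @param strict Validate the 500 bp / 250 bp grid.
#' @return `data.frame` with columns `chrom`, `start`, `end`.
#' @export
read_bed3 <- function(path, strict = TRUE) {
  bins <- data.table::fread(path, header = FALSE, sep = "\t",
                            col.names = c("chrom", "start", "end"),
                            data.table = FALSE)
  if (nrow(bins) == 0) stop("empty BED file: ", path, call. = FALSE)
  if (strict) {
    w <- bins$end - bins$start
    bad <- which(w != 500L)
    if (length(bad))
      stop("BED line ", bad[1], ": bin width ", w[bad[1]],
           " != 500 (strict grid)", call. = FALSE)
    off <- which(bins$start %% 250L != 0L)
    if (length(off))
      stop("BED line ", off[1], ": start ", bins$start[off[1]],
           " not on the 250 bp grid; coordinates must be 0-based half-open ",
           "(a 1-based file would show starts offset by 1)", call. = FALSE)
  }
  bins
}

#' @rdname read_bed3
#' @param bins Bin `data.frame` (`chrom`, `start`, `end`).
#' @export
write_bed3 <- function(bins, path) {
  data.table::fwrite(bins[, c("chrom", "start", "end")], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read or write a bin-by-sample methylation matrix as TSV
#'
#' First column `bin` holds the bin id `chrom_start`; remaining columns are
#' samples. `read_bin_matrix()` pairs the TSV with a BED3 file and checks the
#' row ids against the bin grid.
#'
#' @param mat Numeric matrix, bins in rows (rownames = bin ids).
#' @param path TSV file path.
#' @export
write_matrix_tsv <- function(mat, path) {
  dt <- data.table::data.table(bin = rownames(mat))
  # 17 significant digits so every double round-trips exactly through text
  chr <- data.table::as.data.table(
    lapply(seq_len(ncol(mat)), function(j) sprintf("%.17g", mat[, j])))
  data.table::setnames(chr, colnames(mat))
  data.table::fwrite(cbind(dt, chr), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  mat <- as.matrix(dt[, -1, drop = FALSE])
  rownames(mat) <- dt[[1]]
  mat
}

#' @rdname write_matrix_tsv
#' @param bed_path,tsv_path Paths to the BED3 bin file and the matrix TSV.
#' @param strict Passed to [read_bed3()].
#' @return `read_bin_matrix()`: list with `bins` and `matrix`.
#' @export
read_bin_matrix <- function(bed_path, tsv_path, strict = TRUE) {
  bins <- read_bed3(bed_path, strict = strict)
  mat <- read_matrix_tsv(tsv_path)
  expected <- paste(bins$chrom, bins$start, sep = "_")
  if (!identical(rownames(mat), expected)) {
    bad <- which(rownames(mat) != expected)[1]
    stop("matrix row ", bad, " id '", rownames(mat)[bad],
         "' does not match BED bin '", expected[bad], "'", call. = FALSE)
  }
  list(bins = bins, matrix = mat)
}

#' Read or write the cohort table as CSV
#'
#' One row per sample-visit with columns `sample_id`, `individual_id`,
#' `family_id`, `zygosity` (MZ/DZ/SGL), `cwp` (0/1), `age`, `bmi`, `smoking`
#' (never/ex/current/NA), WBC counts (`neut`, `eos`, `mono`, `lymph`),
#' `visit`, `visit_year` and `cotwin_cwp` (the cotwin's affection status,
#' recorded also for singletons).
#'
#' @param cohort Cohort `data.frame`.
#' @param path CSV file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  data.table::fwrite(cohort, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  ch <- data.table::fread(path, data.table = FALSE)
  req <- c("sample_id", "individual_id", "family_id", "zygosity", "cwp",
           "age", "visit")
  miss <- setdiff(req, names(ch))
  if (length(miss))
    stop("cohort CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ch
}

#' Write all inputs of a simulated cohort to a directory
#'
#' Writes `bins.bed` (BED3), `methylation.tsv`, `cohort.csv` and
#' `truth.json`, the standard pipeline input formats.
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_cohort_inputs <- function(sim, dir) {
  stopifnot(inherits(sim, "twin_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bed3(sim$bins, file.path(dir, "bins.bed"))
  write_matrix_tsv(sim$matrix, file.path(dir, "methylation.tsv"))
  write_cohort_csv(sim$cohort, file.path(dir, "cohort.csv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
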