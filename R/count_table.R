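#' Construct an ASV count table
#'
#' The community object flowing through filtering, merging, diversity and
#' network stages: a samples x ASVs matrix of non-negative integer read
#' counts with optional per-sample metadata (habitat location and reactor).
#'
#' @param counts numeric matrix, samples in rows, ASVs in columns,
#'   non-negative integers. Row and column names are used as sample and ASV
#'   ids; defaults are generated when absent.
#' @param sample_meta optional data.frame with one row per sample; typical
#'   columns are `location` (anode / cathode / suspension) and `reactor`.
#' @return An object of class `mec_count_table`: a list with `counts`
#'   (integer matrix) and `sample_meta`.
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("S", 1:3), paste0("ASV", 1:4)))
#' count_table(m)
#' @export
count_table <- function(counts, sample_meta = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop("empty count table")
  if (anyNA(counts)) stop("count table contains missing values")
  if (any(counts < 0)) stop("count table contains negative counts")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("count table must contain integer counts")
  storage.mode(counts) <- "double"
  counts <- round(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)) && ncol(counts) > 0)
    colnames(counts) <- paste0("ASV", seq_len(ncol(counts)))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate ASV ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids")
  if (!is.null(sample_meta)) {
    sample_meta <- as.data.frame(sample_meta)
    if (nrow(sample_meta) != nrow(counts))
      stop("sample_meta must have one row per sample")
    rownames(sample_meta) <- rownames(counts)
  }
  structure(list(counts = counts, sample_meta = sample_meta),
            class = "mec_count_table")
}

#' @export
print.mec_count_table <- function(x, ...) {
  cat("ASV count table:", nrow(x$counts), "samples x", ncol(x$counts),
      "ASVs\n")
  cat("  reads per sample: median", format(stats::median(rowSums(x$counts))),
      "\n")
  if (!is.null(x$sample_meta) && "location" %in% names(x$sample_meta)) {
    tab <- table(x$sample_meta$location)
    cat("  locations:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Per-sample relative abundances
#'
#' @param table a `mec_count_table` or counts matrix (samples x ASVs).
#' @return matrix of proportions; each row sums to 1 (all-zero rows stay 0).
#' @export
relative_abundance <- function(table) {
  m <- if (inherits(table, "mec_count_table")) table$counts else as.matrix(table)
  rs <- rowSums(m)
  rs[rs == 0] <- 1
  m / rs
}

#' Read an ASV count table from TSV
#'
#' Expects ASVs in rows and samples in columns (the conventional amplicon
#' layout), with a header row of sample ids and the first column holding ASV
#' ids. The returned object is transposed to the internal samples x ASVs
#' orientation. Non-integer or negative counts, duplicate ids, and ragged
#' rows are rejected with the offending line number.
#'
#' @param path TSV file path.
#' @param sample_meta optional per-sample metadata data.frame.
#' @return a `mec_count_table`.
#' @export
read_count_table <- function(path, sample_meta = NULL) {
  if (!file.exists(path)) stop("count table file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L || all(!nzchar(lines)))
    stop("empty count table file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_head <- length(fields[[1L]])
  if (ncol_head < 2L) stop("count table needs at least one sample column")
  samples <- fields[[1L]][-1L]
  body <- fields[-1L]
  for (k in seq_along(body)) {
    line_no <- k + 1L
    if (length(body[[k]]) != ncol_head)
      stop("ragged row at line ", line_no, ": expected ", ncol_head,
           " fields, got ", length(body[[k]]))
    vals <- suppressWarnings(as.numeric(body[[k]][-1L]))
    if (anyNA(vals))
      stop("non-numeric count at line ", line_no)
    if (any(vals < 0))
      stop("negative count at line ", line_no)
    if (any(abs(vals - round(vals)) > 1e-8))
      stop("non-integer count at line ", line_no)
  }
  asv_ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(asv_ids))
    stop("duplicate ASV ids: ",
         paste(unique(asv_ids[duplicated(asv_ids)]), collapse = ", "))
  m <- t(vapply(body, function(f) as.numeric(f[-1L]), numeric(ncol_head - 1L)))
  dimnames(m) <- list(asv_ids, samples)
  count_table(t(m), sample_meta = sample_meta)
}

#' Write an ASV count table as TSV
#'
#' Written with ASVs in rows and samples in columns, round-tripping through
#' [read_count_table()].
#'
#' @param table a `mec_count_table`.
#' @param path output TSV path.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "mec_count_table"))
  m <- t(table$counts)   # ASVs x samples on disk
  df <- data.frame(asv_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
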