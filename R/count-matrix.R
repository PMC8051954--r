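#' Construct a validated UMI count matrix
#'
#' Count matrices are stored features x barcodes as sparse
#' [Matrix::dgCMatrix] objects with feature ids as rownames and barcode
#' strings as colnames. The constructor enforces the count-matrix contract:
#' non-negative integral entries and unique feature/barcode identifiers.
#'
#' @param counts A matrix or Matrix of non-negative integers,
#'   features x barcodes.
#' @param feature_ids,barcode_ids Optional character vectors overriding the
#'   dimnames of `counts`.
#' @return A `dgCMatrix` with validated dimnames.
#' @examples
#' m <- count_matrix(matrix(0:3, 2, 2), c("CD3", "CD4"), c("bc1", "bc2"))
#' Matrix::colSums(m)
#' @export
count_matrix <- function(counts, feature_ids = rownames(counts),
                         barcode_ids = colnames(counts)) {
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
                   "generalMatrix")
  rownames(m) <- feature_ids
  colnames(m) <- barcode_ids
  validate_count_matrix(m)
  m
}

#' Validate the count-matrix contract
#'
#' @param m A features x barcodes matrix.
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_count_matrix <- function(m) {
  vals <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
  check(all(vals >= 0), "count matrix contains negative entries")
  check(all(vals == round(vals)), "count matrix contains non-integer entries")
  check(!is.null(rownames(m)) && !anyDuplicated(rownames(m)),
        "feature ids must be present and unique")
  check(!is.null(colnames(m)) || ncol(m) == 0L,
        "barcode ids must be present")
  check(!anyDuplicated(colnames(m)), "barcode ids must be unique")
  invisible(m)
}

open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

find_sidecar <- function(dir, stems) {
  for (stem in stems) {
    for (ext in c("", ".gz")) {
      p <- file.path(dir, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
  }
  stop(sprintf("missing file: none of [%s] found in '%s'",
               paste(stems, collapse = ", "), dir), call. = FALSE)
}

#' Read a CellRanger-style Matrix Market count directory
#'
#' Expects `matrix.mtx`, `barcodes.tsv` and `features.tsv` (or `genes.tsv`),
#' each optionally gzipped. Features files may carry one, two or three
#' tab-separated columns (id, name, type); the first column is used as the
#' feature id. The returned matrix is always features x barcodes, whatever
#' the on-disk orientation (detected by matching dimension lengths).
#'
#' @param directory_path Directory containing the triplet files.
#' @return A features x barcodes count matrix (see [count_matrix()]).
#' @export
read_counts_mtx <- function(directory_path) {
  check(dir.exists(directory_path), "missing file: directory '%s' does not exist",
        directory_path)
  mtx <- find_sidecar(directory_path, "matrix.mtx")
  bc_path <- find_sidecar(directory_path, "barcodes.tsv")
  ft_path <- find_sidecar(directory_path, c("features.tsv", "genes.tsv"))

  m <- Matrix::readMM(mtx)
  # pattern/logical Matrix Market variants come back as n/l matrices
  if (!methods::is(m, "dMatrix")) m <- methods::as(m, "dMatrix")
  m <- methods::as(m, "CsparseMatrix")
  barcodes <- readLines(con <- open_maybe_gz(bc_path)); close(con)
  ft_lines <- readLines(con <- open_maybe_gz(ft_path)); close(con)
  features <- vapply(strsplit(ft_lines, "\t", fixed = TRUE), `[`, "", 1L)

  if (nrow(m) == length(features) && ncol(m) == length(barcodes)) {
    # features x barcodes on disk
  } else if (nrow(m) == length(barcodes) && ncol(m) == length(features)) {
    m <- Matrix::t(m)
  } else {
    stop(sprintf("matrix dimensions %d x %d match neither %d features nor %d barcodes",
                 nrow(m), ncol(m), length(features), length(barcodes)), call. = FALSE)
  }
  vals <- m@x
  check(all(vals == round(vals)), "format error: non-integer entries in '%s'", mtx)
  count_matrix(m, feature_ids = features, barcode_ids = barcodes)
}

#' Write a count matrix as a Matrix Market triplet directory
#'
#' The on-disk layout mirrors the CellRanger dialect read by
#' [read_counts_mtx()] (features x barcodes `matrix.mtx`, `barcodes.tsv`,
#' `features.tsv`), so write/read round-trips are exact.
#'
#' @param m A features x barcodes count matrix.
#' @param directory_path Output directory (created if needed).
#' @param gzip Write gzipped sidecar files.
#' @return `directory_path`, invisibly.
#' @export
write_counts_mtx <- function(m, directory_path, gzip = FALSE) {
  validate_count_matrix(m)
  dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(m, "CsparseMatrix"), file.path(directory_path, "matrix.mtx"))
  ext <- if (gzip) ".gz" else ""
  wcon <- function(stem) {
    p <- file.path(directory_path, paste0(stem, ext))
    if (gzip) gzfile(p, "wt") else file(p, "wt")
  }
  con <- wcon("barcodes.tsv")
  writeLines(as.character(if (is.null(colnames(m))) character() else colnames(m)),
             con)
  close(con)
  con <- wcon("features.tsv")
  writeLines(paste(rownames(m), rownames(m), "Antibody Capture", sep = "\t"), con)
  close(con)
  invisible(directory_path)
}

#' Read a count matrix from CSV
#'
#' @param path CSV file with a header row and row names in the first column.
#' @param orientation `"features_by_barcodes"` (default) if rows are
#'   features, `"barcodes_by_features"` if rows are barcodes.
#' @return A features x barcodes count matrix.
#' @export
read_counts_csv <- function(path,
                            orientation = c("features_by_barcodes",
                                            "barcodes_by_features")) {
  orientation <- match.arg(orientation)
  check(file.exists(path), "missing file: '%s'", path)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  check(is.numeric(m), "format error: non-numeric entries in '%s'", path)
  check(all(m >= 0), "format error: negative entries in '%s'", path)
  check(all(m == round(m)), "format error: non-integer entries in '%s'", path)
  if (orientation == "barcodes_by_features") m <- t(m)
  count_matrix(m)
}

#' Write a count matrix as CSV (features x barcodes, row-named)
#' @param m A count matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(m, path) {
  validate_count_matrix(m)
  utils::write.csv(as.matrix(m), path)
  invisible(path)
}
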