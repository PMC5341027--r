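#' Individuals-by-locations count matrix
#'
#' The basic input of individual-based clustering: a matrix `w` whose entry
#' `w[j, l]` is the number of times (or years, or tweets) individual `j` was
#' observed at location `l`. Rows are individuals, columns locations.
#'
#' Entries must be nonnegative integers, every individual must have been
#' observed at least once (row totals `n_j >= 1`; a never-observed individual
#' carries no information and breaks the multinomial likelihood), and labels
#' must be unique within rows and within columns.
#'
#' @param values integer matrix (or something coercible), individuals in rows.
#' @param row_labels character vector of individual IDs; defaults to existing
#'   rownames or `ind001, ind002, ...`.
#' @param col_labels character vector of location labels; defaults to existing
#'   colnames or `L01, L02, ...`.
#' @return an object of class `ibc_counts`: an integer matrix with dimnames.
#' @examples
#' w <- count_matrix(rbind(c(3, 1, 0), c(0, 2, 2)))
#' row_totals(w)
#' @export
count_matrix <- function(values, row_labels = NULL, col_labels = NULL) {
  m <- as.matrix(values)
  if (length(dim(m)) != 2L || nrow(m) < 1L || ncol(m) < 1L) {
    stop("`values` must be a matrix with at least one row and one column", call. = FALSE)
  }
  if (!is.numeric(m)) {
    stop("count matrix entries must be numeric integers", call. = FALSE)
  }
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "count matrix entries must be nonnegative integers; first offender at row %d, column %d (value %g)",
      bad[1, 1], bad[1, 2], m[bad[1, 1], bad[1, 2]]
    ), call. = FALSE)
  }
  storage.mode(m) <- "integer"

  if (is.null(row_labels)) {
    row_labels <- rownames(m)
    if (is.null(row_labels)) {
      row_labels <- sprintf("ind%03d", seq_len(nrow(m)))
    }
  }
  if (is.null(col_labels)) {
    col_labels <- colnames(m)
    if (is.null(col_labels)) {
      col_labels <- sprintf("L%02d", seq_len(ncol(m)))
    }
  }
  row_labels <- as.character(row_labels)
  col_labels <- as.character(col_labels)
  if (length(row_labels) != nrow(m)) stop("row_labels length must match number of rows", call. = FALSE)
  if (length(col_labels) != ncol(m)) stop("col_labels length must match number of columns", call. = FALSE)
  if (anyDuplicated(row_labels)) {
    stop(sprintf("duplicate individual IDs: %s",
                 paste(unique(row_labels[duplicated(row_labels)]), collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(col_labels)) {
    stop(sprintf("duplicate location labels: %s",
                 paste(unique(col_labels[duplicated(col_labels)]), collapse = ", ")), call. = FALSE)
  }
  dimnames(m) <- list(row_labels, col_labels)

  n_j <- rowSums(m)
  if (any(n_j < 1L)) {
    stop(sprintf(
      "individuals never observed (zero row total) are not allowed: %s",
      paste(row_labels[n_j < 1L], collapse = ", ")
    ), call. = FALSE)
  }
  structure(m, class = c("ibc_counts", "matrix", "array"))
}

#' @rdname count_matrix
#' @param x an `ibc_counts` object.
#' @export
row_totals <- function(x) {
  stopifnot(inherits(x, "ibc_counts"))
  rowSums(unclass(x))
}

#' @export
print.ibc_counts <- function(x, ...) {
  cat(sprintf("Individuals-by-locations counts: %d individuals x %d locations, %d observations\n",
              nrow(x), ncol(x), sum(x)))
  print(utils::head(unclass(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... (%d more individuals)\n", nrow(x) - 6L))
  invisible(x)
}

#' Read a count matrix from delimited text
#'
#' Expects a header row of location labels and a first column of individual
#' IDs; the delimiter (comma or tab) is auto-detected from the header line.
#' Entries must be nonnegative integers; violations are reported with their
#' row and column coordinates.
#'
#' @param path path to the file.
#' @param delim `","`, `"\t"`, or `NULL` to auto-detect.
#' @return an [count_matrix()] object.
#' @export
read_counts <- function(path, delim = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop(sprintf("empty file: %s", path), call. = FALSE)
  if (is.null(delim)) {
    delim <- if (lengths(regmatches(header, gregexpr("\t", header))) >
                 lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if (ncol(df) < 2L) stop("expected an ID column followed by at least one location column", call. = FALSE)
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    nonnum <- which(!vapply(df[-1L], is.numeric, logical(1L)))
    stop(sprintf("non-numeric entries in column(s): %s",
                 paste(colnames(df)[-1L][nonnum], collapse = ", ")), call. = FALSE)
  }
  count_matrix(vals, row_labels = ids, col_labels = colnames(df)[-1L])
}

#' Write a count matrix as delimited text
#'
#' Inverse of [read_counts()]: header of location labels, first column of
#' individual IDs, comma-delimited UTF-8.
#'
#' @param x an `ibc_counts` object.
#' @param path output file path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, delim = ",") {
  stopifnot(inherits(x, "ibc_counts"))
  df <- data.frame(id = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utf8 <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(utf8))
  utils::write.table(df, utf8, sep = delim, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
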