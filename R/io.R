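# Delimited-table reading/writing for data matrices and embeddings.

#' Read a numeric data table
#'
#' Reads a CSV or TSV file with a header row. A leading non-numeric column
#' is treated as row labels. Any row containing a non-finite value (NA, NaN,
#' Inf) is an error, reported with its row numbers.
#'
#' @param path File path; the delimiter is a tab for `.tsv` files and
#'   inferred from the header line otherwise.
#' @return List with `X` (numeric matrix) and `labels` (character or
#'   `NULL`).
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE) || grepl("\t", first))
    "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 1L) stop("no columns in ", path)
  labels <- NULL
  if (!is.numeric(df[[1L]]) && suppressWarnings(anyNA(as.numeric(df[[1L]])))) {
    labels <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  if (ncol(df) == 0L) stop("no numeric columns in ", path)
  X <- as.matrix(df)
  suppressWarnings(storage.mode(X) <- "double")
  bad <- which(!apply(X, 1L, function(r) all(is.finite(r))))
  if (length(bad) > 0L)
    stop(sprintf("non-finite values in %s at row(s): %s", path,
                 paste(bad, collapse = ", ")))
  list(X = X, labels = labels)
}

.format_full <- function(x) {
  out <- sprintf("%.17g", x)
  out
}

#' Write an embedding table
#'
#' Columns: `label`, `angle_1..angle_d'`, `recon_1..recon_d`, `sqdist`,
#' written with 17 significant digits so a read-back reproduces the numbers
#' to full double precision. Empty labels become sequential integers.
#'
#' @param embedding An `srca_embedding` (from [srca_fit()] or
#'   [srca_transform()]).
#' @param path Output path (`.csv` or `.tsv`).
#' @param labels Optional row labels.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path, labels = NULL) {
  stopifnot(inherits(embedding, "srca_embedding"))
  n <- nrow(embedding$reconstructed)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (length(labels) != n) stop("'labels' must have one entry per row")
  A <- embedding$angles
  Rm <- embedding$reconstructed
  tab <- cbind(label = labels,
               matrix(.format_full(A), nrow = n,
                      dimnames = list(NULL, paste0("angle_", seq_len(ncol(A))))),
               matrix(.format_full(Rm), nrow = n,
                      dimnames = list(NULL, paste0("recon_", seq_len(ncol(Rm))))),
               sqdist = .format_full(embedding$per_point_sqdist))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Write a data matrix as CSV/TSV
#'
#' Full-precision companion to [read_table()]; used by the simulation CLI.
#'
#' @param X Numeric matrix.
#' @param path Output path.
#' @param labels Optional leading label column.
#' @return `path`, invisibly.
#' @export
write_table <- function(X, path, labels = NULL) {
  X <- as.matrix(X)
  cols <- colnames(X)
  if (is.null(cols)) cols <- paste0("V", seq_len(ncol(X)))
  M <- matrix(.format_full(X), nrow = nrow(X), dimnames = list(NULL, cols))
  if (!is.null(labels)) M <- cbind(label = as.character(labels), M)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(M, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
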