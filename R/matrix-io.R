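#' Expression matrices and missing-value masks
#'
#' Expression data are held as plain numeric matrices with genes in rows
#' and samples in columns (`rownames` are gene identifiers, `colnames`
#' sample identifiers). Missingness never lives inside the matrix as a
#' sentinel: it is carried separately by a logical mask of identical
#' shape, `TRUE` meaning missing. All entries of an expression matrix are
#' finite; consumers must consult the mask before reading a cell.
#'
#' `expr_matrix()` validates and normalises a matrix into this form;
#' `check_mask()` validates a matrix/mask pair and is called by every
#' operation that consumes one.
#'
#' @param values Numeric matrix, genes in rows.
#' @param gene_ids,sample_ids Optional identifier vectors; defaults are
#'   `g1, g2, ...` and `s1, s2, ...`. Must be unique.
#' @return `expr_matrix()`: the validated numeric matrix with dimnames set.
#' @examples
#' m <- expr_matrix(matrix(rnorm(6), 3, 2))
#' rownames(m)
#' @export
expr_matrix <- function(values, gene_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("expression matrix must have at least one gene and one sample",
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression matrix values must all be finite; ",
         "carry missingness in a mask, not as NA/NaN/Inf", call. = FALSE)
  gene_ids <- gene_ids %||% rownames(values) %||% paste0("g", seq_len(nrow(values)))
  sample_ids <- sample_ids %||% colnames(values) %||% paste0("s", seq_len(ncol(values)))
  if (length(gene_ids) != nrow(values) || anyDuplicated(gene_ids))
    stop("gene_ids must be unique and match the row count", call. = FALSE)
  if (length(sample_ids) != ncol(values) || anyDuplicated(sample_ids))
    stop("sample_ids must be unique and match the column count", call. = FALSE)
  dimnames(values) <- list(as.character(gene_ids), as.character(sample_ids))
  values
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname expr_matrix
#' @param x Numeric expression matrix.
#' @param mask Logical matrix, same shape as `x`; `TRUE` = missing.
#' @param allow_full_rows If `FALSE` (default), a gene with every entry
#'   masked is an error: the pipeline requires at least one observed value
#'   per gene.
#' @export
check_mask <- function(x, mask, allow_full_rows = FALSE) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  if (!identical(dim(x), dim(mask)))
    stop("matrix and mask shapes differ: ",
         paste(dim(x), collapse = "x"), " vs ",
         paste(dim(mask), collapse = "x"), call. = FALSE)
  if (anyNA(mask)) stop("mask must not contain NA", call. = FALSE)
  if (!allow_full_rows && any(rowSums(mask) == ncol(mask)))
    stop("gene(s) with all values missing: ",
         paste(head(which(rowSums(mask) == ncol(mask))), collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

empty_mask <- function(x) {
  matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x))
}

#' Read / write expression matrices as tab-separated text
#'
#' The on-disk dialect is a TSV with sample identifiers in the first row,
#' gene identifiers in the first column, and the literal token `NA`
#' (case-sensitive) marking missing cells. Orientation is fixed:
#' genes in rows, samples in columns; no auto-transposition.
#'
#' On reading, masked cells are stored as `0` placeholders in the returned
#' matrix and flagged in the mask; consumers must consult the mask. On
#' writing, numeric cells are printed with 10 significant digits so that
#' a write/read round-trip reproduces values to printed precision and the
#' mask exactly.
#'
#' @param path File path.
#' @return `read_expr_matrix()`: a list with elements `values` (numeric
#'   matrix) and `mask` (logical matrix).
#' @export
read_expr_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("matrix file must contain a header row and at least one gene row",
         call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  sample_ids <- header[-1L]
  if (length(sample_ids) < 1L)
    stop("matrix file has an empty data region (no sample columns)",
         call. = FALSE)
  body <- cells[-1L]
  widths <- lengths(body)
  if (any(widths != length(header)))
    stop("ragged row(s) at line(s): ",
         paste(head(which(widths != length(header)) + 1L), collapse = ", "),
         call. = FALSE)
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene IDs: ",
         paste(head(unique(gene_ids[duplicated(gene_ids)])), collapse = ", "),
         call. = FALSE)
  raw <- matrix(unlist(lapply(body, `[`, -1L), use.names = FALSE),
                nrow = length(body), byrow = TRUE)
  mask <- raw == "NA"
  values <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(values) & !mask, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell '%s' at gene row %d, sample column %d",
                 raw[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2]),
         call. = FALSE)
  values[mask] <- 0
  dimnames(values) <- list(gene_ids, sample_ids)
  dimnames(mask) <- dimnames(values)
  list(values = expr_matrix(values), mask = mask)
}

#' @rdname read_expr_matrix
#' @param x Numeric expression matrix (genes x samples).
#' @param mask Optional logical mask; masked cells are written as `NA`.
#' @export
write_expr_matrix <- function(x, path, mask = NULL) {
  x <- expr_matrix(x)
  if (is.null(mask)) mask <- empty_mask(x)
  check_mask(x, mask, allow_full_rows = TRUE)
  txt <- matrix(formatC(x, digits = 10, format = "g"), nrow(x), ncol(x))
  txt[mask] <- "NA"
  lines <- c(paste(c("", colnames(x)), collapse = "\t"),
             paste(rownames(x), apply(txt, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# Fixed column order of the long-format results table.
results_columns <- function() {
  c("repetition", "dataset_kind", "fs_method", "rule", "n_features",
    "mv_rate", "noise_mean", "block_sd", "block_corr", "mask_mode",
    "seed", "error", "nrmse")
}

#' Read / write experiment result tables
#'
#' Results are stored long-format as TSV, one row per
#' (repetition, dataset kind, feature-selection method, rule,
#' feature-set size) combination, with the simulation condition columns
#' repeated on every row so a grid sweep can stream into one file.
#' `write_results(..., append = TRUE)` appends without re-emitting the
#' header, supporting incremental grids and resume.
#'
#' @param records A data frame with (at least) the columns
#'   `r paste(results_columns(), collapse = ", ")`.
#' @param path File path.
#' @param append Append to an existing file instead of overwriting.
#' @return `read_results()`: a tibble.
#' @export
write_results <- function(records, path, append = FALSE) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data frame", call. = FALSE)
  missing_cols <- setdiff(results_columns(), names(records))
  if (length(missing_cols) > 0)
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  records <- as.data.frame(records)[, results_columns()]
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = !append || !file.exists(path), append = append)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing_cols <- setdiff(results_columns(), names(df))
  if (length(missing_cols) > 0)
    stop("results file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tibble::as_tibble(df)
}
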