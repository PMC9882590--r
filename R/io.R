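#' Read a single-cell expression count matrix
#'
#' Expects a rectangular delimited table: header row of gene names, first
#' column of cell identifiers, remaining columns non-negative integer
#' counts. Validation mirrors [infer_autoregulation()]'s count policy:
#' negative values and duplicate gene names are errors, and non-integer
#' entries are an error unless `allow_noninteger = TRUE` (which rounds with
#' a warning — the method is defined on molecule counts).
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"csv"` or `"tsv"`.
#' @param allow_noninteger Round non-integer counts instead of erroring.
#' @return Expression tibble: `cell` column plus integer gene columns.
#' @export
read_expression <- function(path, format = c("auto", "csv", "tsv"),
                            allow_noninteger = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  reader <- if (format == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 2) stop("expected a cell-id column plus gene columns", call. = FALSE)
  names(raw)[1] <- "cell"
  raw$cell <- as.character(raw$cell)
  counts <- validate_counts(raw, allow_noninteger)
  storage.mode(counts) <- "integer"
  dplyr::bind_cols(tibble::tibble(cell = raw$cell), tibble::as_tibble(counts))
}

#' Write an expression matrix (and optional truth sidecar)
#'
#' CSV with header of gene names and the cell identifier as first column —
#' the inverse of [read_expression()]. When the matrix carries ground-truth
#' labels (from [synthetic_expression()]) and `truth_path` is given, they
#' are written as a two-column TSV sidecar (`gene`, `true_autoregulation`).
#'
#' @param matrix Expression tibble.
#' @param path Output CSV path.
#' @param truth_path Optional path for the truth sidecar TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(matrix, path, truth_path = NULL) {
  readr::write_csv(tibble::as_tibble(matrix), path, progress = FALSE)
  truth <- attr(matrix, "truth")
  if (!is.null(truth_path)) {
    if (is.null(truth)) stop("matrix carries no truth labels", call. = FALSE)
    readr::write_tsv(truth, truth_path, progress = FALSE)
  }
  invisible(path)
}

#' Write a per-gene VMR / calls report
#'
#' Writes a TSV with columns `gene`, `verdict`, `proposition`, `n`, `mean`,
#' `variance`, `vmr`, `ci_lo`, `ci_hi`, `caveats` (semicolon-joined) for
#' calls, or the corresponding subset for plain VMR test tables.
#'
#' @param x An `autoreg_calls` object or per-gene VMR tibble.
#' @param path Output TSV path.
#' @param digits Significant digits for numeric columns (`Inf` for full
#'   precision).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, digits = 6) {
  tbl <- if (inherits(x, "autoreg_calls")) tidy(x) else tibble::as_tibble(x)
  if (is.finite(digits)) {
    num <- vapply(tbl, is.numeric, logical(1)) & names(tbl) != "n"
    tbl[num] <- lapply(tbl[num], signif, digits = digits)
  }
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}
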