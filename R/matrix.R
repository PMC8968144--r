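#' Validate a connectivity matrix
#'
#' Enforces the weight-matrix contract shared by all downstream operations:
#' square, symmetric, non-negative, zero main diagonal. Float-level
#' asymmetry (at most `tol`) is repaired by averaging `W` with its
#' transpose; larger asymmetry is an error reporting the worst offending
#' cell. A nonzero diagonal is zeroed with a warning, since self-connections
#' carry no meaning for parcel-to-parcel coupling.
#'
#' @param weights Numeric square matrix of non-negative association weights.
#' @param tol Symmetry tolerance; absolute row/column disagreement up to
#'   this value is silently symmetrized.
#' @return The validated (possibly repaired) matrix, invisibly classed as a
#'   plain base matrix.
#' @export
validate_matrix <- function(weights, tol = 1e-8) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop_cw("connectivity weights must be a numeric matrix",
            class = "cw_format_error")
  }
  if (nrow(weights) != ncol(weights)) {
    stop_cw("connectivity matrix must be square, got ",
            nrow(weights), " x ", ncol(weights),
            class = "cw_dimension_error")
  }
  if (anyNA(weights)) {
    stop_cw("connectivity matrix contains missing values",
            class = "cw_format_error")
  }
  asym <- abs(weights - t(weights))
  worst <- max(asym)
  if (worst > tol) {
    at <- which(asym == worst, arr.ind = TRUE)[1, ]
    stop_cw(sprintf(
      "matrix is asymmetric beyond tolerance %g: |W[%d,%d] - W[%d,%d]| = %g",
      tol, at[1], at[2], at[2], at[1], worst),
      class = "cw_symmetry_error")
  }
  if (worst > 0) {
    weights <- (weights + t(weights)) / 2
  }
  if (any(weights < 0)) {
    neg <- which(weights < 0, arr.ind = TRUE)[1, ]
    stop_cw(sprintf("negative weight at [%d,%d]; weights must be >= 0",
                    neg[1], neg[2]),
            class = "cw_domain_error")
  }
  if (any(diag(weights) != 0)) {
    warning("nonzero diagonal entries set to zero", call. = FALSE)
    diag(weights) <- 0
  }
  invisible(weights)
}

#' Read a connectivity matrix from delimited text
#'
#' Accepts whitespace- or comma-delimited numeric text (auto-detected), one
#' matrix row per line. The loaded matrix is passed through
#' [validate_matrix()]: it must be square and symmetric (within `tol`,
#' repaired by averaging), with non-negative weights and a zero diagonal.
#'
#' @param path Path to the matrix text file.
#' @inheritParams validate_matrix
#' @return A base numeric matrix.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("0 1", "1 0"), f)
#' load_matrix(f)
load_matrix <- function(path, tol = 1e-8) {
  if (!file.exists(path)) {
    stop_cw("matrix file not found: ", path, class = "cw_format_error")
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop_cw("matrix file is empty: ", path, class = "cw_format_error")
  }
  sep <- if (grepl(",", lines[[1]], fixed = TRUE)) "\\s*,\\s*" else "\\s+"
  rows <- lapply(strsplit(lines, sep), function(x) {
    suppressWarnings(as.numeric(x[nzchar(x)]))
  })
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) {
    stop_cw("ragged matrix rows: row lengths ",
            paste(unique(lens), collapse = ", "),
            class = "cw_dimension_error")
  }
  if (any(vapply(rows, anyNA, logical(1)))) {
    stop_cw("non-numeric entry in matrix file ", path,
            class = "cw_format_error")
  }
  m <- do.call(rbind, rows)
  if (nrow(m) != ncol(m)) {
    stop_cw("connectivity matrix must be square, got ",
            nrow(m), " x ", ncol(m), class = "cw_dimension_error")
  }
  m <- validate_matrix(m, tol = tol)
  m
}

#' Write a connectivity matrix as fixed-precision text
#'
#' Writes whitespace-delimited fixed-decimal text so that a save/reload
#' round trip reproduces the weights exactly at the printed precision.
#'
#' @param weights Matrix to write.
#' @param path Output path.
#' @param digits Number of decimal places to print.
#' @return `path`, invisibly.
#' @export
save_matrix <- function(weights, path, digits = 10) {
  txt <- apply(weights, 1, function(r) {
    paste(sprintf(paste0("%.", digits, "f"), r), collapse = " ")
  })
  writeLines(txt, path)
  invisible(path)
}
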