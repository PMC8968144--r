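#' Read an atlas table
#'
#' The atlas fixes the identity, display order and grouping of the network
#' nodes: row order is meaningful (the first parcel is drawn at the top of
#' the connectogram circle and order proceeds clockwise). The table must
#' have a `parcel` column (unique names) and a `legend` column (short
#' human-readable label per parcel); an optional `group` column carries a
#' higher-level grouping tag (e.g. anatomical lobe), and any further columns
#' are kept as attribute columns usable for selection. Column headers are
#' matched case-insensitively.
#'
#' @param path Path to a `.csv` or `.xlsx`/`.xls` file.
#' @param dialect `"auto"` (by file extension), `"csv"` or `"spreadsheet"`.
#' @return A tibble with columns `parcel`, `legend`, optionally `group`,
#'   plus any attribute columns, preserving file row order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("parcel,legend,group", "A,a,Fro", "B,b,Fro"), f)
#' load_atlas(f)
load_atlas <- function(path, dialect = c("auto", "csv", "spreadsheet")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_cw("atlas file not found: ", path, class = "cw_format_error")
  }
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("xls", "xlsx")) "spreadsheet" else "csv"
  }
  tbl <- if (dialect == "spreadsheet") {
    readxl::read_excel(path, col_types = "text")
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE)
  }
  names(tbl) <- ifelse(tolower(names(tbl)) %in% c("parcel", "legend", "group"),
                       tolower(names(tbl)), names(tbl))
  if (!"parcel" %in% names(tbl)) {
    stop_cw("atlas must have a 'parcel' column", class = "cw_format_error")
  }
  if (!"legend" %in% names(tbl)) {
    stop_cw("atlas must have a 'legend' column", class = "cw_format_error")
  }
  tbl <- dplyr::mutate(tbl, dplyr::across(dplyr::everything(),
                                          ~ trimws(as.character(.x))))
  validate_atlas(tbl)
  core <- intersect(c("parcel", "legend", "group"), names(tbl))
  dplyr::relocate(tbl, dplyr::all_of(core))
}

validate_atlas <- function(atlas) {
  if (!is.data.frame(atlas) || !all(c("parcel", "legend") %in% names(atlas))) {
    stop_cw("atlas must be a data frame with 'parcel' and 'legend' columns",
            class = "cw_format_error")
  }
  p <- atlas$parcel
  if (any(is.na(p) | !nzchar(p))) {
    stop_cw("empty parcel name at row ",
            which(is.na(p) | !nzchar(p))[1], class = "cw_format_error")
  }
  dup <- p[duplicated(p)]
  if (length(dup) > 0) {
    stop_cw("duplicate parcel name(s): ",
            paste(unique(dup), collapse = ", "), class = "cw_format_error")
  }
  l <- atlas$legend
  if (any(is.na(l) | !nzchar(l))) {
    stop_cw("missing legend at row ", which(is.na(l) | !nzchar(l))[1],
            class = "cw_format_error")
  }
  invisible(atlas)
}

# Names of atlas columns usable as attribute selectors.
atlas_attribute_columns <- function(atlas) {
  setdiff(names(atlas), c("parcel", "legend", "group"))
}

#' Read a label file
#'
#' One parcel name per line, in the exact row/column order of the
#' connectivity matrix it accompanies. Blank lines are ignored and
#' surrounding whitespace is stripped; matching against the atlas is exact
#' and case-sensitive.
#'
#' @param path Path to a plain-text label file.
#' @return Character vector of parcel names, in file order.
#' @export
load_labels <- function(path) {
  if (!file.exists(path)) {
    stop_cw("label file not found: ", path, class = "cw_format_error")
  }
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x)]
  if (length(x) == 0L) {
    stop_cw("label file is empty: ", path, class = "cw_format_error")
  }
  dup <- unique(x[duplicated(x)])
  if (length(dup) > 0) {
    stop_cw("duplicate label(s): ", paste(dup, collapse = ", "),
            class = "cw_format_error")
  }
  x
}
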