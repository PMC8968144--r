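#' Create a per-run output folder
#'
#' Each execution writes its figures and reports into its own
#' timestamped folder under `base`, so runs never overwrite each other.
#'
#' @param base Parent directory.
#' @param prefix Folder name prefix.
#' @return Path of the created directory.
#' @export
create_run_dir <- function(base = ".", prefix = "run") {
  stamp <- format(Sys.time(), "%Y%m%d_%H%M%S")
  path <- file.path(base, paste(prefix, stamp, sep = "_"))
  i <- 0
  while (dir.exists(path)) {
    i <- i + 1
    path <- file.path(base, paste(prefix, stamp, i, sep = "_"))
  }
  dir.create(path, recursive = TRUE)
  path
}

#' Write a JSON run manifest
#'
#' Records the settings of a run (input files, seeds, thresholds,
#' consensus conventions such as `mean_over`, package version) next to its
#' outputs, for reproducibility.
#'
#' @param dir Run directory.
#' @param params Named list of settings to record.
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(dir, params = list()) {
  manifest <- c(
    list(
      package = "connectoweave",
      version = as.character(utils::packageVersion("connectoweave")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    params
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Bundled 165-parcel atlas template
#'
#' Path to (or the loaded content of) the Destrieux-style atlas template
#' shipped with the package: 75 cortical parcels per hemisphere plus 7
#' subcortical structures per hemisphere and the brainstem, 165 parcels in
#' total, with anatomical-lobe grouping and a hemisphere attribute.
#'
#' @param load If `TRUE` return the loaded atlas tibble, else the file
#'   path.
#' @return A path or an atlas tibble.
#' @export
destrieux_template <- function(load = TRUE) {
  path <- system.file("extdata", "atlas_destrieux165.csv",
                      package = "connectoweave")
  if (!nzchar(path)) {
    stop_cw("bundled atlas template not found", class = "cw_format_error")
  }
  if (load) load_atlas(path) else path
}

#' Bundled example of reference-versus-case global indices
#'
#' A worked-example table of whole-brain global graph indices from a
#' structural-connectivity stroke case study: a healthy-control consensus
#' network (`hc`) against two single-subject stroke cases (`case1`,
#' `case2`), including the network densities in percent. Useful for
#' exercising [delta_report()] without recomputing metrics.
#'
#' @param load If `TRUE` return the loaded tibble, else the file path.
#' @return A path or a tibble with columns `index`, `hc`, `case1`,
#'   `case2`.
#' @export
example_global_indices <- function(load = TRUE) {
  path <- system.file("extdata", "example_global_indices.csv",
                      package = "connectoweave")
  if (!nzchar(path)) {
    stop_cw("bundled example table not found", class = "cw_format_error")
  }
  if (!load) return(path)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
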