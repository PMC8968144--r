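#' Reference-versus-case percent delta report
#'
#' For every shared index, computes the percent change of a case network
#' relative to a reference network, `delta = (ref - case) * 100 / ref`:
#' positive when the case value is below the reference. Deltas are also
#' rounded (half away from zero) to 1 decimal for display; indices with a
#' zero reference value are flagged undefined (`NA`).
#'
#' @param reference,case `cw_global_metrics` objects, data frames with
#'   `index`/`value` columns (extra columns ignored), or named numeric
#'   vectors. Both must cover the same index set.
#' @param reference_label,case_label Labels recorded in the report.
#' @return A tibble with columns `index`, `reference`, `case`, `delta`
#'   (raw), `delta_1dp` (display rounding), `reference_label`,
#'   `case_label`.
#' @export
#' @examples
#' delta_report(c(average_degree = 77.915), c(average_degree = 30.582))
delta_report <- function(reference, case,
                         reference_label = "reference", case_label = "case") {
  ref <- as_index_values(reference)
  cas <- as_index_values(case)
  if (!setequal(names(ref), names(cas))) {
    stop_cw("reference and case report different index sets",
            class = "cw_format_error")
  }
  cas <- cas[names(ref)]
  delta <- ifelse(ref == 0, NA_real_, (ref - cas) * 100 / ref)
  tibble::tibble(
    index = names(ref),
    reference = unname(ref),
    case = unname(cas),
    delta = unname(delta),
    delta_1dp = round_half_up(unname(delta) * 10) / 10,
    reference_label = reference_label,
    case_label = case_label
  )
}

as_index_values <- function(x) {
  if (inherits(x, "cw_global_metrics")) {
    return(x$values)
  }
  if (is.data.frame(x)) {
    if (!all(c("index", "value") %in% names(x))) {
      stop_cw("data-frame input needs 'index' and 'value' columns",
              class = "cw_format_error")
    }
    return(stats::setNames(x$value, x$index))
  }
  if (is.numeric(x) && !is.null(names(x))) {
    return(x)
  }
  stop_cw("cannot interpret index values; give a metrics object, a ",
          "data frame with index/value, or a named numeric vector",
          class = "cw_format_error")
}

#' Top/bottom highlighting classes for a local index
#'
#' Classifies each node as `top`, `bottom` or `mid`: the `k` nodes with the
#' highest values form the top class and the `k` lowest the bottom class,
#' with `k = round(fraction * N)` (half away from zero, so 10% of 165
#' parcels gives 17). Ties are broken by a single ranking (value
#' descending, display order ascending), so classes are always disjoint and
#' of size exactly `k`.
#'
#' @param values Numeric per-node metric, in atlas display order.
#' @param fraction Fraction per class, in (0, 0.5). Default 0.10.
#' @return Factor of levels `top`, `mid`, `bottom`, same length as
#'   `values`.
#' @export
#' @examples
#' table(highlight_classes(rnorm(165)))
highlight_classes <- function(values, fraction = 0.10) {
  n <- length(values)
  if (n < 1L) {
    stop_cw("no values to classify", class = "cw_domain_error")
  }
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 0.5) {
    stop_cw("fraction must be in (0, 0.5)", class = "cw_fraction_error")
  }
  k <- round_half_up(fraction * n)
  if (2 * k > n) {
    stop_cw("fraction ", fraction, " would overlap top and bottom classes ",
            "(2k = ", 2 * k, " > N = ", n, ")", class = "cw_fraction_error")
  }
  ord <- order(-values, seq_len(n))
  cls <- rep("mid", n)
  if (k > 0) {
    cls[ord[seq_len(k)]] <- "top"
    cls[ord[seq.int(n - k + 1, n)]] <- "bottom"
  }
  factor(cls, levels = c("top", "mid", "bottom"))
}
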