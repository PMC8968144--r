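#' Circular node layout in atlas order
#'
#' Places the displayed parcels at equal angular spacing on the unit
#' circle, first displayed atlas parcel at the top (angle `pi/2`) and
#' subsequent parcels clockwise in atlas order. Angles are reported
#' unwrapped (strictly decreasing from `pi/2`).
#'
#' @param atlas Atlas tibble in display order.
#' @param displayed Optional integer display indices to place (default
#'   all).
#' @return A tibble with columns `index`, `parcel`, `legend`, `group` (if
#'   present), `angle`, `x`, `y`.
#' @export
circular_layout <- function(atlas, displayed = NULL) {
  validate_atlas(atlas)
  idx <- sort(unique(displayed %||% seq_len(nrow(atlas))))
  if (length(idx) == 0L) {
    stop_cw("no parcels to lay out", class = "cw_selection_error")
  }
  m <- length(idx)
  angle <- pi / 2 - 2 * pi * (seq_len(m) - 1) / m
  out <- tibble::tibble(
    index = idx,
    parcel = atlas$parcel[idx],
    legend = atlas$legend[idx],
    angle = angle,
    x = cos(angle),
    y = sin(angle)
  )
  if ("group" %in% names(atlas)) {
    out <- dplyr::mutate(out, group = atlas$group[idx], .after = "legend")
  }
  out
}

#' Geodesic arc of the Poincare disk between two boundary points
#'
#' An edge between perimeter nodes is drawn as the hyperbolic geodesic of
#' the Poincare disk: the circular arc through `u` and `v` orthogonal to
#' the unit circle. Its center `c` satisfies `u . c = 1` and `v . c = 1`
#' (a 2x2 linear solve) and its radius `r = sqrt(|c|^2 - 1)`; the arc drawn
#' is the one lying inside the unit disk. Antipodal endpoints degenerate to
#' a straight chord through the origin.
#'
#' @param u,v Numeric length-2 points on the unit circle (checked to
#'   within `tol`).
#' @param tol Tolerance for the unit-norm and antipodality checks.
#' @return A one-row tibble with columns `kind` (`"arc"` or `"chord"`),
#'   `ux`, `uy`, `vx`, `vy`, `cx`, `cy`, `r`, `a0`, `a1` (start/end angles
#'   at the arc center; `NA` for chords).
#' @export
#' @examples
#' poincare_arc(c(1, 0), c(0, 1)) # center (1,1), radius 1
poincare_arc <- function(u, v, tol = 1e-9) {
  if (abs(sqrt(sum(u^2)) - 1) > tol || abs(sqrt(sum(v^2)) - 1) > tol) {
    stop_cw("arc endpoints must lie on the unit circle",
            class = "cw_geometry_error")
  }
  if (sqrt(sum((u - v)^2)) <= tol) {
    stop_cw("arc endpoints coincide", class = "cw_geometry_error")
  }
  if (sqrt(sum((u + v)^2)) <= tol) {
    return(tibble::tibble(kind = "chord", ux = u[1], uy = u[2],
                          vx = v[1], vy = v[2], cx = NA_real_,
                          cy = NA_real_, r = NA_real_,
                          a0 = NA_real_, a1 = NA_real_))
  }
  cc <- solve(rbind(u, v), c(1, 1))
  r <- sqrt(sum(cc^2) - 1)
  a0 <- atan2(u[2] - cc[2], u[1] - cc[1])
  a1 <- atan2(v[2] - cc[2], v[1] - cc[1])
  # the arc inside the unit disk subtends the short way around the center
  if (a1 - a0 > pi) a1 <- a1 - 2 * pi
  if (a0 - a1 > pi) a0 <- a0 - 2 * pi
  tibble::tibble(kind = "arc", ux = u[1], uy = u[2], vx = v[1], vy = v[2],
                 cx = cc[1], cy = cc[2], r = r, a0 = a0, a1 = a1)
}

# Interpolate an arc (one row from poincare_arc()) into drawable points.
arc_points <- function(arc, n = 64) {
  if (arc$kind == "chord") {
    tibble::tibble(x = seq(arc$ux, arc$vx, length.out = n),
                   y = seq(arc$uy, arc$vy, length.out = n))
  } else {
    t <- seq(arc$a0, arc$a1, length.out = n)
    tibble::tibble(x = arc$cx + arc$r * cos(t),
                   y = arc$cy + arc$r * sin(t))
  }
}
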