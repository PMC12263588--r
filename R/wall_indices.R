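# Wall shear index maps from time-resolved wall-shear vector fields.
# Standard literature definitions over one cardiac cycle of length T:
#   TAWSS = (1/T) int |tau| dt
#   OSI   = 0.5 (1 - |int tau dt| / int |tau| dt)        in [0, 0.5]
#   RRT   = 1 / ((1 - 2 OSI) TAWSS)                      (Pa^-1)
# Time integrals use the trapezoid rule on the field's sample grid.

#' @keywords internal
trapz_weights <- function(t) {
  m <- length(t)
  d <- diff(t)
  c(d[1] / 2, (d[-1] + d[-(m - 1)]) / 2, d[m - 1] / 2)
}

#' @keywords internal
check_field <- function(field) {
  if (!inherits(field, "wss_field")) stop("expected a wss_field")
  t <- field$times
  if (length(t) < 2) stop("need at least 2 time samples")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  if (abs((t[length(t)] - t[1]) - field$period) > 1e-9 * field$period) {
    stop("time samples must span exactly one period")
  }
  invisible(TRUE)
}

#' Time-averaged wall shear stress magnitude
#'
#' @param field a `wss_field` (surface mesh, time samples spanning one
#'   period, per-node per-time shear vectors in Pa).
#' @return per-node TAWSS (Pa).
#' @export
tawss <- function(field) {
  check_field(field)
  w <- trapz_weights(field$times)
  mag <- sqrt(field$vectors[, , 1]^2 + field$vectors[, , 2]^2 +
                field$vectors[, , 3]^2)
  as.numeric(mag %*% w) / field$period
}

#' Oscillatory shear index
#'
#' 0 for unidirectional shear, 0.5 for perfectly reversing (zero-mean)
#' shear. Degenerate nodes with a vanishing magnitude integral get OSI 0;
#' their count is attached as attribute `n_degenerate`.
#'
#' @inheritParams tawss
#' @return per-node OSI in [0, 0.5].
#' @export
osi <- function(field) {
  check_field(field)
  w <- trapz_weights(field$times)
  int_vec_x <- as.numeric(field$vectors[, , 1] %*% w)
  int_vec_y <- as.numeric(field$vectors[, , 2] %*% w)
  int_vec_z <- as.numeric(field$vectors[, , 3] %*% w)
  mag <- sqrt(field$vectors[, , 1]^2 + field$vectors[, , 2]^2 +
                field$vectors[, , 3]^2)
  int_mag <- as.numeric(mag %*% w)
  num <- sqrt(int_vec_x^2 + int_vec_y^2 + int_vec_z^2)
  out <- numeric(length(int_mag))
  ok <- int_mag > 0
  out[ok] <- 0.5 * (1 - num[ok] / int_mag[ok])
  out <- pmin(pmax(out, 0), 0.5)
  attr(out, "n_degenerate") <- sum(!ok)
  out
}

#' Relative residence time
#'
#' RRT = 1 / ((1 - 2 OSI) TAWSS), a proxy for near-wall stagnation. Nodes
#' where OSI reaches 0.5 or TAWSS vanishes are singular: they are returned
#' as `Inf` unless `cap` is given, in which case values are clamped at
#' `cap`.
#'
#' @param tawss_map per-node TAWSS (Pa).
#' @param osi_map per-node OSI.
#' @param cap optional finite upper bound (Pa^-1).
#' @return per-node RRT (Pa^-1).
#' @export
rrt <- function(tawss_map, osi_map, cap = NULL) {
  if (length(tawss_map) != length(osi_map)) stop("maps must be aligned")
  denom <- (1 - 2 * osi_map) * tawss_map
  out <- ifelse(denom > 0, 1 / denom, Inf)
  if (!is.null(cap)) out <- pmin(out, cap)
  out
}

#' Compute all three index maps of a field
#'
#' @inheritParams tawss
#' @param cap optional RRT cap (Pa^-1).
#' @return a `wall_index_maps` list: `tawss`, `osi`, `rrt`, `areas`
#'   (barycentric node weights, m^2).
#' @export
wall_index_maps <- function(field, cap = NULL) {
  tw <- tawss(field)
  os <- osi(field)
  structure(list(tawss = tw, osi = os, rrt = rrt(tw, os, cap),
                 areas = node_area_weights(field$surface)),
            class = "wall_index_maps")
}

#' Area fraction beyond a threshold
#'
#' Area-weighted fraction of nodes whose index value lies strictly below /
#' above the threshold (ties excluded). Node weights are barycentric
#' (one third of incident triangle areas) and must sum to the total
#' surface area.
#'
#' @param values per-node index values.
#' @param threshold cut value (same unit as `values`).
#' @param direction `"below"` or `"above"`.
#' @param areas per-node area weights (m^2).
#' @return an `area_fraction_report`: `threshold`, `direction`, `fraction`,
#'   `area` (m^2) and `total_area` (m^2).
#' @examples
#' area_fraction(c(0.1, 1, 2), 0.4, "below", c(1, 1, 2))
#' @export
area_fraction <- function(values, threshold, direction = c("below", "above"),
                          areas) {
  direction <- match.arg(direction)
  if (length(values) != length(areas)) {
    stop("values and area weights must be aligned")
  }
  sel <- if (direction == "below") values < threshold else values > threshold
  sel[is.na(sel)] <- FALSE
  total <- sum(areas)
  structure(list(threshold = threshold, direction = direction,
                 fraction = sum(areas[sel]) / total,
                 area = sum(areas[sel]), total_area = total),
            class = "area_fraction_report")
}

#' @export
print.area_fraction_report <- function(x, ...) {
  cat(sprintf("<area_fraction> %s %.4g: %.4f (%.4g of %.4g m^2)\n",
              x$direction, x$threshold, x$fraction, x$area, x$total_area))
  invisible(x)
}

#' Threshold report for all three indices
#'
#' Convenience wrapper producing the three standard area fractions: low
#' TAWSS (< 0.4 Pa), high OSI (> 0.4) and high RRT (> 10 Pa^-1) by
#' default. Degenerate-OSI nodes are excluded from the high-OSI count by
#' construction (their OSI is 0).
#'
#' @param maps a `wall_index_maps` object.
#' @param tawss_threshold,osi_threshold,rrt_threshold cut values.
#' @return named list of `area_fraction_report`s
#'   (`low_tawss`, `high_osi`, `high_rrt`).
#' @export
threshold_report <- function(maps, tawss_threshold = 0.4,
                             osi_threshold = 0.4, rrt_threshold = 10) {
  list(low_tawss = area_fraction(maps$tawss, tawss_threshold, "below",
                                 maps$areas),
       high_osi = area_fraction(maps$osi, osi_threshold, "above",
                                maps$areas),
       high_rrt = area_fraction(maps$rrt, rrt_threshold, "above",
                                maps$areas))
}

#' Write per-node index maps as CSV
#' @param maps a `wall_index_maps`.
#' @param path CSV path.
#' @export
write_index_csv <- function(maps, path) {
  utils::write.csv(data.frame(node = seq_along(maps$tawss),
                              tawss = maps$tawss, osi = as.numeric(maps$osi),
                              rrt = maps$rrt, area = maps$areas),
                   path, row.names = FALSE)
  invisible(path)
}
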