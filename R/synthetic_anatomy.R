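# Synthetic anatomy: every input the pipeline needs -- sac surfaces, outlet
# sets, pulsatile waveforms and ground-truth wall-shear fields -- generated
# with known ground truth so downstream stages are testable without patient
# data.

#' Generate a closed aneurysm-sac surface
#'
#' Builds a watertight triangulated sphere or ellipsoid by icosahedral
#' subdivision, as a stand-in for a segmented aneurysm sac. The returned
#' object carries the mesh, its volume and centroid, an analytic signed
#' distance function (negative inside), and the radius of the largest
#' inscribed sphere.
#'
#' @param shape `"sphere"` or `"ellipsoid"`.
#' @param dimensions for a sphere, the radius (m); for an ellipsoid, the
#'   three semi-axes (m).
#' @param resolution target edge length (m); must be smaller than the
#'   smallest dimension. Finer resolution gives a mesh volume closer to the
#'   analytic solid volume.
#' @param center sac centroid, 3-vector (m).
#' @return an object of class `sac_geometry` with elements `surface`
#'   (mesh list), `volume` (m^3, signed mesh volume), `centroid`,
#'   `semi_axes`, `inscribed_radius`, `analytic_volume` and `sdf`
#'   (vectorised signed-distance closure taking an n x 3 matrix).
#' @examples
#' sac <- make_sac("sphere", 0.009, resolution = 0.002)
#' abs(sac$volume / sac$analytic_volume - 1) < 0.01
#' @export
make_sac <- function(shape = c("sphere", "ellipsoid"), dimensions,
                     resolution = min(dimensions) / 6,
                     center = c(0, 0, 0)) {
  shape <- match.arg(shape)
  if (any(dimensions <= 0)) {
    stop("sac dimensions must be positive, got: ",
         paste(dimensions, collapse = ", "))
  }
  semi <- if (shape == "sphere") rep(dimensions[1], 3) else {
    if (length(dimensions) != 3) stop("ellipsoid needs three semi-axes")
    as.numeric(dimensions)
  }
  if (resolution >= min(semi)) {
    stop("resolution must be finer than the smallest dimension")
  }
  # icosahedron edge on the unit sphere is ~1.0515; each subdivision halves
  # it. Choose the level that brings the largest-axis edge under the target,
  # with a floor that keeps the polyhedral volume within 1% of analytic.
  s <- ceiling(log2(1.05146 * max(semi) / resolution))
  s <- max(s, 3L)
  mesh <- icosphere(s)
  mesh$vertices <- sweep(mesh$vertices %*% diag(semi), 2, center, "+")
  vol <- mesh_volume(mesh)
  a <- semi
  ctr <- center
  sdf <- if (shape == "sphere") {
    function(p) {
      p <- matrix(p, ncol = 3)
      sqrt(rowSums(sweep(p, 2, ctr)^2)) - a[1]
    }
  } else {
    # scaled-space estimate (Quilez form): exact sign, near-exact magnitude
    # for the mildly eccentric sacs generated here
    function(p) {
      p <- matrix(p, ncol = 3)
      q <- sweep(p, 2, ctr)
      k0 <- sqrt(rowSums(sweep(q, 2, a, "/")^2))
      k1 <- sqrt(rowSums(sweep(q, 2, a^2, "/")^2))
      ifelse(k1 > 0, k0 * (k0 - 1) / k1, -min(a))
    }
  }
  structure(list(surface = mesh, volume = vol, centroid = center,
                 semi_axes = semi, inscribed_radius = min(semi),
                 analytic_volume = 4 / 3 * pi * prod(semi), sdf = sdf,
                 shape = shape, subdivisions = s),
            class = "sac_geometry")
}

#' @export
print.sac_geometry <- function(x, ...) {
  cat(sprintf("<sac_geometry> %s, semi-axes %s m, %d vertices, volume %.4g m^3\n",
              x$shape, paste(signif(x$semi_axes, 4), collapse = "/"),
              nrow(x$surface$vertices), x$volume))
  invisible(x)
}

#' Load the packaged Windkessel boundary-condition table
#'
#' Returns the individualized 3-element Windkessel parameters (R1, R2, C per
#' outlet, two patients) shipped with the package as a verbatim fixture.
#'
#' @param patient optional `"Patient-1"` or `"Patient-2"` to filter.
#' @return data.frame with columns `patient`, `outlet`, `R1`, `R2`, `C`
#'   (Pa s/m^3, Pa s/m^3, m^3/Pa).
#' @export
windkessel_table <- function(patient = NULL) {
  path <- system.file("extdata", "table1_windkessel.csv",
                      package = "hemocoil", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tab) <- c("patient", "outlet", "R1", "R2", "C")
  if (!is.null(patient)) {
    tab <- tab[tab$patient == patient, , drop = FALSE]
    if (nrow(tab) == 0) stop("unknown patient: ", patient)
    rownames(tab) <- NULL
  }
  tab
}

#' Generate a four-branch aortic arch outlet set
#'
#' Produces the four outflow branches of the arch (BT, LCC, LSA, DA) with
#' cross-sectional areas that sum exactly to `total_area`. Area ratios are
#' derived from the packaged Windkessel table by inverting the
#' parallel-resistance split (area proportional to 1/R_total per outlet), so
#' the descending aorta carries the largest area and a subsequent
#' calibration orders the outlet resistances like the reference table.
#'
#' @param template `"patient1_like"` or `"patient2_like"`.
#' @param total_area summed cross-sectional area of the four branches (m^2).
#' @return an `outlet_set` data.frame with columns `name`, `area` (m^2),
#'   `diastolic_diameter` (m) and `diastolic_area` (m^2).
#' @export
make_outlet_set <- function(template = c("patient1_like", "patient2_like"),
                            total_area = 8e-4) {
  template <- match.arg(template)
  if (total_area <= 0) stop("total_area must be positive")
  pat <- if (template == "patient1_like") "Patient-1" else "Patient-2"
  tab <- windkessel_table(pat)
  rtot <- tab$R1 + tab$R2
  frac <- (1 / rtot) / sum(1 / rtot)
  area <- total_area * frac
  # absorb rounding into the largest branch so the sum is exact
  imax <- which.max(area)
  area[imax] <- area[imax] + (total_area - sum(area))
  d <- 2 * sqrt(area / pi)
  out <- data.frame(name = tab$outlet, area = area,
                    diastolic_diameter = d,
                    diastolic_area = pi * d^2 / 4,
                    stringsAsFactors = FALSE)
  class(out) <- c("outlet_set", "data.frame")
  out
}

#' Synthesize a periodic inlet waveform
#'
#' Builds one cardiac cycle of a pressure or flow waveform with prescribed
#' extrema. The `two_phase_pulse` shape has a systolic rise-and-decay
#' followed by a dicrotic ripple and diastolic relaxation; `sinusoid` is a
#' single harmonic. Samples are rescaled so the sampled maximum and minimum
#' hit the requested extrema exactly; the generator is deterministic.
#'
#' @param kind `"pressure"` (Pa) or `"flow"` (m^3/s).
#' @param max_value,min_value waveform extrema in SI units.
#' @param period cardiac period (s); the default 0.84 s corresponds to 84
#'   steps of 0.01 s.
#' @param n_samples samples per period (>= 8); sample j sits at
#'   (j-1) * period / n_samples.
#' @param shape `"two_phase_pulse"` or `"sinusoid"`.
#' @return an `inlet_waveform` object with `times`, `values`, `period`,
#'   `kind`, `qmax`, `qmin` and `extrema_interval` (s between the sampled
#'   maximum and minimum).
#' @examples
#' wf <- make_waveform("pressure", mmHg_to_pa(117), mmHg_to_pa(82))
#' range(wf$values)
#' @export
make_waveform <- function(kind = c("pressure", "flow"), max_value, min_value,
                          period = 0.84, n_samples = 84,
                          shape = c("two_phase_pulse", "sinusoid")) {
  kind <- match.arg(kind)
  shape <- match.arg(shape)
  if (max_value < min_value) stop("max_value must be >= min_value")
  if (period <= 0) stop("period must be positive")
  if (n_samples < 8) stop("need at least 8 samples per period")
  t <- (seq_len(n_samples) - 1) * period / n_samples
  x <- t / period
  raw <- switch(shape,
    sinusoid = sin(2 * pi * x),
    two_phase_pulse = {
      # systolic rise to the peak, fall to a dicrotic notch, then
      # exponential diastolic relaxation toward the minimum at end-cycle
      xp <- 0.15; xn <- 0.40; notch <- 0.45; taud <- 0.40
      ifelse(x <= xp, sin(pi * x / (2 * xp))^2,
        ifelse(x <= xn,
               notch + (1 - notch) * (1 + cos(pi * (x - xp) / (xn - xp))) / 2,
               notch * exp(-(x - xn) / taud)))
    })
  rng <- max(raw) - min(raw)
  raw01 <- if (rng > 0) (raw - min(raw)) / rng else raw * 0
  if (shape == "two_phase_pulse" && rng > 0) {
    # warp the normalized shape so its cycle mean is exactly one third of
    # the pulse height above the minimum, matching the cuff estimate
    # Pm = Pd + (Ps - Pd)/3 that the calibration uses for mean pressure
    g <- stats::uniroot(function(g) mean(raw01^g) - 1 / 3,
                        c(0.05, 20), tol = 1e-12)$root
    raw01 <- raw01^g
  }
  vals <- if (max_value == min_value || rng == 0) {
    rep(max_value, n_samples)
  } else {
    min_value + (max_value - min_value) * raw01
  }
  i_max <- which.max(vals)
  i_min <- which.min(vals)
  dt_ex <- abs(t[i_max] - t[i_min])
  if (dt_ex == 0) dt_ex <- period / 2
  structure(list(times = t, values = vals, period = period, kind = kind,
                 qmax = max(vals), qmin = min(vals),
                 extrema_interval = dt_ex, shape = shape),
            class = "inlet_waveform")
}

#' Evaluate a waveform at arbitrary times
#'
#' Periodic linear interpolation of the sampled cycle.
#'
#' @param wf an `inlet_waveform`.
#' @param t times (s), any real values.
#' @return interpolated values.
#' @export
waveform_value <- function(wf, t) {
  tt <- t %% wf$period
  xs <- c(wf$times, wf$period)
  ys <- c(wf$values, wf$values[1])
  stats::approx(xs, ys, xout = tt, rule = 2)$y
}

#' Time-averaged value of a waveform over one period
#' @param wf an `inlet_waveform`.
#' @return scalar mean (trapezoid over the closed cycle).
#' @export
waveform_mean <- function(wf) {
  xs <- c(wf$times, wf$period)
  ys <- c(wf$values, wf$values[1])
  sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2) / wf$period
}

#' @export
print.inlet_waveform <- function(x, ...) {
  cat(sprintf("<inlet_waveform> %s %s, T = %g s, %d samples, range [%.4g, %.4g]\n",
              x$shape, x$kind, x$period, length(x$times), x$qmin, x$qmax))
  invisible(x)
}

#' Write / read a waveform as CSV (columns time,value)
#' @param wf an `inlet_waveform`.
#' @param path CSV file path.
#' @return `path` (write) or an `inlet_waveform` (read).
#' @export
write_waveform_csv <- function(wf, path) {
  utils::write.csv(data.frame(time = wf$times, value = wf$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @param kind waveform kind for the read object.
#' @param period cycle period; defaults to extrapolating the sample grid.
#' @export
read_waveform_csv <- function(path, kind = "pressure", period = NULL) {
  tab <- utils::read.csv(path)
  t <- tab$time
  if (is.null(period)) period <- t[length(t)] + (t[2] - t[1])
  v <- tab$value
  i_max <- which.max(v); i_min <- which.min(v)
  dt_ex <- abs(t[i_max] - t[i_min])
  if (dt_ex == 0) dt_ex <- period / 2
  structure(list(times = t, values = v, period = period, kind = kind,
                 qmax = max(v), qmin = min(v), extrema_interval = dt_ex,
                 shape = "sampled"),
            class = "inlet_waveform")
}

#' Write an outlet set as CSV
#' @param outlets an `outlet_set`.
#' @param path CSV file path.
#' @export
write_outlet_csv <- function(outlets, path) {
  utils::write.csv(as.data.frame(outlets), path, row.names = FALSE)
  invisible(path)
}

#' Synthesize a time-resolved wall-shear field with planted ground truth
#'
#' Builds per-node wall-shear stress vectors over one cardiac cycle on a
#' sac surface, with a controllable fraction of the surface area assigned a
#' low time-averaged magnitude. Nodes are ranked deterministically and
#' flagged "low" until the cumulative barycentric node area reaches the
#' requested fraction (one-triangle granularity). Patterns:
#' \describe{
#'   \item{steady}{constant vector per node; OSI is exactly 0.}
#'   \item{reversing}{single-harmonic sign-reversing vector; the zero-mean
#'     cycle makes OSI exactly 0.5. Amplitudes are scaled by pi/2 so the
#'     time-averaged magnitude equals the target TAWSS.}
#'   \item{mixed}{alternate nodes steady / reversing.}
#' }
#'
#' @param sac a `sac_geometry` (or bare mesh list) supplying the surface.
#' @param pattern `"steady"`, `"reversing"` or `"mixed"`.
#' @param low_area_fraction fraction of total area planted below
#'   `low_tawss` in time-averaged magnitude, in [0, 1].
#' @param period cycle period (s).
#' @param n_times time samples spanning the closed period (>= 9).
#' @param low_tawss,high_tawss target time-averaged magnitudes (Pa) for the
#'   low and high regions; the defaults straddle the 0.4 Pa threshold.
#' @return a `wss_field` with `surface`, `times`, `vectors`
#'   (n_nodes x n_times x 3 array, Pa), `period`, `low_nodes` (logical
#'   ground-truth labels) and `achieved_low_fraction`.
#' @export
make_wss_field <- function(sac, pattern = c("steady", "reversing", "mixed"),
                           low_area_fraction = 0, period = 0.84,
                           n_times = 33, low_tawss = 0.1, high_tawss = 1.5) {
  pattern <- match.arg(pattern)
  if (low_area_fraction < 0 || low_area_fraction > 1) {
    stop("low_area_fraction must lie in [0, 1]")
  }
  mesh <- if (inherits(sac, "sac_geometry")) sac$surface else sac
  n <- nrow(mesh$vertices)
  w <- node_area_weights(mesh)
  total <- sum(w)
  # deterministic ranking: sort nodes by z then x, accumulate area
  ord <- order(mesh$vertices[, 3], mesh$vertices[, 1])
  csum <- cumsum(w[ord])
  k <- findInterval(low_area_fraction * total, c(0, csum))
  # pick the cut (k-1, k or k+1 nodes) whose achieved fraction is closest
  cand <- unique(pmax(0, pmin(n, c(k - 1, k, k + 1))))
  ach <- vapply(cand, function(m) if (m == 0) 0 else csum[m] / total, 0)
  k <- cand[which.min(abs(ach - low_area_fraction))]
  low <- rep(FALSE, n)
  if (k > 0) low[ord[seq_len(k)]] <- TRUE
  times <- seq(0, period, length.out = n_times)
  # deterministic per-node unit directions
  i <- seq_len(n)
  dirs <- cbind(sin(1.7 * i), cos(2.3 * i), sin(3.1 * i + 1))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  target <- ifelse(low, low_tawss, high_tawss)
  reversing_node <- switch(pattern,
    steady = rep(FALSE, n),
    reversing = rep(TRUE, n),
    mixed = (i %% 2 == 0))
  vec <- array(0, dim = c(n, n_times, 3))
  s_rev <- sin(2 * pi * times / period)
  for (j in seq_len(n_times)) {
    amp <- ifelse(reversing_node, target * (pi / 2) * s_rev[j], target)
    vec[, j, ] <- dirs * amp
  }
  structure(list(surface = mesh, times = times, vectors = vec,
                 period = period, pattern = pattern, low_nodes = low,
                 achieved_low_fraction = if (k == 0) 0 else csum[k] / total),
            class = "wss_field")
}

#' @export
print.wss_field <- function(x, ...) {
  cat(sprintf("<wss_field> %s, %d nodes x %d times, T = %g s, planted low fraction %.4f\n",
              x$pattern, dim(x$vectors)[1], dim(x$vectors)[2], x$period,
              x$achieved_low_fraction))
  invisible(x)
}
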