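# Virtual coil embolization: seeded construction of planar-stacked and
# helical (precessing-axis) coil centerlines confined to an aneurysm sac,
# with non-overlap / non-intersection / containment enforcement, packing
# metrics and a tube-swept surface export.
#
# The generator lays the wire down turn by turn as a constrained random
# walk of circular loops. planar2D stacks loops along one fixed axis
# (lateral jitter only); helical3D precesses the loop axis between turns
# with a containment bias. A candidate turn is accepted only if every
# point keeps a half-wire margin to the sac wall and every new segment
# keeps one wire diameter of clearance to all non-adjacent existing
# segments; rejected turns are redrawn (retreat) under a bounded retry
# budget.

#' Coil specification
#'
#' Defaults mirror a standard embolization device: 0.6 mm platinum wire
#' wound into 18 mm loops, 40 cm long.
#'
#' @param wire_diameter wire (strand) diameter (m).
#' @param loop_diameter deployed loop diameter (m).
#' @param total_length wire length (m); typical series 0.4 / 0.8 / 1.6 m.
#' @param morphology `"planar2D"` (stacked parallel loops) or
#'   `"helical3D"` (precessing loop axis, spiral winding).
#' @param seed integer seed making the construction reproducible.
#' @return a `coil_spec` list.
#' @export
coil_spec <- function(wire_diameter = 6e-4, loop_diameter = 1.8e-2,
                      total_length = 0.4,
                      morphology = c("planar2D", "helical3D"),
                      seed = 42L) {
  morphology <- match.arg(morphology)
  if (wire_diameter >= loop_diameter) {
    stop("wire_diameter must be smaller than loop_diameter")
  }
  if (total_length <= loop_diameter) {
    stop("total_length must exceed loop_diameter")
  }
  structure(list(wire_diameter = wire_diameter,
                 loop_diameter = loop_diameter,
                 total_length = total_length, morphology = morphology,
                 seed = as.integer(seed)),
            class = "coil_spec")
}

#' Wire volume of a coil
#'
#' Cylinder volume pi (d/2)^2 L of the strand.
#'
#' @param spec a `coil_spec`.
#' @return volume (m^3).
#' @export
coil_volume <- function(spec) {
  pi * (spec$wire_diameter / 2)^2 * spec$total_length
}

#' Packing density of one or more coils in a sac
#'
#' Summed wire volume divided by sac volume.
#'
#' @param specs a `coil_spec` or list of them (may be empty).
#' @param sac a `sac_geometry`.
#' @return dimensionless fraction.
#' @export
packing_density <- function(specs, sac) {
  if (inherits(specs, "coil_spec")) specs <- list(specs)
  if (sac$volume <= 0) stop("sac volume must be positive")
  if (length(specs) == 0) return(0)
  sum(vapply(specs, coil_volume, 0)) / sac$volume
}

# run expr with a private RNG stream, restoring the caller's state
#' @keywords internal
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Rodrigues rotation of row vectors v about unit axis by angle
#' @keywords internal
rotate_about <- function(v, axis, angle) {
  v <- matrix(v, ncol = 3)
  k <- axis / sqrt(sum(axis^2))
  cs <- cos(angle); sn <- sin(angle)
  kx <- cbind(k[2] * v[, 3] - k[3] * v[, 2],
              k[3] * v[, 1] - k[1] * v[, 3],
              k[1] * v[, 2] - k[2] * v[, 1])
  kdot <- as.numeric(v %*% k)
  v * cs + kx * sn + outer(kdot * (1 - cs), k)
}

#' @keywords internal
unit <- function(v) v / sqrt(sum(v^2))

#' @keywords internal
perp_basis <- function(ax) {
  h <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit(pracma_cross(ax, h))
  v <- pracma_cross(ax, u)
  list(u = u, v = v)
}

#' @keywords internal
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# exact min distances between segment sets (interior-interior solution if
# valid, else best endpoint-to-segment distance); all pairs (i in A, j in B)
# restricted by a caller-supplied keep mask on the index grid
#' @keywords internal
segment_pair_dist <- function(pa1, pa2, pb1, pb2, ia, ib, keep) {
  if (!any(keep)) return(numeric(0))
  gi <- rep(seq_along(ia), times = length(ib))[keep]
  gj <- rep(seq_along(ib), each = length(ia))[keep]
  p1 <- pa1[gi, , drop = FALSE]; q1 <- pa2[gi, , drop = FALSE]
  p2 <- pb1[gj, , drop = FALSE]; q2 <- pb2[gj, , drop = FALSE]
  u <- q1 - p1; v <- q2 - p2; w0 <- p1 - p2
  a <- rowSums(u * u); b <- rowSums(u * v); cc <- rowSums(v * v)
  d <- rowSums(u * w0); e <- rowSums(v * w0)
  den <- a * cc - b * b
  sc <- ifelse(den > 0, (b * e - cc * d) / den, -1)
  tc <- ifelse(den > 0, (a * e - b * d) / den, -1)
  interior <- sc >= 0 & sc <= 1 & tc >= 0 & tc <= 1
  diffv <- w0 + u * sc - v * tc
  d_int <- sqrt(rowSums(diffv * diffv))
  pt_seg <- function(p, s1, sd, ss) {
    t <- rowSums((p - s1) * sd) / ss
    t <- pmin(pmax(t, 0), 1)
    dv <- p - (s1 + sd * t)
    sqrt(rowSums(dv * dv))
  }
  ssa <- pmax(a, .Machine$double.eps)
  ssb <- pmax(cc, .Machine$double.eps)
  d_end <- pmin(pt_seg(p1, p2, v, ssb), pt_seg(q1, p2, v, ssb),
                pt_seg(p2, p1, u, ssa), pt_seg(q2, p1, u, ssa))
  ifelse(interior, pmin(d_int, d_end), d_end)
}

# min clearance between new segments [n0+1 .. n0+m] and all segments of the
# polyline so far, exempting pairs within `window` indices of each other
#' @keywords internal
min_clearance_new <- function(pts, n0, window = 2L) {
  n_seg <- nrow(pts) - 1L
  if (n_seg < 2L) return(Inf)
  new_idx <- (n0 + 1L):n_seg
  all_idx <- 1L:n_seg
  ia <- new_idx; ib <- all_idx
  grid_i <- rep(ia, times = length(ib))
  grid_j <- rep(ib, each = length(ia))
  keep <- grid_j < grid_i & (grid_i - grid_j) > window
  if (!any(keep)) return(Inf)
  d <- segment_pair_dist(pts[ia, , drop = FALSE],
                         pts[ia + 1L, , drop = FALSE],
                         pts[ib, , drop = FALSE],
                         pts[ib + 1L, , drop = FALSE],
                         ia, ib, keep)
  min(d)
}

#' Generate a coil centerline inside a sac
#'
#' Seeded, constraint-enforced construction of the coil wire centerline.
#' The loop radius is never larger than the specified one; it adapts
#' downward when the sac is too small to hold the nominal loop with a
#' half-wire wall margin. The wire is laid down loop by loop; each
#' candidate loop must keep every point at least half a wire diameter
#' inside the sac and every segment at least one wire diameter away from
#' all non-adjacent segments, otherwise the loop is redrawn. The final
#' point is interpolated so the polyline arc length equals the specified
#' wire length to machine precision.
#'
#' @param spec a [coil_spec()].
#' @param sac a `sac_geometry` from [make_sac()].
#' @param n_per_turn polyline points per full loop.
#' @param pitch_factor loop-to-loop spacing in wire diameters (planar
#'   stacking).
#' @param max_retries total retreat budget before a packing failure is
#'   raised.
#' @return a `coil_centerline`: `points` (n x 3, m), `arc_length` (m),
#'   `turn_index` per point, `loop_diameter_effective`,
#'   `min_self_clearance`, `min_wall_margin` and the generating `spec`.
#' @export
generate_coil <- function(spec, sac, n_per_turn = 48L, pitch_factor = 1.2,
                          max_retries = 1000L) {
  stopifnot(inherits(spec, "coil_spec"), inherits(sac, "sac_geometry"))
  wire_r <- spec$wire_diameter / 2
  if (sac$volume <= coil_volume(spec)) {
    stop("sac volume too small for the requested wire volume")
  }
  if (spec$loop_diameter > 2 * sac$inscribed_radius) {
    stop("loop diameter exceeds the sac's largest inscribed sphere")
  }
  r_loop <- min(spec$loop_diameter / 2,
                sac$inscribed_radius - wire_r - 5e-4)
  helical <- spec$morphology == "helical3D"
  dtheta <- 2 * pi / n_per_turn
  # axial advance per turn: planar stacks at just over one wire diameter;
  # helical loops tilt between turns, so spacing grows with the maximum
  # precession angle to preserve clearance on the tilted side
  beta_max <- 0.12
  pitch <- if (helical) {
    max(pitch_factor * spec$wire_diameter, 2.2 * r_loop * sin(beta_max))
  } else {
    pitch_factor * spec$wire_diameter
  }
  n_turns <- ceiling(spec$total_length / (2 * pi * r_loop)) + 1L
  with_local_seed(spec$seed, {
    ax <- unit(stats::rnorm(3))
    basis <- perp_basis(ax)
    u <- basis$u; v <- basis$v
    # start so the stack is centred on the sac centroid along the axis
    start <- sac$centroid - ax * (n_turns * pitch / 2)
    pts <- matrix(start + r_loop * u, nrow = 1)
    centre <- start
    phi <- 0
    turn_id <- 0L
    turn_of <- integer(1)
    retries <- 0L
    total_len <- 0
    target <- spec$total_length
    while (total_len < target) {
      placed <- FALSE
      for (attempt in seq_len(50L)) {
        if (turn_id > 0L) {
          if (helical) {
            # precess the loop axis: random tilt, biased back toward the
            # centroid when the current loop centre drifts outward
            beta <- stats::runif(1, 0.5 * beta_max, beta_max)
            tilt_axis <- unit(pracma_cross(ax, unit(stats::rnorm(3))))
            ax_c <- unit(as.numeric(rotate_about(ax, tilt_axis, beta)))
            drift <- centre - sac$centroid
            room <- sac$inscribed_radius - r_loop - wire_r
            lam <- min(1, sqrt(sum(drift^2)) / max(room, 1e-9))
            if (lam > 0.4) {
              pull <- unit(-drift)
              ax_c <- unit(ax_c + 0.8 * lam * pull)
            }
          } else {
            ax_c <- ax
          }
          b <- perp_basis(ax_c)
          # keep the angular phase; re-anchor the centre so the new loop
          # starts exactly at the last laid point
          u_c <- as.numeric(rotate_about(b$u, ax_c, phi_offset(u, v, b, phi)))
          v_c <- pracma_cross(ax_c, u_c)
          jit <- if (helical) c(0, 0, 0) else {
            j <- stats::rnorm(3, sd = 1e-4)
            j - ax_c * sum(j * ax_c)        # lateral only
          }
          centre_c <- pts[nrow(pts), ] -
            r_loop * (cos(phi) * u_c + sin(phi) * v_c)
        } else {
          ax_c <- ax; u_c <- u; v_c <- v; centre_c <- centre
          jit <- c(0, 0, 0)
        }
        k <- seq_len(n_per_turn)
        th <- phi + k * dtheta
        frac <- k / n_per_turn
        block <- matrix(rep(centre_c, each = n_per_turn), ncol = 3) +
          outer(pitch * frac, ax_c) + outer(frac, jit) +
          outer(cos(th), r_loop * u_c) + outer(sin(th), r_loop * v_c)
        # containment with half-wire margin
        if (max(sac$sdf(block)) > -wire_r) {
          retries <- retries + 1L
          if (retries > max_retries) {
            stop(sprintf(
              "coil packing failed after %d retreats; achieved length %.4f m of %.4f m",
              retries - 1L, total_len, target))
          }
          next
        }
        cand <- rbind(pts, block)
        if (min_clearance_new(cand, nrow(pts) - 1L) <
            spec$wire_diameter) {
          retries <- retries + 1L
          if (retries > max_retries) {
            stop(sprintf(
              "coil packing failed after %d retreats; achieved length %.4f m of %.4f m",
              retries - 1L, total_len, target))
          }
          next
        }
        pts <- cand
        centre <- centre_c + pitch * ax_c + jit
        ax <- ax_c; u <- u_c; v <- v_c
        turn_id <- turn_id + 1L
        turn_of <- c(turn_of, rep(turn_id, n_per_turn))
        seg_len <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                                   pts[-nrow(pts), , drop = FALSE])^2))
        total_len <- sum(seg_len)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop(sprintf(
          "coil packing failed after %d retreats; achieved length %.4f m of %.4f m",
          retries, total_len, target))
      }
    }
  })
  # trim to the exact wire length: walk segments, interpolate the last one
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  cs <- cumsum(seg)
  last <- which(cs >= spec$total_length)[1]
  excess <- cs[last] - spec$total_length
  frac <- 1 - excess / seg[last]
  end_pt <- pts[last, ] + frac * (pts[last + 1, ] - pts[last, ])
  pts <- rbind(pts[seq_len(last), , drop = FALSE], end_pt)
  turn_of <- c(turn_of[seq_len(last)], turn_of[last + 1L])
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  out <- structure(list(points = pts, arc_length = sum(seg),
                        turn_index = turn_of,
                        loop_diameter_effective = 2 * r_loop,
                        n_per_turn = n_per_turn, spec = spec),
                   class = "coil_centerline")
  chk <- check_constraints(out, spec, sac)
  out$min_self_clearance <- chk$min_self_clearance
  out$min_wall_margin <- chk$min_wall_margin
  out
}

# angle offset needed so the rotated basis keeps point continuity; with the
# phase preserved the offset is zero, kept explicit for clarity
#' @keywords internal
phi_offset <- function(u, v, b, phi) 0

#' @export
print.coil_centerline <- function(x, ...) {
  cat(sprintf(
    "<coil_centerline> %s, %.4f m over %d points (%d turns), loop %.1f mm\n",
    x$spec$morphology, x$arc_length, nrow(x$points), max(x$turn_index),
    1000 * x$loop_diameter_effective))
  invisible(x)
}

#' Brute-force constraint verification of a coil centerline
#'
#' Independent verifier: exact minimum distance over all pairs of
#' non-adjacent segments (adjacency window of `window` indices exempted to
#' allow curvature), and the wall margin from signed distances at densely
#' resampled points. Deliberately shares no spatial indexing with the
#' generator.
#'
#' @param centerline a `coil_centerline` (or list with `points`).
#' @param spec the governing [coil_spec()].
#' @param sac the containing `sac_geometry`.
#' @param window adjacency exemption in segment indices.
#' @param resample densification factor for the wall-margin scan.
#' @return list with `min_self_clearance` (m), `min_wall_margin` (m,
#'   negative if any point leaves the sac), and `pass`.
#' @export
check_constraints <- function(centerline, spec, sac, window = 2L,
                              resample = 4L) {
  pts <- centerline$points
  n_seg <- nrow(pts) - 1L
  wire_r <- spec$wire_diameter / 2
  # all-pairs segment clearance, chunked to bound memory
  min_d <- Inf
  if (n_seg > window + 1L) {
    chunk <- 200L
    starts <- seq(1L, n_seg, by = chunk)
    for (s0 in starts) {
      ia <- s0:min(s0 + chunk - 1L, n_seg)
      ib <- 1L:n_seg
      grid_i <- rep(ia, times = length(ib))
      grid_j <- rep(ib, each = length(ia))
      keep <- grid_j < grid_i & (grid_i - grid_j) > window
      if (!any(keep)) next
      d <- segment_pair_dist(pts[ia, , drop = FALSE],
                             pts[ia + 1L, , drop = FALSE],
                             pts[ib, , drop = FALSE],
                             pts[ib + 1L, , drop = FALSE],
                             ia, ib, keep)
      min_d <- min(min_d, d)
    }
  }
  # wall margin on a densified polyline
  t <- seq(0, 1, length.out = resample + 1L)[-1L]
  a <- pts[-nrow(pts), , drop = FALSE]
  b <- pts[-1L, , drop = FALSE]
  dense <- rbind(pts[1L, , drop = FALSE],
                 do.call(rbind, lapply(t, function(f) a + (b - a) * f)))
  margin <- -max(sac$sdf(dense))
  tol <- 1e-9
  list(min_self_clearance = min_d, min_wall_margin = margin,
       pass = (min_d >= spec$wire_diameter * (1 - tol)) &&
         (margin >= wire_r * (1 - tol)))
}

#' Measure per-loop diameters of a coil centerline
#'
#' Independent of generator metadata: the cumulative turning angle of the
#' polyline is accumulated and cut at multiples of 2 pi; each complete
#' turn's diameter is twice the mean distance of its points from the turn
#' centroid (equal to the circle diameter for circular loops).
#'
#' @param centerline a `coil_centerline`.
#' @return numeric vector of per-turn diameters (m).
#' @export
measure_loop_diameters <- function(centerline) {
  pts <- centerline$points
  d <- pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  dn <- d / len
  cosang <- rowSums(dn[-1, , drop = FALSE] * dn[-nrow(dn), , drop = FALSE])
  ang <- acos(pmin(pmax(cosang, -1), 1))
  cum <- c(0, cumsum(ang))                 # turning angle at each interior vertex
  turn <- floor(cum / (2 * pi))
  ids <- unique(turn)
  complete <- ids[ids < max(turn)]         # drop the trailing partial turn
  vapply(complete, function(m) {
    sel <- which(turn == m)
    p <- pts[sel, , drop = FALSE]
    ctr <- colMeans(p)
    2 * mean(sqrt(rowSums(sweep(p, 2, ctr)^2)))
  }, 0)
}

#' Sweep a tube surface around a centerline
#'
#' Builds a closed triangulated tube of circular cross-section using
#' parallel-transported frames, with flat end caps. Ring vertices are
#' placed at the circumscribed-polygon radius (d/2)/cos(pi/sides) so the
#' polygon's inscribed circle matches the wire surface.
#'
#' @param centerline a `coil_centerline` or n x 3 point matrix.
#' @param wire_diameter tube (wire) diameter (m).
#' @param sides polygon sides per ring (>= 6).
#' @return a watertight mesh list with attribute `ring_vertices` (count of
#'   lateral-surface vertices; the final two are the cap centres).
#' @export
sweep_tube <- function(centerline, wire_diameter, sides = 12L) {
  pts <- if (is.matrix(centerline)) centerline else centerline$points
  if (sides < 6L) stop("need at least 6 polygon sides")
  seg <- pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  if (any(len == 0)) stop("degenerate (zero-length) centerline segment")
  n <- nrow(pts)
  dirs <- seg / len
  # per-vertex tangents: average of adjacent segment directions
  tans <- rbind(dirs[1, ],
                (dirs[-1, , drop = FALSE] + dirs[-nrow(dirs), , drop = FALSE]) / 2,
                dirs[nrow(dirs), ])
  tans <- tans / sqrt(rowSums(tans^2))
  rad <- (wire_diameter / 2) / cos(pi / sides)
  # parallel transport an initial normal along the polyline
  nrm <- matrix(0, n, 3)
  nrm[1, ] <- perp_basis(tans[1, ])$u
  for (i in 2:n) {
    cr <- pracma_cross(tans[i - 1, ], tans[i, ])
    s <- sqrt(sum(cr^2))
    if (s < 1e-12) {
      nrm[i, ] <- nrm[i - 1, ]
    } else {
      angle <- asin(pmin(s, 1))
      if (sum(tans[i - 1, ] * tans[i, ]) < 0) angle <- pi - angle
      nrm[i, ] <- as.numeric(rotate_about(nrm[i - 1, ], cr / s, angle))
    }
    nrm[i, ] <- unit(nrm[i, ] - tans[i, ] * sum(nrm[i, ] * tans[i, ]))
  }
  binl <- cbind(tans[, 2] * nrm[, 3] - tans[, 3] * nrm[, 2],
                tans[, 3] * nrm[, 1] - tans[, 1] * nrm[, 3],
                tans[, 1] * nrm[, 2] - tans[, 2] * nrm[, 1])
  ang <- (seq_len(sides) - 1) * 2 * pi / sides
  verts <- matrix(0, n * sides + 2L, 3)
  for (i in seq_len(n)) {
    ring <- matrix(rep(pts[i, ], each = sides), ncol = 3) +
      rad * (outer(cos(ang), nrm[i, ]) + outer(sin(ang), binl[i, ]))
    verts[((i - 1) * sides + 1):(i * sides), ] <- ring
  }
  c0 <- n * sides + 1L
  c1 <- n * sides + 2L
  verts[c0, ] <- pts[1, ]
  verts[c1, ] <- pts[n, ]
  faces <- vector("list", n - 1L + 2L)
  for (i in seq_len(n - 1L)) {
    a <- (i - 1) * sides + seq_len(sides)
    b <- a + sides
    a2 <- (i - 1) * sides + c(2:sides, 1)
    b2 <- a2 + sides
    faces[[i]] <- rbind(cbind(a, b, a2), cbind(a2, b, b2))
  }
  first <- seq_len(sides)
  faces[[n]] <- cbind(c0, first, c(2:sides, 1))
  lastr <- (n - 1) * sides + seq_len(sides)
  faces[[n + 1L]] <- cbind(c1, (n - 1) * sides + c(2:sides, 1), lastr)
  mesh <- new_trimesh(verts, do.call(rbind, faces))
  attr(mesh, "ring_vertices") <- n * sides
  mesh
}

#' Measure the wire diameter of a swept tube
#'
#' Twice the mean distance of lateral-surface vertices to the nearest
#' point of the centerline polyline, corrected for the circumscribed
#' polygon (multiplied by cos(pi/sides)).
#'
#' @param mesh a tube mesh from [sweep_tube()].
#' @param centerline the generating `coil_centerline` or point matrix.
#' @param sides polygon sides used in the sweep.
#' @return estimated wire diameter (m).
#' @export
measure_tube_diameter <- function(mesh, centerline, sides = 12L) {
  pts <- if (is.matrix(centerline)) centerline else centerline$points
  nring <- attr(mesh, "ring_vertices")
  vv <- mesh$vertices[seq_len(nring), , drop = FALSE]
  a <- pts[-nrow(pts), , drop = FALSE]
  b <- pts[-1, , drop = FALSE]
  d <- b - a
  ss <- pmax(rowSums(d * d), .Machine$double.eps)
  # distance of each vertex to nearest segment, chunked over vertices
  mind <- numeric(nrow(vv))
  chunk <- 500L
  for (s0 in seq(1L, nrow(vv), by = chunk)) {
    idx <- s0:min(s0 + chunk - 1L, nrow(vv))
    dm <- matrix(Inf, length(idx), nrow(a))
    for (j in seq_len(nrow(a))) {
      w <- sweep(vv[idx, , drop = FALSE], 2, a[j, ])
      t <- pmin(pmax((w %*% d[j, ]) / ss[j], 0), 1)
      dv <- w - outer(as.numeric(t), d[j, ])
      dm[, j] <- sqrt(rowSums(dv * dv))
    }
    mind[idx] <- apply(dm, 1, min)
  }
  2 * mean(mind) * cos(pi / sides)
}

#' Write a coil centerline as CSV (columns x,y,z)
#' @param centerline a `coil_centerline`.
#' @param path CSV path.
#' @export
write_centerline_csv <- function(centerline, path) {
  p <- centerline$points
  utils::write.csv(data.frame(x = p[, 1], y = p[, 2], z = p[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}
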