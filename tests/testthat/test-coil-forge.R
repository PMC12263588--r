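test_that("coil specs validate device geometry", {
  spec <- coil_spec()
  expect_equal(spec$wire_diameter, 6e-4)
  expect_equal(spec$loop_diameter, 1.8e-2)
  expect_error(coil_spec(wire_diameter = 0.02), "wire_diameter")
  expect_error(coil_spec(total_length = 0.01), "total_length")
})

test_that("wire volume and packing density follow the cylinder model", {
  # hand evaluation: pi * (3e-4)^2 * 0.4
  expect_equal(coil_volume(coil_spec(total_length = 0.4)), 1.1310e-7,
               tolerance = 1e-4)
  expect_equal(coil_volume(coil_spec(total_length = 0.8)),
               2 * coil_volume(coil_spec(total_length = 0.4)))
  sac <- make_sac("sphere", 0.009, resolution = 5e-4)
  expect_equal(packing_density(coil_spec(total_length = 0.4), sac),
               0.03704, tolerance = 5e-3)
  expect_identical(packing_density(list(), sac), 0)
  dens <- vapply(c(0.4, 0.8, 1.6), function(L) {
    packing_density(coil_spec(total_length = L), sac)
  }, 0)
  expect_equal(dens[2] / dens[1], 2)
  expect_equal(dens[3] / dens[1], 4)
})

test_that("generated coils hit the specified length under all constraints", {
  sac <- test_sac()
  for (L in c(0.4, 1.6)) {
    cl <- generate_coil(coil_spec(total_length = L, seed = 42L), sac)
    expect_equal(cl$arc_length, L, tolerance = 1e-3)
    expect_gte(cl$min_self_clearance, 6e-4)
    expect_gte(cl$min_wall_margin, 3e-4)
    chk <- check_constraints(cl, cl$spec, sac)
    expect_true(chk$pass)
  }
})

test_that("coil generation is deterministic under its seed", {
  sac <- test_sac()
  a <- generate_coil(coil_spec(seed = 5L), sac)
  b <- generate_coil(coil_spec(seed = 5L), sac)
  expect_identical(a$points, b$points)
  c_ <- generate_coil(coil_spec(seed = 6L), sac)
  expect_false(isTRUE(all.equal(a$points, c_$points)))
})

test_that("generator and brute-force verifier agree across seeded runs", {
  sac <- test_sac()
  for (seed in 1:6) {
    for (morph in c("planar2D", "helical3D")) {
      cl <- generate_coil(coil_spec(total_length = 0.4, morphology = morph,
                                    seed = seed), sac)
      chk <- check_constraints(cl, cl$spec, sac)
      expect_true(chk$pass, label = sprintf("seed %d %s", seed, morph))
      expect_gte(chk$min_self_clearance, cl$spec$wire_diameter)
    }
  }
})

test_that("the verifier rejects escapes and overlaps", {
  sac <- test_sac()
  spec <- coil_spec()
  line <- list(points = cbind(seq(-0.03, 0.03, length.out = 20), 0, 0))
  chk <- check_constraints(line, spec, sac)
  expect_false(chk$pass)
  expect_lt(chk$min_wall_margin, 0)
  th <- seq(0, 2 * pi, length.out = 49)[-49]
  loop <- cbind(0.009 * cos(th), 0.009 * sin(th), 0)
  twice <- list(points = rbind(loop, loop))
  chk2 <- check_constraints(twice, spec, sac)
  expect_false(chk2$pass)
  expect_lt(chk2$min_self_clearance, 1e-9)
})

test_that("morphologies differ as labelled: stacked planes vs winding axes", {
  sac <- test_sac()
  per_turn_svd <- function(cl) {
    lapply(split(seq_len(nrow(cl$points)), cl$turn_index), function(ix) {
      if (length(ix) < 10) return(NULL)
      p <- cl$points[ix, , drop = FALSE]
      svd(sweep(p, 2, colMeans(p)))
    })
  }
  pl <- generate_coil(coil_spec(seed = 3L), sac)
  res <- vapply(Filter(Negate(is.null), per_turn_svd(pl)), function(s) {
    max(abs(s$u[, 3] * s$d[3]))
  }, 0)
  expect_true(all(res < pl$spec$wire_diameter))  # near-planar loops
  hx <- generate_coil(coil_spec(morphology = "helical3D", seed = 3L), sac)
  axes <- t(vapply(Filter(Negate(is.null), per_turn_svd(hx)),
                   function(s) s$v[, 3], numeric(3)))
  angles <- acos(pmin(abs(rowSums(axes[-1, ] * axes[-nrow(axes), ])), 1))
  expect_gt(mean(angles), 0.01)                  # consecutive axes vary
})

test_that("loop diameters measured on the polyline match the device", {
  sac <- test_sac()
  cl <- generate_coil(coil_spec(seed = 42L), sac)
  d <- measure_loop_diameters(cl)
  expect_gt(length(d), 4)
  expect_equal(mean(d), 1.8e-2, tolerance = 0.05)
})

test_that("arc length is invariant under 2x resampling", {
  sac <- test_sac()
  cl <- generate_coil(coil_spec(seed = 2L), sac)
  p <- cl$points
  mid <- (p[-1, , drop = FALSE] + p[-nrow(p), , drop = FALSE]) / 2
  dense <- matrix(0, nrow(p) + nrow(mid), 3)
  dense[seq(1, nrow(dense), by = 2), ] <- p
  dense[seq(2, nrow(dense), by = 2), ] <- mid
  len <- function(q) sum(sqrt(rowSums((q[-1, ] - q[-nrow(q), ])^2)))
  expect_equal(len(dense), cl$arc_length, tolerance = 1e-4)
})

test_that("packing failures are explicit, not silent", {
  small <- make_sac("sphere", 0.002, resolution = 5e-4)
  expect_error(generate_coil(coil_spec(), small), "inscribed|volume")
  tiny <- make_sac("sphere", 0.0095, resolution = 2e-3)
  # loop fits the inscribed sphere but a long wire cannot stack: the
  # retreat budget must end in a packing-failure diagnostic
  expect_error(
    generate_coil(coil_spec(total_length = 3, loop_diameter = 1.8e-2),
                  tiny, max_retries = 30L),
    "packing failed")
})

test_that("swept tubes are watertight with the right area and radius", {
  cylpts <- cbind(0, 0, seq(0, 0.1, length.out = 2))
  tube <- sweep_tube(cylpts, 6e-4, sides = 24)
  expect_true(is_watertight(tube))
  target <- pi * 6e-4 * 0.1 + 2 * pi * (3e-4)^2
  expect_equal(sum(triangle_areas(tube)), target, tolerance = 0.015)
  sac <- test_sac()
  cl <- generate_coil(coil_spec(seed = 42L), sac)
  coil_tube <- sweep_tube(cl, 6e-4, sides = 12)
  expect_true(is_watertight(coil_tube))
  expect_equal(measure_tube_diameter(coil_tube, cl, sides = 12), 6e-4,
               tolerance = 0.01)
  expect_error(sweep_tube(rbind(c(0, 0, 0), c(0, 0, 0)), 6e-4),
               "degenerate")
  expect_error(sweep_tube(cylpts, 6e-4, sides = 3), "sides")
})

test_that("centerline CSV export holds the polyline", {
  sac <- test_sac()
  cl <- generate_coil(coil_spec(seed = 9L), sac)
  path <- withr::local_tempfile(fileext = ".csv")
  write_centerline_csv(cl, path)
  tab <- utils::read.csv(path)
  expect_identical(nrow(tab), nrow(cl$points))
  expect_equal(as.matrix(tab), cl$points, ignore_attr = TRUE,
               tolerance = 1e-9)
})
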