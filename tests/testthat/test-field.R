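test_that("straight channel reproduces the analytic uniform-field limit", {
  dev <- straight_device()        # 0.1 cm long, 100 V
  sol <- dev$solution
  L_m <- dev$geometry$length_cm * 1e-2
  E_exact <- dev$voltage / L_m
  # away from the inlet/outlet faces the field is uniform within 1%
  interior <- sol$Emag[, 10:(ncol(sol$Emag) - 10)]
  expect_true(all(abs(interior - E_exact) / E_exact < 0.01))
  # potential at the channel midpoint is V/2 by symmetry
  mid <- ncol(sol$phi) %/% 2
  expect_lt(abs(mean(sol$phi[, mid:(mid + 1)]) - dev$voltage / 2),
            0.01 * dev$voltage)
  # capture parameter vanishes for a uniform field (roundoff only)
  expect_lt(max(abs(sol$cap), na.rm = TRUE), 1e-3 * E_exact / L_m)
  expect_lt(sol$residual, 1e-8)
})

test_that("gate throat concentrates the field and the capture parameter", {
  geom <- build_reference_geometry(n_gates = 1, widths_um = 30, group_size = 1,
                                   length_cm = 0.04, background_width_um = 100)
  mask <- rasterize(geom, 1)
  sol <- solve_potential(mask, 100)
  throat <- mask$throats[[1]]
  throat_E <- max(sol$Emag[throat$rows, throat$col], na.rm = TRUE)
  bulk_E <- stats::median(sol$Emag[, 20], na.rm = TRUE)
  expect_gt(throat_E, 2 * bulk_E)
  # the largest capture parameter on the centreline sits on the approach to
  # the gate, within the tooth's field-disturbance region
  mid <- as.integer(round(mean(range(throat$rows))))
  centre <- sol$cap[mid, ]
  reach <- ((35 + 6) * tan(pi / 6) + 35) / mask$spacing_um + 3
  expect_lt(abs(which.max(centre) - throat$col), reach)
})

test_that("fields and thresholds scale linearly with applied voltage", {
  dev <- toy_device(voltage = 1000)
  sol2 <- solve_potential(dev$mask, 2000)
  ok <- !is.na(dev$solution$cap) & !is.na(sol2$cap) &
    abs(dev$solution$cap) > 1e-3 * max(abs(dev$solution$cap), na.rm = TRUE)
  ratio <- sol2$cap[ok] / dev$solution$cap[ok]
  expect_true(all(abs(ratio - 2) < 0.02))
  # unit-voltage gate profiles agree across solve voltages within 1%
  p1 <- dev$profile
  p2 <- gate_thresholds(sol2, dev$mask)
  expect_true(all(abs(p2$c_unit_voltage / p1$c_unit_voltage - 1) < 0.01))
})

test_that("solution is mirror-symmetric about the channel axis", {
  dev <- toy_device()
  E <- dev$solution$Emag
  flipped <- E[rev(seq_len(nrow(E))), ]
  ok <- !is.na(E) & !is.na(flipped)
  expect_true(all(abs(E[ok] - flipped[ok]) <= 1e-6 * max(E, na.rm = TRUE)))
})

test_that("reference profile is monotone: narrower gates oppose harder", {
  prof <- ref_device()$profile
  expect_identical(nrow(prof), 27L)
  # equal-width gates share a threshold; group means strictly increase
  grp <- rep(seq_len(9), each = 3)
  within_spread <- tapply(prof$c_unit_voltage, grp,
                          function(x) diff(range(x)) / mean(x))
  expect_true(all(within_spread < 0.02))
  gm <- tapply(prof$c_unit_voltage, grp, mean)
  expect_true(all(diff(gm) > 0))
  # consecutive thresholds non-decreasing up to discretization jitter
  expect_true(all(diff(prof$c_unit_voltage) > -0.02 * prof$c_unit_voltage[-27]))
})

test_that("threshold scaling to an applied voltage is elementwise", {
  prof <- make_profile(c(1e6, 2e6))
  expect_equal(thresholds_at(prof, 1200), c(1.2e9, 2.4e9))
  expect_equal(thresholds_at(prof, 0), c(0, 0))
  expect_equal(thresholds_at(prof, 2000), 2 * thresholds_at(prof, 1000))
  expect_error(thresholds_at(prof, -1), "non-negative")
})

test_that("a channel without gates yields an empty profile", {
  dev <- straight_device()
  prof <- gate_thresholds(dev$solution, dev$mask)
  expect_identical(nrow(prof), 0L)
})

test_that("gate thresholds converge under grid refinement", {
  geom <- toy_device()$geometry
  mask2 <- rasterize(geom, 1)
  p2 <- gate_thresholds(solve_potential(mask2, 1000), mask2)
  mask1 <- rasterize(geom, 0.5)
  p1 <- gate_thresholds(solve_potential(mask1, 1000), mask1)
  rel <- abs(p1$c_unit_voltage / p2$c_unit_voltage - 1)
  # per-gate discretization uncertainty stays below 10% per halving, and the
  # profile as a whole moves by less than 5%
  expect_true(all(rel < 0.10))
  expect_lt(abs(mean(p1$c_unit_voltage / p2$c_unit_voltage) - 1), 0.05)
  # threshold ratios (which set the spectrum geometry) are grid-stable
  r1 <- p1$c_unit_voltage / p1$c_unit_voltage[1]
  r2 <- p2$c_unit_voltage / p2$c_unit_voltage[1]
  expect_true(all(abs(r1 / r2 - 1) < 0.1))
})

test_that("disconnected or degenerate domains are rejected", {
  geom <- build_reference_geometry(n_gates = 1, widths_um = 30, group_size = 1,
                                   length_cm = 0.04, background_width_um = 100)
  mask <- rasterize(geom, 1)
  expect_error(solve_potential(mask, -5), "positive")
})
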