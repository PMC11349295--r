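test_that("background subtraction clamps at zero and rejects bad input", {
  expect_equal(subtract_background(100, 30), 70)
  expect_equal(subtract_background(30, 30), 0)
  expect_equal(subtract_background(10, 30), 0)
  expect_equal(subtract_background(c(100, 10), 30), c(70, 0))
  expect_error(subtract_background(-1, 0), "non-negative")
})

simple_table <- function(intensities, voltage = 1200, condition = "n",
                         replicate = 1L) {
  data.frame(condition = condition, replicate = replicate,
             voltage_V = voltage, gate_index = seq_along(intensities),
             intensity = intensities)
}

test_that("per-voltage normalization divides by the group maximum or sum", {
  tb <- simple_table(c(2, 4, 8))
  expect_equal(normalize_per_voltage(tb)$intensity, c(0.25, 0.5, 1))
  expect_equal(normalize_per_voltage(tb, "sum")$intensity, c(2, 4, 8) / 14)
  # idempotence for the max convention
  once <- normalize_per_voltage(tb)
  expect_equal(normalize_per_voltage(once)$intensity, once$intensity)
  # degenerate all-zero group passes through with a warning
  expect_warning(z <- normalize_per_voltage(simple_table(c(0, 0))), "all-zero")
  expect_equal(z$intensity, c(0, 0))
  # groups are normalized independently per replicate and voltage
  tb2 <- rbind(simple_table(c(1, 2), replicate = 1L),
               simple_table(c(5, 10), replicate = 2L))
  expect_equal(normalize_per_voltage(tb2)$intensity, c(0.5, 1, 0.5, 1))
})

test_that("same-width gate triplets aggregate to one spectrum row each", {
  geom <- build_reference_geometry()
  prof <- make_profile(rep(seq(1e6, 9e6, by = 1e6), each = 3),
                       widths = geom$gates$width_um)
  tb <- simple_table(seq(0, 1, length.out = 27))
  agg <- aggregate_gate_triplets(tb, geom, prof)
  expect_identical(nrow(agg), 9L)
  expect_equal(agg$ekmr_V_per_m2, 1200 * seq(1e6, 9e6, by = 1e6))
  # mean identity: equal intensities within a group aggregate to that value
  tb2 <- simple_table(rep(c(0.2, 0.7, 0.4), each = 3, times = 3))
  agg2 <- aggregate_gate_triplets(tb2, geom, prof)
  expect_equal(agg2$intensity[1:3], c(0.2, 0.7, 0.4))
  # aggregation commutes with uniform rescaling
  tb3 <- tb; tb3$intensity <- tb3$intensity * 3.7
  expect_equal(aggregate_gate_triplets(tb3, geom, prof)$intensity,
               3.7 * agg$intensity)
  expect_error(aggregate_gate_triplets(simple_table(rep(1, 30)), geom, prof),
               "gate indices")
})

test_that("spectra are normalized, ordered and carry replicate SEMs", {
  geom <- build_reference_geometry()
  prof <- make_profile(rep(seq(1e6, 9e6, by = 1e6), each = 3),
                       widths = geom$gates$width_um)
  tb <- rbind(simple_table(1:27, replicate = 1L),
              simple_table(27:1, replicate = 2L))
  sp <- build_spectrum(tb, geom, prof)
  expect_s3_class(sp, "ekmr_spectrum")
  expect_identical(nrow(sp), 9L)
  expect_true(all(sp$mean_intensity >= 0 & sp$mean_intensity <= 1))
  expect_true(all(diff(sp$ekmr_V_per_m2) > 0))
  expect_identical(unique(sp$n_replicates), 2L)
  expect_true(all(is.finite(sp$sem)))
  # a single replicate has no SEM
  sp1 <- build_spectrum(simple_table(1:27), geom, prof)
  expect_true(all(is.na(sp1$sem)))
})

test_that("a zero-dispersion population concentrates all mass at one EKMr", {
  dev <- ref_device()
  cfg <- mixture_config(6e9, dispersions = 0, n_particles = 200)
  pop <- sample_population(cfg, seed = 3)
  scan <- run_scan(pop, dev$profile, scan_protocol(), noise_sd = 0)
  sp <- build_spectrum(scan$intensities, dev$geometry, dev$profile)
  for (v in unique(sp$voltage_V)) {
    nonzero <- sum(sp$mean_intensity[sp$voltage_V == v] > 0)
    expect_lte(nonzero, 1L)
  }
})

test_that("well-separated mixture components are recovered as spectrum peaks", {
  dev <- ref_device()
  locs <- c(8e9, 1.4e10)
  cfg <- mixture_config(locs, weights = c(0.5, 0.5), dispersions = 0,
                        n_particles = 400)
  pop <- sample_population(cfg, seed = 13)
  scan <- run_scan(pop, dev$profile, scan_protocol(), noise_sd = 0)
  obs <- spectrum_observations(scan$intensities, dev$geometry, dev$profile,
                               voltage = 1200)
  obs <- obs[order(obs$ekmr_V_per_m2), ]
  top2 <- sort(order(obs$intensity, decreasing = TRUE)[1:2])
  level_ekmr <- obs$ekmr_V_per_m2
  for (i in seq_along(locs)) {
    lv <- top2[i]
    # the component EKMr lies within one threshold spacing of its peak level
    lo <- if (lv == 1L) 0 else level_ekmr[lv - 1L]
    hi <- if (lv == nrow(obs)) Inf else level_ekmr[lv + 1L]
    expect_gt(locs[i], lo)
    expect_lte(locs[i], hi)
  }
})
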