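test_that("default protocol blocks high then steps down in 300 V decrements", {
  p <- scan_protocol()
  expect_equal(p$blocking_voltage, 2100)
  expect_length(p$readout_voltages, 5L)
  expect_equal(p$readout_voltages, c(1800, 1500, 1200, 900, 600))
  expect_true(all(diff(p$readout_voltages) == -300))
  single <- scan_protocol(900, 900, 900, 300)
  expect_equal(single$readout_voltages, 900)
  expect_error(scan_protocol(2100, 1800, 600, 250), "divisible")
  expect_error(scan_protocol(1000, 1800, 600, 300), ">=")
})

test_that("capture gate follows the pass-through / capture-at rule", {
  prof <- make_profile(c(2e6, 4e6, 8e6))
  # hand-evaluated: 1000 V thresholds are 2e9, 4e9, 8e9
  expect_identical(capture_gate(5e9, prof, 1000), 3L)
  expect_identical(capture_gate(8e9, prof, 1000), 3L)   # equality captures
  expect_identical(capture_gate(9e9, prof, 1000), 4L)   # exits
  expect_identical(capture_gate(1e9, prof, 1000), 1L)
  # re-evaluation from a downstream entry never moves upstream
  expect_identical(capture_gate(1e9, prof, 1000, entry = 2L), 2L)
  expect_identical(capture_gate(5e9, prof, 1000, entry = 3L), 3L)
  expect_identical(capture_gate(5e9, prof, 1000, entry = 4L), 4L)
  expect_error(capture_gate(1e9, make_profile(numeric(0)), 1000), "empty")
})

test_that("a fully blocked population never passes the first gate", {
  prof <- make_profile(c(2e6, 4e6, 8e6))
  pop <- data.frame(ekmr = c(1e9, 2e9, 4e9), weight = 1)
  # 2100 V: first-gate threshold 4.2e9 exceeds every EKMr
  scan <- run_scan(pop, prof, scan_protocol(2100, 1800, 600, 300))
  expect_true(all(scan$history$blocking == 1L))
  expect_true(all(scan$blocked))
})

test_that("scan intensities localize particles per the capture rule", {
  prof <- make_profile(c(2e6, 4e6, 8e6))
  single <- scan_protocol(1000, 1000, 1000, 300)
  pop <- data.frame(ekmr = c(5e9, 9e9), weight = 1)
  scan <- run_scan(pop, prof, single)
  expect_equal(scan$intensities$intensity, c(0, 0, 1))   # one captured, one exited
  expect_identical(scan$history[["1000"]], c(3L, 4L))

  low <- data.frame(ekmr = 1e9, weight = 1)
  full <- run_scan(low, prof, scan_protocol(2100, 1800, 600, 300))
  g1 <- full$intensities[full$intensities$gate_index == 1L, ]
  expect_true(all(g1$intensity == 1))
  expect_true(all(full$intensities$intensity[full$intensities$gate_index != 1L] == 0))
})

test_that("scans conserve particles and only move them downstream", {
  dev <- ref_device()
  pop <- sample_population(default_mixtures(500)$g, "g", seed = 21)
  scan <- run_scan(pop, dev$profile, scan_protocol(), noise_sd = 0)
  G <- nrow(dev$profile)
  locs <- do.call(cbind, scan$history)
  expect_true(all(locs >= 1L & locs <= G + 1L))
  # conservation at every stage
  expect_true(all(colSums(!is.na(locs)) == nrow(pop)))
  # monotone downstream progression as the voltage decreases
  expect_true(all(apply(locs, 1, function(l) all(diff(l) >= 0))))
  # consistency of every capture with the thresholds at its voltage
  volts <- as.numeric(colnames(locs)[-1])
  for (k in seq_along(volts)) {
    th <- thresholds_at(dev$profile, volts[k])
    loc <- locs[, k + 1]
    held <- loc <= G
    expect_true(all(th[loc[held]] >= pop$ekmr[held] * (1 - 1e-12)))
    prev <- pmax(locs[, k], 1L)
    for (i in which(held)) {
      passed <- seq_len(loc[i] - 1L)
      passed <- passed[passed >= prev[i]]
      if (length(passed)) expect_true(all(th[passed] < pop$ekmr[i]))
    }
  }
  # particles above all thresholds at 600 V have exited by the end
  th600 <- thresholds_at(dev$profile, 600)
  expect_true(all(locs[pop$ekmr > max(th600) * (1 + 1e-9), ncol(locs)] == G + 1L))
})

test_that("scans with readout noise are reproducible under a fixed seed", {
  prof <- make_profile(c(2e6, 4e6, 8e6))
  pop <- data.frame(ekmr = c(3e9, 5e9, 9e9), weight = c(1, 2, 1))
  s1 <- run_scan(pop, prof, noise_sd = 0.5, seed = 9)
  s2 <- run_scan(pop, prof, noise_sd = 0.5, seed = 9)
  expect_identical(s1$intensities, s2$intensities)
  s3 <- run_scan(pop, prof, noise_sd = 0.5, seed = 10)
  expect_false(identical(s1$intensities$intensity, s3$intensities$intensity))
})
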