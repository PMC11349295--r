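# Multi-voltage scanning protocol: a high blocking voltage first excludes the
# sample, then stepwise lower readout voltages let successively lower-EKMr
# subpopulations enter and distribute along the gate series.

#' Scanning-voltage protocol
#'
#' The default protocol blocks at 2100 V and reads out at 1800, 1500, 1200,
#' 900 and 600 V (300 V decrements).
#'
#' @param blocking_voltage initial high voltage, V.
#' @param start_voltage first (highest) readout voltage, V.
#' @param end_voltage last (lowest) readout voltage, V.
#' @param step voltage decrement between readouts, V.
#' @return list of class `scan_protocol` with `blocking_voltage` and the
#'   decreasing vector `readout_voltages`.
#' @export
scan_protocol <- function(blocking_voltage = 2100, start_voltage = 1800,
                          end_voltage = 600, step = 300) {
  if (!(blocking_voltage >= start_voltage && start_voltage >= end_voltage &&
        end_voltage > 0))
    stop("require blocking_voltage >= start_voltage >= end_voltage > 0")
  if (step <= 0) stop("step must be positive")
  span <- start_voltage - end_voltage
  if (span > 0 && abs(span / step - round(span / step)) > 1e-9)
    stop("(start_voltage - end_voltage) must be divisible by step")
  readout <- if (span == 0) start_voltage else seq(start_voltage, end_voltage, by = -step)
  structure(list(blocking_voltage = blocking_voltage,
                 readout_voltages = readout, step = step),
            class = "scan_protocol")
}

# location coding: 0 = inlet (not yet entered), 1..G = captured at gate g,
# G + 1 = exited at the outlet.
LOC_INLET <- 0L

exit_code <- function(profile) nrow(profile) + 1L

#' Gate at which a particle is captured
#'
#' Walking downstream from its entry position, a particle passes every gate
#' whose capture threshold (at the applied voltage) is below its EKMr and is
#' captured at the first gate whose threshold meets or exceeds it (equality
#' captures). If no such gate remains it exits the channel.
#'
#' @param ekmr_value particle EKMr, V/m^2 (vectorized).
#' @param profile a [gate_thresholds()] profile (non-empty).
#' @param voltage applied voltage, V.
#' @param entry entry location: 0 for the inlet or a gate index from which to
#'   re-evaluate (vectorized, recycled against `ekmr_value`).
#' @param rel_tol relative tolerance for the equality comparison.
#' @return integer location vector: gate index, or `nrow(profile) + 1` for
#'   exited. Particles already exited stay exited.
#' @export
capture_gate <- function(ekmr_value, profile, voltage, entry = 0L,
                         rel_tol = 1e-12) {
  stopifnot(inherits(profile, "gate_profile"))
  G <- nrow(profile)
  if (G == 0L) stop("profile is empty")
  th <- thresholds_at(profile, voltage)
  n <- length(ekmr_value)
  entry <- rep_len(as.integer(entry), n)
  out <- integer(n)
  for (i in seq_len(n)) {
    if (entry[i] > G) { out[i] <- G + 1L; next }
    g0 <- max(1L, entry[i])
    hit <- which(th[g0:G] >= ekmr_value[i] * (1 - rel_tol))
    out[i] <- if (length(hit) == 0L) G + 1L else g0 + hit[1L] - 1L
  }
  out
}

#' Run a scanning-voltage separation
#'
#' At the blocking voltage every particle whose EKMr is at or below the first
#' gate's threshold is held at gate 1 (flagged blocked-at-inlet); others are
#' placed by [capture_gate()] from the inlet. At each subsequent readout
#' voltage every particle advances from its current location; thresholds fall
#' with the voltage, so motion is downstream-only. The per-gate fluorescence
#' intensity at each readout voltage is the sum of the weights of the
#' particles captured there, with optional additive readout noise.
#'
#' @param population a [sample_population()] result (or any data.frame with
#'   `ekmr` and `weight` columns).
#' @param profile a [gate_thresholds()] profile.
#' @param protocol a [scan_protocol()].
#' @param noise_sd standard deviation of additive Gaussian readout noise on
#'   each (voltage, gate) intensity, in the same arbitrary units as the
#'   fluorescence weights; negative values are clamped to 0.
#' @param seed seed for the readout noise.
#' @return list of class `scan_result` with `intensities` (data.frame:
#'   `condition`, `replicate`, `voltage_V`, `gate_index`, `intensity`),
#'   `history` (particle locations per protocol stage, blocking stage first)
#'   and `blocked` (logical, blocked at the inlet during the blocking stage).
#' @export
run_scan <- function(population, profile, protocol = scan_protocol(),
                     noise_sd = 0, seed = 1L) {
  stopifnot(inherits(profile, "gate_profile"), inherits(protocol, "scan_protocol"))
  if (!all(c("ekmr", "weight") %in% names(population)))
    stop("population must carry ekmr and weight columns")
  G <- nrow(profile)
  condition <- attr(population, "condition") %||% "sample"
  replicate <- attr(population, "replicate") %||% 1L

  th_block <- thresholds_at(profile, protocol$blocking_voltage)
  blocked <- population$ekmr <= th_block[1L] * (1 + 1e-12)
  loc <- ifelse(blocked, 1L,
                capture_gate(population$ekmr, profile,
                             protocol$blocking_voltage, entry = LOC_INLET))
  history <- list(blocking = loc)

  rows <- vector("list", length(protocol$readout_voltages))
  noise <- withr::with_seed(as.integer(seed), {
    matrix(stats::rnorm(length(protocol$readout_voltages) * G, 0, max(noise_sd, 0)),
           nrow = length(protocol$readout_voltages))
  })
  for (k in seq_along(protocol$readout_voltages)) {
    v <- protocol$readout_voltages[k]
    loc <- capture_gate(population$ekmr, profile, v, entry = loc)
    history[[as.character(v)]] <- loc
    inten <- vapply(seq_len(G), function(g) sum(population$weight[loc == g]),
                    numeric(1))
    if (noise_sd > 0) inten <- pmax(inten + noise[k, ], 0)
    rows[[k]] <- data.frame(condition = condition, replicate = replicate,
                            voltage_V = v, gate_index = seq_len(G),
                            intensity = inten)
  }
  structure(list(intensities = do.call(rbind, rows),
                 history = history, blocked = blocked),
            class = "scan_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
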