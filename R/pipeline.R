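# End-to-end study pipeline: geometry -> field -> thresholds -> simulated
# scans for two conditions -> spectra -> ANOVA.

#' Calibrate a gate profile to a reference EKMr
#'
#' The absolute scale of the capture parameter depends on tooth-shape details
#' that are configuration, not physics, so the profile carries a single
#' multiplicative calibration factor. This helper rescales a profile so that
#' a chosen gate's threshold at a chosen voltage equals a chosen EKMr. The
#' default pins the last (narrowest) gate at 1800 V to 2.3e10 V/m^2 — the
#' largest EKMr at which particles are resolved at the highest readout
#' voltage — so the scan sweep spans the EKMr window the device is meant to
#' probe.
#'
#' @param profile a [gate_thresholds()] profile.
#' @param voltage pinning voltage, V.
#' @param ekmr target threshold at `voltage` for `gate`, V/m^2.
#' @param gate gate index to pin (default: last gate).
#' @return the rescaled `gate_profile`; its `calibration` attribute holds the
#'   cumulative factor.
#' @export
calibrate_profile <- function(profile, voltage = 1800, ekmr = 2.3e10,
                              gate = nrow(profile)) {
  stopifnot(inherits(profile, "gate_profile"))
  if (nrow(profile) == 0L) stop("cannot calibrate an empty profile")
  if (voltage <= 0 || ekmr <= 0) stop("voltage and ekmr must be positive")
  current <- voltage * profile$c_unit_voltage[gate]
  factor <- ekmr / current
  out <- profile
  out$c_unit_voltage <- profile$c_unit_voltage * factor
  attr(out, "calibration") <- attr(profile, "calibration") * factor
  out
}

#' Build the reference device and its calibrated gate profile
#'
#' Convenience wrapper: reference geometry, rasterization, Laplace solve and
#' per-gate thresholds, calibrated per `config$solver$calibrate_to`.
#'
#' @param config a [default_run_config()]-style list.
#' @return list with `geometry`, `mask`, `solution`, `profile`.
#' @export
build_device <- function(config = default_run_config()) {
  g <- config$geometry
  geometry <- build_reference_geometry(
    n_gates = g$n_gates, first_width_um = g$first_width_um,
    last_width_um = g$last_width_um, group_size = g$group_size,
    length_cm = g$length_cm, depth_um = g$depth_um,
    background_width_um = g$background_width_um,
    apex_angle_deg = g$apex_angle_deg)
  mask <- rasterize(geometry, spacing_um = config$solver$spacing_um)
  solution <- solve_potential(mask, config$solver$reference_voltage)
  profile <- gate_thresholds(solution, mask)
  cal <- config$solver$calibrate_to
  if (!is.null(cal))
    profile <- calibrate_profile(profile, voltage = cal$voltage, ekmr = cal$ekmr)
  list(geometry = geometry, mask = mask, solution = solution, profile = profile)
}

#' Simulate a two-condition scanning study
#'
#' The synthetic-data generator: emulates the per-gate intensity tables of a
#' two-condition experiment — untreated ("n", 3 biological replicates) and
#' glucose-stimulated ("g", 4 replicates) vesicles, 27 gates, five readout
#' voltages. Each replicate draws a fresh population from its condition's
#' mixture (biological sampling variation) and is scanned independently, with
#' additive readout noise.
#'
#' @param profile a calibrated [gate_thresholds()] profile.
#' @param protocol a [scan_protocol()].
#' @param mixtures named list of [mixture_config()]s, one per condition.
#' @param replicates named integer vector of replicate counts per condition.
#' @param noise_sd readout noise sd (arbitrary units of summed fluorescence).
#' @param weight_jitter between-replicate biological variation: per
#'   replicate, mixture weights are perturbed multiplicatively by
#'   `exp(N(0, weight_jitter))` and renormalized, emulating preparation-to-
#'   preparation differences in subpopulation composition.
#' @param seed base seed; per-replicate seeds are derived deterministically.
#' @return intensity data.frame (all conditions and replicates combined).
#' @export
simulate_study <- function(profile, protocol = scan_protocol(),
                           mixtures = default_mixtures(),
                           replicates = c(n = 3L, g = 4L),
                           noise_sd = 2, weight_jitter = 0.25, seed = 1L) {
  stopifnot(all(names(replicates) %in% names(mixtures)))
  seed <- as.integer(seed)
  tabs <- list()
  for (ci in seq_along(replicates)) {
    cond <- names(replicates)[ci]
    for (r in seq_len(replicates[[ci]])) {
      rep_seed <- (abs(seed) * 211L + ci * 7919L + r * 104729L) %% 2147483629L
      mix <- mixtures[[cond]]
      if (weight_jitter > 0) {
        jit <- withr::with_seed(rep_seed + 2L,
                                stats::rnorm(length(mix$weights), 0, weight_jitter))
        mix$weights <- mix$weights * exp(jit)
        mix$weights <- mix$weights / sum(mix$weights)
      }
      pop <- sample_population(mix, condition_label = cond,
                               replicate_id = r, seed = rep_seed)
      scan <- run_scan(pop, profile, protocol, noise_sd = noise_sd,
                       seed = rep_seed + 1L)
      tabs[[length(tabs) + 1L]] <- scan$intensities
    }
  }
  do.call(rbind, tabs)
}

#' Run the full study pipeline
#'
#' Device construction, two-condition simulated scan, spectra, and the
#' between-condition two-way ANOVA with Bonferroni post hoc tests at the
#' configured comparison voltage.
#'
#' @param config a [default_run_config()]-style list.
#' @param device optional pre-built [build_device()] result (the solve is the
#'   expensive step; reuse it across runs).
#' @return list of class `study_result`: `config`, `device`, `intensities`,
#'   `spectrum`, `observations`, `anova`, `posthoc`.
#' @export
run_study <- function(config = default_run_config(), device = NULL) {
  if (is.null(device)) device <- build_device(config)
  protocol <- scan_protocol(config$protocol$blocking_voltage,
                            config$protocol$start_voltage,
                            config$protocol$end_voltage,
                            config$protocol$step)
  mixtures <- lapply(config$populations, function(p)
    mixture_config(locations = p$locations, weights = p$weights,
                   dispersions = p$dispersions,
                   n_particles = p$n_particles))
  replicates <- vapply(config$populations, function(p) as.integer(p$replicates),
                       integer(1))
  tab <- simulate_study(device$profile, protocol, mixtures, replicates,
                        noise_sd = config$noise_sd,
                        weight_jitter = config$weight_jitter %||% 0.25,
                        seed = config$seed)
  spectrum <- build_spectrum(tab, device$geometry, device$profile,
                             normalize = config$normalize)
  obs <- spectrum_observations(tab, device$geometry, device$profile,
                               voltage = config$stats$voltage,
                               normalize = config$normalize)
  anova <- two_way_anova(obs)
  posthoc <- bonferroni_posthoc(anova, alpha = config$stats$alpha)
  structure(list(config = config, device = device, intensities = tab,
                 spectrum = spectrum, observations = obs,
                 anova = anova, posthoc = posthoc),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  it <- interaction_test(x$anova)
  cat(sprintf("<study_result> %d intensity rows; interaction F(%d, %d) = %.3f, p = %.4g at %g V\n",
              nrow(x$intensities), it$df1, it$df2, it$F, it$p,
              x$config$stats$voltage))
  invisible(x)
}
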