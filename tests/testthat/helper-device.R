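# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# straight rectangular channel (no gates): analytic field limit
straight_device <- function(length_cm = 0.1, width_um = 50, spacing_um = 2,
                            voltage = 100) {
  cached(sprintf("straight_%g_%g_%g_%g", length_cm, width_um, spacing_um, voltage), {
    gates <- data.frame(index = integer(0), width_um = numeric(0),
                        axial_position_um = numeric(0))
    geom <- channel_geometry(gates, length_cm = length_cm,
                             background_width_um = width_um)
    mask <- rasterize(geom, spacing_um)
    sol <- solve_potential(mask, voltage)
    list(geometry = geom, mask = mask, solution = sol, voltage = voltage)
  })
}

# small 3-gate sawtooth toy: fast full solve at 2 um
toy_device <- function(voltage = 1000) {
  cached(sprintf("toy_%g", voltage), {
    geom <- build_reference_geometry(
      n_gates = 3L, widths_um = c(60, 45, 30), group_size = 1L,
      length_cm = 0.12, background_width_um = 100, pitch_um = 350)
    mask <- rasterize(geom, 2)
    sol <- solve_potential(mask, voltage)
    prof <- gate_thresholds(sol, mask)
    list(geometry = geom, mask = mask, solution = sol, profile = prof)
  })
}

# full 27-gate reference device at 3 um spacing (the expensive fixture)
ref_device <- function() {
  cached("ref", build_device(default_run_config(seed = 1)))
}

# hand-built gate profile for scanner unit tests (unit-voltage thresholds)
make_profile <- function(c_unit, widths = NULL) {
  structure(
    data.frame(gate_index = seq_along(c_unit),
               width_um = widths %||% rev(seq_along(c_unit)) + 20,
               c_unit_voltage = c_unit),
    class = c("gate_profile", "data.frame"), calibration = 1, solved_at = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force two-way ANOVA decomposition for BALANCED designs, computed
# from cell/marginal means only (independent of lm/car)
bf_anova_balanced <- function(d) {
  d$condition <- factor(d$condition); d$ekmr_level <- factor(d$ekmr_level)
  n <- nrow(d)
  gm <- mean(d$intensity)
  cm <- tapply(d$intensity, d$condition, mean)
  lm_ <- tapply(d$intensity, d$ekmr_level, mean)
  cell <- tapply(d$intensity, list(d$condition, d$ekmr_level), mean)
  reps <- n / (nlevels(d$condition) * nlevels(d$ekmr_level))
  ss_a <- reps * nlevels(d$ekmr_level) * sum((cm - gm)^2)
  ss_b <- reps * nlevels(d$condition) * sum((lm_ - gm)^2)
  ss_int <- reps * sum((sweep(sweep(cell, 1, cm), 2, lm_) + gm)^2)
  ss_tot <- sum((d$intensity - gm)^2)
  ss_err <- ss_tot - ss_a - ss_b - ss_int
  df_a <- nlevels(d$condition) - 1L
  df_b <- nlevels(d$ekmr_level) - 1L
  df_int <- df_a * df_b
  df_err <- n - nlevels(d$condition) * nlevels(d$ekmr_level)
  list(ss = c(condition = ss_a, ekmr_level = ss_b, interaction = ss_int,
              error = ss_err, total = ss_tot),
       df = c(condition = df_a, ekmr_level = df_b, interaction = df_int,
              error = df_err),
       F_int = (ss_int / df_int) / (ss_err / df_err))
}

# balanced factorial dataset with known cell means plus iid noise
make_obs <- function(conds, levels, reps, means = NULL, sd = 0, seed = 1) {
  grid <- expand.grid(condition = conds, ekmr_level = levels,
                      replicate = seq_len(reps), stringsAsFactors = FALSE)
  mu <- if (is.null(means)) 0 else
    means[cbind(match(grid$condition, conds), match(grid$ekmr_level, levels))]
  grid$intensity <- mu + withr::with_seed(seed, stats::rnorm(nrow(grid), 0, sd))
  grid
}

# capture-predictor vs trajectory-integrator comparison on the toy device,
# cached because advect() dominates runtime
oracle_agreement <- function() {
  cached("oracle_agreement", {
    dev <- toy_device()
    voltage <- 1000
    th <- thresholds_at(dev$profile, voltage)
    # EKMr values spanning the profile, excluding the 5% band around each
    # threshold where predictor and integrator may legitimately disagree
    ek <- exp(seq(log(min(th) * 0.55), log(max(th) * 1.35), length.out = 24))
    near_tie <- vapply(ek, function(e) any(abs(e - th) / th < 0.05), logical(1))
    ek <- ek[!near_tie]
    mu_ek <- 2e-8
    sol_v <- solve_potential(dev$mask, voltage)
    pred <- capture_gate(ek, dev$profile, voltage)
    got <- vapply(seq_along(ek), function(i) {
      tr <- advect(mu_ek = mu_ek, mu_dep = -mu_ek / ek[i], solution = sol_v,
                   mask = dev$mask, max_steps = 30000L, seed = i)
      if (tr$status == "exited") nrow(dev$profile) + 1L
      else if (tr$status == "captured") tr$gate
      else NA_integer_
    }, integer(1))
    list(ekmr = ek, predicted = pred, integrated = got,
         agreement = mean(pred == got, na.rm = FALSE))
  })
}
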