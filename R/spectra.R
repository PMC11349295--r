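# From per-gate intensity tables to EKMr spectra: background subtraction,
# per-voltage normalization, triplet-gate aggregation, replicate averaging.

#' Subtract the image background from a raw intensity
#'
#' The intensity of a nearby open area of the channel is subtracted from the
#' intensity at each gate to adjust for illumination variation; results are
#' clamped at zero.
#'
#' @param raw raw gate intensity, arbitrary units (vectorized).
#' @param background background intensity, arbitrary units.
#' @return `max(raw - background, 0)`, elementwise.
#' @export
subtract_background <- function(raw, background) {
  if (any(raw < 0) || any(background < 0))
    stop("intensities must be non-negative")
  pmax(raw - background, 0)
}

#' Normalize intensities within each voltage dataset
#'
#' Within each (condition, replicate, voltage) group, intensities are divided
#' by the group's maximum (default) or sum. Groups that are all zero pass
#' through unchanged with a warning.
#'
#' @param table intensity data.frame with columns `condition`, `replicate`,
#'   `voltage_V`, `gate_index`, `intensity`.
#' @param method `"max"` divides by the group maximum, `"sum"` by the group
#'   total.
#' @return the table with normalized `intensity`.
#' @export
normalize_per_voltage <- function(table, method = c("max", "sum")) {
  method <- match.arg(method)
  check_intensity_table(table)
  key <- interaction(table$condition, table$replicate, table$voltage_V,
                     drop = TRUE)
  out <- table
  degenerate <- FALSE
  for (k in levels(key)) {
    i <- which(key == k)
    denom <- if (method == "max") max(table$intensity[i]) else sum(table$intensity[i])
    if (denom <= 0) degenerate <- TRUE else
      out$intensity[i] <- table$intensity[i] / denom
  }
  if (degenerate)
    warning("all-zero intensity group(s) left unnormalized")
  out
}

#' Aggregate same-width gate groups into EKMr spectrum rows
#'
#' Consecutive gates sharing one width (reference device: 9 groups of 3)
#' share a capture threshold, hence an EKMr value, and are averaged into one
#' spectrum row per group. Each group's EKMr value is the applied voltage
#' times the group mean of the unit-voltage thresholds (near-identical within
#' a group up to discretization).
#'
#' @param table an intensity data.frame (typically normalized), one voltage's
#'   rows or several.
#' @param geometry the [channel_geometry()] the table was recorded on.
#' @param profile the matching [gate_thresholds()] profile.
#' @return data.frame with one row per (condition, replicate, voltage,
#'   gate group): `condition`, `replicate`, `voltage_V`, `ekmr_level` (group
#'   ordinal), `ekmr_V_per_m2`, `intensity` (mean over the group's gates).
#' @export
aggregate_gate_triplets <- function(table, geometry, profile) {
  check_intensity_table(table)
  stopifnot(inherits(geometry, "channel_geometry"),
            inherits(profile, "gate_profile"))
  G <- nrow(geometry$gates)
  if (nrow(profile) != G) stop("profile does not match geometry gate count")
  gs <- geometry$group_size
  if (G %% gs != 0L) stop("gate count not divisible by group size")
  if (!all(table$gate_index %in% seq_len(G)))
    stop("table contains gate indices outside the geometry")
  group_of <- (seq_len(G) - 1L) %/% gs + 1L
  c_group <- tapply(profile$c_unit_voltage, group_of, mean)
  tb <- table
  tb$ekmr_level <- group_of[tb$gate_index]
  agg <- stats::aggregate(
    intensity ~ condition + replicate + voltage_V + ekmr_level,
    data = tb, FUN = mean)
  agg$ekmr_V_per_m2 <- agg$voltage_V * as.numeric(c_group[agg$ekmr_level])
  agg[order(agg$condition, agg$replicate, -agg$voltage_V, agg$ekmr_level),
      c("condition", "replicate", "voltage_V", "ekmr_level",
        "ekmr_V_per_m2", "intensity")]
}

#' Build an EKMr spectrum from an intensity table
#'
#' Full reduction: per-voltage normalization (per replicate, so replicates
#' are comparable), same-width gate-group aggregation, then mean and standard
#' error across replicates.
#'
#' @inheritParams aggregate_gate_triplets
#' @param normalize normalization denominator, `"max"` or `"sum"`.
#' @return data.frame of class `ekmr_spectrum`: `condition`, `voltage_V`,
#'   `ekmr_level`, `ekmr_V_per_m2`, `mean_intensity`, `sem` (`NA` for a
#'   single replicate), `n_replicates`; rows ordered by increasing EKMr
#'   within voltage.
#' @export
build_spectrum <- function(table, geometry, profile,
                           normalize = c("max", "sum")) {
  normalize <- match.arg(normalize)
  norm <- normalize_per_voltage(table, method = normalize)
  per_rep <- aggregate_gate_triplets(norm, geometry, profile)
  sp <- stats::aggregate(intensity ~ condition + voltage_V + ekmr_level +
                           ekmr_V_per_m2,
                         data = per_rep,
                         FUN = function(x) c(mean = mean(x),
                                             sem = stats::sd(x) / sqrt(length(x)),
                                             n = length(x)))
  sp <- cbind(sp[, c("condition", "voltage_V", "ekmr_level", "ekmr_V_per_m2")],
              as.data.frame(sp$intensity))
  names(sp)[names(sp) == "mean"] <- "mean_intensity"
  sp$n_replicates <- as.integer(sp$n)
  sp$n <- NULL
  sp <- sp[order(sp$condition, -sp$voltage_V, sp$ekmr_V_per_m2), ]
  rownames(sp) <- NULL
  structure(sp, class = c("ekmr_spectrum", "data.frame"))
}

#' Per-replicate spectrum observations for the between-condition comparison
#'
#' Returns the per-replicate aggregated intensities at one voltage in the
#' layout the two-way ANOVA consumes.
#'
#' @inheritParams build_spectrum
#' @param voltage the readout voltage to extract, V.
#' @return data.frame with `condition`, `ekmr_level`, `replicate`,
#'   `intensity` (and `ekmr_V_per_m2` for reference).
#' @export
spectrum_observations <- function(table, geometry, profile, voltage,
                                  normalize = c("max", "sum")) {
  normalize <- match.arg(normalize)
  tb <- table[table$voltage_V == voltage, , drop = FALSE]
  if (nrow(tb) == 0L) stop("no rows at the requested voltage")
  norm <- normalize_per_voltage(tb, method = normalize)
  per_rep <- aggregate_gate_triplets(norm, geometry, profile)
  per_rep[, c("condition", "ekmr_level", "replicate", "intensity",
              "ekmr_V_per_m2")]
}

#' Plot an EKMr spectrum
#'
#' Intensity against EKMr, one panel set per voltage, conditions overlaid.
#'
#' @param x an [build_spectrum()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ekmr_spectrum <- function(x, ...) {
  volts <- sort(unique(x$voltage_V), decreasing = TRUE)
  conds <- sort(unique(x$condition))
  op <- graphics::par(mfrow = c(length(volts), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (v in volts) {
    sv <- x[x$voltage_V == v, ]
    graphics::plot(NA, xlim = range(sv$ekmr_V_per_m2),
                   ylim = c(0, max(sv$mean_intensity, na.rm = TRUE) * 1.1),
                   xlab = "EKMr (V/m^2)", ylab = "normalized intensity",
                   main = sprintf("%g V", v), ...)
    for (i in seq_along(conds)) {
      sc <- sv[sv$condition == conds[i], ]
      graphics::lines(sc$ekmr_V_per_m2, sc$mean_intensity, type = "b",
                      pch = c(19, 22)[1 + (i - 1) %% 2], col = i + 1)
    }
    graphics::legend("topright", legend = conds, col = seq_along(conds) + 1,
                     pch = 19, bty = "n")
  }
  invisible(x)
}

check_intensity_table <- function(table) {
  req <- c("condition", "replicate", "voltage_V", "gate_index", "intensity")
  missing <- setdiff(req, names(table))
  if (length(missing) > 0)
    stop("intensity table lacks columns: ", paste(missing, collapse = ", "))
  if (any(table$intensity < 0)) stop("intensities must be non-negative")
  invisible(table)
}
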