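#' Construct a sawtooth channel geometry
#'
#' A DC-iDEP separation channel is a straight channel constricted by pairs of
#' insulating triangles ("teeth") whose facing tips leave an opening — a
#' "gate" — of specified width. Narrower gates generate larger electric-field
#' gradients and therefore larger capture-parameter thresholds, so a series of
#' gates of decreasing width sorts particles by their EKMr.
#'
#' @param gates data.frame with columns `index` (1-based ordinal), `width_um`
#'   (gate opening, micrometres) and `axial_position_um` (distance of the gate
#'   centre from the inlet, micrometres).
#' @param length_cm channel length from inlet to outlet, centimetres.
#' @param depth_um channel depth, micrometres. Carried as metadata only; the
#'   field model is two-dimensional.
#' @param background_width_um unconstricted channel width, micrometres.
#' @param apex_angle_deg full apex angle of each triangular tooth, degrees.
#' @param tip_flat_um truncation of the tooth apex: the tip is a flat of this
#'   nominal height cut from an extended triangle, reflecting the rounding of
#'   photolithographically fabricated tips (a mathematically sharp tip would
#'   also make the discretized field singular at the corner).
#' @param group_size number of consecutive gates sharing one width.
#' @return An object of class `channel_geometry`.
#' @seealso [build_reference_geometry()], [rasterize()]
#' @export
channel_geometry <- function(gates, length_cm, depth_um = 20,
                             background_width_um = 200, apex_angle_deg = 60,
                             tip_flat_um = 6, group_size = 1L) {
  stopifnot(is.data.frame(gates),
            all(c("index", "width_um", "axial_position_um") %in% names(gates)))
  gates <- gates[order(gates$index), , drop = FALSE]
  if (length_cm <= 0 || background_width_um <= 0 || depth_um <= 0)
    stop("channel dimensions must be positive")
  n <- nrow(gates)
  group_size <- as.integer(group_size)
  if (group_size < 1L || n %% group_size != 0L)
    stop("group_size must divide the number of gates")
  if (n > 0L) {
    if (any(gates$width_um <= 0)) stop("gate widths must be positive")
    if (any(diff(gates$axial_position_um) <= 0))
      stop("gate axial positions must be strictly increasing")
    if (any(diff(gates$width_um) > 1e-9))
      stop("gate widths must be non-increasing from inlet to outlet")
    if (any(gates$width_um >= background_width_um))
      stop("gate widths must be smaller than the background channel width")
    if (max(gates$axial_position_um) >= length_cm * 1e4)
      stop("gate positions must lie within the channel length")
  }
  structure(list(
    gates = gates,
    length_cm = length_cm,
    depth_um = depth_um,
    background_width_um = background_width_um,
    apex_angle_deg = apex_angle_deg,
    tip_flat_um = tip_flat_um,
    group_size = group_size
  ), class = "channel_geometry")
}

#' Reference 27-gate sawtooth device
#'
#' Builds the reference separation device: a 3.5 cm channel with 27 gates in
#' 9 equal-width groups of 3, the gate opening stepping linearly from 73 um
#' at the inlet to 25 um at the outlet (step 6 um per group). Any parameter
#' can be overridden to build toy devices.
#'
#' @param n_gates number of gates.
#' @param first_width_um,last_width_um widths of the first and last gate
#'   groups, micrometres. Ignored when `widths_um` is given.
#' @param widths_um optional explicit width vector: either one width per gate
#'   or one per width group.
#' @param group_size consecutive gates sharing one width (reference: 3).
#' @param length_cm channel length (reference: 3.5 cm).
#' @param depth_um channel depth metadata (reference: ~20 um).
#' @param background_width_um unconstricted channel width, micrometres.
#' @param apex_angle_deg tooth apex angle, degrees.
#' @param tip_flat_um tooth tip truncation, micrometres (see
#'   [channel_geometry()]).
#' @param pitch_um axial spacing between gate centres; default places the
#'   gates uniformly so all fit within the channel length.
#' @return A [channel_geometry()] object.
#' @examples
#' geom <- build_reference_geometry()
#' nrow(geom$gates)            # 27
#' range(geom$gates$width_um)  # 25 73
#' @export
build_reference_geometry <- function(n_gates = 27L,
                                     first_width_um = 73,
                                     last_width_um = 25,
                                     widths_um = NULL,
                                     group_size = 3L,
                                     length_cm = 3.5,
                                     depth_um = 20,
                                     background_width_um = 200,
                                     apex_angle_deg = 60,
                                     tip_flat_um = 6,
                                     pitch_um = NULL) {
  n_gates <- as.integer(n_gates)
  group_size <- as.integer(group_size)
  if (n_gates < 1L) stop("n_gates must be positive")
  if (group_size < 1L || n_gates %% group_size != 0L)
    stop("group_size must divide the number of gates")
  n_groups <- n_gates %/% group_size
  if (is.null(widths_um)) {
    if (first_width_um <= 0 || last_width_um <= 0)
      stop("gate widths must be positive")
    group_widths <- if (n_groups == 1L) first_width_um else
      seq(first_width_um, last_width_um, length.out = n_groups)
  } else {
    if (length(widths_um) == n_gates) {
      group_widths <- NULL
    } else if (length(widths_um) == n_groups) {
      group_widths <- widths_um
    } else {
      stop("widths_um must have one entry per gate or per width group")
    }
  }
  widths <- if (is.null(group_widths)) widths_um else rep(group_widths, each = group_size)
  if (any(widths <= 0)) stop("gate widths must be positive")
  length_um <- length_cm * 1e4
  if (is.null(pitch_um)) pitch_um <- length_um / n_gates
  positions <- (seq_len(n_gates) - 0.5) * pitch_um
  gates <- data.frame(index = seq_len(n_gates),
                      width_um = widths,
                      axial_position_um = positions)
  geom <- channel_geometry(gates, length_cm = length_cm, depth_um = depth_um,
                           background_width_um = background_width_um,
                           apex_angle_deg = apex_angle_deg,
                           tip_flat_um = tip_flat_um,
                           group_size = group_size)
  geom$pitch_um <- pitch_um
  geom
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("<channel_geometry> %d gates, %.2f cm, widths %.0f-%.0f um (%d groups of %d)\n",
              nrow(x$gates), x$length_cm,
              x$gates$width_um[1], x$gates$width_um[nrow(x$gates)],
              nrow(x$gates) %/% x$group_size, x$group_size))
  invisible(x)
}

tooth_half_height <- function(geometry) {
  (geometry$background_width_um - geometry$gates$width_um) / 2
}

tooth_half_base <- function(geometry) {
  # axial half-footprint of a truncated tooth on the wall
  (tooth_half_height(geometry) + (geometry$tip_flat_um %||% 0)) *
    tan(geometry$apex_angle_deg * pi / 360)
}

#' Rasterize a channel geometry onto a regular grid
#'
#' Discretizes the fluid domain on a square grid of cell centres. Each gate's
#' paired triangles narrow the fluid region to the specified opening at the
#' throat. Cells are classified fluid or insulator; the inlet and outlet faces
#' and each gate's throat line segment are recorded for the field solver.
#'
#' @param geometry a [channel_geometry()].
#' @param spacing_um grid spacing, micrometres. Must resolve the narrowest
#'   gate with at least 8 cells.
#' @return An object of class `domain_mask`: a list with the logical
#'   fluid-occupancy matrix `fluid` (rows transverse, columns axial), the grid
#'   `spacing_um`, `inlet_rows`/`outlet_rows` (fluid rows of the first/last
#'   column), `throats` (per-gate list with the throat column and fluid row
#'   range), and the source `geometry`.
#' @export
rasterize <- function(geometry, spacing_um = 2) {
  stopifnot(inherits(geometry, "channel_geometry"))
  if (spacing_um <= 0) stop("spacing must be positive")
  if (nrow(geometry$gates) > 0L) {
    wmin <- min(geometry$gates$width_um)
    if (wmin / spacing_um < 8)
      stop(sprintf("spacing %.3g um too coarse: narrowest gate (%.3g um) spans < 8 cells",
                   spacing_um, wmin))
  }
  h <- spacing_um
  length_um <- geometry$length_cm * 1e4
  W <- geometry$background_width_um
  nx <- max(2L, as.integer(round(length_um / h)))
  ny <- max(2L, as.integer(round(W / h)))
  x <- (seq_len(nx) - 0.5) * h
  y <- (seq_len(ny) - 0.5) * h

  # fluid lies between the lower and upper tooth envelopes; each tooth is a
  # triangle with a truncated (flat) tip: the profile of a taller triangle
  # with the same apex angle, clipped at the gate half-height
  lower <- numeric(nx)              # top of bottom teeth
  upper <- rep(W, nx)               # bottom of top teeth, measured from y = 0
  hh <- tooth_half_height(geometry)
  tip <- geometry$tip_flat_um %||% 0
  ta <- tan(geometry$apex_angle_deg * pi / 360)
  for (g in seq_len(nrow(geometry$gates))) {
    # snap the apex to the nearest cell centre so that equal-width gates
    # rasterize identically regardless of their sub-cell axial offset
    xg <- (round(geometry$gates$axial_position_um[g] / h + 0.5) - 0.5) * h
    if (hh[g] <= 0) next
    hb_ext <- (hh[g] + tip) * ta
    span <- abs(x - xg) < hb_ext
    prof <- pmin(hh[g], (hh[g] + tip) * (1 - abs(x[span] - xg) / hb_ext))
    prof <- pmax(prof, 0)
    lower[span] <- pmax(lower[span], prof)
    upper[span] <- pmin(upper[span], W - prof)
  }
  if (any(upper - lower < h))
    stop("teeth close the channel completely at this spacing")

  fluid <- matrix(FALSE, ny, nx)
  for (ix in seq_len(nx)) {
    fluid[, ix] <- y > lower[ix] & y < upper[ix]
  }
  # connectivity: one interval per column; consecutive intervals must overlap
  for (ix in seq_len(nx)) {
    rows <- which(fluid[, ix])
    if (length(rows) == 0L) stop("fluid region disconnected: empty column")
    if (any(diff(rows) != 1L)) stop("fluid region not a single interval in a column")
    if (ix > 1L) {
      prev <- which(fluid[, ix - 1L])
      if (max(rows) < min(prev) || max(prev) < min(rows))
        stop("fluid region disconnected between adjacent columns")
    }
  }

  throats <- lapply(seq_len(nrow(geometry$gates)), function(g) {
    ix <- which.min(abs(x - geometry$gates$axial_position_um[g]))
    rows <- which(fluid[, ix])
    list(gate = g, col = ix, rows = rows)
  })

  structure(list(
    fluid = fluid,
    spacing_um = h,
    nx = nx, ny = ny,
    inlet_rows = which(fluid[, 1L]),
    outlet_rows = which(fluid[, nx]),
    throats = throats,
    geometry = geometry
  ), class = "domain_mask")
}

#' @export
print.domain_mask <- function(x, ...) {
  cat(sprintf("<domain_mask> %d x %d cells at %.3g um, %d gates, %.0f%% fluid\n",
              x$ny, x$nx, x$spacing_um, length(x$throats),
              100 * mean(x$fluid)))
  invisible(x)
}

#' Throat widths measured on the raster
#'
#' @param mask a [rasterize()] result.
#' @return numeric vector, per-gate throat opening in micrometres as resolved
#'   on the grid.
#' @export
throat_widths <- function(mask) {
  stopifnot(inherits(mask, "domain_mask"))
  vapply(mask$throats, function(t) length(t$rows) * mask$spacing_um, numeric(1))
}

#' Export a domain mask as a plain-text matrix or portable grey map
#'
#' @param mask a [rasterize()] result.
#' @param path output file path.
#' @param format `"txt"` writes a 0/1 matrix (1 = fluid); `"pgm"` writes a
#'   plain (P2) portable grey map, fluid white.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, format = c("txt", "pgm")) {
  format <- match.arg(format)
  m <- mask$fluid * 1L
  if (format == "txt") {
    utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  } else {
    write_pgm(m * 255L, path, maxval = 255L)
  }
  invisible(path)
}
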