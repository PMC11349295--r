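# Electrostatics on the rasterized channel.
#
# The potential solves Laplace's equation on the fluid region with Dirichlet
# values on the inlet (applied voltage) and outlet (ground) faces and
# insulating (zero normal derivative) walls. A finite-volume 5-point stencil
# makes the insulating condition exact at the discrete level: each fluid cell
# balances fluxes only with its fluid neighbours. The domain is long and thin,
# so the sparse system is effectively banded and a direct Cholesky solve
# (Matrix/CHOLMOD) is fast even for the full 27-gate device.

# value of m at (i+di, j+dj), padded with `fill`
shift_mat <- function(m, di, dj, fill = NA) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  si <- seq_len(ny); sj <- seq_len(nx)
  ti <- si + di; tj <- sj + dj
  keep_i <- ti >= 1L & ti <= ny
  keep_j <- tj >= 1L & tj <= nx
  out[si[keep_i], sj[keep_j]] <- m[ti[keep_i], tj[keep_j]]
  out
}

#' Solve the electrostatic potential in a rasterized channel
#'
#' @param mask a [rasterize()] result with a connected fluid domain.
#' @param voltage applied inlet-outlet potential difference, volts. The inlet
#'   face is held at `voltage`, the outlet at 0.
#' @return An object of class `field_solution`: grids (rows transverse,
#'   columns axial; `NA` outside the fluid) for the potential `phi` (V), field
#'   components `Ex`, `Ey` and magnitude `Emag` (V/m), the gradient of the
#'   squared field `gE2x`, `gE2y` (V^2/m^3), and the capture parameter `cap`
#'   (V/m^2); plus `voltage`, `spacing_um` and the maximum discrete residual.
#' @details The electric field is `E = -grad(phi)`, evaluated with central
#'   differences in the interior and one-sided differences against walls.
#'   `grad|E|^2` is differenced from the assembled `|E|^2` grid rather than by
#'   twice-differentiating field components, which avoids compounding stencil
#'   errors. The capture parameter is `(grad|E|^2 . E) / |E|^2`; cells where
#'   `|E|` falls below `1e-6` times the median field are flagged `NA`.
#' @export
solve_potential <- function(mask, voltage) {
  stopifnot(inherits(mask, "domain_mask"))
  if (voltage <= 0) stop("voltage must be positive")
  fluid <- mask$fluid
  ny <- mask$ny; nx <- mask$nx
  if (nx < 3L) stop("domain too short to solve")

  unknown <- fluid
  unknown[, c(1L, nx)] <- FALSE
  n_unknown <- sum(unknown)
  if (n_unknown == 0L) stop("no interior fluid cells to solve for")
  uid <- matrix(NA_integer_, ny, nx)
  uid[unknown] <- seq_len(n_unknown)

  phi_fix <- matrix(NA_real_, ny, nx)
  phi_fix[fluid[, 1L], 1L] <- voltage
  phi_fix[fluid[, nx], nx] <- 0

  diag_cnt <- numeric(n_unknown)
  rhs <- numeric(n_unknown)
  ii <- integer(0); jj <- integer(0)
  for (d in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))) {
    nb_fluid <- shift_mat(fluid, d[1], d[2], fill = FALSE)
    sel <- unknown & nb_fluid
    ids <- uid[sel]
    diag_cnt[ids] <- diag_cnt[ids] + 1
    nb_uid <- shift_mat(uid, d[1], d[2])
    nb_fix <- shift_mat(phi_fix, d[1], d[2])
    to_unknown <- sel & !is.na(nb_uid)
    ii <- c(ii, uid[to_unknown]); jj <- c(jj, nb_uid[to_unknown])
    to_fix <- sel & is.na(nb_uid)
    if (any(to_fix)) {
      v <- nb_fix[to_fix]
      v[is.na(v)] <- 0  # cannot happen for valid masks; defensive
      idf <- uid[to_fix]
      rhs[idf] <- rhs[idf] + v
    }
  }
  A <- Matrix::sparseMatrix(
    i = c(seq_len(n_unknown), ii),
    j = c(seq_len(n_unknown), jj),
    x = c(diag_cnt, rep(-1, length(ii))),
    dims = c(n_unknown, n_unknown)
  )
  A <- Matrix::forceSymmetric(A)
  sol <- tryCatch(
    as.numeric(Matrix::solve(A, rhs)),
    error = function(e) stop("Laplace system could not be solved (disconnected or singular domain): ",
                             conditionMessage(e))
  )
  residual <- max(abs(A %*% sol - rhs)) / max(abs(rhs), 1)

  phi <- matrix(NA_real_, ny, nx)
  phi[unknown] <- sol
  phi[!is.na(phi_fix)] <- phi_fix[!is.na(phi_fix)]

  h_m <- mask$spacing_um * 1e-6
  gphi <- grad_grid(phi, h_m)
  Ex <- -gphi$gx; Ey <- -gphi$gy
  E2 <- Ex^2 + Ey^2
  Emag <- sqrt(E2)
  gE2 <- grad_grid(E2, h_m)

  floor_E <- 1e-6 * stats::median(Emag, na.rm = TRUE)
  cap <- (gE2$gx * Ex + gE2$gy * Ey) / E2
  cap[!is.na(Emag) & Emag < floor_E] <- NA_real_

  structure(list(
    phi = phi, Ex = Ex, Ey = Ey, Emag = Emag,
    gE2x = gE2$gx, gE2y = gE2$gy, cap = cap,
    voltage = voltage, spacing_um = mask$spacing_um,
    residual = residual
  ), class = "field_solution")
}

# gradient on a grid with NAs outside the domain: central differences where
# both neighbours exist, one-sided at walls, NA where no neighbour exists.
# x is the column (axial) direction, y the row direction; h in metres.
grad_grid <- function(f, h) {
  fR <- shift_mat(f, 0L, 1L); fL <- shift_mat(f, 0L, -1L)
  fU <- shift_mat(f, 1L, 0L); fD <- shift_mat(f, -1L, 0L)
  gx <- one_dim_grad(f, fL, fR, h)
  gy <- one_dim_grad(f, fD, fU, h)
  list(gx = gx, gy = gy)
}

one_dim_grad <- function(f, fminus, fplus, h) {
  g <- matrix(NA_real_, nrow(f), ncol(f))
  both <- !is.na(fminus) & !is.na(fplus)
  g[both] <- (fplus[both] - fminus[both]) / (2 * h)
  fwd <- is.na(fminus) & !is.na(fplus) & !is.na(f)
  g[fwd] <- (fplus[fwd] - f[fwd]) / h
  bwd <- is.na(fplus) & !is.na(fminus) & !is.na(f)
  g[bwd] <- (f[bwd] - fminus[bwd]) / h
  g[is.na(f)] <- NA_real_
  g
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("<field_solution> %d x %d grid at %.3g um, %g V applied, residual %.2e\n",
              nrow(x$phi), ncol(x$phi), x$spacing_um, x$voltage, x$residual))
  invisible(x)
}

#' Capture parameter of a field solution
#'
#' The capture parameter `(grad|E|^2 . E) / |E|^2` (V/m^2) is the field-side
#' quantity of the trapping condition: a particle is held where it meets or
#' exceeds the particle's EKMr. The E vector points along the direction of
#' electrokinetic motion (inlet to outlet), so positive values oppose motion
#' into a gate.
#'
#' @param solution a [solve_potential()] result.
#' @return scalar grid (matrix) of the capture parameter, `NA` where the field
#'   magnitude underflows or outside the fluid.
#' @export
capture_parameter <- function(solution) {
  stopifnot(inherits(solution, "field_solution"))
  solution$cap
}

#' Per-gate capture thresholds at unit applied voltage
#'
#' For each gate, the capture threshold is the maximum positive capture
#' parameter along the channel centreline — the path of a particle entering
#' the gate — over an axial window spanning the tooth (the throat column
#' dilated by the tooth half-base), rescaled to 1 V applied. Capture occurs
#' where opposition is strongest along the particle's path; the centreline
#' is used rather than the full throat cross-section because the capture
#' parameter diverges at the sharp tooth-tip corners (a grid-dependent
#' artefact of the Laplace corner singularity a travelling particle never
#' samples). Because the potential is linear in the applied voltage, the
#' unit-voltage profile is voltage-independent and scales linearly via
#' [thresholds_at()].
#'
#' @param solution a [solve_potential()] result computed on `mask`.
#' @param mask the [rasterize()] result the solution was computed on.
#' @param dilate extra axial window half-width in cells beyond the tooth
#'   half-base.
#' @param calibration multiplicative calibration factor applied to all
#'   thresholds (default 1). The absolute threshold scale depends on tooth
#'   shape details, so a single factor is exposed to pin the profile to a
#'   measured EKMr if desired (see [calibrate_profile()]).
#' @return An object of class `gate_profile`: data.frame with `gate_index`,
#'   `width_um` and `c_unit_voltage` (V/m^2 per volt), with the calibration
#'   factor and solver voltage as attributes.
#' @export
gate_thresholds <- function(solution, mask, dilate = 2L, calibration = 1) {
  stopifnot(inherits(solution, "field_solution"), inherits(mask, "domain_mask"))
  cap <- solution$cap
  ny <- mask$ny; nx <- mask$nx
  h <- mask$spacing_um
  # the field disturbance of a tooth extends over ~ its height + half-base,
  # and the capture-parameter peak on the centreline sits upstream of the
  # throat, so the axial search window must span that whole approach region
  reach_um <- tooth_half_base(mask$geometry) + tooth_half_height(mask$geometry)
  vals <- vapply(mask$throats, function(t) {
    reach <- as.integer(ceiling(reach_um[t$gate] / h)) + dilate
    cols <- max(1L, t$col - reach):min(nx, t$col + reach)
    mid <- as.integer(round(mean(range(t$rows))))
    rows <- max(1L, mid - 1L):min(ny, mid + 1L)
    w <- cap[rows, cols, drop = FALSE]
    w <- w[!is.na(w) & mask$fluid[rows, cols] & w > 0]
    if (length(w) == 0L)
      stop(sprintf("gate %d: throat window has no defined positive capture parameter", t$gate))
    max(w)
  }, numeric(1))
  prof <- data.frame(
    gate_index = vapply(mask$throats, `[[`, integer(1), "gate"),
    width_um = mask$geometry$gates$width_um,
    c_unit_voltage = vals / solution$voltage * calibration
  )
  structure(prof, class = c("gate_profile", "data.frame"),
            calibration = calibration, solved_at = solution$voltage)
}

#' Gate thresholds at an applied voltage
#'
#' @param profile a [gate_thresholds()] result.
#' @param voltage applied voltage, volts (non-negative).
#' @return numeric vector of per-gate capture thresholds in V/m^2; a particle
#'   with EKMr at or below a gate's threshold is captured there.
#' @export
thresholds_at <- function(profile, voltage) {
  stopifnot(inherits(profile, "gate_profile"))
  if (voltage < 0) stop("voltage must be non-negative")
  voltage * profile$c_unit_voltage
}

#' Write a field grid as CSV or portable grey map
#'
#' @param grid a matrix from a [solve_potential()] result.
#' @param path output path.
#' @param format `"csv"` for a plain matrix, `"pgm"` for a grey-map image
#'   (values rescaled to 0-255, `NA` black).
#' @return `path`, invisibly.
#' @export
write_field_grid <- function(grid, path, format = c("csv", "pgm")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.table(grid, path, row.names = FALSE, col.names = FALSE, sep = ",")
  } else {
    rng <- range(grid, na.rm = TRUE)
    g <- (grid - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
    g[is.na(g)] <- 0
    write_pgm(round(g * 255), path, maxval = 255L)
  }
  invisible(path)
}
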