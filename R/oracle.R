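# Particle-transport integrator: an independent check of the capture
# predictor. Integrates dx/dt = mu_EK * E + mu_DEP * grad|E|^2 (plus an
# optional Brownian term) through the solved field with reflecting walls.

# bilinear interpolation of a grid at point (x_um, y_um); cell centres at
# (i - 0.5) * h. Falls back to the nearest finite corner where neighbours
# are outside the fluid.
interp_grid <- function(grid, x_um, y_um, h) {
  ny <- nrow(grid); nx <- ncol(grid)
  fx <- x_um / h + 0.5; fy <- y_um / h + 0.5
  j0 <- floor(fx); i0 <- floor(fy)
  tx <- fx - j0; ty <- fy - i0
  j0 <- min(max(j0, 1L), nx - 1L); i0 <- min(max(i0, 1L), ny - 1L)
  v <- c(grid[i0, j0], grid[i0, j0 + 1], grid[i0 + 1, j0], grid[i0 + 1, j0 + 1])
  w <- c((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty)
  ok <- !is.na(v)
  if (!any(ok)) return(NA_real_)
  if (!all(ok)) { v <- v[ok]; w <- w[ok]; w <- w / sum(w) }
  sum(v * w)
}

in_fluid <- function(mask, x_um, y_um) {
  h <- mask$spacing_um
  j <- as.integer(ceiling(x_um / h)); i <- as.integer(ceiling(y_um / h))
  if (j < 1L || j > mask$nx || i < 1L || i > mask$ny) return(FALSE)
  mask$fluid[i, j]
}

#' Integrate a particle trajectory through the solved field
#'
#' Euler-Maruyama integration of the electrokinetic + dielectrophoretic
#' drift, `v = mu_ek * E + mu_dep * grad|E|^2`, with bilinearly interpolated
#' field grids, reflecting walls, and an optional Brownian displacement. The
#' step size adapts so no step exceeds half a grid cell. The trajectory
#' terminates when the particle leaves the outlet (exited), when its mean
#' displacement over `stagnation_window` consecutive steps falls below
#' `stagnation_tol` grid cells (captured), or at the step cap.
#'
#' @param mu_ek electrokinetic mobility, m^2/(V s).
#' @param mu_dep dielectrophoretic mobility, m^4/(V^2 s). For repulsive
#'   (negative) DEP — the regime in which gates oppose entry — this is
#'   negative, and `abs(mu_ek / mu_dep)` is the particle's EKMr.
#' @param solution a [solve_potential()] result.
#' @param mask the [rasterize()] result the solution was computed on.
#' @param start numeric `c(x_um, y_um)` start position; default: mid-height
#'   just inside the inlet.
#' @param diffusion isotropic diffusion coefficient, m^2/s (0 = off).
#' @param max_steps step cap.
#' @param seed seed for the Brownian term.
#' @param stagnation_window,stagnation_tol capture detection: window length
#'   in steps and mean-displacement threshold in grid cells.
#' @param dt_scale multiplier (<= 1) on the adaptive step size, for
#'   refinement studies.
#' @param record_every keep every k-th path point.
#' @return list of class `trajectory_result`: `status` ("exited", "captured"
#'   or "max_steps"), `gate` (nearest gate at/downstream of the final
#'   position when captured, else `NA`), `final` position (um), `path`
#'   matrix (t_s, x_um, y_um), `steps`, `seed`.
#' @export
advect <- function(mu_ek, mu_dep, solution, mask, start = NULL,
                   diffusion = 0, max_steps = 200000L, seed = 1L,
                   stagnation_window = 500L, stagnation_tol = 0.01,
                   dt_scale = 1, record_every = 50L) {
  stopifnot(inherits(solution, "field_solution"), inherits(mask, "domain_mask"))
  h <- mask$spacing_um
  if (is.null(start)) {
    start <- c(1.5 * h, stats::median(mask$inlet_rows) * h - 0.5 * h)
  }
  if (!in_fluid(mask, start[1], start[2]))
    stop("start position is outside the fluid domain")
  length_um <- ncol(mask$fluid) * h

  pos <- start
  path <- list(c(0, pos))
  t_now <- 0
  recent <- numeric(0)
  status <- "max_steps"
  # characteristic EK drift speed (um/s) sets the step-size cap: near a
  # stagnation point the local speed vanishes, and without a cap an adaptive
  # half-cell step would carry the particle straight through the trap
  v_char <- abs(mu_ek) * mean(solution$Emag, na.rm = TRUE) * 1e6
  dt_cap <- if (v_char > 0) 0.5 * h / v_char else 1e-3
  withr::with_seed(as.integer(seed), {
    for (step in seq_len(max_steps)) {
      ex <- interp_grid(solution$Ex, pos[1], pos[2], h)
      ey <- interp_grid(solution$Ey, pos[1], pos[2], h)
      gx <- interp_grid(solution$gE2x, pos[1], pos[2], h)
      gy <- interp_grid(solution$gE2y, pos[1], pos[2], h)
      if (anyNA(c(ex, ey, gx, gy))) { ex <- ey <- gx <- gy <- 0 }
      vx <- (mu_ek * ex + mu_dep * gx) * 1e6  # um/s
      vy <- (mu_ek * ey + mu_dep * gy) * 1e6
      speed <- sqrt(vx^2 + vy^2)
      dt <- dt_scale * (if (speed > 0) min(0.5 * h / speed, dt_cap) else dt_cap)
      if (diffusion > 0) {
        # cap dt so the rms Brownian step also stays below half a cell
        sig_um <- function(dt) sqrt(2 * diffusion * dt) * 1e6
        while (sig_um(dt) > 0.5 * h) dt <- dt / 2
        step_b <- stats::rnorm(2, 0, sig_um(dt))
      } else step_b <- c(0, 0)
      prop <- pos + c(vx, vy) * dt + step_b
      moved <- c(0, 0)
      if (in_fluid(mask, prop[1], prop[2])) {
        moved <- prop - pos; pos <- prop
      } else if (in_fluid(mask, prop[1], pos[2])) {   # slide along the wall
        moved <- c(prop[1] - pos[1], 0); pos[1] <- prop[1]
      } else if (in_fluid(mask, pos[1], prop[2])) {
        moved <- c(0, prop[2] - pos[2]); pos[2] <- prop[2]
      }
      t_now <- t_now + dt
      if (step %% record_every == 0L) path[[length(path) + 1L]] <- c(t_now, pos)
      if (pos[1] >= length_um - h) { status <- "exited"; break }
      recent <- c(recent, sqrt(sum(moved^2)))
      if (length(recent) > stagnation_window)
        recent <- recent[-1L]
      if (length(recent) == stagnation_window &&
          mean(recent) < stagnation_tol * h) { status <- "captured"; break }
    }
  })
  path[[length(path) + 1L]] <- c(t_now, pos)
  gate <- NA_integer_
  if (status == "captured" && length(mask$throats) > 0) {
    throat_x <- vapply(mask$throats, function(t) t$col * h, numeric(1))
    downstream <- which(throat_x >= pos[1] - 2 * h)
    if (length(downstream) > 0) gate <- downstream[1L]
  }
  path <- do.call(rbind, path)
  colnames(path) <- c("t_s", "x_um", "y_um")
  structure(list(status = status, gate = gate, final = pos, path = path,
                 steps = step, seed = as.integer(seed)),
            class = "trajectory_result")
}

#' Write a trajectory to CSV
#'
#' @param trajectory an [advect()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  write_csv_with_header(as.data.frame(trajectory$path), path,
                        metadata = list(status = trajectory$status,
                                        gate = trajectory$gate,
                                        seed = trajectory$seed))
}

#' Stokes-Einstein diffusion coefficient
#'
#' Default diffusion model for a vesicle of radius `r` in the suspension
#' medium when Brownian motion is enabled.
#'
#' @param r particle radius, m.
#' @param medium a [medium_properties()].
#' @param temperature_K absolute temperature.
#' @return diffusion coefficient, m^2/s.
#' @export
stokes_einstein <- function(r, medium = medium_properties(),
                            temperature_K = 293.15) {
  if (any(r <= 0)) stop("radius must be positive")
  1.380649e-23 * temperature_K / (6 * pi * medium$viscosity * r)
}
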