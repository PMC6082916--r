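#' One Verlet leapfrog step
#'
#' Standard leapfrog update: `v(t + dt/2) = v(t - dt/2) + dt f(t)/m`,
#' `x(t + dt) = x(t) + dt v(t + dt/2)`. Velocities are stored at half
#' steps; positions are wrapped into the box when one is given.
#'
#' @param positions N x 3 matrix.
#' @param velocities N x 3 half-step velocities.
#' @param forces N x 3 forces at the current positions.
#' @param masses length-N vector.
#' @param dt timestep, `> 0`.
#' @param box optional length-3 box for periodic wrapping.
#' @return list with `positions` and `velocities` (new half-step).
#' @export
leapfrog_step <- function(positions, velocities, forces, masses, dt,
                          box = NULL) {
  stopifnot(dt > 0)
  if (any(!is.finite(forces)))
    stop("non-finite force encountered; integration aborted", call. = FALSE)
  v <- velocities + dt * forces / masses
  x <- positions + dt * v
  if (!is.null(box)) x <- wrap_positions(x, box)
  list(positions = x, velocities = v)
}

## Soft-sphere r^-12 repulsion, energy-shifted to zero at the cutoff.
soft_sphere_eval <- function(sys, epsilon, sigma, cutoff) {
  n <- nrow(sys$positions)
  F <- matrix(0, n, 3)
  pr <- neighbor_pairs(sys, cutoff)
  if (!length(pr$i)) return(list(U = 0, forces = F))
  sr12 <- (sigma / pr$r)^12
  shift <- (sigma / cutoff)^12
  U <- epsilon * sum(sr12 - shift)
  fmag <- 12 * epsilon * sr12 / pr$r
  fv <- (fmag / pr$r) * pr$dx
  F <- accumulate_rows(F, pr$i, fv)
  F <- accumulate_rows(F, pr$j, -fv)
  list(U = U, forces = F)
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Gaussian velocities at temperature `T` (k_B = 1 in reduced units) with
#' the center-of-mass drift removed.
#'
#' @param sys a [charge_system()].
#' @param temperature target temperature.
#' @param seed integer RNG seed.
#' @return N x 3 velocity matrix.
#' @export
maxwell_velocities <- function(sys, temperature, seed) {
  n <- nrow(sys$positions)
  with_seed(seed, {
    v <- matrix(stats::rnorm(n * 3), n, 3) *
      sqrt(temperature / sys$masses)
    sweep(v, 2, colSums(v * sys$masses) / sum(sys$masses))
  })
}

kinetic_temperature <- function(velocities, masses) {
  sum(masses * rowSums(velocities^2)) / (3 * length(masses))
}

#' Minimal leapfrog MD over LIPS/FFT forces
#'
#' Integrates a periodic ionic system under the split electrostatic
#' potential (short-range real-space sum plus FFT mesh long-range forces;
#' the constant boundary term is force-free) plus a shifted soft-sphere
#' `r^-12` repulsion that keeps opposite charges from collapsing. The mesh
#' energy array and spline factors are built once and reused along the run.
#' NVE by default; `thermostat = list(type = "rescale", T = ..., interval
#' = ...)` applies simple velocity rescaling.
#'
#' Input velocities (or the ones drawn from `temperature`/`seed`) are
#' interpreted as half-step leapfrog velocities; logged kinetic energies use
#' the on-step estimate `v(t) = (v(t - dt/2) + v(t + dt/2)) / 2`. The small
#' net force left by the mesh interpolation is subtracted each step by
#' default so linear momentum is conserved.
#'
#' @param sys a [charge_system()]; if it carries no velocities they are
#'   drawn at `temperature` with `seed`.
#' @param sp a [split_potential()].
#' @param mesh a [mesh_config()] on the system's box.
#' @param n_steps number of integration steps.
#' @param dt timestep.
#' @param thermostat `NULL` (NVE) or `list(type = "rescale", T, interval)`.
#' @param soft_sphere list with `epsilon`, `sigma`, `cutoff` for the
#'   repulsion (set `epsilon = 0` to disable).
#' @param save_every store a frame (with on-step velocities) every this many
#'   steps.
#' @param remove_net_force subtract the residual net force each step.
#' @param temperature,seed used only when `sys` has no velocities.
#' @return An object of class `"md_run"`: list with `trajectory`, `energies`
#'   (data.frame: step, time, U_S, U_L, U_B, U_ss, potential, kinetic,
#'   total, temperature), `final` (the end-state [charge_system()]), and the
#'   saved step indices `saved_steps`.
#' @export
run_md <- function(sys, sp, mesh, n_steps, dt, thermostat = NULL,
                   soft_sphere = list(epsilon = 1, sigma = 0.25,
                                      cutoff = 0.625),
                   save_every = 10, remove_net_force = TRUE,
                   temperature = 1, seed = 1) {
  stopifnot(inherits(sys, "charge_system"), inherits(sp, "split_potential"),
            inherits(mesh, "mesh_config"), n_steps >= 1, dt > 0)
  ctx <- mesh_context(sp, mesh)
  x <- sys$positions
  v <- if (is.null(sys$velocities))
    maxwell_velocities(sys, temperature, seed) else sys$velocities
  m <- sys$masses
  ss_on <- soft_sphere$epsilon > 0
  eval_forces <- function(x) {
    s <- charge_system(x, sys$charges, sys$box, masses = m,
                       species = sys$species)
    el <- lips_fft_eval(s, sp, mesh, ctx)
    ss <- if (ss_on)
      soft_sphere_eval(s, soft_sphere$epsilon, soft_sphere$sigma,
                       soft_sphere$cutoff)
    else list(U = 0, forces = 0)
    F <- el$forces + ss$forces
    if (remove_net_force)
      F <- sweep(F, 2, colMeans(F))
    list(F = F, el = el, U_ss = ss$U)
  }
  nsave <- length(seq(save_every, n_steps, by = save_every))
  frames <- vector("list", nsave)
  saved_steps <- integer(nsave)
  isave <- 0L
  log <- vector("list", n_steps)
  cur <- eval_forces(x)
  for (step in seq_len(n_steps)) {
    v_new <- v + dt * cur$F / m
    v_on <- (v + v_new) / 2
    KE <- 0.5 * sum(m * rowSums(v_on^2))
    Upot <- cur$el$U_total + cur$U_ss
    log[[step]] <- data.frame(
      step = step - 1L, time = (step - 1L) * dt,
      U_S = cur$el$U_S, U_L = cur$el$U_L, U_B = cur$el$U_B,
      U_ss = cur$U_ss, potential = Upot, kinetic = KE,
      total = Upot + KE,
      temperature = kinetic_temperature(v_on, m))
    if (step %% save_every == 0) {
      isave <- isave + 1L
      frames[[isave]] <- charge_system(x, sys$charges, sys$box,
                                       velocities = v_on, masses = m,
                                       species = sys$species)
      saved_steps[isave] <- step - 1L
    }
    x <- wrap_positions(x + dt * v_new, sys$box)
    v <- v_new
    if (!is.null(thermostat) && identical(thermostat$type, "rescale") &&
        step %% thermostat$interval == 0) {
      Tk <- kinetic_temperature(v, m)
      if (Tk > 0) v <- v * sqrt(thermostat$T / Tk)
    }
    cur <- eval_forces(x)
  }
  structure(list(
    trajectory = trajectory(frames[seq_len(isave)],
                            timestep = save_every * dt),
    energies = do.call(rbind, log),
    final = charge_system(x, sys$charges, sys$box, velocities = v,
                          masses = m, species = sys$species),
    saved_steps = saved_steps[seq_len(isave)]),
    class = "md_run")
}

#' @export
print.md_run <- function(x, ...) {
  e <- x$energies
  cat(sprintf(
    "<md_run> %d steps  E0 = %.6g  drift = %.3g  <T> = %.4g\n",
    nrow(e), e$total[1], energy_drift(x), mean(e$temperature)))
  invisible(x)
}

#' Relative secular energy drift of an MD run
#'
#' The difference between the mean total energy over the last and first 5%
#' of the run, relative to the magnitude of the mean total energy — a
#' measure of secular drift insensitive to the bounded `O(dt^2)` leapfrog
#' energy fluctuation.
#'
#' @param run an `"md_run"` (or a numeric vector of total energies).
#' @param fraction tail fraction averaged on each side (default 0.05).
#' @return scalar relative drift.
#' @export
energy_drift <- function(run, fraction = 0.05) {
  e <- if (inherits(run, "md_run")) run$energies$total else as.numeric(run)
  n <- length(e)
  k <- max(1L, floor(fraction * n))
  abs(mean(e[(n - k + 1):n]) - mean(e[1:k])) / abs(mean(e))
}
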