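#' Ordered sequence of periodic frames
#'
#' A fixed-N, fixed-box (NVT-style) trajectory: the container consumed by
#' the observable calculators.
#'
#' @param frames list of [charge_system()] objects with identical particle
#'   count and box.
#' @param timestep time between consecutive frames.
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(frames, timestep = NA_real_) {
  stopifnot(is.list(frames), length(frames) >= 1,
            all(vapply(frames, inherits, TRUE, "charge_system")))
  n <- nrow(frames[[1]]$positions)
  box <- frames[[1]]$box
  ok <- vapply(frames, function(f)
    nrow(f$positions) == n && isTRUE(all.equal(f$box, box)), TRUE)
  if (!all(ok)) stop("frames must share N and box", call. = FALSE)
  structure(list(frames = frames, timestep = timestep, box = box, N = n),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames  N = %d  dt = %s\n",
              length(x$frames), x$N, format(x$timestep)))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$frames)

#' Root-mean-squared force deviation
#'
#' `delta_f = sqrt( sum_i sum_alpha |f_{alpha,i} - f_{alpha,i,ref}|^2 /
#' (3N - 1) )` — note the `3N - 1` denominator of the convention used here.
#'
#' @param F,F_ref N x 3 force matrices of equal shape, `N >= 1`.
#' @return scalar `delta_f >= 0`.
#' @export
force_rmsd <- function(F, F_ref) {
  F <- as.matrix(F); F_ref <- as.matrix(F_ref)
  if (!all(dim(F) == dim(F_ref)) || nrow(F) < 1)
    stop("force sets must be non-empty and of equal shape", call. = FALSE)
  sqrt(sum((F - F_ref)^2) / (3 * nrow(F) - 1))
}

#' Largest single-component force error
#'
#' `e_f_max = max_{i,alpha} |f_{alpha,i} - f_{alpha,i,ref}|`.
#'
#' @inheritParams force_rmsd
#' @return scalar `e_f_max >= 0`.
#' @export
max_force_error <- function(F, F_ref) {
  F <- as.matrix(F); F_ref <- as.matrix(F_ref)
  if (!all(dim(F) == dim(F_ref)) || nrow(F) < 1)
    stop("force sets must be non-empty and of equal shape", call. = FALSE)
  max(abs(F - F_ref))
}

#' Radial distribution function
#'
#' `g(r) = V / (4 pi r^2 dr N (N - 1)) * sum_i n_i(r)` averaged over frames,
#' where `n_i(r)` counts neighbors of particle `i` in the shell
#' `[r, r + dr)`. Bin centers sit at `(k + 1/2) dr`. The `N (N - 1)`
#' normalization (no pair factor 2; neighbor counts are ordered) is applied
#' exactly as written, so an ideal gas converges to `g = 1`.
#'
#' @param traj a [trajectory()] (or a single [charge_system()]).
#' @param dr bin width, `> 0`.
#' @param r_max histogram range; requires `r_max <= min(box)/2`.
#' @return data.frame with columns `r` (bin centers) and `g`; per-frame
#'   values are attached as attribute `"per_frame"` (frames x bins) for
#'   uncertainty estimates.
#' @export
rdf <- function(traj, dr, r_max = min(traj$box) / 2) {
  if (inherits(traj, "charge_system")) traj <- trajectory(list(traj))
  stopifnot(inherits(traj, "trajectory"))
  if (dr <= 0) stop("dr must be positive", call. = FALSE)
  if (r_max > min(traj$box) / 2 + 1e-12)
    stop("r_max exceeds half the shortest box edge", call. = FALSE)
  nb <- floor(r_max / dr)
  edges <- (0:nb) * dr
  N <- traj$N
  V <- prod(traj$box)
  per_frame <- t(vapply(traj$frames, function(f) {
    g <- pair_geometry(f)
    r <- g$r[upper.tri(g$r)]
    r <- r[r < edges[nb + 1]]
    2 * tabulate(findInterval(r, edges), nbins = nb)  # ordered pairs
  }, numeric(nb)))
  if (is.null(dim(per_frame))) per_frame <- matrix(per_frame, nrow = 1)
  centers <- (0:(nb - 1) + 0.5) * dr
  norm <- V / (4 * pi * centers^2 * dr * N * (N - 1))
  gpf <- sweep(per_frame, 2, norm, `*`)
  out <- data.frame(r = centers, g = colMeans(gpf))
  attr(out, "per_frame") <- gpf
  out
}

#' Velocity autocorrelation function
#'
#' `C(t) = sum_i v_i(t) . v_i(0) / sum_i v_i(0) . v_i(0)`, relative to the
#' first frame.
#'
#' @param traj a [trajectory()] whose frames carry velocities.
#' @return data.frame with columns `t` and `C`; `C(0) = 1` by construction.
#' @export
vacf <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (any(vapply(traj$frames, function(f) is.null(f$velocities), TRUE)))
    stop("trajectory frames carry no velocities", call. = FALSE)
  v0 <- traj$frames[[1]]$velocities
  denom <- sum(v0 * v0)
  if (denom == 0) stop("zero initial velocities", call. = FALSE)
  C <- vapply(traj$frames, function(f) sum(f$velocities * v0) / denom,
              numeric(1))
  dt <- if (is.na(traj$timestep)) 1 else traj$timestep
  data.frame(t = (seq_along(C) - 1) * dt, C = C)
}

## Unwrap a trajectory by accumulating minimum-image inter-frame
## displacements; returns array n_frames x N x 3.
unwrap_trajectory <- function(traj) {
  nf <- length(traj$frames); N <- traj$N
  u <- array(0, c(nf, N, 3))
  u[1, , ] <- traj$frames[[1]]$positions
  for (k in 2:nf) {
    d <- mic(traj$frames[[k]]$positions - traj$frames[[k - 1]]$positions,
             traj$box)
    u[k, , ] <- u[k - 1, , ] + d
  }
  u
}

#' Self-diffusion coefficient by the Einstein relation
#'
#' Unwraps the trajectory, computes the mean-squared displacement
#' `MSD(t) = < |r_i(t0 + t) - r_i(t0)|^2 >` averaged over particles and
#' (strided) time origins, and fits `D = slope / 6` by least squares over
#' the long-time window. The default window `[t_max/4, t_max/2]` avoids the
#' ballistic start and the poorly averaged tail. A log-log slope of the MSD
#' is reported as a linearity diagnostic (1 for diffusive motion, 2 for
#' ballistic); fits with slope outside `1 +- 0.3` are flagged nonlinear.
#'
#' @param traj a [trajectory()] with a finite timestep.
#' @param fit_window length-2 vector of times bracketing the fit (defaults
#'   to `c(t_max/4, t_max/2)`).
#' @param origin_stride origin subsampling stride (default about 100
#'   origins).
#' @return An object of class `"msd_fit"`: list with `D`, `msd`
#'   (data.frame `t`, `msd`), `loglog_slope`, `nonlinear`, `window`.
#' @export
msd_diffusion <- function(traj, fit_window = NULL, origin_stride = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- length(traj$frames)
  if (nf < 4) stop("trajectory too short", call. = FALSE)
  dt <- traj$timestep
  if (is.na(dt) || dt <= 0) stop("trajectory needs a timestep", call. = FALSE)
  u <- unwrap_trajectory(traj)
  t_max <- (nf - 1) * dt
  if (is.null(fit_window)) fit_window <- c(t_max / 4, t_max / 2)
  if (fit_window[1] >= fit_window[2] || fit_window[2] > t_max + 1e-12)
    stop("fit window outside trajectory", call. = FALSE)
  if (is.null(origin_stride)) origin_stride <- max(1L, nf %/% 100L)
  lags <- 1:(nf - 1)
  msd <- vapply(lags, function(lag) {
    orig <- seq(1L, nf - lag, by = origin_stride)
    d <- u[orig + lag, , , drop = FALSE] - u[orig, , , drop = FALSE]
    sum(d^2) / (length(orig) * dim(u)[2])
  }, numeric(1))
  tt <- lags * dt
  in_win <- tt >= fit_window[1] & tt <= fit_window[2]
  if (sum(in_win) < 2) stop("fit window contains fewer than 2 lags",
                            call. = FALSE)
  fit <- stats::lm(msd[in_win] ~ tt[in_win])
  D <- unname(stats::coef(fit)[2]) / 6
  pos <- in_win & msd > 0
  ll <- if (sum(pos) >= 2)
    unname(stats::coef(stats::lm(log(msd[pos]) ~ log(tt[pos])))[2])
  else NA_real_
  structure(list(D = D, msd = data.frame(t = tt, msd = msd),
                 loglog_slope = ll,
                 nonlinear = is.finite(ll) && abs(ll - 1) > 0.3,
                 window = fit_window),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("<msd_fit> D = %.6g  log-log slope = %.3g%s\n", x$D,
              x$loglog_slope, if (x$nonlinear) "  [nonlinear]" else ""))
  invisible(x)
}

## Sum `values` into `nb` bins at indices `k` (1-based, already clamped).
bin_sum <- function(values, k, nb) {
  out <- numeric(nb)
  s <- rowsum(values, group = k)
  out[as.integer(rownames(s))] <- s
  out
}

axis_bins <- function(box, axis, bin) {
  if (bin <= 0) stop("bin must be positive", call. = FALSE)
  L <- box[axis]
  nb <- max(1L, floor(L / bin))
  edges <- seq(0, L, length.out = nb + 1)
  list(nb = nb, edges = edges, centers = (edges[-1] + edges[-(nb + 1)]) / 2,
       width = L / nb)
}

#' Mass density profile along a box axis
#'
#' Frame-averaged histogram of particle mass per slab volume.
#'
#' @param traj a [trajectory()] (or single [charge_system()]).
#' @param axis slab normal: 1, 2 or 3 (default 3, the z axis).
#' @param bin slab thickness, `> 0`.
#' @return data.frame with columns `z` (bin centers) and `rho`.
#' @export
density_profile <- function(traj, axis = 3, bin) {
  if (inherits(traj, "charge_system")) traj <- trajectory(list(traj))
  stopifnot(inherits(traj, "trajectory"), axis %in% 1:3)
  b <- axis_bins(traj$box, axis, bin)
  slab_vol <- prod(traj$box[-axis]) * b$width
  acc <- numeric(b$nb)
  for (f in traj$frames) {
    k <- pmin(b$nb, pmax(1L, findInterval(f$positions[, axis], b$edges,
                                          rightmost.closed = TRUE)))
    acc <- acc + bin_sum(f$masses, k, b$nb)
  }
  data.frame(z = b$centers, rho = acc / (slab_vol * length(traj$frames)))
}

#' Electrostatic potential profile by double Poisson integration
#'
#' `psi(z) - psi(0) = -(1/eps0) int_0^z int_0^z' rho_c(z'') dz'' dz'`,
#' computed from the frame-averaged binned charge density by two cumulative
#' trapezoid passes over the bin centers. The first bin is the reference
#' (`psi(0) = 0`), the vacuum side by the usual slab convention.
#'
#' @param traj a [trajectory()] (or single [charge_system()]).
#' @param axis slab normal (default 3).
#' @param bin slab thickness, `> 0`.
#' @param epsilon0 vacuum permittivity in the working unit system (1 in
#'   reduced units).
#' @return data.frame with columns `z` and `psi` (= `psi(z) - psi(0)`).
#' @export
potential_profile <- function(traj, axis = 3, bin, epsilon0 = 1) {
  if (inherits(traj, "charge_system")) traj <- trajectory(list(traj))
  stopifnot(inherits(traj, "trajectory"), axis %in% 1:3)
  b <- axis_bins(traj$box, axis, bin)
  slab_vol <- prod(traj$box[-axis]) * b$width
  acc <- numeric(b$nb)
  for (f in traj$frames) {
    k <- pmin(b$nb, pmax(1L, findInterval(f$positions[, axis], b$edges,
                                          rightmost.closed = TRUE)))
    acc <- acc + bin_sum(f$charges, k, b$nb)
  }
  rho_c <- acc / (slab_vol * length(traj$frames))
  I1 <- pracma::cumtrapz(b$centers, rho_c)
  psi <- -drop(pracma::cumtrapz(b$centers, I1)) / epsilon0
  data.frame(z = b$centers, psi = psi)
}
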