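## Run `code` under a fixed RNG seed without disturbing the caller's random
## state: every generator is a pure function of its arguments.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Random neutral ionic configuration
#'
#' `N/2` charges of +1 and `N/2` of -1 at uniform random positions, with a
#' minimum-separation rejection radius of `0.05 min(box)` to keep the `1/r`
#' energies bounded. Deterministic in the seed.
#'
#' @param N even particle count.
#' @param box length-3 box vector (scalar recycled).
#' @param seed integer RNG seed.
#' @param min_sep rejection radius (default `0.05 * min(box)`).
#' @return A [charge_system()] with zero net charge.
#' @export
random_neutral_system <- function(N, box, seed, min_sep = NULL) {
  if (length(box) == 1) box <- rep(box, 3)
  if (N %% 2 != 0) stop("N must be even", call. = FALSE)
  if (is.null(min_sep)) min_sep <- 0.05 * min(box)
  with_seed(seed, {
    pos <- matrix(NA_real_, N, 3)
    rejections <- 0L
    placed <- 0L
    while (placed < N) {
      cand <- stats::runif(3) * box
      ok <- placed == 0L ||
        all(sqrt(rowSums(mic(pos[seq_len(placed), , drop = FALSE] -
                               matrix(cand, placed, 3, byrow = TRUE),
                             box)^2)) >= min_sep)
      if (ok) {
        placed <- placed + 1L
        pos[placed, ] <- cand
      } else {
        rejections <- rejections + 1L
        if (rejections > 1e5)
          stop("could not pack ", N, " particles at minimum separation ",
               min_sep, call. = FALSE)
      }
    }
    charge_system(pos, rep(c(1, -1), N / 2), box)
  })
}

#' Neutral dipolar slab configuration
#'
#' `N/2` +1/-1 dipolar pairs confined to a central slab covering
#' `slab_fraction` of the box along z, with vacuum on either side — a
#' minimal emulation of a liquid-vapor interface geometry for the profile
#' observables.
#'
#' @param N even particle count.
#' @param box length-3 box vector (scalar recycled).
#' @param slab_fraction fraction of the z edge occupied by the slab
#'   (0 < f <= 1).
#' @param seed integer RNG seed.
#' @param pair_offset intramolecular +/- separation (default
#'   `0.02 * min(box)`).
#' @return A [charge_system()] whose z coordinates all lie inside the slab.
#' @export
slab_system <- function(N, box, slab_fraction, seed, pair_offset = NULL) {
  if (length(box) == 1) box <- rep(box, 3)
  if (N %% 2 != 0) stop("N must be even", call. = FALSE)
  stopifnot(slab_fraction > 0, slab_fraction <= 1)
  if (is.null(pair_offset)) pair_offset <- 0.02 * min(box)
  zlo <- box[3] * (0.5 - slab_fraction / 2)
  zhi <- box[3] * (0.5 + slab_fraction / 2)
  with_seed(seed, {
    npair <- N / 2
    pos <- matrix(NA_real_, N, 3)
    for (p in seq_len(npair)) {
      a <- c(stats::runif(2) * box[1:2],
             stats::runif(1, zlo + pair_offset, zhi - pair_offset))
      repeat {
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        b <- a + pair_offset * dir
        if (b[3] >= zlo && b[3] <= zhi) break
      }
      pos[2 * p - 1, ] <- a
      pos[2 * p, ] <- b
    }
    charge_system(pos, rep(c(1, -1), npair), box)
  })
}

#' Single +1/-1 pair at controlled separation
#'
#' The canonical two-body input for closed-form checks: a +1 charge and a
#' -1 charge placed symmetrically about the box center along x.
#'
#' @param separation pair distance.
#' @param offset length-3 rigid shift of the pair (default none).
#' @param box length-3 box vector (scalar recycled).
#' @return A [charge_system()] with exactly two particles.
#' @export
dipole_pair <- function(separation, offset = c(0, 0, 0), box) {
  if (length(box) == 1) box <- rep(box, 3)
  stopifnot(separation > 0, separation < min(box) / 2)
  center <- box / 2
  pos <- rbind(center + c(-separation / 2, 0, 0) + offset,
               center + c(separation / 2, 0, 0) + offset)
  charge_system(pos, c(1, -1), box)
}

#' Brownian-walker trajectory with known diffusion coefficient
#'
#' Independent Gaussian displacements of variance `2 D0 dt` per axis per
#' step: ground truth for the Einstein-relation recovery. Frames are wrapped
#' into the box; the unwrapped walk is attached as attribute `"unwrapped"`
#' (frames x walkers x 3).
#'
#' @param n_walkers number of independent walkers.
#' @param n_steps number of displacement steps (the trajectory has
#'   `n_steps + 1` frames).
#' @param D0 target diffusion coefficient.
#' @param dt timestep.
#' @param box length-3 box vector (scalar recycled).
#' @param seed integer RNG seed.
#' @return A [trajectory()]; walkers carry alternating +1/-1 charges so the
#'   frames are also valid neutral electrostatic inputs.
#' @export
brownian_trajectory <- function(n_walkers, n_steps, D0, dt, box, seed) {
  if (length(box) == 1) box <- rep(box, 3)
  stopifnot(n_walkers >= 1, n_steps >= 1, D0 >= 0, dt > 0)
  q <- rep_len(c(1, -1), n_walkers)
  with_seed(seed, {
    start <- matrix(stats::runif(n_walkers * 3), n_walkers, 3) %*% diag(box)
    sd <- sqrt(2 * D0 * dt)
    u <- array(0, c(n_steps + 1, n_walkers, 3))
    u[1, , ] <- start
    if (D0 > 0) {
      for (k in seq_len(n_steps))
        u[k + 1, , ] <- u[k, , ] +
          matrix(stats::rnorm(n_walkers * 3, sd = sd), n_walkers, 3)
    } else {
      for (k in seq_len(n_steps)) u[k + 1, , ] <- u[k, , ]
    }
    frames <- lapply(seq_len(n_steps + 1), function(k)
      charge_system(matrix(u[k, , ], ncol = 3), q, box))
    tr <- trajectory(frames, timestep = dt)
    attr(tr, "unwrapped") <- u
    tr
  })
}
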