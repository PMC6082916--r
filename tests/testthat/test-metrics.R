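test_that("force deviation metrics obey their closed forms", {
  set.seed(41)
  F <- matrix(rnorm(30), 10, 3)
  expect_identical(force_rmsd(F, F), 0)
  expect_identical(max_force_error(F, F), 0)
  # single particle deviating by (1,0,0): 3N - 1 = 2
  expect_equal(force_rmsd(matrix(c(1, 0, 0), 1, 3), matrix(0, 1, 3)),
               sqrt(1 / 2))
  planted <- F
  planted[4, 2] <- planted[4, 2] + 0.3
  expect_equal(max_force_error(planted, F), 0.3)
  G <- F + matrix(rnorm(30, sd = 0.2), 10, 3)
  expect_equal(force_rmsd(F, G), naive_force_rmsd(F, G), tolerance = 1e-14)
  # norm inequality linking the two metrics
  N <- nrow(F)
  expect_gte(max_force_error(F, G),
             force_rmsd(F, G) * sqrt((3 * N - 1) / (3 * N)) - 1e-14)
  expect_error(force_rmsd(F, F[1:3, ]), "equal shape")
})

test_that("force metrics are permutation invariant and triangle-like", {
  set.seed(43)
  F <- matrix(rnorm(24), 8, 3)
  G <- matrix(rnorm(24), 8, 3)
  H <- matrix(rnorm(24), 8, 3)
  p <- sample(8)
  expect_equal(force_rmsd(F[p, ], G[p, ]), force_rmsd(F, G))
  expect_equal(max_force_error(F[p, ], G[p, ]), max_force_error(F, G))
  expect_lte(force_rmsd(F, H), force_rmsd(F, G) + force_rmsd(G, H) + 1e-14)
  expect_lte(max_force_error(F, H),
             max_force_error(F, G) + max_force_error(G, H) + 1e-14)
})

test_that("radial distribution function: two-body closed form and empty bins", {
  box <- 5
  d <- 1.23
  pair <- dipole_pair(d, box = box)
  dr <- 0.1
  g <- rdf(pair, dr = dr, r_max = 2.5)
  k <- floor(d / dr) + 1
  V <- box^3
  # sum_i n_i = 2 in the bin holding d; Eq. normalization with N(N-1) = 2
  expected <- V / (4 * pi * g$r[k]^2 * dr * 2) * 2
  expect_equal(g$g[k], expected, tolerance = 1e-12)
  expect_true(all(g$g[-k] == 0))
  expect_error(rdf(pair, dr = -0.1), "positive")
  expect_error(rdf(pair, dr = 0.1, r_max = 3), "half")
})

test_that("ideal-gas rdf is unity within sampling error", {
  frames <- lapply(1:30, function(s) lipsfft:::with_seed(500 + s,
    charge_system(matrix(runif(256 * 3), 256, 3), rep(c(1, -1), 128), 1)))
  g <- rdf(trajectory(frames), dr = 0.025, r_max = 0.5)
  pf <- attr(g, "per_frame")
  se <- apply(pf, 2, sd) / sqrt(nrow(pf))
  dev <- abs(g$g - 1) / se
  expect_lt(max(dev[-1]), 3)
})

test_that("velocity autocorrelation: normalization and decorrelation", {
  box <- 5
  n <- 40
  base <- lipsfft:::with_seed(61, matrix(rnorm(n * 3), n, 3))
  pos <- lipsfft:::with_seed(62, matrix(runif(n * 3) * box, n, 3))
  const_frames <- lapply(1:5, function(k)
    charge_system(pos, rep(c(1, -1), n / 2), box, velocities = base))
  vc <- vacf(trajectory(const_frames, timestep = 0.1))
  expect_equal(vc$C, rep(1, 5), tolerance = 1e-12)
  # independent random-sign refresh decorrelates instantly
  flip_frames <- lapply(1:40, function(k)
    charge_system(pos, rep(c(1, -1), n / 2), box,
                  velocities = base * lipsfft:::with_seed(70 + k,
                    matrix(sample(c(-1, 1), n * 3, TRUE), n, 3))))
  vf <- vacf(trajectory(flip_frames, timestep = 0.1))
  expect_equal(vf$C[1], 1)
  expect_lt(max(abs(vf$C[-1])), 4 / sqrt(3 * n))
  no_vel <- trajectory(list(charge_system(pos, rep(c(1, -1), n / 2), box)))
  expect_error(vacf(no_vel), "velocities")
  zero_vel <- trajectory(lapply(1:3, function(k)
    charge_system(pos, rep(c(1, -1), n / 2), box,
                  velocities = matrix(0, n, 3))))
  expect_error(vacf(zero_vel), "zero initial velocities")
})

test_that("Einstein fit: stationary, diffusive, and ballistic regimes", {
  still <- brownian_trajectory(10, 50, D0 = 0, dt = 0.1, box = 5, seed = 1)
  expect_equal(msd_diffusion(still)$D, 0)
  diff_tr <- brownian_trajectory(60, 400, D0 = 0.02, dt = 0.05, box = 8,
                                 seed = 2)
  fit <- msd_diffusion(diff_tr)
  expect_lt(abs(fit$D / 0.02 - 1), 0.25)
  expect_false(fit$nonlinear)
  # ballistic walkers: msd ~ t^2, flagged by the log-log diagnostic
  box <- 50
  v <- lipsfft:::with_seed(8, matrix(rnorm(20 * 3), 20, 3))
  start <- lipsfft:::with_seed(9, matrix(runif(20 * 3) * box, 20, 3))
  frames <- lapply(0:100, function(k)
    charge_system(start + 0.004 * k * v, rep(c(1, -1), 10), box))
  bal <- msd_diffusion(trajectory(frames, timestep = 1))
  expect_equal(bal$loglog_slope, 2, tolerance = 0.05)
  expect_true(bal$nonlinear)
  expect_error(msd_diffusion(diff_tr, fit_window = c(10, 100)), "window")
})

test_that("density profile conserves mass and resolves a slab", {
  box <- c(2, 2, 6)
  sys <- slab_system(400, box, slab_fraction = 0.4, seed = 14)
  prof <- density_profile(sys, axis = 3, bin = 0.2)
  slab_area <- box[1] * box[2]
  binw <- diff(prof$z[1:2])
  expect_equal(sum(prof$rho) * slab_area * binw, sum(sys$masses),
               tolerance = 1e-12)
  inside <- prof$z > 2.0 & prof$z < 4.0
  outside <- prof$z < 1.5 | prof$z > 4.5
  expect_gt(mean(prof$rho[inside]), 10 * max(mean(prof$rho[outside]), 1e-12))
  expect_error(density_profile(sys, bin = 0), "positive")
})

test_that("potential profile: zero field, capacitor step, charge linearity", {
  box <- c(2, 2, 10)
  n <- 40
  pos <- lipsfft:::with_seed(15, matrix(runif(n * 3), n, 3) %*% diag(box))
  null <- charge_system(pos, numeric(n), box)
  expect_equal(potential_profile(null, bin = 0.2)$psi, rep(0, 50))
  # parallel oppositely charged sheets: step of sigma * d / eps0
  M <- 30
  xy <- lipsfft:::with_seed(16, matrix(runif(2 * M * 2) * 2, 2 * M, 2))
  sheets <- charge_system(cbind(xy, rep(c(3, 7), each = M)),
                          rep(c(1, -1), each = M), box)
  ps <- potential_profile(sheets, axis = 3, bin = 0.1)
  expect_equal(ps$psi[1], 0)
  sigma <- M / (box[1] * box[2])
  gap <- 4
  step <- mean(ps$psi[ps$z > 8]) - mean(ps$psi[ps$z < 2])
  expect_equal(abs(step), sigma * gap / 1, tolerance = 0.02)
  doubled <- charge_system(sheets$positions, 2 * sheets$charges, box)
  expect_equal(potential_profile(doubled, bin = 0.1)$psi, 2 * ps$psi,
               tolerance = 1e-12)
})
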