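test_that("cardinal B-splines: support, peak, partition of unity", {
  expect_equal(bspline(2, 1.0), 1)
  w_out <- c(-2, -0.001, 0, 8, 9)
  for (n in c(2, 4, 6, 8)) {
    expect_true(all(bspline(n, c(-1, 0, n, n + 2)) == 0))
  }
  set.seed(31)
  for (n in c(2, 4, 6, 8)) {
    w <- runif(100, 0, n)
    pou <- rowSums(sapply(-(n + 2):(n + 2), function(k) bspline(n, w - k)))
    expect_equal(pou, rep(1, 100), tolerance = 1e-12)
  }
})

test_that("B-spline derivative identity matches finite differences", {
  expect_equal(bspline_derivative(2, 0.5), 1)
  set.seed(32)
  for (n in c(2, 4, 8)) {
    w <- runif(50, 0.1, n - 0.1)
    h <- 1e-6
    fd <- (bspline(n, w + h) - bspline(n, w - h)) / (2 * h)
    expect_equal(bspline_derivative(n, w), fd, tolerance = 1e-6)
    # compact support integrates the derivative to zero (trapezoid error is
    # O(h) at the order-2 step discontinuities, hence the loose tolerance)
    grid <- seq(0, n, length.out = 4001)
    expect_lt(abs(pracma::trapz(grid, bspline_derivative(n, grid))), 2e-3)
  }
})

test_that("charge spreading conserves charge and matches the naive loop", {
  box <- c(3, 4, 5)
  mesh <- mesh_config(box, K = c(18, 20, 24), order = 4)
  one <- charge_system(matrix(c(0.77, 1.13, 4.9), 1, 3), 1, box)
  expect_equal(sum(spread_charges(one, mesh)$Q), 1, tolerance = 1e-12)
  sys <- random_neutral_system(20, box, seed = 6)
  Q <- spread_charges(sys, mesh)$Q
  expect_equal(sum(Q), sum(sys$charges), tolerance = 1e-12)
  expect_equal(Q, naive_spread(sys, mesh), tolerance = 1e-13)
})

test_that("translating by one grid cell cyclically permutes the charge array", {
  box <- 4
  mesh <- mesh_config(box, K = 16, order = 4)
  sys <- random_neutral_system(10, box, seed = 9)
  Q <- spread_charges(sys, mesh)$Q
  shift <- c(box / 16, 0, 0)
  sys2 <- charge_system(sweep(sys$positions, 2, -shift), sys$charges, box)
  Q2 <- spread_charges(sys2, mesh)$Q
  perm <- c(16, 1:15)  # cyclic shift by one node along axis 1
  expect_equal(Q2, Q[perm, , ], tolerance = 1e-12)
})

test_that("reciprocal spline factors: unit zero mode and conjugate symmetry", {
  for (n in c(4, 8)) {
    mesh <- mesh_config(4, K = c(20, 24, 32), order = n)
    B <- compute_bfactors(mesh)$B
    expect_equal(B[1, 1, 1], 1, tolerance = 1e-12)
    expect_true(all(B >= 0))
    # m -> K - m symmetry along each axis
    K <- mesh$K
    flip <- function(K) c(1, K:2)
    expect_equal(B, B[flip(K[1]), flip(K[2]), flip(K[3])], tolerance = 1e-12)
  }
})

test_that("energy array: origin value, cutoff zeros, inversion symmetry", {
  box <- 4
  sp <- split_potential(reaction_field_potential(), 1.0, 2.0)
  mesh <- mesh_config(box, K = 20, order = 8)
  Pg <- build_energy_array(mesh, sp)
  expect_equal(Pg$Phi_star[1, 1, 1], long_range_at_zero(sp),
               tolerance = 1e-12)
  # entries with minimum-image distance >= R_c are exactly zero
  K <- mesh$K
  d1 <- lipsfft:::mic((0:(K[1] - 1)) / K[1] * box, box)
  r <- sqrt(array(d1^2, K) + array(rep(d1^2, each = K[1]), K) +
              array(rep(d1^2, each = K[1] * K[2]), K))
  expect_true(all(Pg$Phi_star[r >= sp$R_c] == 0))
  flip <- function(K) c(1, K:2)
  expect_equal(Pg$Phi_star,
               Pg$Phi_star[flip(K[1]), flip(K[2]), flip(K[3])],
               tolerance = 1e-14)
})

test_that("mesh long-range energy is bilinear and converges to the direct sum", {
  box <- 4
  sp <- split_potential(coulomb_potential(), 1.0, 2.0)
  sys <- random_neutral_system(16, box, seed = 3)
  ref <- direct_long_range(sys, sp, include_self = TRUE)$U_L
  errs <- sapply(c(0.25, 0.125, 0.0625), function(d) {
    mesh <- mesh_config(box, spacing = d)
    Qg <- spread_charges(sys, mesh)
    Pg <- build_energy_array(mesh, sp)
    Bg <- compute_bfactors(mesh)
    U <- long_range_energy(Qg, Pg, Bg)
    # bilinearity and the zero-charge annihilator, once per grid
    if (d == 0.25) {
      sys2 <- charge_system(sys$positions, 2 * sys$charges, box)
      expect_equal(long_range_energy(spread_charges(sys2, mesh), Pg, Bg),
                   4 * U, tolerance = 1e-10)
      sys0 <- charge_system(sys$positions, numeric(16), box)
      expect_equal(long_range_energy(spread_charges(sys0, mesh), Pg, Bg), 0)
    }
    abs(U - ref)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("mesh forces are the exact gradient of the mesh energy", {
  sys <- random_neutral_system(10, 3, seed = 11)
  sp <- split_potential(reaction_field_potential(), 0.8, 1.5)
  mesh <- mesh_config(sys$box, K = 24, order = 8)
  Pg <- build_energy_array(mesh, sp)
  Bg <- compute_bfactors(mesh)
  F <- long_range_forces(sys, mesh, Pg, Bg)
  h <- 1e-6
  num <- matrix(0, 10, 3)
  for (i in 1:10) for (a in 1:3) {
    pp <- sys$positions
    pp[i, a] <- pp[i, a] + h
    up <- long_range_energy(
      spread_charges(charge_system(pp, sys$charges, sys$box), mesh), Pg, Bg)
    pp[i, a] <- pp[i, a] - 2 * h
    dn <- long_range_energy(
      spread_charges(charge_system(pp, sys$charges, sys$box), mesh), Pg, Bg)
    num[i, a] <- -(up - dn) / (2 * h)
  }
  expect_lt(max(abs(F - num)) / max(abs(F)), 1e-5)
  # zero charges give zero forces
  sys0 <- charge_system(sys$positions, numeric(10), sys$box)
  expect_equal(long_range_forces(sys0, mesh, Pg, Bg), matrix(0, 10, 3))
})

test_that("opposite charges mirrored about the box center feel opposite forces", {
  sp <- split_potential(reaction_field_potential(), 1.0, 2.0)
  mesh <- mesh_config(4, K = 32, order = 8)
  pair <- dipole_pair(1.2, box = 4)
  Pg <- build_energy_array(mesh, sp)
  Bg <- compute_bfactors(mesh)
  F <- long_range_forces(pair, mesh, Pg, Bg)
  expect_lt(max(abs(F[1, ] + F[2, ])), 1e-8 * max(abs(F)))
})

test_that("assembled total matches the two-body closed form and is order-invariant", {
  box <- 4
  sp <- split_potential(reaction_field_potential(), 1.0, 2.0)
  d <- 0.8
  pair <- dipole_pair(d, box = box)
  mesh <- mesh_config(box, spacing = 0.1)
  res <- total_energy_forces(pair, sp, mesh)
  comp <- split_components(sp, d)
  closed <- -(comp$u_S + comp$u_L + comp$u_B)  # q1 q2 = -1
  expect_equal(res$U_total, closed, tolerance = 1e-4)
  expect_equal(res$U_total, res$U_S + res$U_L + res$U_B)
  # zero-charge system: all components vanish
  z <- charge_system(pair$positions, c(0, 0), box)
  rz <- total_energy_forces(z, sp, mesh)
  expect_equal(c(rz$U_S, rz$U_L, rz$U_B, rz$U_total), rep(0, 4))
  # particle reordering leaves energies and the force map unchanged
  sys <- random_neutral_system(20, box, seed = 19)
  r1 <- total_energy_forces(sys, sp, mesh)
  perm <- sample(20)
  sys2 <- charge_system(sys$positions[perm, ], sys$charges[perm], box)
  r2 <- total_energy_forces(sys2, sp, mesh)
  expect_equal(r2$U_total, r1$U_total, tolerance = 1e-11)
  expect_equal(r2$forces, r1$forces[perm, ], tolerance = 1e-9)
})

test_that("mesh configuration enforces spline-order and grid constraints", {
  expect_error(mesh_config(4, K = 16, order = 7), "even")
  expect_error(mesh_config(4, K = 8, order = 8), "2 \\* order")
  m <- mesh_config(c(3, 4, 5), spacing = 0.1, order = 4)
  expect_true(all(m$box / m$K <= 0.1 + 1e-15))
  expect_error(
    build_energy_array(mesh_config(4, K = 20, order = 8),
                       split_potential(coulomb_potential(), 1, 2.5)),
    "half")
})
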