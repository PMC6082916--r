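# Independent brute-force references used across the suite. These are kept
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can serve as oracles for the vectorized paths.

# Minimum-image displacement by exhaustive search over the 27 periodic images.
brute_min_image <- function(ri, rj, box) {
  best <- NULL
  best_r <- Inf
  for (n1 in -1:1) for (n2 in -1:1) for (n3 in -1:1) {
    d <- ri - rj + c(n1, n2, n3) * box
    r <- sqrt(sum(d^2))
    if (r < best_r) {
      best_r <- r
      best <- d
    }
  }
  best
}

# All-pairs short-range energy by an explicit double loop.
naive_short_range <- function(sys, sp) {
  n <- nrow(sys$positions)
  U <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- brute_min_image(sys$positions[i, ], sys$positions[j, ], sys$box)
    r <- sqrt(sum(d^2))
    if (r < sp$r_c) {
      u <- evaluate_lips(sp$base, r, sp$r_c) -
        evaluate_lips(sp$base, sp$r_c, sp$r_c)
      U <- U + sp$prefactor * sys$charges[i] * sys$charges[j] * u
    }
  }
  U
}

# Boundary energy by an explicit double loop.
naive_boundary <- function(sys, sp) {
  n <- nrow(sys$positions)
  uB <- evaluate_lips(sp$base, sp$R_c, sp$R_c)
  U <- 0
  if (n < 2) return(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- brute_min_image(sys$positions[i, ], sys$positions[j, ], sys$box)
    if (sqrt(sum(d^2)) < sp$R_c)
      U <- U + sp$prefactor * uB * sys$charges[i] * sys$charges[j]
  }
  U
}

# Charge deposition by an explicit quadruple loop over particles and the
# full stencil, wrapping indices by hand.
naive_spread <- function(sys, mesh) {
  K <- mesh$K
  n <- mesh$order
  Q <- array(0, K)
  for (i in seq_len(nrow(sys$positions))) {
    w <- sys$positions[i, ] * K / mesh$box
    for (j1 in 0:(n - 1)) for (j2 in 0:(n - 1)) for (j3 in 0:(n - 1)) {
      k <- floor(w) - c(j1, j2, j3)
      wt <- bspline(n, w[1] - k[1]) * bspline(n, w[2] - k[2]) *
        bspline(n, w[3] - k[3])
      idx <- (k %% K) + 1
      Q[idx[1], idx[2], idx[3]] <- Q[idx[1], idx[2], idx[3]] +
        sys$charges[i] * wt
    }
  }
  Q
}

# Flat-loop force RMSD with the 3N - 1 denominator.
naive_force_rmsd <- function(F, F_ref) {
  acc <- 0
  for (i in seq_len(nrow(F))) for (a in 1:3)
    acc <- acc + (F[i, a] - F_ref[i, a])^2
  sqrt(acc / (3 * nrow(F) - 1))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(1, abs(expected)), tol)
}
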