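#' Mesh configuration for the FFT long-range path
#'
#' Fixes the grid dimensions `K = (K1, K2, K3)` and the cardinal B-spline
#' interpolation order `n` used to spread point charges onto the mesh.
#' Either `K` is given directly or it is derived from a target grid spacing
#' as `K_alpha = ceiling(L_alpha / spacing)`, which guarantees an effective
#' spacing `L_alpha / K_alpha <= spacing`. The spline order must be even
#' (odd orders can zero the reciprocal-space spline denominator at the
#' Nyquist mode) and each axis must carry at least `2 n` grid points.
#'
#' @param box length-3 box vector (scalar recycled).
#' @param spacing target grid spacing (same unit as the box); ignored when
#'   `K` is given.
#' @param K integer length-3 vector of grid points per axis (scalar
#'   recycled).
#' @param order even B-spline order `n >= 2` (default 8).
#' @return An object of class `"mesh_config"`.
#' @export
mesh_config <- function(box, spacing = NULL, K = NULL, order = 8) {
  if (length(box) == 1) box <- rep(box, 3)
  stopifnot(length(box) == 3, all(box > 0))
  order <- as.integer(order)
  if (order < 2 || order %% 2 != 0)
    stop("spline order must be even and >= 2", call. = FALSE)
  if (is.null(K)) {
    if (is.null(spacing) || spacing <= 0)
      stop("either K or a positive target spacing must be given",
           call. = FALSE)
    K <- as.integer(ceiling(box / spacing))
  } else {
    if (length(K) == 1) K <- rep(K, 3)
    K <- as.integer(K)
    stopifnot(length(K) == 3, all(K >= 1))
  }
  if (any(K < 2L * order))
    stop("each axis needs at least 2 * order grid points", call. = FALSE)
  structure(list(box = as.numeric(box), K = K, order = order,
                 spacing = if (is.null(spacing)) NA_real_ else spacing),
            class = "mesh_config")
}

#' @export
print.mesh_config <- function(x, ...) {
  cat(sprintf("<mesh_config> K = %d x %d x %d  order = %d  spacing = %s\n",
              x$K[1], x$K[2], x$K[3], x$order,
              paste(signif(x$box / x$K, 4), collapse = " x ")))
  invisible(x)
}

#' Cardinal B-spline
#'
#' `M_n(w)`, the cardinal B-spline of order `n`: the `n`-fold convolution of
#' the unit-interval indicator, supported on `(0, n)`, evaluated by the
#' standard recursion
#' `M_n(w) = (w M_{n-1}(w) + (n - w) M_{n-1}(w - 1)) / (n - 1)` with
#' `M_1 = 1` on `[0, 1)`.
#'
#' @param n order, integer `>= 1`.
#' @param w evaluation point(s).
#' @return numeric vector of weights.
#' @export
bspline <- function(n, w) {
  stopifnot(n >= 1)
  if (n == 1) return(as.numeric(w >= 0 & w < 1))
  (w * bspline(n - 1, w) + (n - w) * bspline(n - 1, w - 1)) / (n - 1)
}

#' Derivative of the cardinal B-spline
#'
#' `d M_n / d w = M_{n-1}(w) - M_{n-1}(w - 1)`, the exact derivative
#' identity used for the analytic mesh forces.
#'
#' @param n order, integer `>= 2`.
#' @param w evaluation point(s).
#' @return numeric vector.
#' @export
bspline_derivative <- function(n, w) {
  stopifnot(n >= 2)
  bspline(n - 1, w) - bspline(n - 1, w - 1)
}

## Per-particle spreading stencil: scaled fractional coordinates
## w_alpha = K_alpha r_alpha / L_alpha; each particle touches the n nodes
## k = floor(w) - j, j = 0..n-1, per axis, with weight M_n(frac + j).
## Returns idx[[axis]] (N x n, 1-based wrapped grid indices), W[[axis]] and
## dW[[axis]] (N x n weights and dM/dw).
spread_stencil <- function(sys, mesh, derivatives = FALSE) {
  K <- mesh$K; L <- mesh$box; n <- mesh$order
  if (!isTRUE(all.equal(sys$box, mesh$box)))
    stop("system and mesh boxes differ", call. = FALSE)
  if (any(!is.finite(sys$positions)))
    stop("non-finite position", call. = FALSE)
  idx <- vector("list", 3); W <- vector("list", 3); dW <- vector("list", 3)
  j <- 0:(n - 1)
  for (a in 1:3) {
    w <- sys$positions[, a] * K[a] / L[a]
    fl <- floor(w)
    arg <- outer(w - fl, j, `+`)          # in (0, n)
    W[[a]] <- bspline(n, arg)
    if (derivatives) dW[[a]] <- bspline_derivative(n, arg)
    idx[[a]] <- (outer(fl, j, `-`) %% K[a]) + 1
  }
  list(idx = idx, W = W, dW = if (derivatives) dW else NULL)
}

#' Spread point charges onto the mesh
#'
#' Builds the charge array
#' `Q(k) = sum_i q_i prod_alpha M_n(w_alpha_i - k_alpha - n_alpha K_alpha)`
#' by depositing each charge onto the `n` nearest grid nodes per axis with
#' periodic wrap. By the spline partition of unity, `sum(Q) = sum(q_i)`.
#'
#' @param sys a [charge_system()].
#' @param mesh a [mesh_config()] sharing the system's box.
#' @return An object of class `"charge_grid"` with the array `Q`.
#' @export
spread_charges <- function(sys, mesh) {
  stopifnot(inherits(sys, "charge_system"), inherits(mesh, "mesh_config"))
  st <- spread_stencil(sys, mesh)
  K <- mesh$K
  Q <- array(0, K)
  for (i in seq_len(nrow(sys$positions))) {
    blk <- sys$charges[i] * (st$W[[1]][i, ] %o% st$W[[2]][i, ] %o%
                               st$W[[3]][i, ])
    i1 <- st$idx[[1]][i, ]; i2 <- st$idx[[2]][i, ]; i3 <- st$idx[[3]][i, ]
    Q[i1, i2, i3] <- Q[i1, i2, i3] + blk
  }
  structure(list(Q = Q, K = K, mesh = mesh), class = "charge_grid")
}

#' Reciprocal-space B-spline factors
#'
#' Per-axis factors `b_i(m) = exp(2 pi I (n-1) m / K) /
#' sum_{k=0}^{n-2} M_n(k+1) exp(2 pi I m k / K)` and their combined squared
#' modulus `B(m) = |b_1|^2 |b_2|^2 |b_3|^2`, which deconvolves the spline
#' spreading of both charge factors in the energy sum. Modes whose
#' denominator modulus falls below `1e-10` are set to `B = 0`.
#'
#' @param mesh a [mesh_config()] (even spline order enforced there).
#' @return An object of class `"bfactor_grid"` with the array `B`.
#' @export
compute_bfactors <- function(mesh) {
  stopifnot(inherits(mesh, "mesh_config"))
  n <- mesh$order
  axis_b2 <- function(K) {
    m <- 0:(K - 1)
    k <- 0:(n - 2)
    Mv <- bspline(n, k + 1)
    D <- drop(exp(2i * pi * outer(m, k) / K) %*% Mv)
    out <- numeric(K)
    ok <- Mod(D) >= 1e-10
    out[ok] <- 1 / Mod(D[ok])^2
    out
  }
  B <- axis_b2(mesh$K[1]) %o% axis_b2(mesh$K[2]) %o% axis_b2(mesh$K[3])
  structure(list(B = B, K = mesh$K, order = n), class = "bfactor_grid")
}

#' Tabulate the long-range pair potential on the mesh
#'
#' The energy array `Phi*(k) = sum_images u_L(|d(k + n K)|)` where
#' `d_alpha = (k_alpha / K_alpha) L_alpha` maps grid-index offsets to
#' Cartesian displacements, summed over images `n in {-1,0,1}^3` whose
#' distance is strictly below `R_c` (at most one image can contribute when
#' `R_c <= L/2`, but the full image set is scanned for robustness at the
#' boundary). The zero-displacement entry is the finite limit
#' [long_range_at_zero()].
#'
#' @param mesh a [mesh_config()].
#' @param sp a [split_potential()] with `R_c <= min(box)/2`.
#' @return An object of class `"energy_grid"` with the array `Phi_star`.
#' @export
build_energy_array <- function(mesh, sp) {
  stopifnot(inherits(mesh, "mesh_config"), inherits(sp, "split_potential"))
  if (sp$R_c > min(mesh$box) / 2)
    stop("R_c exceeds half the shortest box edge", call. = FALSE)
  K <- mesh$K; L <- mesh$box
  base <- lapply(1:3, function(a) (0:(K[a] - 1)) / K[a] * L[a])
  Phi <- array(0, K)
  nk <- prod(K)
  for (n1 in -1:1) for (n2 in -1:1) for (n3 in -1:1) {
    d1 <- (base[[1]] + n1 * L[1])^2
    d2 <- (base[[2]] + n2 * L[2])^2
    d3 <- (base[[3]] + n3 * L[3])^2
    r2 <- array(d1, K) +
      array(rep(d2, each = K[1]), K) +
      array(rep(d3, each = K[1] * K[2]), K)
    mask <- r2 < sp$R_c^2
    if (any(mask)) Phi[mask] <- Phi[mask] + u_long(sp, sqrt(r2[mask]))
  }
  structure(list(Phi_star = Phi, K = K, r_c = sp$r_c, R_c = sp$R_c),
            class = "energy_grid")
}

#' Long-range energy by FFT convolution
#'
#' `U_L = 1/(2 K1 K2 K3) sum_m B(m) |F(Q)(m)|^2 Re F(Phi*)(m)`, the discrete
#' convolution energy of the spread charges with the tabulated long-range
#' pair potential, deconvolved by the B-spline factors. The result
#' approximates `1/2 sum_i sum_j q_i q_j u_L(r_ij)` *including* the `i = j`
#' self term `1/2 (sum q_i^2) u_L(0)`, with error vanishing as the grid is
#' refined. Energies are per unit `coulomb_prefactor`; the assembly in
#' [total_energy_forces()] applies the prefactor and (by default) removes
#' the self term.
#'
#' @param Qg a `"charge_grid"` from [spread_charges()].
#' @param Pg an `"energy_grid"` from [build_energy_array()].
#' @param Bg a `"bfactor_grid"` from [compute_bfactors()].
#' @return scalar energy.
#' @export
long_range_energy <- function(Qg, Pg, Bg) {
  stopifnot(inherits(Qg, "charge_grid"), inherits(Pg, "energy_grid"),
            inherits(Bg, "bfactor_grid"))
  if (!identical(Qg$K, Pg$K) || !identical(Qg$K, Bg$K))
    stop("grid shapes differ", call. = FALSE)
  FQ <- stats::fft(Qg$Q)
  FP <- stats::fft(Pg$Phi_star)
  sum(Bg$B * (Mod(FQ)^2) * Re(FP)) / (2 * prod(Qg$K))
}

## Convolved mesh potential sampled at the grid nodes:
## conv = F^{-1}[ B F(Q) F(Phi*) ] / (K1 K2 K3).
## U_L = 1/2 sum_k Q(k) conv(k) and d U_L / d Q(k) = conv(k) (the kernel is
## real and inversion-symmetric), which is what the analytic forces use.
mesh_convolution <- function(Qg, Pg, Bg) {
  FQ <- stats::fft(Qg$Q)
  FP <- stats::fft(Pg$Phi_star)
  Re(stats::fft(Bg$B * FQ * FP, inverse = TRUE)) / prod(Qg$K)
}

#' Analytic mesh forces
#'
#' The exact negative gradient of the discrete long-range energy with
#' respect to particle positions:
#' `f_{alpha,i} = - sum_k (d Q(k) / d r_{alpha,i}) conv(k)` where `conv` is
#' the convolved mesh potential and the spreading derivative uses the
#' B-spline derivative identity with the chain-rule factor
#' `K_alpha / L_alpha`.
#'
#' @param sys a [charge_system()].
#' @param mesh a [mesh_config()].
#' @param Pg an `"energy_grid"`.
#' @param Bg a `"bfactor_grid"`.
#' @param Qg optional precomputed `"charge_grid"` (recomputed when `NULL`).
#' @return N x 3 force matrix (per unit `coulomb_prefactor`).
#' @export
long_range_forces <- function(sys, mesh, Pg, Bg, Qg = NULL) {
  stopifnot(inherits(sys, "charge_system"), inherits(mesh, "mesh_config"))
  if (is.null(Qg)) Qg <- spread_charges(sys, mesh)
  if (!identical(Qg$K, Pg$K) || !identical(Qg$K, Bg$K))
    stop("grid shapes differ", call. = FALSE)
  conv <- mesh_convolution(Qg, Pg, Bg)
  st <- spread_stencil(sys, mesh, derivatives = TRUE)
  n <- mesh$order
  scale <- mesh$K / mesh$box
  N <- nrow(sys$positions)
  F <- matrix(0, N, 3)
  for (i in seq_len(N)) {
    i1 <- st$idx[[1]][i, ]; i2 <- st$idx[[2]][i, ]; i3 <- st$idx[[3]][i, ]
    sub <- conv[i1, i2, i3]                       # n x n x n
    w1 <- st$W[[1]][i, ]; w2 <- st$W[[2]][i, ]; w3 <- st$W[[3]][i, ]
    d1 <- st$dW[[1]][i, ]; d2 <- st$dW[[2]][i, ]; d3 <- st$dW[[3]][i, ]
    m <- matrix(sub, n, n * n)
    t23 <- as.vector(w2 %o% w3)
    F[i, 1] <- -sys$charges[i] * scale[1] * sum(d1 * (m %*% t23))
    m2 <- matrix(drop(w1 %*% m), n, n)            # contracted over axis 1
    F[i, 2] <- -sys$charges[i] * scale[2] * drop(d2 %*% m2 %*% w3)
    F[i, 3] <- -sys$charges[i] * scale[3] * drop(w2 %*% m2 %*% d3)
  }
  F
}

## Reusable mesh context (energy array + spline factors) for repeated
## evaluations over a fixed box/potential, e.g. along an MD run.
mesh_context <- function(sp, mesh) {
  list(Pg = build_energy_array(mesh, sp), Bg = compute_bfactors(mesh),
       uL0 = long_range_at_zero(sp))
}

lips_fft_eval <- function(sys, sp, mesh, ctx, self_correction = TRUE) {
  srs <- short_range_sum(sys, sp)
  U_B <- boundary_sum(sys, sp)
  Qg <- spread_charges(sys, mesh)
  UL_raw <- long_range_energy(Qg, ctx$Pg, ctx$Bg)
  if (self_correction)
    UL_raw <- UL_raw - 0.5 * sum(sys$charges^2) * ctx$uL0
  U_L <- sp$prefactor * UL_raw
  FL <- sp$prefactor * long_range_forces(sys, mesh, ctx$Pg, ctx$Bg, Qg = Qg)
  forces <- srs$forces + FL
  structure(list(U_S = srs$U_S, U_L = U_L, U_B = U_B,
                 U_total = srs$U_S + U_L + U_B,
                 forces = forces,
                 metadata = list(method = "lips_fft",
                                 potential = sp$base$label,
                                 r_c = sp$r_c, R_c = sp$R_c,
                                 K = mesh$K, order = mesh$order,
                                 self_correction = self_correction)),
            class = "force_energy")
}

#' Total LIPS/FFT energy and forces
#'
#' Assembles `U_total = U_S + U_L + U_B`: the real-space short-range sum, the
#' FFT-convolution long-range energy, and the real-space boundary term.
#' The FFT convolution inherently contains the `i = j` self interaction
#' `1/2 (sum q_i^2) u_L(0)`; since `u_L(0)` is a finite constant this is
#' subtracted exactly by default so that the total matches the pairwise
#' direct sum, and can be retained with `self_correction = FALSE`.
#' Forces are the short-range pair gradients plus the analytic mesh forces
#' (the boundary term is constant and force-free).
#'
#' @param sys a [charge_system()].
#' @param sp a [split_potential()] with `r_c < R_c <= min(box)/2`.
#' @param mesh a [mesh_config()] on the system's box.
#' @param self_correction subtract the mesh self term (default `TRUE`).
#' @return An object of class `"force_energy"` with fields `U_S`, `U_L`,
#'   `U_B`, `U_total`, `forces` (N x 3), and `metadata`.
#' @export
total_energy_forces <- function(sys, sp, mesh, self_correction = TRUE) {
  stopifnot(inherits(sys, "charge_system"), inherits(sp, "split_potential"),
            inherits(mesh, "mesh_config"))
  ctx <- mesh_context(sp, mesh)
  lips_fft_eval(sys, sp, mesh, ctx, self_correction = self_correction)
}

#' @export
print.force_energy <- function(x, ...) {
  cat(sprintf("<force_energy> %s  U_S = %.8g  U_L = %.8g  U_B = %.8g  U_total = %.8g\n",
              x$metadata$method, x$U_S, x$U_L, x$U_B, x$U_total))
  invisible(x)
}
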