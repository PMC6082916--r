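#' Brute-force pairwise reference energy and forces
#'
#' The O(N^2) minimum-image ground truth the mesh path is tested against:
#' `U = 1/2 sum_{i != j, r_ij < R_c} q_i q_j u_eff(r_ij, R_c)`, decomposed
#' into the same short-range / long-range / boundary bookkeeping as the
#' split sums, with forces from the analytic pair derivative (five-point
#' central differences when the plug-in ships no derivative).
#'
#' @param sys a [charge_system()].
#' @param sp a [split_potential()] with `R_c <= min(box)/2` (minimum image
#'   suffices).
#' @return A `"force_energy"` object (`metadata$method == "direct"`).
#' @export
direct_lips <- function(sys, sp) {
  stopifnot(inherits(sys, "charge_system"), inherits(sp, "split_potential"))
  if (sp$R_c > min(sys$box) / 2)
    stop("R_c exceeds half the shortest box edge", call. = FALSE)
  n <- nrow(sys$positions)
  F <- matrix(0, n, 3)
  empty <- structure(list(U_S = 0, U_L = 0, U_B = 0, U_total = 0,
                          forces = F,
                          metadata = list(method = "direct",
                                          potential = sp$base$label,
                                          r_c = sp$r_c, R_c = sp$R_c)),
                     class = "force_energy")
  if (n == 1) return(empty)
  g <- pair_geometry(sys)
  keep <- upper.tri(g$r) & g$r < sp$R_c
  if (!any(keep)) return(empty)
  idx <- which(keep, arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  r <- g$r[keep]
  dx <- cbind(g$dx[keep], g$dy[keep], g$dz[keep])
  q <- sys$charges
  qq <- q[i] * q[j]
  comp <- split_components(sp, r)
  pf <- sp$prefactor
  U_S <- pf * sum(qq * comp$u_S)
  U_L <- pf * sum(qq * comp$u_L)
  U_B <- pf * sum(qq * comp$u_B)
  dudr <- lips_dudr(sp$base, r, sp$R_c)
  fv <- (-pf * qq * dudr / r) * dx
  F <- accumulate_rows(F, i, fv)
  F <- accumulate_rows(F, j, -fv)
  structure(list(U_S = U_S, U_L = U_L, U_B = U_B,
                 U_total = U_S + U_L + U_B, forces = F,
                 metadata = list(method = "direct",
                                 potential = sp$base$label,
                                 r_c = sp$r_c, R_c = sp$R_c)),
            class = "force_energy")
}

#' Direct pairwise long-range sum
#'
#' `1/2 sum_{i != j} q_i q_j u_L(r_ij)` by the minimum-image double loop,
#' optionally including the `j = i` self term `1/2 (sum q_i^2) u_L(0)` —
#' the reference for the FFT-convolution path, which inherently carries that
#' term.
#'
#' @param sys a [charge_system()].
#' @param sp a [split_potential()] with `R_c <= min(box)/2`.
#' @param include_self include the self term (default `FALSE`).
#' @return list with `U_L` (scalar) and `forces` (N x 3).
#' @export
direct_long_range <- function(sys, sp, include_self = FALSE) {
  stopifnot(inherits(sys, "charge_system"), inherits(sp, "split_potential"))
  if (sp$R_c > min(sys$box) / 2)
    stop("R_c exceeds half the shortest box edge", call. = FALSE)
  n <- nrow(sys$positions)
  q <- sys$charges
  pf <- sp$prefactor
  F <- matrix(0, n, 3)
  U <- 0
  if (n > 1) {
    g <- pair_geometry(sys)
    keep <- upper.tri(g$r) & g$r < sp$R_c
    if (any(keep)) {
      idx <- which(keep, arr.ind = TRUE)
      i <- idx[, 1]; j <- idx[, 2]
      r <- g$r[keep]
      dx <- cbind(g$dx[keep], g$dy[keep], g$dz[keep])
      qq <- q[i] * q[j]
      U <- pf * sum(qq * u_long(sp, r))
      fv <- (-pf * qq * du_long(sp, r) / r) * dx
      F <- accumulate_rows(F, i, fv)
      F <- accumulate_rows(F, j, -fv)
    }
  }
  if (include_self)
    U <- U + 0.5 * pf * sum(q^2) * long_range_at_zero(sp)
  list(U_L = U, forces = F)
}
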