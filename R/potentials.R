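#' Pair potential with a periodic reaction field
#'
#' A pseudo pair potential of the isotropic-periodic-sum (IPS/LIPS) family is
#' the sum of a bare pair interaction `u(r)` (for example the charge-normalized
#' Coulomb interaction `1/r`) and a reaction-field term `phi(r, R_c)` produced
#' by the isotropically distributed periodic images inside the cutoff sphere of
#' radius `R_c`. This constructor wraps the two functions (and optionally their
#' analytic radial derivatives) into a plug-in object consumed by
#' [split_potential()].
#'
#' The contract on the plug-in is:
#' * `u(r)` is finite and continuously differentiable for all `r > 0`;
#' * `phi(r, R_c)` is finite on the whole closed range `0 <= r <= R_c`
#'   (the reaction field carries no singularity at the origin).
#'
#' @param u vectorized function of `r`: the bare pair interaction per unit
#'   charge product.
#' @param phi vectorized function of `(r, R_c)`: the reaction-field term.
#' @param du optional analytic derivative `du/dr`; when `NULL`, derivatives
#'   fall back to five-point central differences.
#' @param dphi optional analytic derivative `d phi/d r` at fixed `R_c`.
#' @param label identifier string used in metadata and by the registry.
#' @return An object of class `"pair_potential"`.
#' @seealso [coulomb_potential()], [poly_reaction_field()], [split_potential()]
#' @export
pair_potential <- function(u, phi, du = NULL, dphi = NULL, label = "custom") {
  stopifnot(is.function(u), is.function(phi))
  if (!is.null(du)) stopifnot(is.function(du))
  if (!is.null(dphi)) stopifnot(is.function(dphi))
  structure(list(u = u, phi = phi, du = du, dphi = dphi,
                 label = as.character(label)[1]),
            class = "pair_potential")
}

#' @export
print.pair_potential <- function(x, ...) {
  cat("<pair_potential>", x$label,
      if (is.null(x$du) || is.null(x$dphi)) "(numerical derivatives)" else
        "(analytic derivatives)", "\n")
  invisible(x)
}

#' Bare truncated Coulomb potential (null reaction field)
#'
#' The degenerate member of the pseudo-pair-potential family: `u(r) = 1/r`
#' with `phi == 0`. Splitting this potential gives plain shifted-truncated
#' Coulomb interactions; it is the baseline against which reaction-field
#' plug-ins are compared and the simplest input for testing the mesh path.
#'
#' @return A `"pair_potential"` object.
#' @export
coulomb_potential <- function() {
  pair_potential(
    u    = function(r) 1 / r,
    phi  = function(r, Rc) numeric(length(r)),
    du   = function(r) -1 / r^2,
    dphi = function(r, Rc) numeric(length(r)),
    label = "coulomb")
}

#' Polynomial reaction-field family
#'
#' A six-coefficient polynomial reaction field
#' `phi(r, R_c) = (1/R_c) * sum_{k=0}^{5} c_k (r/R_c)^k`
#' added to the bare Coulomb interaction `1/r`. Published closed-form LIPS
#' reaction-field coefficients can be entered directly as `c_0..c_5`; the
#' `1/R_c` prefactor keeps the coefficients dimensionless.
#'
#' A classic example is the continuum reaction field
#' `c = (-3/2, 0, 1/2)`, for which the pseudo potential
#' `1/r + r^2/(2 R_c^3) - 3/(2 R_c)` and its derivative both vanish at
#' `r = R_c` (see [reaction_field_potential()]).
#'
#' @param coefficients numeric vector of length 1..6, the coefficients
#'   `c_0..c_5` (missing trailing entries are zero).
#' @return A `"pair_potential"` object with analytic derivatives.
#' @export
poly_reaction_field <- function(coefficients) {
  stopifnot(is.numeric(coefficients), length(coefficients) >= 1,
            length(coefficients) <= 6, all(is.finite(coefficients)))
  ck <- c(coefficients, numeric(6 - length(coefficients)))
  dk <- ck[2:6] * (1:5)
  pair_potential(
    u    = function(r) 1 / r,
    phi  = function(r, Rc) {
      x <- r / Rc
      drop(outer(x, 0:5, `^`) %*% ck) / Rc
    },
    dphi = function(r, Rc) {
      x <- r / Rc
      drop(outer(x, 0:4, `^`) %*% dk) / Rc^2
    },
    du   = function(r) -1 / r^2,
    label = "poly5")
}

#' Continuum reaction-field pseudo potential
#'
#' Convenience wrapper for [poly_reaction_field()] with `c = (-3/2, 0, 1/2)`,
#' i.e. `u_eff = 1/r + r^2/(2 R_c^3) - 3/(2 R_c)`. Both the value and the
#' radial derivative of this pseudo potential vanish at the cutoff, which
#' makes it the natural choice for energy-conserving molecular dynamics with
#' the toy integrator.
#'
#' @return A `"pair_potential"` object.
#' @export
reaction_field_potential <- function() {
  p <- poly_reaction_field(c(-1.5, 0, 0.5))
  p$label <- "reaction_field"
  p
}

#' Look up a shipped potential by name
#'
#' @param name `"coulomb"`, `"reaction_field"`, or `"poly5"`.
#' @param coefficients required when `name == "poly5"`.
#' @return A `"pair_potential"` object.
#' @export
get_potential <- function(name, coefficients = NULL) {
  switch(name,
    coulomb = coulomb_potential(),
    reaction_field = reaction_field_potential(),
    poly5 = {
      if (is.null(coefficients))
        stop("potential 'poly5' requires coefficients", call. = FALSE)
      poly_reaction_field(coefficients)
    },
    stop("unknown potential: ", name, call. = FALSE))
}

#' Evaluate the pseudo pair potential
#'
#' `u_eff(r, R_c) = u(r) + phi(r, R_c)`, per unit charge product.
#'
#' @param pot a [pair_potential()].
#' @param r interaction distance(s), must be `> 0`.
#' @param R_c cutoff radius of the reaction field, `> 0`.
#' @return numeric vector of pair energies per unit charge product.
#' @export
evaluate_lips <- function(pot, r, R_c) {
  stopifnot(inherits(pot, "pair_potential"))
  if (any(r <= 0)) stop("r must be positive", call. = FALSE)
  if (R_c <= 0) stop("R_c must be positive", call. = FALSE)
  pot$u(r) + pot$phi(r, R_c)
}

## d u_eff / d r at fixed R_c; analytic when the plug-in provides it,
## else five-point central differences with step 1e-6 * R_c.
lips_dudr <- function(pot, r, R_c) {
  if (!is.null(pot$du) && !is.null(pot$dphi))
    return(pot$du(r) + pot$dphi(r, R_c))
  h <- 1e-6 * R_c
  f <- function(x) evaluate_lips(pot, x, R_c)
  (f(r - 2 * h) - 8 * f(r - h) + 8 * f(r + h) - f(r + 2 * h)) / (12 * h)
}

#' Split a pseudo pair potential at an auxiliary short-range cutoff
#'
#' Divides the pseudo pair potential `u_eff(r, R_c)` into three parts:
#' \describe{
#'   \item{short-range}{`u_S(r) = u_eff(r, r_c) - u_eff(r_c, r_c)` for
#'     `r < r_c`, else 0 — summed directly in real space;}
#'   \item{long-range}{`u_L(r) = u_eff(r, R_c) - u_S(r) - u_B(r)` for
#'     `r < R_c`, else 0 — bounded (the `1/r` singularities cancel), so it can
#'     be tabulated on a mesh and summed by FFT convolution;}
#'   \item{boundary}{`u_B(r) = u_eff(R_c, R_c)` for `r < R_c`, else 0 — a
#'     constant, hence force-free.}
#' }
#' At `r` exactly equal to a cutoff the zero branch is taken (the nonzero
#' branch vanishes there by continuity anyway).
#'
#' @param base a [pair_potential()] plug-in.
#' @param r_c short-range cutoff (same length unit as positions).
#' @param R_c reaction-field cutoff; requires `0 < r_c < R_c`.
#' @param coulomb_prefactor unit-system constant multiplying
#'   `q_i q_j u(r_ij)`; 1 in reduced units.
#' @return An object of class `"split_potential"`.
#' @export
split_potential <- function(base, r_c, R_c, coulomb_prefactor = 1) {
  stopifnot(inherits(base, "pair_potential"),
            is.numeric(r_c), is.numeric(R_c),
            length(r_c) == 1, length(R_c) == 1)
  if (!(r_c > 0 && R_c > r_c))
    stop("cutoffs must satisfy 0 < r_c < R_c", call. = FALSE)
  structure(list(base = base, r_c = r_c, R_c = R_c,
                 prefactor = coulomb_prefactor),
            class = "split_potential")
}

#' @export
print.split_potential <- function(x, ...) {
  cat(sprintf("<split_potential> %s  r_c = %g  R_c = %g  prefactor = %g\n",
              x$base$label, x$r_c, x$R_c, x$prefactor))
  invisible(x)
}

#' Short-range / long-range / boundary components at given distances
#'
#' @param sp a [split_potential()].
#' @param r distance(s), `> 0`.
#' @return A list with numeric vectors `u_S`, `u_L`, `u_B` (per unit charge
#'   product; the `coulomb_prefactor` is applied by the energy sums, not
#'   here). For `0 < r < r_c` the three components sum to
#'   `u_eff(r, R_c)` to machine precision.
#' @export
split_components <- function(sp, r) {
  stopifnot(inherits(sp, "split_potential"))
  if (any(r <= 0)) stop("r must be positive", call. = FALSE)
  pot <- sp$base; rc <- sp$r_c; Rc <- sp$R_c
  u_rc <- evaluate_lips(pot, rc, rc)   # u_eff(r_c, r_c)
  u_Rc <- evaluate_lips(pot, Rc, Rc)   # u_eff(R_c, R_c)
  inner <- r < rc
  mid   <- !inner & r < Rc
  u_S <- numeric(length(r))
  u_L <- numeric(length(r))
  u_B <- numeric(length(r))
  if (any(inner)) {
    ri <- r[inner]
    u_S[inner] <- pot$u(ri) + pot$phi(ri, rc) - u_rc
    # cancelled form of u_eff(r, R_c) - u_S - u_B: the bare u(r) drops out
    u_L[inner] <- pot$phi(ri, Rc) - pot$phi(ri, rc) + u_rc - u_Rc
  }
  if (any(mid)) {
    rm_ <- r[mid]
    u_L[mid] <- pot$u(rm_) + pot$phi(rm_, Rc) - u_Rc
  }
  u_B[r < Rc] <- u_Rc
  list(u_S = u_S, u_L = u_L, u_B = u_B)
}

#' Zero-distance limit of the long-range component
#'
#' `u_L` is bounded on `[0, R_c]` because the `1/r` singularities of
#' `u_eff(r, R_c)` and of the short-range part cancel. The limit at `r = 0`
#' is needed for the zero-displacement entry of the mesh energy array and for
#' the mesh self-energy correction. It is evaluated analytically as
#' `phi(0, R_c) - phi(0, r_c) + u_eff(r_c, r_c) - u_eff(R_c, R_c)` whenever
#' the plug-in's `phi` is finite at 0; otherwise by Richardson extrapolation
#' of `u_L` at `r = 1e-3 r_c` and `1e-4 r_c`.
#'
#' @param sp a [split_potential()].
#' @return The finite limit `u_L(0)` (per unit charge product).
#' @export
long_range_at_zero <- function(sp) {
  stopifnot(inherits(sp, "split_potential"))
  pot <- sp$base; rc <- sp$r_c; Rc <- sp$R_c
  val <- tryCatch(
    pot$phi(0, Rc) - pot$phi(0, rc) +
      evaluate_lips(pot, rc, rc) - evaluate_lips(pot, Rc, Rc),
    error = function(e) NA_real_)
  if (length(val) == 1 && is.finite(val)) return(as.numeric(val))
  r1 <- 1e-3 * rc; r2 <- 1e-4 * rc
  f1 <- split_components(sp, r1)$u_L
  f2 <- split_components(sp, r2)$u_L
  lim <- f2 - (f1 - f2) * r2 / (r1 - r2)
  if (!is.finite(lim))
    stop("long-range component has no finite limit at r = 0; ",
         "the plugged-in reaction field violates the pair_potential contract",
         call. = FALSE)
  lim
}

## u_L(r) vectorized including r = 0 (the finite limit); used by the mesh
## tabulation and the direct long-range oracle.
u_long <- function(sp, r) {
  if (any(r < 0)) stop("r must be nonnegative", call. = FALSE)
  out <- numeric(length(r))
  z <- r == 0
  if (any(z)) out[z] <- long_range_at_zero(sp)
  if (any(!z)) out[!z] <- split_components(sp, r[!z])$u_L
  out
}

## d u_L / d r for r > 0 (used by the direct long-range oracle forces).
du_long <- function(sp, r) {
  pot <- sp$base; rc <- sp$r_c; Rc <- sp$R_c
  out <- numeric(length(r))
  inner <- r > 0 & r < rc
  mid   <- r >= rc & r < Rc
  if (!is.null(pot$dphi)) {
    if (any(inner))
      out[inner] <- pot$dphi(r[inner], Rc) - pot$dphi(r[inner], rc)
  } else if (any(inner)) {
    h <- 1e-6 * rc
    g <- function(x) split_components(sp, x)$u_L
    ri <- r[inner]
    out[inner] <- (g(ri - 2 * h) - 8 * g(ri - h) +
                   8 * g(ri + h) - g(ri + 2 * h)) / (12 * h)
  }
  if (any(mid)) out[mid] <- lips_dudr(pot, r[mid], Rc)
  out
}
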