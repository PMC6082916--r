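#' Periodic point-charge configuration
#'
#' One frame of a periodic system: particle positions (nm), charges
#' (elementary-charge units) and an orthorhombic box. Positions are wrapped
#' into `[0, L_alpha)` on construction. Optional per-particle velocities and
#' masses are carried along for the trajectory observables and the toy MD
#' integrator.
#'
#' @param positions N x 3 numeric matrix.
#' @param charges numeric vector of length N.
#' @param box numeric length-3 vector of box edges (a scalar is recycled to a
#'   cubic box).
#' @param velocities optional N x 3 matrix.
#' @param masses optional numeric vector (defaults to unit masses).
#' @param species optional character vector of element labels (defaults "X").
#' @return An object of class `"charge_system"`.
#' @export
charge_system <- function(positions, charges, box, velocities = NULL,
                          masses = NULL, species = NULL) {
  positions <- as.matrix(positions)
  if (length(box) == 1) box <- rep(box, 3)
  stopifnot(ncol(positions) == 3, nrow(positions) >= 1,
            length(box) == 3, all(box > 0),
            length(charges) == nrow(positions),
            all(is.finite(positions)), all(is.finite(charges)))
  n <- nrow(positions)
  positions <- wrap_positions(positions, box)
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    stopifnot(nrow(velocities) == n, ncol(velocities) == 3,
              all(is.finite(velocities)))
  }
  if (is.null(masses)) masses <- rep(1, n)
  stopifnot(length(masses) == n, all(masses > 0))
  if (is.null(species)) species <- rep("X", n)
  structure(list(positions = positions, charges = as.numeric(charges),
                 box = as.numeric(box), velocities = velocities,
                 masses = as.numeric(masses), species = species),
            class = "charge_system")
}

#' @export
print.charge_system <- function(x, ...) {
  cat(sprintf("<charge_system> N = %d  box = %g x %g x %g  net charge = %g\n",
              nrow(x$positions), x$box[1], x$box[2], x$box[3],
              sum(x$charges)))
  invisible(x)
}

wrap_positions <- function(positions, box) {
  for (a in 1:3) {
    L <- box[a]
    positions[, a] <- positions[, a] - floor(positions[, a] / L) * L
  }
  positions
}

## Reduce displacement components into (-L/2, L/2]; d may be a vector of one
## component, a length-3 vector, or an N x 3 matrix (columns are axes).
mic <- function(d, box) {
  if (is.matrix(d)) {
    for (a in 1:3) {
      L <- box[a]
      x <- d[, a] - box[a] * round(d[, a] / box[a])
      x[x == -L / 2] <- L / 2
      d[, a] <- x
    }
    return(d)
  }
  x <- d - box * round(d / box)
  half <- box / 2
  x[x == -half] <- half[x == -half]
  x
}

#' Minimum-image displacement
#'
#' Displacement `ri - rj` with each component reduced into
#' `(-L_alpha/2, L_alpha/2]`: the nearest periodic image of the pair.
#'
#' @param ri,rj positions: length-3 vectors or N x 3 matrices of equal shape.
#' @param box length-3 box vector (scalar recycled).
#' @return displacement(s), same shape as the inputs.
#' @export
minimum_image <- function(ri, rj, box) {
  if (length(box) == 1) box <- rep(box, 3)
  stopifnot(all(box > 0))
  mic(ri - rj, box)
}

## All-pairs minimum-image displacement components and distances.
## Returns list(dx, dy, dz, r) of N x N matrices (diagonal zero).
pair_geometry <- function(sys) {
  p <- sys$positions; box <- sys$box
  d <- lapply(1:3, function(a) {
    m <- outer(p[, a], p[, a], `-`)
    L <- box[a]
    m <- m - L * round(m / L)
    m[m == -L / 2] <- L / 2
    m
  })
  list(dx = d[[1]], dy = d[[2]], dz = d[[3]],
       r = sqrt(d[[1]]^2 + d[[2]]^2 + d[[3]]^2))
}

## Pairs (i < j) with minimum-image distance strictly below `cutoff`,
## enumerated through a cell list with cell edge >= cutoff when the box
## accommodates at least 3 cells per axis, else by the all-pairs path.
## Both paths apply the identical strict r < cutoff criterion.
## Returns list(i, j, dx [n_pairs x 3], r).
neighbor_pairs <- function(sys, cutoff) {
  p <- sys$positions; box <- sys$box; n <- nrow(p)
  ncell <- pmax(1L, as.integer(floor(box / cutoff)))
  if (n < 40 || any(ncell < 3L)) {
    g <- pair_geometry(sys)
    keep <- upper.tri(g$r) & g$r < cutoff
    idx <- which(keep, arr.ind = TRUE)
    return(list(i = idx[, 1], j = idx[, 2],
                dx = cbind(g$dx[keep], g$dy[keep], g$dz[keep]),
                r = g$r[keep]))
  }
  cellsz <- box / ncell
  cidx <- sapply(1:3, function(a)
    pmin(ncell[a] - 1L, as.integer(floor(p[, a] / cellsz[a]))))
  cell_id <- cidx[, 1] + ncell[1] * (cidx[, 2] + ncell[2] * cidx[, 3])
  members <- split(seq_len(n), cell_id)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ii <- integer(0); jj <- integer(0)
  dxl <- vector("list", n); rl <- vector("list", n)
  np <- 0L
  for (i in seq_len(n)) {
    nb <- (t(off) + cidx[i, ]) %% ncell  # 3 x 27, columns wrapped
    nb_id <- unique(nb[1, ] + ncell[1] * (nb[2, ] + ncell[2] * nb[3, ]))
    cand <- unlist(members[as.character(nb_id)], use.names = FALSE)
    cand <- cand[cand > i]
    if (!length(cand)) next
    d <- mic(p[cand, , drop = FALSE] -
               matrix(p[i, ], length(cand), 3, byrow = TRUE), box)
    r <- sqrt(rowSums(d^2))
    keep <- r < cutoff
    if (!any(keep)) next
    np <- np + 1L
    ii <- c(ii, rep.int(i, sum(keep))); jj <- c(jj, cand[keep])
    dxl[[np]] <- -d[keep, , drop = FALSE]  # convention: r_i - r_j
    rl[[np]] <- r[keep]
  }
  list(i = ii, j = jj,
       dx = if (np) do.call(rbind, dxl[seq_len(np)]) else matrix(0, 0, 3),
       r = if (np) unlist(rl[seq_len(np)]) else numeric(0))
}

## Scatter-add rows of `vals` (n x 3) into F (N x 3) at row indices `idx`
## (with repeats allowed).
accumulate_rows <- function(F, idx, vals) {
  if (!length(idx)) return(F)
  s <- rowsum(vals, group = idx)
  rows <- as.integer(rownames(s))
  F[rows, ] <- F[rows, ] + s
  F
}

#' Real-space short-range energy and forces
#'
#' `U_S = 1/2 sum_i q_i sum_{r_ij < r_c, j != i} q_j u_S(r_ij)` with the
#' short-range component of the split pseudo potential, and the exact
#' negative gradient as forces. Pairs are enumerated by a cell list with
#' cell edge at least `r_c`.
#'
#' @param sys a [charge_system()].
#' @param sp a [split_potential()]; requires `r_c <= min(box)/2`.
#' @return list with `U_S` (energy) and `forces` (N x 3).
#' @export
short_range_sum <- function(sys, sp) {
  stopifnot(inherits(sys, "charge_system"), inherits(sp, "split_potential"))
  if (sp$r_c > min(sys$box) / 2)
    stop("r_c exceeds half the shortest box edge", call. = FALSE)
  n <- nrow(sys$positions)
  F <- matrix(0, n, 3)
  pr <- neighbor_pairs(sys, sp$r_c)
  if (!length(pr$i)) return(list(U_S = 0, forces = F))
  q <- sys$charges
  qq <- q[pr$i] * q[pr$j]
  uS <- split_components(sp, pr$r)$u_S
  U <- sp$prefactor * sum(qq * uS)
  # d u_S/d r = d u_eff(r, r_c)/d r on the open branch
  dudr <- lips_dudr(sp$base, pr$r, sp$r_c)
  fmag <- -sp$prefactor * qq * dudr        # along unit vector r_i - r_j
  fv <- (fmag / pr$r) * pr$dx
  F <- accumulate_rows(F, pr$i, fv)
  F <- accumulate_rows(F, pr$j, -fv)
  list(U_S = U, forces = F)
}

#' Real-space boundary energy
#'
#' `U_B = 1/2 u_eff(R_c, R_c) sum_i q_i sum_{r_ij < R_c, j != i} q_j`:
#' the constant boundary component summed over all pairs inside the cutoff
#' sphere. It contributes no force. Uses the direct all-pairs double loop
#' (with `R_c` close to `L/2` nearly every pair is a neighbor, so a cell
#' list would not help).
#'
#' @param sys a [charge_system()].
#' @param sp a [split_potential()]; requires `R_c <= min(box)/2`.
#' @return scalar energy `U_B`.
#' @export
boundary_sum <- function(sys, sp) {
  stopifnot(inherits(sys, "charge_system"), inherits(sp, "split_potential"))
  if (sp$R_c > min(sys$box) / 2)
    stop("R_c exceeds half the shortest box edge", call. = FALSE)
  n <- nrow(sys$positions)
  if (n == 1) return(0)
  g <- pair_geometry(sys)
  mask <- g$r < sp$R_c & upper.tri(g$r)
  if (!any(mask)) return(0)
  q <- sys$charges
  qq <- outer(q, q)
  uB <- evaluate_lips(sp$base, sp$R_c, sp$R_c)
  sp$prefactor * uB * sum(qq[mask])
}

# ---------------------------------------------------------------------------
# Extended-XYZ I/O
#
# Dialect: line 1 = N; line 2 carries Lattice="Lx 0 0 0 Ly 0 0 0 Lz" and
# Properties=species:S:1:pos:R:3:charge:R:1[:vel:R:3]; data lines are
# symbol, x, y, z, q [, vx, vy, vz]. Only diagonal (orthorhombic) lattices
# are accepted.
# ---------------------------------------------------------------------------

#' Read periodic frames from an extended-XYZ file
#'
#' @param path file path.
#' @param timestep time between frames, attached when the file holds more
#'   than one frame.
#' @return A [charge_system()] for a single frame, or a [trajectory()] for a
#'   multi-frame file.
#' @export
read_xyz <- function(path, timestep = NA_real_) {
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) > 1 & lines == "" &
                     seq_along(lines) == length(lines))]
  frames <- list()
  pos <- 1L
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1) stop("malformed XYZ: bad particle count at line ",
                                pos, call. = FALSE)
    header <- lines[pos + 1L]
    lat <- regmatches(header, regexec('Lattice="([^"]+)"', header))[[1]]
    if (length(lat) < 2) stop("missing Lattice in XYZ header", call. = FALSE)
    lv <- as.numeric(strsplit(trimws(lat[2]), "\\s+")[[1]])
    if (length(lv) != 9) stop("Lattice must have 9 components", call. = FALSE)
    offdiag <- lv[-c(1, 5, 9)]
    if (any(offdiag != 0))
      stop("only orthorhombic (diagonal) lattices are supported",
           call. = FALSE)
    box <- lv[c(1, 5, 9)]
    props <- regmatches(header, regexec("Properties=(\\S+)", header))[[1]]
    has_vel <- length(props) >= 2 && grepl("vel:R:3", props[2])
    body <- lines[(pos + 2L):(pos + 1L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    ncols <- lengths(toks)
    want <- 5L + if (has_vel) 3L else 0L
    if (any(ncols < want)) stop("malformed XYZ data line", call. = FALSE)
    m <- t(vapply(toks, function(tk) as.numeric(tk[2:want]), numeric(want - 1)))
    species <- vapply(toks, `[`, "", 1L)
    frames[[length(frames) + 1L]] <- charge_system(
      positions = m[, 1:3, drop = FALSE], charges = m[, 4],
      box = box,
      velocities = if (has_vel) m[, 5:7, drop = FALSE] else NULL,
      species = species)
    pos <- pos + 2L + n
  }
  if (!length(frames)) stop("empty XYZ file", call. = FALSE)
  if (length(frames) == 1) frames[[1]] else trajectory(frames, timestep)
}

format_xyz_frame <- function(sys) {
  n <- nrow(sys$positions)
  has_vel <- !is.null(sys$velocities)
  props <- paste0("Properties=species:S:1:pos:R:3:charge:R:1",
                  if (has_vel) ":vel:R:3" else "")
  header <- sprintf('Lattice="%.17g 0 0 0 %.17g 0 0 0 %.17g" %s',
                    sys$box[1], sys$box[2], sys$box[3], props)
  dat <- cbind(sys$positions, sys$charges,
               if (has_vel) sys$velocities else NULL)
  body <- vapply(seq_len(n), function(i)
    paste(sys$species[i], paste(sprintf("%.17g", dat[i, ]), collapse = " ")),
    "")
  c(as.character(n), header, body)
}

#' Write a system or trajectory to an extended-XYZ file
#'
#' @param x a [charge_system()] or [trajectory()].
#' @param path output file path.
#' @export
write_xyz <- function(x, path) {
  if (inherits(x, "charge_system")) {
    writeLines(format_xyz_frame(x), path)
  } else if (inherits(x, "trajectory")) {
    writeLines(unlist(lapply(x$frames, format_xyz_frame)), path)
  } else stop("x must be a charge_system or trajectory", call. = FALSE)
  invisible(path)
}
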