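# ---------------------------------------------------------------------------
# Grid specification
# ---------------------------------------------------------------------------

#' Grid specification
#'
#' A rectangular lattice: `origin` (Angstrom), uniform `spacing` (Angstrom)
#' and per-axis point `counts`. Points are enumerated x-fastest (x varies
#' quickest, then y, then z), indexed from 1 — descriptor `S_i`/`E_i` refers
#' to grid point `i` in this order.
#'
#' @param origin numeric length-3 vector.
#' @param spacing positive scalar.
#' @param counts integer length-3 vector, each >= 1.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(origin, spacing, counts) {
  origin <- as.numeric(origin)
  counts <- as.integer(counts)
  stopifnot(length(origin) == 3L, length(counts) == 3L,
            is.finite(spacing), spacing > 0, all(counts >= 1L))
  structure(list(origin = origin, spacing = as.numeric(spacing),
                 counts = counts),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> origin (%.3f, %.3f, %.3f) A, spacing %.3f A, counts %d x %d x %d = %d points\n",
              x$origin[1], x$origin[2], x$origin[3], x$spacing,
              x$counts[1], x$counts[2], x$counts[3], n_grid_points(x)))
  invisible(x)
}

#' Number of points in a grid
#' @param grid a `grid_spec`.
#' @return integer point count.
#' @export
n_grid_points <- function(grid) prod(grid$counts)

#' Grid point coordinates
#'
#' @param grid a `grid_spec`.
#' @return an `n x 3` matrix of point coordinates in x-fastest order.
#' @export
grid_points <- function(grid) {
  ax <- lapply(1:3, function(d)
    grid$origin[d] + grid$spacing * (seq_len(grid$counts[d]) - 1L))
  pts <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                     KEEP.OUT.ATTRS = FALSE)
  as.matrix(pts)
}

#' Build the grid enclosing a set of aligned molecules
#'
#' The grid spans the joint bounding box of all atoms extended by `margin` on
#' every side; the span endpoint is included, so per-axis counts are
#' `floor(span / spacing) + 1`.
#'
#' @param molecules list of `molecule` objects (already aligned).
#' @param spacing lattice spacing, Angstrom (default 2).
#' @param margin box extension, Angstrom (default 4).
#' @return a `grid_spec`.
#' @export
build_grid <- function(molecules, spacing = 2, margin = 4) {
  stopifnot(length(molecules) >= 1L, spacing > 0, margin >= 0)
  allxyz <- do.call(rbind, lapply(molecules, coords))
  lo <- apply(allxyz, 2, min) - margin
  hi <- apply(allxyz, 2, max) + margin
  counts <- floor((hi - lo) / spacing + 1e-9) + 1L
  grid_spec(origin = lo, spacing = spacing, counts = counts)
}

# ---------------------------------------------------------------------------
# Probe
# ---------------------------------------------------------------------------

#' Probe atom specification
#'
#' Defaults are the conventional CoMFA probe: an sp3 carbon (rmin 1.70 A,
#' epsilon 0.107 kcal/mol) carrying a +1 elementary charge.
#'
#' @param rmin probe Lennard-Jones radius contribution, Angstrom.
#' @param epsilon probe well depth, kcal/mol.
#' @param charge probe charge, elementary charges.
#' @return object of class `probe_spec`.
#' @export
probe_spec <- function(rmin = 1.70, epsilon = 0.107, charge = 1.0) {
  stopifnot(rmin > 0, epsilon >= 0, is.finite(charge))
  structure(list(rmin = rmin, epsilon = epsilon, charge = charge),
            class = "probe_spec")
}

# Coulomb conversion, kcal mol^-1 A e^-2
COULOMB_K <- 332.0636

# squared distances from every grid point to every atom: n_points x n_atoms
point_atom_dist <- function(grid, mol) {
  P <- grid_points(grid)
  A <- coords(mol)
  d2 <- outer(rowSums(P^2), rowSums(A^2), "+") - 2 * tcrossprod(P, A)
  sqrt(pmax(d2, 0))
}

#' Steric (Lennard-Jones) probe field
#'
#' At each grid point p the probe-molecule van der Waals energy
#' `E_S(p) = sum_atoms eps_ij * ((R_ij / r)^12 - 2 (R_ij / r)^6)` with
#' `eps_ij = sqrt(eps_atom * eps_probe)` and `R_ij = rmin_atom + rmin_probe`
#' (the pairwise LJ-minimum distance). Values are clamped from above at
#' `cutoff`; a grid point coinciding with an atom position contributes the
#' cutoff, never a division error.
#'
#' @param mol aligned `molecule` with vdW parameters assigned.
#' @param grid `grid_spec`.
#' @param probe `probe_spec`.
#' @param cutoff truncation bound, kcal/mol (default +30).
#' @return numeric vector, one steric energy per grid point.
#' @export
steric_field <- function(mol, grid, probe = probe_spec(), cutoff = 30) {
  if (anyNA(mol$atoms$rmin) || anyNA(mol$atoms$epsilon))
    stop("molecule '", mol$id, "' lacks vdW parameters; run assign_vdw()")
  r <- point_atom_dist(grid, mol)
  Rij <- mol$atoms$rmin + probe$rmin
  eps <- sqrt(mol$atoms$epsilon * probe$epsilon)
  # per-atom LJ term; guard r = 0 (value will exceed any finite cutoff)
  rr <- sweep(1 / pmax(r, 1e-12), 2, Rij, "*")  # R_ij / r
  e <- sweep(rr^12 - 2 * rr^6, 2, eps, "*")
  pmin(rowSums(e), cutoff)
}

#' Electrostatic (Coulomb) probe field
#'
#' At each grid point `E_E(p) = sum_atoms k q_atom q_probe / (D(r) r)` in
#' kcal/mol with `k = 332.0636`; the dielectric is either constant
#' (`D(r) = d0`) or distance-dependent (`D(r) = d0 * r`). Values are clamped
#' to `[-cutoff, +cutoff]`; `r = 0` contributes the (signed) cutoff.
#'
#' @param mol aligned `molecule` with partial charges.
#' @param grid `grid_spec`.
#' @param probe `probe_spec`.
#' @param dielectric `"constant"` or `"distance"`.
#' @param d0 dielectric constant prefactor (default 1).
#' @param cutoff truncation bound, kcal/mol (default 30).
#' @return numeric vector, one electrostatic energy per grid point.
#' @export
electrostatic_field <- function(mol, grid, probe = probe_spec(),
                                dielectric = c("constant", "distance"),
                                d0 = 1, cutoff = 30) {
  dielectric <- match.arg(dielectric)
  if (anyNA(mol$atoms$charge))
    stop("molecule '", mol$id, "' lacks partial charges")
  r <- pmax(point_atom_dist(grid, mol), 1e-12)
  denom <- if (dielectric == "constant") d0 * r else d0 * r^2
  e <- sweep(COULOMB_K / denom, 2, mol$atoms$charge * probe$charge, "*")
  pmin(pmax(rowSums(e), -cutoff), cutoff)
}
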