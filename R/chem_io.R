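# ---------------------------------------------------------------------------
# Molecule container
# ---------------------------------------------------------------------------

#' Construct a molecule
#'
#' A molecule is an identifier plus an ordered atom table (element, Cartesian
#' coordinates in Angstrom, partial charge in elementary charges, and
#' Lennard-Jones parameters `rmin` (Angstrom) and `epsilon` (kcal/mol)) and an
#' optional bond table. Bonds are only needed by the fallback charge
#' assignment; the field engine works from atoms alone.
#'
#' @param id compound identifier (length-1 character).
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` and
#'   optionally `charge`, `rmin`, `epsilon`.
#' @param bonds optional data.frame with columns `from`, `to`, `order`
#'   (1-based atom indices).
#' @return an object of class `molecule`.
#' @export
molecule <- function(id, atoms, bonds = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  atoms <- as.data.frame(atoms)
  req <- c("element", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) < 1L) stop("molecule '", id, "' has no atoms")
  for (col in c("charge", "rmin", "epsilon"))
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in molecule '", id, "'")
  if (!is.null(bonds)) {
    bonds <- as.data.frame(bonds)
    stopifnot(all(c("from", "to", "order") %in% names(bonds)))
  }
  structure(list(id = id, atoms = atoms, bonds = bonds), class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule>", x$id, "-", nrow(x$atoms), "atoms")
  if (!is.null(x$bonds)) cat(",", nrow(x$bonds), "bonds")
  rmsd <- attr(x, "alignment_rmsd")
  if (!is.null(rmsd)) cat(sprintf(", aligned (RMSD %.4g A)", rmsd))
  cat("\n")
  invisible(x)
}

#' Atom coordinates as a matrix
#' @param mol a `molecule`.
#' @return numeric n x 3 matrix.
#' @export
coords <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

# ---------------------------------------------------------------------------
# van der Waals parameter table
# ---------------------------------------------------------------------------

#' Packaged element -> Lennard-Jones parameter table
#'
#' Tripos-5.2-like per-element radii (`rmin`, the probe-atom optimal
#' separation contribution, Angstrom) and well depths (`epsilon`, kcal/mol).
#' Override by passing your own data.frame with the same columns to
#' [read_sdf()] or [assign_vdw()].
#'
#' @return data.frame with columns `element`, `rmin`, `epsilon`.
#' @export
default_vdw_table <- function() {
  path <- system.file("extdata", "vdw_params.csv", package = "gridqsar",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Assign van der Waals parameters to a molecule's atoms
#'
#' @param mol a `molecule`.
#' @param vdw_table data.frame `element,rmin,epsilon`.
#' @return the molecule with `rmin`/`epsilon` columns filled.
#' @export
assign_vdw <- function(mol, vdw_table = default_vdw_table()) {
  idx <- match(mol$atoms$element, vdw_table$element)
  if (anyNA(idx)) {
    bad <- unique(mol$atoms$element[is.na(idx)])
    stop("no vdW parameters for ", paste(bad, collapse = ", "))
  }
  mol$atoms$rmin <- vdw_table$rmin[idx]
  mol$atoms$epsilon <- vdw_table$epsilon[idx]
  mol
}

# ---------------------------------------------------------------------------
# SDF (V2000) reading and writing
# ---------------------------------------------------------------------------

parse_sdf_record <- function(lines, record_index, charge_prop) {
  if (length(lines) < 4L)
    stop("SDF record ", record_index, ": truncated header")
  id <- trimws(lines[1L])
  counts <- lines[4L]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(n_atoms) || is.na(n_bonds))
    stop("SDF record ", record_index, ": unparseable counts line")
  if (length(lines) < 4L + n_atoms + n_bonds)
    stop("SDF record ", record_index, ": atom/bond block shorter than counts")
  atom_lines <- lines[5L:(4L + n_atoms)]
  x <- as.numeric(substr(atom_lines, 1L, 10L))
  y <- as.numeric(substr(atom_lines, 11L, 20L))
  z <- as.numeric(substr(atom_lines, 21L, 30L))
  element <- trimws(substr(atom_lines, 31L, 34L))
  if (anyNA(x) || anyNA(y) || anyNA(z) || any(!nzchar(element)))
    stop("SDF record ", record_index, ": malformed atom block")
  bonds <- NULL
  if (n_bonds > 0L) {
    bond_lines <- lines[(5L + n_atoms):(4L + n_atoms + n_bonds)]
    bonds <- data.frame(
      from  = as.integer(substr(bond_lines, 1L, 3L)),
      to    = as.integer(substr(bond_lines, 4L, 6L)),
      order = as.integer(substr(bond_lines, 7L, 9L)))
    if (anyNA(bonds))
      stop("SDF record ", record_index, ": malformed bond block")
  }
  # data fields:  "> <NAME>" followed by value lines up to a blank line
  props <- list()
  tag_lines <- grep("^>", lines)
  for (ti in tag_lines) {
    name <- sub(".*<([^>]+)>.*", "\\1", lines[ti])
    vals <- character()
    j <- ti + 1L
    while (j <= length(lines) && nzchar(trimws(lines[j]))) {
      vals <- c(vals, lines[j])
      j <- j + 1L
    }
    props[[name]] <- vals
  }
  charge <- rep(NA_real_, n_atoms)
  if (!is.null(props[[charge_prop]])) {
    vals <- suppressWarnings(as.numeric(unlist(
      strsplit(trimws(props[[charge_prop]]), "[[:space:],]+"))))
    if (length(vals) != n_atoms || anyNA(vals))
      stop("SDF record ", record_index, ": property '", charge_prop,
           "' does not hold one numeric charge per atom")
    charge <- vals
  }
  if (!nzchar(id)) id <- paste0("mol_", record_index)
  molecule(id,
           data.frame(element = element, x = x, y = y, z = z,
                      charge = charge),
           bonds = bonds)
}

#' Read molecules from an SDF/MOL file (V2000)
#'
#' Partial charges are taken from the SDF data field named by `charge_prop`
#' (one numeric value per atom, whitespace- or newline-separated) when
#' present; otherwise Gasteiger-type charges are computed via
#' [gasteiger_charges()]. Lennard-Jones parameters are filled from
#' `vdw_table`.
#'
#' @param path SDF or MOL file.
#' @param charge_prop name of the SDF data field holding per-atom charges.
#' @param vdw_table element parameter table (see [default_vdw_table()]).
#' @return list of `molecule` objects (possibly empty, with a warning).
#' @export
read_sdf <- function(path, charge_prop = "PARTIAL_CHARGES",
                     vdw_table = default_vdw_table()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(trimws(lines)))) {
    warning("empty SDF file: ", path)
    return(list())
  }
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) ends <- length(lines)  # bare MOL file
  starts <- c(1L, head(ends, -1L) + 1L)
  mols <- vector("list", length(starts))
  ids <- character(length(starts))
  for (k in seq_along(starts)) {
    rec <- lines[starts[k]:ends[k]]
    rec <- rec[!grepl("^\\$\\$\\$\\$", rec)]
    if (!any(nzchar(trimws(rec)))) next
    mol <- parse_sdf_record(rec, k, charge_prop)
    mol <- assign_vdw(mol, vdw_table)
    if (anyNA(mol$atoms$charge)) mol <- gasteiger_charges(mol)
    mols[[k]] <- mol
    ids[k] <- mol$id
  }
  mols <- Filter(Negate(is.null), mols)
  ids <- vapply(mols, function(m) m$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate compound ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mols
}

#' Write molecules to an SDF file (V2000)
#'
#' Partial charges are stored in a `PARTIAL_CHARGES` data field so that a
#' read/write round trip is lossless for the quantities the field engine
#' uses.
#'
#' @param mols list of `molecule` objects.
#' @param path output path.
#' @param charge_prop data field name for charges.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path, charge_prop = "PARTIAL_CHARGES") {
  out <- character()
  for (mol in mols) {
    a <- mol$atoms
    nb <- if (is.null(mol$bonds)) 0L else nrow(mol$bonds)
    rec <- c(mol$id, "  gridqsar", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(a), nb),
             sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     a$x, a$y, a$z, a$element))
    if (nb > 0L)
      rec <- c(rec, sprintf("%3d%3d%3d  0  0  0  0",
                            mol$bonds$from, mol$bonds$to, mol$bonds$order))
    rec <- c(rec, "M  END")
    if (!anyNA(a$charge))
      rec <- c(rec, paste0(">  <", charge_prop, ">"),
               paste(sprintf("%.6f", a$charge), collapse = " "), "")
    out <- c(out, rec, "$$$$")
  }
  writeLines(out, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Activities
# ---------------------------------------------------------------------------

#' Convert an IC50 to pIC50
#'
#' pIC50 is the negative base-10 logarithm of the molar IC50.
#'
#' @param ic50_value positive concentration value.
#' @param unit one of `"M"`, `"mM"`, `"uM"`, `"nM"` (`"µM"` accepted).
#' @return pIC50 (dimensionless).
#' @export
to_pic50 <- function(ic50_value, unit = c("M", "mM", "uM", "nM")) {
  if (identical(unit, "µM")) unit <- "uM"
  unit <- match.arg(unit)
  if (any(!is.finite(ic50_value)) || any(ic50_value <= 0))
    stop("IC50 must be positive and finite")
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)[[unit]]
  -log10(ic50_value * scale)
}

#' Read an activity table
#'
#' Accepts `compound_id,pIC50` directly, or `compound_id,value,unit` which is
#' converted through [to_pic50()].
#'
#' @param path CSV file.
#' @return data.frame with columns `compound_id`, `pIC50`.
#' @export
read_activities <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("compound_id", "pIC50") %in% names(df))) {
    out <- df[, c("compound_id", "pIC50")]
  } else if (all(c("compound_id", "value", "unit") %in% names(df))) {
    out <- data.frame(
      compound_id = df$compound_id,
      pIC50 = vapply(seq_len(nrow(df)),
                     function(i) to_pic50(df$value[i], df$unit[i]),
                     numeric(1)))
  } else {
    stop("activity CSV must have columns compound_id,pIC50 or ",
         "compound_id,value,unit")
  }
  if (anyDuplicated(out$compound_id))
    stop("duplicate compound ids in activity table")
  if (any(!is.finite(out$pIC50))) stop("non-finite pIC50 values")
  out
}

# ---------------------------------------------------------------------------
# Gasteiger-type partial charges (PEOE fallback)
# ---------------------------------------------------------------------------

# Electronegativity polynomial coefficients (a + b q + c q^2) by element and
# hybridisation. Values follow the classic iterative partial-equalisation
# parameterisation for common organic elements.
peoe_params <- function(element, hyb) {
  key <- paste0(element, ".", hyb)
  tab <- c(
    "H.sp3"  = "7.17,6.24,-0.56",
    "C.sp3"  = "7.98,9.18,1.88",
    "C.sp2"  = "8.79,9.32,1.51",
    "C.sp"   = "10.39,9.45,0.73",
    "N.sp3"  = "11.54,10.82,1.36",
    "N.sp2"  = "12.87,11.15,0.85",
    "N.sp"   = "15.68,11.70,-0.27",
    "O.sp3"  = "14.18,12.92,1.39",
    "O.sp2"  = "17.07,13.79,0.47",
    "F.sp3"  = "14.66,13.85,2.31",
    "Cl.sp3" = "11.00,9.69,1.35",
    "Br.sp3" = "10.08,8.47,1.16",
    "I.sp3"  = "9.90,7.96,0.96",
    "S.sp3"  = "10.14,9.13,1.38",
    "S.sp2"  = "10.88,9.49,1.33",
    "P.sp3"  = "8.90,8.24,0.96",
    "B.sp3"  = "5.98,6.82,1.60",
    "Si.sp3" = "7.30,6.57,0.66")
  res <- tab[key]
  # unknown element/hybridisation: fall back to sp3 entry, then to carbon
  res[is.na(res)] <- tab[paste0(element[is.na(res)], ".sp3")]
  res[is.na(res)] <- tab["C.sp3"]
  do.call(rbind, lapply(strsplit(unname(res), ","), as.numeric))
}

#' Gasteiger-type partial charges
#'
#' Iterative partial equalisation of orbital electronegativity (PEOE) using
#' per-element polynomial electronegativities, hybridisation inferred from
#' bond orders, damping factor 0.5 per iteration. This is the delegated
#' fallback used when no charges are supplied with the structures; it targets
#' the qualitative charge pattern, not any specific published charge set.
#'
#' @param mol a `molecule` with a bond table; a molecule without bonds gets
#'   all-zero charges (with a warning).
#' @param n_iter number of equalisation iterations.
#' @return the molecule with the `charge` column filled.
#' @export
gasteiger_charges <- function(mol, n_iter = 8L) {
  n <- nrow(mol$atoms)
  if (is.null(mol$bonds) || nrow(mol$bonds) == 0L) {
    warning("molecule '", mol$id,
            "' has no bond table; assigning zero charges")
    mol$atoms$charge <- rep(0, n)
    return(mol)
  }
  hyb <- rep("sp3", n)
  for (b in seq_len(nrow(mol$bonds))) {
    o <- mol$bonds$order[b]
    if (o >= 3L) {
      hyb[c(mol$bonds$from[b], mol$bonds$to[b])] <- "sp"
    } else if (o == 2L) {
      for (at in c(mol$bonds$from[b], mol$bonds$to[b]))
        if (hyb[at] == "sp3") hyb[at] <- "sp2"
    }
  }
  par <- peoe_params(mol$atoms$element, hyb)
  a <- par[, 1]; b2 <- par[, 2]; c3 <- par[, 3]
  chi_plus <- a + b2 + c3           # cation electronegativity
  chi_plus[mol$atoms$element == "H"] <- 20.02
  q <- rep(0, n)
  nbr <- cbind(mol$bonds$from, mol$bonds$to)
  for (it in seq_len(n_iter)) {
    chi <- a + b2 * q + c3 * q^2
    damp <- 0.5^it
    dq <- rep(0, n)
    for (bidx in seq_len(nrow(nbr))) {
      i <- nbr[bidx, 1]; j <- nbr[bidx, 2]
      if (chi[i] == chi[j]) next
      lo <- if (chi[i] < chi[j]) i else j
      hi <- if (chi[i] < chi[j]) j else i
      transfer <- (chi[hi] - chi[lo]) / chi_plus[lo] * damp
      dq[lo] <- dq[lo] + transfer
      dq[hi] <- dq[hi] - transfer
    }
    q <- q + dq
  }
  mol$atoms$charge <- q
  mol
}

# ---------------------------------------------------------------------------
# Template alignment (Kabsch)
# ---------------------------------------------------------------------------

#' Construct a template map
#'
#' Maps atoms of a molecule onto atoms of a reference (template) molecule for
#' rigid least-squares alignment. Both index vectors must have the same
#' length (>= 3), be injective, and refer to non-collinear atoms.
#'
#' @param reference_atoms integer indices into the reference molecule.
#' @param mol_atoms integer indices into the molecule being aligned; defaults
#'   to `reference_atoms` (shared scaffold numbering).
#' @return object of class `template_map`.
#' @export
template_map <- function(reference_atoms, mol_atoms = reference_atoms) {
  reference_atoms <- as.integer(reference_atoms)
  mol_atoms <- as.integer(mol_atoms)
  if (length(reference_atoms) != length(mol_atoms))
    stop("reference and molecule index vectors differ in length")
  if (length(reference_atoms) < 3L)
    stop("template map needs at least 3 atoms")
  if (anyDuplicated(reference_atoms) || anyDuplicated(mol_atoms))
    stop("template map must be injective")
  structure(list(reference_atoms = reference_atoms, mol_atoms = mol_atoms),
            class = "template_map")
}

#' Rigidly align a molecule onto a reference template
#'
#' Least-squares superposition (Kabsch, via SVD) of the mapped atoms; the
#' whole molecule is transformed with the fitted rotation + translation, so
#' intramolecular geometry is untouched. The residual RMSD over mapped atoms
#' is attached as attribute `alignment_rmsd`.
#'
#' @param mol `molecule` to align.
#' @param reference `molecule` providing the template frame.
#' @param map a `template_map`.
#' @return the transformed molecule with attributes `alignment_rmsd` and
#'   `rotation` (the fitted 3x3 matrix).
#' @export
align_to_template <- function(mol, reference, map) {
  stopifnot(inherits(map, "template_map"))
  P <- coords(mol)[map$mol_atoms, , drop = FALSE]
  Q <- coords(reference)[map$reference_atoms, , drop = FALSE]
  if (nrow(P) < 3L) stop("template map needs at least 3 atoms")
  Pc <- colMeans(P); Qc <- colMeans(Q)
  P0 <- sweep(P, 2, Pc); Q0 <- sweep(Q, 2, Qc)
  # collinearity check: rank of centred coordinates must be >= 2
  if (sum(svd(P0)$d > 1e-8 * max(1, max(abs(P0)))) < 2L ||
      sum(svd(Q0)$d > 1e-8 * max(1, max(abs(Q0)))) < 2L)
    stop("mapped atoms are collinear or degenerate; cannot align")
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  X <- coords(mol)
  Xnew <- sweep(sweep(X, 2, Pc) %*% t(R), 2, Qc, "+")
  out <- mol
  out$atoms$x <- Xnew[, 1]; out$atoms$y <- Xnew[, 2]; out$atoms$z <- Xnew[, 3]
  fitted <- sweep(P0 %*% t(R), 2, Qc, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  attr(out, "alignment_rmsd") <- rmsd
  attr(out, "rotation") <- R
  out
}
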