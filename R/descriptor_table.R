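# ---------------------------------------------------------------------------
# Compound x descriptor matrix
# ---------------------------------------------------------------------------

#' Assemble the compound x grid-field descriptor matrix
#'
#' One row per molecule; columns are all steric descriptors
#' (`S_1 ... S_n`), then all electrostatic descriptors (`E_1 ... E_n`), in
#' grid-point order (x-fastest, 1-based), so the column count is exactly
#' twice the grid point count. The grid, probe and dielectric settings are
#' attached as attributes along with a provenance hash so that matrices from
#' different grids can never be mixed silently.
#'
#' Molecules are expected to be pre-aligned; a molecule carrying no
#' `alignment_rmsd` attribute triggers a warning (synthetic series built
#' aligned by construction can set it explicitly).
#'
#' @param molecules list of `molecule` objects.
#' @param grid `grid_spec`; built from the molecules via [build_grid()] when
#'   `NULL`.
#' @param probe `probe_spec`.
#' @param dielectric,d0 electrostatic dielectric model (see
#'   [electrostatic_field()]).
#' @param steric_cutoff,elec_cutoff truncation bounds, kcal/mol.
#' @param check_alignment warn when a molecule has no alignment provenance.
#' @return numeric matrix with compound-id rownames, descriptor colnames,
#'   and attributes `grid`, `probe`, `grid_hash`.
#' @export
assemble_descriptors <- function(molecules, grid = NULL,
                                 probe = probe_spec(),
                                 dielectric = "constant", d0 = 1,
                                 steric_cutoff = 30, elec_cutoff = 30,
                                 check_alignment = TRUE) {
  stopifnot(length(molecules) >= 1L)
  if (is.null(grid)) grid <- build_grid(molecules)
  ids <- vapply(molecules, function(m) m$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate compound ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (check_alignment) {
    unaligned <- vapply(molecules,
                        function(m) is.null(attr(m, "alignment_rmsd")),
                        logical(1))
    if (any(unaligned))
      warning("molecule(s) without alignment provenance: ",
              paste(ids[unaligned], collapse = ", "))
  }
  np <- n_grid_points(grid)
  M <- matrix(NA_real_, nrow = length(molecules), ncol = 2L * np,
              dimnames = list(ids, c(paste0("S_", seq_len(np)),
                                     paste0("E_", seq_len(np)))))
  for (i in seq_along(molecules)) {
    M[i, seq_len(np)] <- steric_field(molecules[[i]], grid, probe,
                                      cutoff = steric_cutoff)
    M[i, np + seq_len(np)] <- electrostatic_field(molecules[[i]], grid,
                                                  probe, dielectric, d0,
                                                  cutoff = elec_cutoff)
  }
  attr(M, "grid") <- grid
  attr(M, "probe") <- probe
  attr(M, "grid_hash") <- grid_hash(grid, probe, dielectric, d0)
  M
}

#' Provenance hash for a grid + probe combination
#'
#' Descriptors are only comparable across datasets when they come from the
#' same lattice and probe; this hash stamps matrices and models so a
#' mismatch is detected instead of producing meaningless predictions.
#'
#' @param grid `grid_spec`.
#' @param probe `probe_spec`.
#' @param dielectric,d0 dielectric settings.
#' @return character hash.
#' @export
grid_hash <- function(grid, probe = probe_spec(), dielectric = "constant",
                      d0 = 1) {
  digest::digest(list(origin = round(grid$origin, 6), spacing = grid$spacing,
                      counts = grid$counts, probe = unclass(probe),
                      dielectric = dielectric, d0 = d0))
}

#' Remove invariable descriptor columns
#'
#' Drops every column whose value range (max minus min) is at most `tol`,
#' preserving the order of the survivors. The count removed is reported via
#' `message()`.
#'
#' @param matrix compound x descriptor matrix.
#' @param tol absolute range threshold, kcal/mol (default `1e-8`:
#'   exact-constant removal).
#' @return the filtered matrix (attributes preserved).
#' @export
drop_invariable <- function(matrix, tol = 1e-8) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 1L, ncol(matrix) >= 1L)
  rng <- apply(matrix, 2, function(col) max(col) - min(col))
  keep <- rng > tol
  if (!any(keep)) stop("no variable descriptors remain")
  message("drop_invariable: removed ", sum(!keep), " of ", ncol(matrix),
          " descriptors (", sum(keep), " remain)")
  out <- matrix[, keep, drop = FALSE]
  for (at in c("grid", "probe", "grid_hash"))
    attr(out, at) <- attr(matrix, at)
  out
}

#' Write a descriptor matrix to CSV (plus grid sidecar)
#'
#' The matrix goes to `path` as a wide CSV (first column `compound_id`);
#' grid/probe provenance goes to `<path>.json`.
#'
#' @param matrix descriptor matrix from [assemble_descriptors()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(matrix, path) {
  df <- data.frame(compound_id = rownames(matrix), matrix,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  grid <- attr(matrix, "grid")
  probe <- attr(matrix, "probe")
  meta <- list(grid = if (!is.null(grid)) unclass(grid),
               probe = if (!is.null(probe)) unclass(probe),
               grid_hash = attr(matrix, "grid_hash"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a descriptor matrix written by [write_descriptors()]
#'
#' @param path CSV path; the `<path>.json` sidecar is restored when present.
#' @return descriptor matrix with provenance attributes.
#' @export
read_descriptors <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- as.character(df[[1]])
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$grid))
      attr(M, "grid") <- grid_spec(meta$grid$origin, meta$grid$spacing,
                                   meta$grid$counts)
    if (!is.null(meta$probe))
      attr(M, "probe") <- probe_spec(meta$probe$rmin, meta$probe$epsilon,
                                     meta$probe$charge)
    attr(M, "grid_hash") <- meta$grid_hash
  }
  M
}
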