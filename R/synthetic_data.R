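# ---------------------------------------------------------------------------
# Synthetic congeneric series and planted-truth datasets
# ---------------------------------------------------------------------------

# rigid 10-atom scaffold: two fused five-membered rings in the xy plane,
# a stand-in for a shared bicyclic (pyrazoline + thiazole) core
scaffold_atoms <- function() {
  ring1 <- cbind(1.2 * cos(2 * pi * (0:4) / 5),
                 1.2 * sin(2 * pi * (0:4) / 5), 0)
  ring2 <- cbind(2.4 + 1.2 * cos(2 * pi * (0:4) / 5 + pi / 5),
                 1.2 * sin(2 * pi * (0:4) / 5 + pi / 5), 0)
  xyz <- rbind(ring1, ring2)
  data.frame(element = c("C", "C", "N", "N", "C", "C", "S", "C", "C", "C"),
             x = round(xyz[, 1], 4), y = round(xyz[, 2], 4),
             z = round(xyz[, 3], 4),
             charge = c(0.05, 0.05, -0.30, -0.25, 0.10,
                        0.05, -0.15, 0.10, 0.05, 0.10))
}

# substituent attachment points and directions off the scaffold
substituent_sites <- function() {
  list(list(origin = c(-1.8, 0.0, 0.0), dir = c(-1, 0, 0)),
       list(origin = c(3.6, 1.2, 0.0), dir = c(1, 0.3, 0)),
       list(origin = c(1.2, -1.8, 0.0), dir = c(0, -1, 0.3)))
}

#' Generate a synthetic congeneric series
#'
#' A rigid shared scaffold (10 atoms, fixed coordinates) decorated with
#' 1-3 substituent atoms per compound at seeded positions, elements and
#' partial charges — the geometry/chemistry stand-in for a real congeneric
#' inhibitor series. All molecules share the scaffold coordinates exactly,
#' so the series is pre-aligned by construction (alignment RMSD 0 over the
#' scaffold); vdW parameters are populated from the packaged table.
#'
#' @param n_compounds number of molecules (>= 2).
#' @param seed RNG seed; output is fully determined by it.
#' @return list with `molecules` (list of `molecule`), `template_map` (the
#'   scaffold-atom map) and `reference` (the first molecule).
#' @export
make_series <- function(n_compounds, seed) {
  stopifnot(n_compounds >= 2)
  set.seed(seed)
  core <- scaffold_atoms()
  sites <- substituent_sites()
  sub_elements <- c("C", "N", "O", "F", "Cl")
  mols <- vector("list", n_compounds)
  for (i in seq_len(n_compounds)) {
    n_sub <- sample(1:3, 1)
    picked <- sample(seq_along(sites), n_sub)
    subs <- do.call(rbind, lapply(sites[picked], function(s) {
      stretch <- stats::runif(1, 1.2, 2.6)
      jitter <- stats::rnorm(3, 0, 0.25)
      pos <- s$origin + stretch * s$dir / sqrt(sum(s$dir^2)) + jitter
      data.frame(element = sample(sub_elements, 1),
                 x = pos[1], y = pos[2], z = pos[3],
                 charge = stats::runif(1, -0.4, 0.4))
    }))
    mol <- molecule(sprintf("cpd_%02d", i), rbind(core, subs))
    mol <- assign_vdw(mol)
    attr(mol, "alignment_rmsd") <- 0  # aligned by construction
    mols[[i]] <- mol
  }
  list(molecules = mols,
       template_map = template_map(seq_len(nrow(core))),
       reference = mols[[1]])
}

#' Planted-truth descriptor/activity dataset
#'
#' Generates a compound x descriptor matrix with the structural features a
#' real grid-field matrix has — a fraction of exactly-constant columns (the
#' "invariable descriptors" the filter removes) and correlated column
#' blocks (neighbouring grid points; pairwise r about 0.9) — plus
#' activities that follow a sparse linear model on `k_informative` columns
#' with homoscedastic Gaussian noise. Defaults mirror the modelled series:
#' 38 compounds, 3268 descriptors of which 105 are constant, 6 informative
#' descriptors, and an effect-to-noise ratio giving fits around r2 0.95.
#'
#' @param n_compounds rows (default 38).
#' @param n_descriptors columns (default 3268).
#' @param k_informative number of truly active descriptors (default 6).
#' @param coefficient_scale magnitude scale of the planted coefficients
#'   (default 0.5; actual betas are `+-scale * U(0.5, 1.5)`).
#' @param noise_sd activity noise standard deviation, pIC50 units
#'   (default 0.2).
#' @param constant_fraction fraction of exactly-constant columns
#'   (default 105/3268).
#' @param correlated_fraction fraction of variable columns arranged in
#'   correlated triplets (default 0.1).
#' @param intercept true intercept (default 5, a typical pIC50 baseline).
#' @param seed RNG seed.
#' @return list with `matrix`, `activities` (data.frame
#'   `compound_id,pIC50`) and `truth` (class `planted_truth`: informative
#'   names, true betas, intercept, noise sd, seed).
#' @export
make_planted_dataset <- function(n_compounds = 38, n_descriptors = 3268,
                                 k_informative = 6, coefficient_scale = 0.5,
                                 noise_sd = 0.2,
                                 constant_fraction = 105 / 3268,
                                 correlated_fraction = 0.1,
                                 intercept = 5, seed) {
  stopifnot(k_informative < n_descriptors,
            n_compounds > k_informative + 2)
  set.seed(seed)
  n <- n_compounds
  p <- n_descriptors
  m1 <- ceiling(p / 2)
  cn <- c(paste0("S_", seq_len(m1)), paste0("E_", seq_len(p - m1)))
  ids <- sprintf("cpd_%02d", seq_len(n))
  M <- matrix(stats::rnorm(n * p), nrow = n, dimnames = list(ids, cn))
  # correlated triplets: two followers per leader, r ~ 0.9
  n_corr_lead <- floor(correlated_fraction * p / 3)
  if (n_corr_lead > 0) {
    leaders <- seq_len(n_corr_lead) * 3L
    for (l in leaders) {
      if (l + 2L > p) break
      for (f in c(l + 1L, l + 2L))
        M[, f] <- 0.9 * M[, l] + sqrt(1 - 0.9^2) * stats::rnorm(n)
    }
  }
  # exactly-constant columns
  n_const <- round(constant_fraction * p)
  const_cols <- integer(0)
  if (n_const > 0) {
    const_cols <- sample.int(p, n_const)
    M[, const_cols] <- rep(stats::rnorm(n_const), each = n)
  }
  variable_cols <- setdiff(seq_len(p), const_cols)
  informative <- sort(sample(variable_cols, k_informative))
  beta <- coefficient_scale * sample(c(-1, 1), k_informative, TRUE) *
    stats::runif(k_informative, 0.5, 1.5)
  y <- intercept + drop(M[, informative, drop = FALSE] %*% beta) +
    stats::rnorm(n, 0, noise_sd)
  truth <- structure(list(informative = cn[informative],
                          beta = stats::setNames(beta, cn[informative]),
                          intercept = intercept, noise_sd = noise_sd,
                          constant_columns = cn[const_cols],
                          seed = seed),
                     class = "planted_truth")
  list(matrix = M,
       activities = data.frame(compound_id = ids, pIC50 = y),
       truth = truth)
}

#' Selection-recovery score against a planted truth
#'
#' @param selected character vector of selected descriptor names.
#' @param truth a `planted_truth`.
#' @return list with `recall` (fraction of informative descriptors found)
#'   and `false_positives` (count of selected non-informative descriptors).
#' @export
recovery_score <- function(selected, truth) {
  stopifnot(inherits(truth, "planted_truth"))
  list(recall = length(intersect(selected, truth$informative)) /
         length(truth$informative),
       false_positives = length(setdiff(selected, truth$informative)))
}
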