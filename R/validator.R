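# ---------------------------------------------------------------------------
# Model robustness validation
# ---------------------------------------------------------------------------

# fit + score one (possibly label-shuffled) training set; test set keeps
# its true labels so pred_r2 nulls respect the external-validation contract
score_pipeline <- function(X, y, split, f_enter = 4, max_terms = NULL) {
  tr <- match(split$training_ids, rownames(X))
  te <- match(split$test_ids, rownames(X))
  Xtr <- X[tr, , drop = FALSE]
  ytr <- y[tr]
  model <- stepwise_forward(Xtr, ytr, f_enter = f_enter,
                            max_terms = max_terms)
  if (model$k == 0L) {
    q2 <- loo_q2(matrix(numeric(0), nrow = length(ytr), ncol = 0), ytr)
    r2v <- 0
    q2v <- q2$q2
  } else {
    r2v <- model$stats$r2
    q2v <- model$stats$q2
  }
  pr2 <- NA_real_
  if (length(te)) {
    pr2 <- pred_r2(model, X[te, , drop = FALSE], y[te])$pred_r2
  }
  list(model = model, r2 = r2v, q2 = q2v, pred_r2 = pr2)
}

#' Y-randomization robustness test
#'
#' Shuffles the activity labels over the TRAINING compounds (test labels
#' stay true), re-runs the full stepwise-forward selection and scoring for
#' each permutation, and locates the actual model's statistics within the
#' permutation null: `Z_s = (s_actual - mean(s_perm)) / sd(s_perm)` and the
#' empirical `p = (1 + #\{s_perm >= s_actual\}) / (1 + n_permutations)`.
#' Large Z (small p) means the real structure-activity signal stands far
#' above what chance selection achieves on scrambled labels.
#'
#' @param X full compound x descriptor matrix (rownames = ids).
#' @param y activity vector aligned with `rownames(X)`.
#' @param split a `split_result`.
#' @param f_enter,max_terms stepwise parameters (see [stepwise_forward()]).
#' @param n_permutations number of label shuffles (>= 2; default 100).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return object of class `randomization_report`: per-permutation
#'   statistics, Z-scores, normal-curve areas (percent) and empirical
#'   p-values for r2, q2 and (when a test set exists) pred_r2.
#' @export
y_randomization <- function(X, y, split, f_enter = 4, max_terms = NULL,
                            n_permutations = 100, seed) {
  stopifnot(n_permutations >= 2)
  if (missing(seed)) stop("a seed is required")
  actual <- score_pipeline(X, y, split, f_enter, max_terms)
  tr <- match(split$training_ids, rownames(X))
  perm <- matrix(NA_real_, nrow = n_permutations, ncol = 3,
                 dimnames = list(NULL, c("r2", "q2", "pred_r2")))
  set.seed(seed)
  for (b in seq_len(n_permutations)) {
    yb <- y
    yb[tr] <- y[tr][sample.int(length(tr))]
    sc <- score_pipeline(X, yb, split, f_enter, max_terms)
    perm[b, ] <- c(sc$r2, sc$q2, sc$pred_r2)
  }
  stats_names <- c("r2", "q2", if (length(split$test_ids)) "pred_r2")
  zs <- ps <- areas <- stats::setNames(numeric(length(stats_names)),
                                       stats_names)
  for (s in stats_names) {
    obs <- actual[[s]]
    if (is.na(obs))
      stop("actual ", s, " is undefined; cannot place it in a null")
    # permutations whose q2 is undefined (leverage-1 refits) drop out of
    # that statistic's null; the permutation count reflects the rest
    keep <- !is.na(perm[, s])
    mu <- mean(perm[keep, s]); sdv <- stats::sd(perm[keep, s])
    if (!is.finite(sdv) || sdv == 0) stop("degenerate null distribution")
    zs[s] <- (obs - mu) / sdv
    areas[s] <- normal_area(zs[s])
    ps[s] <- (1 + sum(perm[keep, s] >= obs)) / (1 + sum(keep))
  }
  structure(list(n_permutations = n_permutations, seed = seed,
                 actual = actual[c("r2", "q2", "pred_r2")],
                 permuted = perm, z = zs, areas = areas, p = ps),
            class = "randomization_report")
}

#' @export
print.randomization_report <- function(x, ...) {
  cat("<randomization_report>", x$n_permutations, "permutations\n")
  for (s in names(x$z))
    cat(sprintf("  %-8s actual %.4f  Z %.4f  area %.4f%%  p %.4f\n",
                s, x$actual[[s]], x$z[s], x$areas[s], x$p[s]))
  invisible(x)
}

#' Percent area under the standard normal curve left of z
#'
#' `100 * Phi(z)`; the scale on which Z-scores are conventionally reported
#' in QSAR validation (e.g. Z = 1.6521 covers 95.0743% of the curve).
#'
#' @param z finite numeric (vectorized).
#' @return percentage in `[0, 100]`.
#' @export
normal_area <- function(z) {
  stopifnot(all(is.finite(z)))
  100 * stats::pnorm(z)
}

#' Observed vs predicted table for fitness and radar plots
#'
#' @param model a finalized `qsar_model`.
#' @param X full descriptor matrix (rownames = ids).
#' @param y activity vector aligned with `rownames(X)`.
#' @param split a `split_result`.
#' @return data.frame `compound_id, set, observed, predicted`, training
#'   rows first.
#' @export
fitness_data <- function(model, X, y, split) {
  ids <- c(split$training_ids, split$test_ids)
  idx <- match(ids, rownames(X))
  if (anyNA(idx)) stop("split ids absent from the descriptor matrix")
  data.frame(
    compound_id = ids,
    set = c(rep("train", length(split$training_ids)),
            rep("test", length(split$test_ids))),
    observed = y[idx],
    predicted = predict(model, X[idx, , drop = FALSE]),
    row.names = NULL)
}

#' Write a randomization report as JSON
#'
#' @param report a `randomization_report`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_randomization_json <- function(report, path) {
  obj <- list(n_permutations = report$n_permutations, seed = report$seed,
              actual = report$actual, z = as.list(report$z),
              areas = as.list(report$areas), p = as.list(report$p))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
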