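# ---------------------------------------------------------------------------
# Sphere-exclusion train/test splitting
# ---------------------------------------------------------------------------

#' Split result
#'
#' @param training_ids,test_ids character vectors partitioning the dataset.
#' @param radius exclusion radius used (autoscaled descriptor space).
#' @return object of class `split_result`.
#' @export
split_result <- function(training_ids, test_ids, radius = NA_real_) {
  training_ids <- as.character(training_ids)
  test_ids <- as.character(test_ids)
  if (!length(training_ids)) stop("training set must be nonempty")
  if (length(intersect(training_ids, test_ids)))
    stop("training and test sets overlap")
  structure(list(training_ids = training_ids, test_ids = test_ids,
                 radius = radius),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %d training / %d test (radius %.4g)\n",
              length(x$training_ids), length(x$test_ids), x$radius))
  invisible(x)
}

# autoscale columns to zero mean / unit variance; constant columns -> 0
autoscale <- function(M) {
  mu <- colMeans(M)
  sdv <- apply(M, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  sweep(sweep(M, 2, mu), 2, sdv, "/")
}

#' Sphere-exclusion division into training and test sets
#'
#' The descriptor matrix is autoscaled (zero mean, unit variance per
#' column); compounds are ordered by descending pIC50 (ties broken by
#' compound id). Repeatedly, the highest-activity unassigned compound is
#' taken into the TRAINING set and every unassigned compound within
#' Euclidean distance `radius` of it goes to the TEST set, until all
#' compounds are assigned. Seeding by activity keeps the activity extremes
#' inside training, as external validation with the training-mean reference
#' requires.
#'
#' @param matrix compound x descriptor matrix (rownames = compound ids).
#' @param activities data.frame `compound_id,pIC50` covering exactly the
#'   matrix rows.
#' @param radius exclusion radius (>= 0) in autoscaled descriptor space.
#' @return a `split_result`.
#' @export
sphere_exclusion <- function(matrix, activities, radius) {
  stopifnot(is.matrix(matrix), radius >= 0)
  ids <- rownames(matrix)
  if (is.null(ids)) stop("descriptor matrix must have compound-id rownames")
  if (!setequal(ids, activities$compound_id))
    stop("compound ids of matrix and activities disagree")
  y <- activities$pIC50[match(ids, activities$compound_id)]
  Z <- autoscale(matrix)
  ord <- order(-y, ids)
  assigned <- rep(NA_character_, nrow(Z))
  names(assigned) <- ids
  for (i in ord) {
    if (!is.na(assigned[i])) next
    assigned[i] <- "train"
    free <- which(is.na(assigned))
    if (!length(free)) next
    d <- sqrt(colSums((t(Z[free, , drop = FALSE]) - Z[i, ])^2))
    assigned[free[d <= radius]] <- "test"
  }
  split_result(training_ids = ids[assigned == "train"],
               test_ids = ids[assigned == "test"],
               radius = radius)
}

#' Find the exclusion radius giving a target test fraction
#'
#' Bisection over the radius until the test-set size is within `tol_count`
#' of `round(target_test_fraction * n)`. The test size is non-decreasing in
#' the radius, so bisection is valid; when the exact target is unattainable
#' (e.g. duplicate rows force jumps), the closest achievable split is
#' returned with a warning.
#'
#' @param matrix compound x descriptor matrix.
#' @param activities data.frame `compound_id,pIC50`.
#' @param target_test_fraction in (0, 1).
#' @param tol_count acceptable deviation from the target test count.
#' @param max_iter bisection iterations.
#' @return a `split_result` (its `radius` field holds the radius found).
#' @export
find_radius <- function(matrix, activities, target_test_fraction,
                        tol_count = 0L, max_iter = 60L) {
  stopifnot(target_test_fraction > 0, target_test_fraction < 1)
  n <- nrow(matrix)
  target <- round(target_test_fraction * n)
  lo <- 0
  Z <- autoscale(matrix)
  hi <- 2 * sqrt(max(rowSums(Z^2))) + 1  # exceeds any pairwise distance
  best <- NULL
  best_gap <- Inf
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    sp <- sphere_exclusion(matrix, activities, mid)
    nt <- length(sp$test_ids)
    gap <- abs(nt - target)
    if (gap < best_gap) { best <- sp; best_gap <- gap }
    if (gap <= tol_count) return(sp)
    if (nt < target) lo <- mid else hi <- mid
  }
  warning("find_radius: target test size ", target,
          " unreachable; returning closest split (|test| = ",
          length(best$test_ids), ")")
  best
}

#' Read / write split CSV (`compound_id,set` with set in {train, test})
#'
#' @param split a `split_result`.
#' @param path CSV path.
#' @return `path` invisibly for write; a `split_result` for read.
#' @export
write_split <- function(split, path) {
  df <- data.frame(
    compound_id = c(split$training_ids, split$test_ids),
    set = c(rep("train", length(split$training_ids)),
            rep("test", length(split$test_ids))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("compound_id", "set") %in% names(df)),
            all(df$set %in% c("train", "test")))
  split_result(df$compound_id[df$set == "train"],
               df$compound_id[df$set == "test"])
}
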