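# ---------------------------------------------------------------------------
# Library screening with applicability-domain flagging
# ---------------------------------------------------------------------------

#' Signed applicability-domain extrapolation score
#'
#' For each selected descriptor j with training range `[m_j, M_j]` of width
#' `w_j`, the normalized excursion is `(x_j - M_j)/w_j` above the range,
#' `(x_j - m_j)/w_j` below it (negative), and 0 inside. The score is the
#' excursion of maximum magnitude, keeping its sign — 0 exactly when the
#' compound sits inside the training domain on every selected descriptor.
#' Screening conventionally keeps compounds with a score strictly inside
#' (-1, 1).
#'
#' @param model a `qsar_model` with training ranges stored.
#' @param x named descriptor vector (extra descriptors ignored).
#' @return signed scalar score.
#' @export
extrapolation_score <- function(model, x) {
  if (is.null(model$training_ranges))
    stop("model carries no training ranges; cannot score extrapolation")
  m <- model$training_ranges["min", ]
  M <- model$training_ranges["max", ]
  w <- M - m
  if (any(w <= 0))
    stop("zero-width training range for: ",
         paste(model$selected[w <= 0], collapse = ", "))
  missing_d <- setdiff(model$selected, names(x))
  if (length(missing_d))
    stop("missing descriptor(s): ", paste(missing_d, collapse = ", "))
  xv <- x[model$selected]
  d <- numeric(length(xv))
  d[xv > M] <- ((xv - M) / w)[xv > M]
  d[xv < m] <- ((xv - m) / w)[xv < m]
  if (all(d == 0)) return(0)
  d[which.max(abs(d))]
}

#' Screen an external compound library
#'
#' Predicts pIC50 for every library compound with the model and attaches
#' the extrapolation score; results are ranked by descending prediction
#' (ties by compound id). Descriptors must come from the same grid/probe as
#' the training matrix: when both the model and the library matrix carry a
#' provenance hash, a mismatch is an error.
#'
#' @param model a finalized `qsar_model`.
#' @param library_matrix compound x descriptor matrix for the library.
#' @return data.frame `rank, compound_id, predicted_pIC50, extrapolation`
#'   of class `screen_result`.
#' @export
screen_library <- function(model, library_matrix) {
  library_matrix <- as.matrix(library_matrix)
  lib_hash <- attr(library_matrix, "grid_hash")
  if (!is.null(lib_hash) && !is.na(model$grid_hash) &&
      !identical(lib_hash, model$grid_hash))
    stop("grid provenance mismatch: library descriptors come from a ",
         "different grid than the model")
  missing_d <- setdiff(model$selected, colnames(library_matrix))
  if (length(missing_d))
    stop("library matrix lacks descriptor(s): ",
         paste(missing_d, collapse = ", "))
  ids <- rownames(library_matrix)
  if (is.null(ids)) ids <- paste0("lib_", seq_len(nrow(library_matrix)))
  pred <- predict(model, library_matrix)
  extr <- vapply(seq_len(nrow(library_matrix)), function(i)
    extrapolation_score(model, library_matrix[i, ]), numeric(1))
  ord <- order(-pred, ids)
  out <- data.frame(rank = seq_along(ord),
                    compound_id = ids[ord],
                    predicted_pIC50 = pred[ord],
                    extrapolation = extr[ord],
                    row.names = NULL)
  class(out) <- c("screen_result", class(out))
  out
}

#' Filter screening hits by activity and applicability domain
#'
#' Keeps results with predicted activity strictly above `min_activity` and
#' extrapolation strictly inside `extrapolation_bounds` (the conventional
#' screen keeps predicted pIC50 > 8 within (-1, 1)). Rank order is
#' preserved.
#'
#' @param results a `screen_result` data.frame.
#' @param min_activity predicted-pIC50 cutoff (default 8).
#' @param extrapolation_bounds length-2 ordered numeric (default c(-1, 1)).
#' @return the filtered subset.
#' @export
filter_hits <- function(results, min_activity = 8,
                        extrapolation_bounds = c(-1, 1)) {
  stopifnot(length(extrapolation_bounds) == 2L,
            extrapolation_bounds[1] <= extrapolation_bounds[2])
  keep <- results$predicted_pIC50 > min_activity &
    results$extrapolation > extrapolation_bounds[1] &
    results$extrapolation < extrapolation_bounds[2]
  results[keep, , drop = FALSE]
}
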