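# ---------------------------------------------------------------------------
# Ordinary least squares with the statistics QSAR reporting needs
# ---------------------------------------------------------------------------

#' Ordinary least squares fit with QSAR statistics
#'
#' Fits `y ~ X` with an intercept and returns, alongside the coefficients
#' and their standard errors, the training statistics used throughout:
#' `r2 = 1 - SSE/SST` and `r2_se = sqrt(SSE / (n - k - 1))` (degrees of
#' freedom count the intercept).
#'
#' @param X numeric matrix of selected descriptor columns (may have zero
#'   columns for the intercept-only model).
#' @param y response vector (pIC50).
#' @return list with `coefficients` (named), `coef_se`, `intercept`,
#'   `intercept_se`, `fitted`, `residuals`, `r2`, `r2_se`, `sse`, `sst`.
#' @export
ols_fit <- function(X, y) {
  X <- as.matrix(X)
  n <- length(y)
  k <- ncol(X)
  if (n <= k + 1L)
    stop("need more observations (", n, ") than descriptors + 1 (", k + 1L, ")")
  X1 <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(X1)
  if (qrx$rank < ncol(X1)) {
    dropped <- colnames(X1)[qrx$pivot[(qrx$rank + 1L):ncol(X1)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(X1 %*% beta)
  res <- y - fitted
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  sigma2 <- sse / (n - k - 1L)
  XtX_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(pmax(diag(XtX_inv), 0) * sigma2)
  list(coefficients = beta[-1L], coef_se = stats::setNames(se[-1L], colnames(X)),
       intercept = unname(beta[1L]), intercept_se = unname(se[1L]),
       fitted = fitted, residuals = res,
       r2 = if (sst > 0) 1 - sse / sst else NA_real_,
       r2_se = sqrt(sigma2), sse = sse, sst = sst)
}

# ---------------------------------------------------------------------------
# QsarModel container
# ---------------------------------------------------------------------------

#' Construct a QSAR model object
#'
#' Holds the selected descriptors, their coefficients with standard errors,
#' the intercept, the training/validation statistics, and the training
#' metadata (per-descriptor ranges, training-mean activity) that prediction
#' and applicability-domain scoring need.
#'
#' @param selected ordered character vector of descriptor names.
#' @param coefficients named numeric vector (same order as `selected`).
#' @param intercept scalar.
#' @param coef_se named numeric vector of coefficient standard errors.
#' @param stats named list of statistics (`r2`, `r2_se`, `q2`, `q2_se`,
#'   `F`, `pred_r2`, `pred_r2_se`; missing entries allowed).
#' @param training_ranges 2 x k matrix (rows `min`, `max`) of descriptor
#'   ranges over the training set, or `NULL` when unknown (e.g. a published
#'   equation loaded without its training data).
#' @param training_mean_y training-set mean pIC50 (or `NA`).
#' @param n_train training-set size (or `NA`).
#' @param grid_hash provenance hash of the descriptor grid (or `NA`).
#' @return object of class `qsar_model`.
#' @export
qsar_model <- function(selected, coefficients, intercept,
                       coef_se = NULL, stats = list(),
                       training_ranges = NULL, training_mean_y = NA_real_,
                       n_train = NA_integer_, grid_hash = NA_character_) {
  selected <- as.character(selected)
  coefficients <- stats::setNames(as.numeric(coefficients), selected)
  if (length(coefficients) != length(selected))
    stop("coefficients and selected descriptor names differ in length")
  if (!is.null(coef_se))
    coef_se <- stats::setNames(as.numeric(coef_se), selected)
  if (!is.null(training_ranges)) {
    training_ranges <- as.matrix(training_ranges)
    stopifnot(nrow(training_ranges) == 2L,
              ncol(training_ranges) == length(selected))
    rownames(training_ranges) <- c("min", "max")
    colnames(training_ranges) <- selected
  }
  structure(list(selected = selected, coefficients = coefficients,
                 intercept = as.numeric(intercept), coef_se = coef_se,
                 stats = stats, training_ranges = training_ranges,
                 training_mean_y = training_mean_y,
                 n_train = n_train, k = length(selected),
                 grid_hash = grid_hash),
            class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, ...) {
  cat("<qsar_model>", x$k, "descriptors, n_train =", x$n_train, "\n")
  terms <- sprintf("%+.4f x %s", x$coefficients, x$selected)
  cat("  pIC50 =", paste(terms, collapse = " "),
      sprintf("%+.4f", x$intercept), "\n")
  st <- x$stats
  shown <- st[!vapply(st, function(v) is.null(v) || all(is.na(v)), logical(1))]
  if (length(shown))
    cat("  ", paste(sprintf("%s = %.4f", names(shown), unlist(shown)),
                    collapse = ", "), "\n")
  invisible(x)
}

#' Predict pIC50 from a QSAR model
#'
#' @param object a `qsar_model`.
#' @param newdata named numeric vector, or a matrix/data.frame whose columns
#'   include every selected descriptor; extra descriptors are ignored.
#' @param ... unused.
#' @return numeric vector of predicted pIC50 values.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1,
                      dimnames = list(NULL, names(newdata)))
  }
  newdata <- as.matrix(newdata)
  missing_d <- setdiff(object$selected, colnames(newdata))
  if (length(missing_d))
    stop("missing descriptor(s): ", paste(missing_d, collapse = ", "))
  drop(object$intercept +
         newdata[, object$selected, drop = FALSE] %*% object$coefficients)
}

# ---------------------------------------------------------------------------
# Stepwise-forward selection
# ---------------------------------------------------------------------------

#' Stepwise-forward multiple linear regression
#'
#' Starts from the intercept-only model and greedily adds, one descriptor at
#' a time, the candidate with the largest partial F statistic
#' `F_add = (SSE_current - SSE_with) / (SSE_with / (n - p_with - 1))`,
#' as long as `F_add >= f_enter` and fewer than `max_terms` descriptors are
#' in the model. Exact ties in F are broken by descriptor-name order. The
#' scan is computed by projecting all candidates against the current model's
#' orthonormal basis, so each step is a single matrix product.
#'
#' @param X compound x descriptor matrix (colnames required).
#' @param y response vector.
#' @param f_enter F-to-enter threshold (default 4).
#' @param max_terms maximum model size; default `floor(n/4)` (a
#'   1-descriptor-per-4-compounds overfitting guard).
#' @param grid_hash optional provenance hash stored in the model.
#' @return a `qsar_model` with training stats `r2`, `r2_se`, `q2`, `q2_se`,
#'   `F` filled in; the per-step F-to-enter values are attached as attribute
#'   `f_trace`.
#' @export
stepwise_forward <- function(X, y, f_enter = 4, max_terms = NULL,
                             grid_hash = NA_character_) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, f_enter > 0)
  if (is.null(colnames(X))) stop("descriptor matrix must have column names")
  if (is.null(max_terms)) max_terms <- max(1L, floor(n / 4))
  if (max_terms > floor(n / 4))
    warning("max_terms (", max_terms, ") exceeds the n/4 guard (",
            floor(n / 4), ")")

  sst <- sum((y - mean(y))^2)
  Q <- matrix(1 / sqrt(n), nrow = n, ncol = 1)  # orthonormal basis: intercept
  y_r <- y - Q %*% crossprod(Q, y)
  sse_cur <- sum(y_r^2)
  selected <- character()
  f_trace <- numeric()
  candidates <- colnames(X)

  while (length(selected) < max_terms && length(candidates)) {
    Xc <- X[, candidates, drop = FALSE]
    Rc <- Xc - Q %*% crossprod(Q, Xc)          # candidates orthogonal to model
    ss_r <- colSums(Rc^2)
    cov_ry <- drop(crossprod(Rc, y_r))
    ok <- ss_r > 1e-10 * pmax(colSums(Xc^2), 1) # drop collinear candidates
    reduction <- ifelse(ok, cov_ry^2 / ss_r, 0)
    sse_with <- pmax(sse_cur - reduction, 0)
    df_with <- n - (length(selected) + 1L) - 1L
    if (df_with <= 0) break
    Fadd <- reduction * df_with / sse_with   # Inf on a perfect fit
    Fadd[!ok] <- -Inf
    Fadd[is.nan(Fadd)] <- -Inf               # 0/0: no reduction possible
    fmax <- max(Fadd)
    if (fmax < f_enter) break
    winners <- candidates[Fadd == fmax]
    pick <- sort(winners)[1L]                   # ties: lexicographic name
    j <- match(pick, candidates)
    # extend the orthonormal basis with the picked column
    qnew <- Rc[, j] / sqrt(ss_r[j])
    Q <- cbind(Q, qnew)
    y_r <- y_r - qnew * sum(qnew * y)
    sse_cur <- sum(y_r^2)
    selected <- c(selected, pick)
    f_trace <- c(f_trace, fmax)
    candidates <- candidates[-j]
  }

  if (!length(selected)) {
    model <- qsar_model(character(), numeric(), intercept = mean(y),
                        stats = list(r2 = 0, r2_se = stats::sd(y), F = 0),
                        training_mean_y = mean(y), n_train = n,
                        grid_hash = grid_hash)
    attr(model, "f_trace") <- f_trace
    return(model)
  }

  Xsel <- X[, selected, drop = FALSE]
  fit <- ols_fit(Xsel, y)
  # a selected near-indicator column can give a leave-out leverage of 1;
  # the model still exists, but its q2 is undefined rather than an error
  q2 <- tryCatch(loo_q2(Xsel, y),
                 error = function(e) list(q2 = NA_real_, q2_se = NA_real_))
  model <- qsar_model(
    selected = selected,
    coefficients = fit$coefficients,
    intercept = fit$intercept,
    coef_se = fit$coef_se,
    stats = list(r2 = fit$r2, r2_se = fit$r2_se,
                 q2 = q2$q2, q2_se = q2$q2_se,
                 F = if (fit$r2 < 1) f_statistic(fit$r2, n, length(selected))
                     else Inf),
    training_ranges = apply(Xsel, 2, range),
    training_mean_y = mean(y),
    n_train = n,
    grid_hash = grid_hash)
  attr(model, "f_trace") <- f_trace
  model
}

# ---------------------------------------------------------------------------
# Validation statistics
# ---------------------------------------------------------------------------

#' Leave-one-out cross-validated q2
#'
#' For a fixed selected descriptor set, each compound is predicted from a
#' model refit on the remaining n - 1; `q2 = 1 - PRESS / SST` and
#' `q2_se = sqrt(PRESS / (n - k - 1))`. Computed via the exact leverage
#' identity `e_(i) = e_i / (1 - h_ii)` (identical to literally refitting n
#' times, which the test suite verifies by brute force).
#'
#' @param X_selected matrix of the selected descriptor columns.
#' @param y response vector.
#' @return list with `q2`, `q2_se`, `press`.
#' @export
loo_q2 <- function(X_selected, y) {
  X_selected <- as.matrix(X_selected)
  n <- length(y)
  k <- ncol(X_selected)
  if (n <= k + 2L) stop("LOO needs n > k + 2")
  fit <- ols_fit(X_selected, y)
  X1 <- cbind(1, X_selected)
  h <- rowSums(qr.Q(qr(X1))^2)
  if (any(h >= 1 - 1e-10))
    stop("leave-one-out refit is rank-deficient for row(s): ",
         paste(which(h >= 1 - 1e-10), collapse = ", "))
  press <- sum((fit$residuals / (1 - h))^2)
  sst <- sum((y - mean(y))^2)
  list(q2 = 1 - press / sst, q2_se = sqrt(press / (n - k - 1L)),
       press = press)
}

#' External predictivity pred_r2
#'
#' `pred_r2 = 1 - sum((y_test - yhat)^2) / sum((y_test - ybar_train)^2)`,
#' with the training-set mean activity as the reference;
#' `pred_r2_se = sqrt(sum((y_test - yhat)^2) / n_test)`.
#'
#' @param model a finalized `qsar_model` (its `training_mean_y` is used).
#' @param X_test descriptor matrix for the test compounds.
#' @param y_test observed test activities.
#' @return list with `pred_r2`, `pred_r2_se`.
#' @export
pred_r2 <- function(model, X_test, y_test) {
  if (is.na(model$training_mean_y))
    stop("model carries no training mean; cannot compute pred_r2")
  yhat <- predict(model, X_test)
  sse <- sum((y_test - yhat)^2)
  denom <- sum((y_test - model$training_mean_y)^2)
  if (denom == 0) stop("degenerate test set")
  list(pred_r2 = 1 - sse / denom,
       pred_r2_se = sqrt(sse / length(y_test)))
}

#' Fisher F statistic of a fitted regression
#'
#' `F = (r2 / k) / ((1 - r2) / (n - k - 1))`: explained variance per
#' descriptor over residual variance per error degree of freedom.
#'
#' @param r2 squared correlation coefficient in `[0, 1)`.
#' @param n training-set size.
#' @param k number of descriptors.
#' @return the F value.
#' @export
f_statistic <- function(r2, n, k) {
  stopifnot(n > k + 1L)
  if (r2 < 0 || r2 >= 1) stop("r2 must lie in [0, 1)")
  if (k == 0L) return(0)
  (r2 / k) / ((1 - r2) / (n - k - 1L))
}

#' Signed percentage contributions of the selected descriptors
#'
#' `c_j = sign(beta_j) * 100 * |beta_j| s_j / sum_m |beta_m| s_m`, with
#' `s_j` the training standard deviation of descriptor j, so the magnitudes
#' sum to 100. A positive steric contribution marks a position favouring
#' bulk; a positive electrostatic one favours electropositive substituents.
#'
#' @param model a finalized `qsar_model`.
#' @param X_train training descriptor matrix (must contain the selected
#'   columns).
#' @return named numeric vector of signed percentages.
#' @export
contributions <- function(model, X_train) {
  X_train <- as.matrix(X_train)
  missing_d <- setdiff(model$selected, colnames(X_train))
  if (length(missing_d))
    stop("missing descriptor(s): ", paste(missing_d, collapse = ", "))
  s <- apply(X_train[, model$selected, drop = FALSE], 2, stats::sd)
  w <- abs(model$coefficients) * s
  if (sum(w) == 0) stop("all selected descriptors have zero variance")
  sign(model$coefficients) * 100 * w / sum(w)
}

# ---------------------------------------------------------------------------
# The published EGFR inhibition model and (de)serialization
# ---------------------------------------------------------------------------

#' The published thiazolyl-pyrazoline EGFR 3D-QSAR equation
#'
#' The reported 6-descriptor stepwise-MLR model for EGFR tyrosine-kinase
#' inhibition by thiazolyl-pyrazolines, loaded as a `qsar_model`:
#' steric descriptors S_335, S_151 and electrostatic descriptors E_337,
#' E_832, E_424, E_721 with intercept 5.0198. Descriptor indices refer to
#' the original study's grid, so this model predicts only on descriptor
#' vectors expressed in that frame (no training ranges are available; the
#' applicability domain cannot be evaluated for it).
#'
#' @return a `qsar_model`.
#' @export
published_egfr_model <- function() {
  qsar_model(
    selected = c("E_337", "S_335", "E_832", "E_424", "S_151", "E_721"),
    coefficients = c(0.2989, 3.2763, 0.1785, 0.4938, -11.7460, -0.6486),
    coef_se = c(0.0020, 0.5560, 0.0003, 0.0033, 0.3402, 0.0019),
    intercept = 5.0198,
    stats = list(r2 = 0.9751, r2_se = 0.0966, q2 = 0.9491, q2_se = 0.1380,
                 pred_r2 = 0.9525, pred_r2_se = 0.1282, F = 130.3822),
    n_train = 27L)
}

#' Serialize / deserialize a QSAR model as JSON
#'
#' @param model a `qsar_model`.
#' @param path JSON file path.
#' @return `path` invisibly for write; a `qsar_model` for read.
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    selected = model$selected,
    coefficients = unname(model$coefficients),
    coef_se = if (!is.null(model$coef_se)) unname(model$coef_se),
    intercept = model$intercept,
    stats = model$stats,
    training_ranges = if (!is.null(model$training_ranges))
      list(min = unname(model$training_ranges["min", ]),
           max = unname(model$training_ranges["max", ])),
    training_mean_y = model$training_mean_y,
    n_train = model$n_train,
    grid_hash = model$grid_hash)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ranges <- NULL
  if (!is.null(obj$training_ranges) && length(obj$training_ranges$min))
    ranges <- rbind(min = obj$training_ranges$min,
                    max = obj$training_ranges$max)
  qsar_model(selected = obj$selected,
             coefficients = obj$coefficients,
             coef_se = obj$coef_se,
             intercept = obj$intercept,
             stats = obj$stats,
             training_ranges = ranges,
             training_mean_y = obj$training_mean_y %||% NA_real_,
             n_train = obj$n_train %||% NA_integer_,
             grid_hash = obj$grid_hash %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
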