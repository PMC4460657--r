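# in-code fixtures shared across the suite

# V2000 methane record, built programmatically (optionally with a charges
# data field and an overridable carbon element symbol)
methane_sdf_lines <- function(charges = NULL, carbon = "C") {
  xyz <- rbind(c(0, 0, 0), c(0.63, 0.63, 0.63), c(-0.63, -0.63, 0.63),
               c(-0.63, 0.63, -0.63), c(0.63, -0.63, -0.63))
  el <- c(carbon, "H", "H", "H", "H")
  lines <- c("methane", "  fixture", "",
             "  5  4  0  0  0  0  0  0  0  0999 V2000",
             sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     xyz[, 1], xyz[, 2], xyz[, 3], el),
             sprintf("%3d%3d%3d  0  0  0  0", 1L, 2:5, 1L),
             "M  END")
  if (!is.null(charges))
    lines <- c(lines, ">  <PARTIAL_CHARGES>",
               paste(sprintf("%.4f", charges), collapse = " "), "")
  c(lines, "$$$$")
}

write_methane_sdf <- function(path, ...) {
  writeLines(methane_sdf_lines(...), path)
  path
}

# single-atom molecule with vdW parameters assigned
one_atom_mol <- function(id = "a1", element = "C", pos = c(0, 0, 0),
                         charge = 0) {
  m <- molecule(id, data.frame(element = element, x = pos[1], y = pos[2],
                               z = pos[3], charge = charge))
  assign_vdw(m)
}

# small seeded regression instance
seeded_xy <- function(n, k, seed, sd = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * k), n, k,
              dimnames = list(NULL, paste0("D_", seq_len(k))))
  y <- rnorm(n, sd = sd)
  list(X = X, y = y)
}

# independent normal-equations OLS oracle (naive solve, incl. SEs)
ols_oracle <- function(X, y) {
  X1 <- cbind(1, X)
  XtX <- t(X1) %*% X1
  beta <- solve(XtX, t(X1) %*% y)
  res <- y - X1 %*% beta
  sse <- sum(res^2)
  sigma2 <- sse / (length(y) - ncol(X) - 1)
  se <- sqrt(diag(solve(XtX)) * sigma2)
  list(intercept = beta[1], coefficients = drop(beta[-1]),
       intercept_se = se[1], coef_se = se[-1],
       r2 = 1 - sse / sum((y - mean(y))^2), r2_se = sqrt(sigma2))
}

# brute-force leave-one-out oracle: literally refit n times
loo_oracle <- function(X, y) {
  n <- length(y)
  press <- 0
  for (i in seq_len(n)) {
    X1 <- cbind(1, X[-i, , drop = FALSE])
    beta <- solve(t(X1) %*% X1, t(X1) %*% y[-i])
    pred <- drop(c(1, X[i, ]) %*% beta)
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}
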