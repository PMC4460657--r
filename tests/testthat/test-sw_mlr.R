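test_that("ols_fit is exact on noiseless data", {
  x <- matrix(1:10, ncol = 1, dimnames = list(NULL, "d1"))
  y <- 2 * x[, 1] + 1
  fit <- ols_fit(x, y)
  expect_equal(unname(fit$coefficients), 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r2, 1)
  expect_equal(fit$r2_se, 0, tolerance = 1e-10)
})

test_that("ols_fit agrees with the normal-equations oracle to 1e-10", {
  for (case in list(c(n = 12, k = 2, seed = 1), c(n = 40, k = 5, seed = 2),
                    c(n = 100, k = 10, seed = 3))) {
    d <- seeded_xy(case["n"], case["k"], case["seed"])
    fit <- ols_fit(d$X, d$y)
    ora <- ols_oracle(d$X, d$y)
    expect_equal(unname(fit$coefficients), unname(ora$coefficients),
                 tolerance = 1e-10)
    expect_equal(fit$intercept, ora$intercept, tolerance = 1e-10)
    expect_equal(unname(fit$coef_se), unname(ora$coef_se),
                 tolerance = 1e-10)
    expect_equal(fit$r2, ora$r2, tolerance = 1e-10)
    expect_equal(fit$r2_se, ora$r2_se, tolerance = 1e-10)
  }
})

test_that("ols_fit rejects rank-deficient designs, naming a column", {
  d <- seeded_xy(10, 2, seed = 9)
  X <- cbind(d$X, dup = d$X[, 1])
  expect_error(ols_fit(X, d$y), "collinear.*dup|dup")
  expect_error(ols_fit(matrix(rnorm(12), 3, 4), rnorm(3)), "observations")
})

test_that("stepwise_forward recovers planted descriptors", {
  set.seed(77)
  n <- 40; p <- 50
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("D_%02d", 1:p)))
  beta <- c(1.2, -0.9, 0.8)
  planted <- c("D_05", "D_17", "D_42")
  y <- 5 + drop(X[, planted] %*% beta) + rnorm(n, 0, 0.2)
  model <- stepwise_forward(X, y, f_enter = 4)
  expect_true(all(planted %in% model$selected))
  expect_gt(model$stats$r2, 0.9)
  # every accepted step passed the threshold
  expect_true(all(attr(model, "f_trace") >= 4))
  # the model stores training metadata for later screening
  expect_equal(model$n_train, n)
  expect_equal(dim(model$training_ranges), c(2L, model$k))
})

test_that("stepwise_forward degenerate contracts", {
  # a single candidate perfectly correlated with y: picked, then stop
  set.seed(44)
  x <- matrix(seq(-1, 1, length.out = 12), ncol = 1,
              dimnames = list(NULL, "only"))
  y <- 3 * x[, 1] - 2
  m <- stepwise_forward(cbind(x, noise = rnorm(12)), y, f_enter = 4)
  expect_equal(m$selected, "only")
  expect_equal(m$stats$r2, 1)

  # infinite threshold: empty model, intercept = mean(y)
  d <- seeded_xy(16, 4, seed = 5)
  m0 <- stepwise_forward(d$X, d$y, f_enter = Inf)
  expect_length(m0$selected, 0L)
  expect_equal(m0$intercept, mean(d$y))
  expect_equal(predict(m0, d$X), rep(mean(d$y), 16), ignore_attr = TRUE)

  # parameter recovery at zero noise
  set.seed(6)
  X <- matrix(rnorm(200), 20, 10,
              dimnames = list(NULL, paste0("V", 1:10)))
  y <- 1.5 + 2 * X[, "V3"] - X[, "V7"]
  mr <- stepwise_forward(X, y, f_enter = 4)
  expect_setequal(mr$selected, c("V3", "V7"))
  expect_equal(unname(mr$coefficients[c("V3", "V7")]), c(2, -1),
               tolerance = 1e-6)
})

test_that("loo_q2 equals the brute-force refit oracle", {
  for (seed in 1:4) {
    d <- seeded_xy(12, 2, seed = seed)
    y <- d$y + 0.8 * d$X[, 1]
    got <- loo_q2(d$X, y)
    expect_equal(got$q2, loo_oracle(d$X, y), tolerance = 1e-10)
  }
})

test_that("loo_q2 limits: exact data, intercept-only PRESS inflation", {
  x <- matrix(seq_len(14), ncol = 1)
  expect_equal(loo_q2(x, 2 * x[, 1] + 3)$q2, 1, tolerance = 1e-10)
  y <- rnorm(10)
  q0 <- loo_q2(matrix(numeric(0), 10, 0), y)
  expect_lt(q0$q2, 0)  # 1 - (n/(n-1))^2 exactly
  expect_equal(q0$q2, 1 - (10 / 9)^2, tolerance = 1e-10)
})

test_that("q2 <= r2 for any fixed selected set", {
  for (seed in 1:6) {
    d <- seeded_xy(15, 3, seed = 100 + seed)
    y <- d$y + 0.5 * d$X[, 2]
    expect_lte(loo_q2(d$X, y)$q2, ols_fit(d$X, y)$r2)
  }
})

test_that("pred_r2 follows its defining formula", {
  d <- seeded_xy(20, 2, seed = 55)
  y <- 4 + d$X[, 1] - 0.5 * d$X[, 2] + rnorm(20, 0, 0.3)
  tr <- 1:14; te <- 15:20
  fit <- ols_fit(d$X[tr, ], y[tr])
  model <- qsar_model(colnames(d$X), fit$coefficients, fit$intercept,
                      training_mean_y = mean(y[tr]), n_train = 14L)
  got <- pred_r2(model, d$X[te, ], y[te])
  yhat <- predict(model, d$X[te, ])
  expect_equal(got$pred_r2,
               1 - sum((y[te] - yhat)^2) / sum((y[te] - mean(y[tr]))^2),
               tolerance = 1e-12)
  expect_equal(got$pred_r2_se, sqrt(sum((y[te] - yhat)^2) / 6),
               tolerance = 1e-12)

  perfect <- qsar_model("z", 1, 0, training_mean_y = 0)
  Xt <- matrix(1:3, 3, 1, dimnames = list(NULL, "z"))
  expect_equal(pred_r2(perfect, Xt, 1:3)$pred_r2, 1)
  # predicting the training mean scores exactly zero
  null_model <- qsar_model(character(), numeric(), intercept = mean(y[tr]),
                           training_mean_y = mean(y[tr]))
  expect_equal(pred_r2(null_model, d$X[te, ], y[te])$pred_r2, 0,
               tolerance = 1e-12)
  expect_error(pred_r2(null_model, d$X[te, ], rep(mean(y[tr]), 6)),
               "degenerate")
})

test_that("f_statistic matches its closed form and guards r2 = 1", {
  expect_equal(f_statistic(0.5, 12, 1), 10)
  expect_equal(f_statistic(0, 20, 3), 0)
  expect_error(f_statistic(1, 20, 3), "r2")
})

test_that("contributions are signed, scale-weighted, and sum to 100", {
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  m1 <- qsar_model("a", 2, 0, training_ranges = rbind(min = -1, max = 1))
  expect_equal(unname(contributions(m1, X)), 100, ignore_attr = TRUE)

  # two descriptors with equal |beta| * s and opposite signs
  X2 <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  X2[, 2] <- X2[, 2] / sd(X2[, 2]) * sd(X2[, 1])
  m2 <- qsar_model(c("a", "b"), c(1.3, -1.3), 0)
  expect_equal(unname(contributions(m2, X2)), c(50, -50), tolerance = 1e-9)

  for (seed in 1:5) {
    d <- seeded_xy(25, 4, seed = 200 + seed)
    y <- d$y + d$X[, 1]
    m <- stepwise_forward(d$X, y, f_enter = 2)
    if (m$k > 0)
      expect_equal(sum(abs(contributions(m, d$X))), 100, tolerance = 1e-9)
  }
})

test_that("prediction from the published equation behaves linearly", {
  model <- published_egfr_model()
  zeros <- setNames(rep(0, 6), model$selected)
  expect_identical(unname(predict(model, zeros)), 5.0198)
  e337 <- zeros; e337["E_337"] <- 1
  expect_equal(unname(predict(model, e337)), 5.3187, tolerance = 1e-12)

  x1 <- setNames(rnorm(6), model$selected)
  x2 <- setNames(rnorm(6), model$selected)
  expect_equal(predict(model, x1 + x2) - model$intercept,
               (predict(model, x1) - model$intercept) +
                 (predict(model, x2) - model$intercept),
               tolerance = 1e-10)
  expect_error(predict(model, c(E_337 = 1)), "missing descriptor.*S_335")
})

test_that("model JSON serialization round-trips", {
  d <- seeded_xy(20, 6, seed = 31)
  y <- 5 + d$X[, 1] - d$X[, 4] + rnorm(20, 0, 0.1)
  m <- stepwise_forward(d$X, y, f_enter = 4, grid_hash = "abc123")
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- read_model_json(path)
  expect_equal(back$selected, m$selected)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$training_ranges, m$training_ranges)
  expect_equal(back$stats$r2, m$stats$r2)
  expect_equal(back$grid_hash, "abc123")
  x <- setNames(rnorm(m$k), m$selected)
  expect_equal(predict(back, x), predict(m, x))
})
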