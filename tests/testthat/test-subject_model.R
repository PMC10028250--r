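test_that("dataset split: LBW to test, matched NBW validation, no overlap", {
  coh <- generate_cohort(generator_config(n_subjects = 58), seed = 21)
  rows <- coh$strides
  sets <- split_dataset(rows, seed = 1)
  expect_equal(nrow(sets$train) + nrow(sets$validation) + nrow(sets$test),
               nrow(rows))
  expect_length(intersect(sets$train$stride_id, sets$validation$stride_id), 0)
  expect_length(intersect(sets$train$stride_id, sets$test$stride_id), 0)
  expect_true(all(sets$test$birth_weight_category == "LBW"))
  expect_true(all(sets$train$birth_weight_category == "NBW"))
  expect_equal(nrow(sets$validation), nrow(sets$test))
  # seeded: identical on rerun
  sets2 <- split_dataset(rows, seed = 1)
  expect_identical(sets$validation$stride_id, sets2$validation$stride_id)
  # no LBW rows: validation sized by fraction
  nbw <- rows[rows$birth_weight_category == "NBW", ]
  s3 <- split_dataset(nbw, validation_fraction = 0.2, seed = 2)
  expect_equal(nrow(s3$test), 0)
  expect_equal(nrow(s3$validation), round(0.2 * nrow(nbw)))
})

test_that("the assembled model has exactly 36 free parameters", {
  rows <- simulate_linear_strides(n = 60, seed = 1)
  m <- build_model(model_design("age"), rows)
  expect_equal(m$n_parameters, 36)
  expect_equal(length(model_design("age")$predictors), 34)
  expect_equal(model_design("mass")$transform, "log")
  expect_equal(model_design("age")$transform, "identity")
})

test_that("zero-variance predictors are rejected by name", {
  rows <- simulate_linear_strides(n = 60, seed = 2)
  rows$CC4 <- 0
  expect_error(build_model(model_design("age"), rows), "CC4")
  rows2 <- simulate_linear_strides(n = 60, seed = 2)
  rows2$speed <- NULL
  expect_error(build_model(model_design("age"), rows2), "speed")
})

test_that("posterior matches the conjugate closed-form oracle", {
  # near-normal noise; oracle = Bayesian linear regression with the
  # residual scale fixed at its true value (the model estimates it, so a
  # small slack beyond Monte-Carlo error is allowed)
  sigma <- 0.4
  rows <- simulate_linear_strides(n = 500, sigma = sigma, nu = 1000,
                                  seed = 31)
  m <- build_model(model_design("age"), rows)
  bn <- sample_posterior(m, chains = 2, tune = 1000, draws = 1000,
                         seed = 4)
  Z <- cbind(1, m$X)
  s <- sigma / m$y_scale
  V <- solve(crossprod(Z) / s^2 + diag(ncol(Z)) / 4)
  theta <- as.numeric(V %*% crossprod(Z, m$y) / s^2)
  got <- colMeans(bn$draws[, c("intercept", m$design$predictors)])
  expect_lt(max(abs(got - theta)), 0.01)
})

test_that("a dominant known slope is recovered on near-noiseless data", {
  preds <- model_design("age")$predictors
  beta <- rep(0, 34); beta[match("speed", preds)] <- 3
  rows <- simulate_linear_strides(n = 300, beta = beta, alpha = 2,
                                  sigma = 0.05, nu = 30, seed = 7)
  m <- build_model(model_design("age"), rows)
  bn <- sample_posterior(m, seed = 3)
  cd <- coef_draws(bn)
  expect_equal(mean(cd[, "speed"]), 3, tolerance = 0.02)
  expect_equal(mean(cd[, "intercept"]), 2, tolerance = 0.05)
  others <- setdiff(preds, "speed")
  expect_lt(max(abs(colMeans(cd[, others]))), 0.05)
  # regression block converges even at desk scale
  reg <- bn$diagnostics[bn$diagnostics$parameter %in%
                          c("intercept", preds), ]
  expect_lt(max(reg$rhat), 1.02)
})

test_that("sampling is deterministic given the seed", {
  rows <- simulate_linear_strides(n = 120, seed = 13)
  m <- build_model(model_design("age"), rows)
  b1 <- sample_posterior(m, chains = 2, tune = 300, draws = 300, seed = 9)
  b2 <- sample_posterior(m, chains = 2, tune = 300, draws = 300, seed = 9)
  expect_identical(b1$draws, b2$draws)
  p1 <- predict_strides(b1, rows[1:5, ], seed = 2)
  p2 <- predict_strides(b2, rows[1:5, ], seed = 2)
  expect_identical(p1, p2)
  # diagnostics are always emitted
  expect_true(all(c("rhat", "ess") %in% names(b1$diagnostics)))
  expect_equal(nrow(b1$diagnostics), 37)   # 36 model parameters + nu
})

test_that("a collapsed posterior predicts a point at the linear predictor", {
  rows <- simulate_linear_strides(n = 60, seed = 17)
  m <- build_model(model_design("age"), rows)
  nd <- 400
  draws <- matrix(0, nd, 37,
                  dimnames = list(NULL, c("intercept",
                                          m$design$predictors,
                                          "eps", "nu")))
  draws[, "intercept"] <- 0.4
  draws[, "speed"] <- 1.2
  draws[, "eps"] <- 1e-12
  draws[, "nu"] <- 50
  bundle <- structure(list(draws = draws, chains = 1, n_draws = nd,
                           seed = 1, model = m,
                           diagnostics = data.frame(), failed = FALSE),
                      class = "posterior_bundle")
  pr <- predict_strides(bundle, rows[1:4, ], seed = 1)
  xs <- (rows$speed[1:4] - m$x_center["speed"]) / m$x_scale["speed"]
  want <- m$y_center + m$y_scale * (0.4 + 1.2 * xs)
  expect_equal(pr$pred_mean, unname(want), tolerance = 1e-6)
  expect_lt(max(pr$pred_sd), 1e-6)
})

test_that("prediction demands every predictor", {
  rows <- simulate_linear_strides(n = 60, seed = 19)
  m <- build_model(model_design("age"), rows)
  b <- sample_posterior(m, chains = 1, tune = 200, draws = 200, seed = 1)
  bad <- rows[1:3, ]
  bad$CC7 <- NULL
  expect_error(predict_strides(b, bad), "CC7")
  bad2 <- rows[1:3, ]
  bad2$CC7[2] <- NA
  expect_error(predict_strides(b, bad2), "missing predictor values")
})

test_that("log-transformed outcomes are modeled and back-transformed", {
  rows <- simulate_linear_strides(n = 200, alpha = 0.3, sigma = 0.1,
                                  outcome = "mass", seed = 23)
  rows$mass <- exp(rows$mass)                # strictly positive outcome
  m <- build_model(model_design("mass"), rows)
  expect_equal(m$design$transform, "log")
  b <- sample_posterior(m, chains = 2, tune = 500, draws = 500, seed = 5)
  pr <- predict_strides(b, rows, seed = 3)
  expect_true(all(pr$pred_mean > 0))
  # back on the natural scale, predictions straddle the actual values
  expect_lt(abs(median(pr$delta_mean / rows$mass)), 0.2)
  rows$mass[1] <- -1
  expect_error(build_model(model_design("mass"), rows), "positive")
})
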