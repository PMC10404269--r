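test_that("the covariate base model matches a closed-form least-squares solve", {
  X <- cbind(x1 = c(1, 2, 3, 4, 5), x2 = c(0, 1, 0, 1, 1))
  y <- c(1.2, 1.9, 3.1, 4.2, 4.8)
  m <- fit_covariate_base(as.data.frame(X), y)
  Xd <- cbind(1, X)
  beta_hat <- solve(crossprod(Xd), crossprod(Xd, y))
  expect_equal(unname(coef(m)), as.numeric(beta_hat), tolerance = 1e-10)
  expect_equal(m$family, "gaussian")
})

test_that("separation triggers the flagged ridge fallback", {
  set.seed(1)
  covs <- data.frame(sex = rep(c(0, 1), each = 50), age = rnorm(100))
  y <- covs$sex  # perfect separation
  m <- fit_covariate_base(covs, y)
  expect_true("ridge_fallback" %in% m$flags)
  p <- predict(m, covariates = covs)
  expect_gt(auc(p, y), 0.99)
})

test_that("an uninformative outcome gives near-zero covariate R2", {
  set.seed(2)
  covs <- data.frame(sex = rbinom(5000, 1, 0.5), age = runif(5000))
  y <- rnorm(5000)
  m <- fit_covariate_base(covs, y)
  expect_lt(r2_linear(predict(m, covariates = covs), y), 0.01)
})

test_that("infinite penalty zeroes all score weights but keeps covariates", {
  set.seed(3)
  n <- 1000
  lib <- random_library(n, 10, seed = 3)
  covs <- data.frame(sex = rbinom(n, 1, 0.5))
  y <- 0.8 * covs$sex + lib$scores[, 1] * 0.2 + rnorm(n)
  m <- fit_lasso_stack(lib, covs, y, penalty_grid = c(1e4, 1e3), seed = 1)
  expect_true(all(m$score_weights == 0))
  expect_gt(abs(m$cov_weights[["sex"]]), 0.1)
})

test_that("the lasso stack recovers a sparse truth among 50 scores", {
  set.seed(4)
  n <- 5000
  lib <- random_library(n, 50, seed = 4)
  truth <- c("s01", "s02", "s03")
  y <- as.numeric(lib$scores[, truth] %*% c(0.4, 0.35, 0.3)) + rnorm(n)
  covs <- toy_covariates(n, seed = 1000 + 4)
  m <- fit_lasso_stack(lib, covs, y, seed = 2)
  top3 <- names(sort(abs(m$score_weights), decreasing = TRUE))[1:3]
  expect_setequal(top3, truth)
})

test_that("duplicated score columns leave predictions invariant", {
  set.seed(5)
  n <- 800
  S <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, sprintf("s%02d", 1:5)))
  y <- S[, 1] + rnorm(n)
  covs <- toy_covariates(n, seed = 1000 + 5)
  lib1 <- score_library(S)
  S2 <- cbind(S, s_dup = S[, 1])
  lib2 <- score_library(S2)
  m1 <- fit_lasso_stack(lib1, covs, y, seed = 3)
  m2 <- fit_lasso_stack(lib2, covs, y, seed = 3)
  p1 <- predict(m1, lib1, covs)
  p2 <- predict(m2, lib2, covs)
  expect_gt(cor(p1, p2), 0.999)
  # total weight mass on the duplicated signal is preserved
  expect_equal(m2$score_weights[["s01"]] + m2$score_weights[["s_dup"]],
               m1$score_weights[["s01"]], tolerance = 0.05)
})

test_that("boosted trees: constant outcome, determinism, response scale", {
  n <- 300
  lib <- random_library(n, 5, seed = 6)
  covs <- toy_covariates(n, seed = 1000 + 6)
  m <- fit_xgb_stack(lib, covs, rep(1.5, n), family = "gaussian", seed = 1)
  expect_lt(sd(predict(m, lib, covs)), 1e-8)

  set.seed(7)
  y <- rbinom(n, 1, 0.4)
  m1 <- fit_xgb_stack(lib, covs, y, seed = 9)
  m2 <- fit_xgb_stack(lib, covs, y, seed = 9)
  expect_identical(predict(m1, lib, covs), predict(m2, lib, covs))
  expect_true(all(predict(m1, lib, covs) >= 0 & predict(m1, lib, covs) <= 1))
})

test_that("a sex-age interaction favors the boosted covariate model", {
  set.seed(8)
  n <- 8000
  covs <- data.frame(sex = rbinom(n, 1, 0.5), age = runif(n, 1, 35))
  # risk driven purely by the interaction: linear-in-covariates logistic
  # regression cannot represent it
  liab <- 1.5 * (covs$sex * 2 - 1) * as.numeric(scale(covs$age)) + rnorm(n)
  y <- as.integer(liab > quantile(liab, 0.7))
  tr <- 1:6000; te <- 6001:8000
  glm_m <- fit_covariate_base(covs[tr, ], y[tr])
  xgb_m <- fit_xgb_stack(NULL, covs[tr, ], y[tr], covariates_only = TRUE,
                         nrounds = 50, seed = 1)
  r2_glm <- r2_linear(predict(glm_m, covariates = covs[te, ]), y[te])
  r2_xgb <- r2_linear(predict(xgb_m, library = NULL,
                              covariates = covs[te, ]), y[te])
  expect_gt(r2_xgb, r2_glm)
})

test_that("the mixed stack matches the lasso stack under a linear truth", {
  set.seed(9)
  n <- 4000
  lib <- random_library(n, 10, seed = 9)
  covs <- toy_covariates(n, seed = 1000 + 9)
  lin <- 0.5 * lib$scores[, 1] + 0.4 * lib$scores[, 2] +
    0.3 * (covs$sex - 0.5)
  y <- as.integer(lin + rnorm(n) > 0.8)
  tr <- 1:3000; te <- 3001:4000
  lib_tr <- lib; lib_tr$scores <- lib$scores[tr, ]
  lib_te <- lib; lib_te$scores <- lib$scores[te, ]
  ml <- fit_lasso_stack(lib_tr, covs[tr, ], y[tr], seed = 4)
  # stage 1 gets enough boosting rounds to actually fit the covariates;
  # the default 10 rounds at eta 0.01 leaves it essentially untrained
  mm <- fit_mixed_stack(lib_tr, covs[tr, ], y[tr], eta = 0.1, nrounds = 200,
                        seed = 4)
  r2l <- r2_linear(predict(ml, lib_te, covs[te, ]), y[te])
  r2m <- r2_linear(predict(mm, lib_te, covs[te, ]), y[te])
  expect_lt(abs(r2l - r2m), 0.05)
})

test_that("a constant stage-1 score degrades the mixed stack to scores-only lasso", {
  set.seed(10)
  n <- 1000
  lib <- random_library(n, 5, seed = 10)
  covs <- data.frame(c1 = rep(1, n), c2 = rep(2, n))  # constant covariates
  y <- as.integer(lib$scores[, 1] + rnorm(n) > 0.5)
  mm <- fit_mixed_stack(lib, covs, y, seed = 1)
  expect_true("constant_stage1" %in% mm$flags)
  p <- predict(mm, lib, covs)
  expect_gt(auc(p, y), 0.6)
})

test_that("simplification keeps |weight| > threshold scores and refits", {
  n <- 2000
  lib <- random_library(n, 3, seed = 11)
  covs <- toy_covariates(n, seed = 1000 + 11)
  set.seed(11)
  y <- 0.5 * lib$scores[, 1] + rnorm(n)
  model <- fit_lasso_stack(lib, covs, y, seed = 5)
  # threshold rule on a constructed weight vector
  model$score_weights <- setNames(c(0.02, -0.011, 0.009),
                                  colnames(lib$scores))
  s <- simplify_stack(model, lib, covs, y, threshold = 0.01, seed = 5)
  expect_setequal(s$selected_tags, c("s01", "s02"))
  expect_true("simplified" %in% s$flags)

  model$score_weights[] <- c(0.005, -0.002, 0.001)
  s0 <- simplify_stack(model, lib, covs, y, threshold = 0.01, seed = 5)
  expect_true("empty_selection" %in% s0$flags)
  expect_equal(s0$kind, "covariates_only")
})

test_that("the simplified stack predicts like the full stack on a sparse truth", {
  set.seed(12)
  n <- 4000
  lib <- random_library(n, 50, seed = 12)
  covs <- toy_covariates(n, seed = 1000 + 12)
  y <- as.numeric(lib$scores[, 1:3] %*% c(0.4, 0.35, 0.3)) + rnorm(n)
  tr <- 1:3000; te <- 3001:4000
  lib_tr <- lib; lib_tr$scores <- lib$scores[tr, ]
  lib_te <- lib; lib_te$scores <- lib$scores[te, ]
  full <- fit_lasso_stack(lib_tr, covs[tr, ], y[tr], seed = 6)
  simp <- simplify_stack(full, lib_tr, covs[tr, ], y[tr], seed = 6)
  r2f <- r2_linear(predict(full, lib_te, covs[te, ]), y[te])
  r2s <- r2_linear(predict(simp, lib_te, covs[te, ]), y[te])
  expect_lt(abs(r2f - r2s), 0.03)
})

test_that("stack models serialize to JSON with their nonzero weights", {
  n <- 500
  lib <- random_library(n, 5, seed = 13)
  covs <- toy_covariates(n, seed = 1000 + 13)
  set.seed(13)
  y <- lib$scores[, 2] + rnorm(n)
  m <- fit_lasso_stack(lib, covs, y, seed = 7)
  path <- file.path(tempfile("mod"), "model.json")
  dir.create(dirname(path))
  write_stack_model(m, path)
  desc <- jsonlite::fromJSON(path)
  expect_equal(desc$kind, "lasso")
  expect_true("s02" %in% names(desc$score_weights))
})
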