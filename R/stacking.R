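#' Fit a covariates-only base model
#'
#' Unregularized generalized linear fit (logistic for binary outcomes,
#' ordinary least squares for continuous) of the outcome on the covariates.
#' Used as the baseline whose variance explained is subtracted in the
#' adjusted R2, and as the stage-1 input of the mixed stack. On (quasi-)
#' separation the fit falls back to a tiny-ridge penalized fit and is
#' flagged.
#'
#' @param covariates data.frame or matrix of covariates (no missing values).
#' @param y outcome vector (binary 0/1 or continuous).
#' @param family `"auto"`, `"binomial"` or `"gaussian"`.
#' @return a `stack_model` of kind `"covariates_only"`.
#' @export
fit_covariate_base <- function(covariates, y, family = "auto") {
  X <- as.matrix(covariates)
  stopifnot(!anyNA(X), !anyNA(y), nrow(X) == length(y))
  family <- resolve_family(y, family)
  flagged <- FALSE
  if (family == "binomial") {
    fit <- suppressWarnings(glm(y ~ X, family = binomial()))
    sep <- !fit$converged || any(abs(coef(fit)[-1]) > 20, na.rm = TRUE) ||
      anyNA(coef(fit))
    if (sep) {
      flagged <- TRUE
      rfit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                             lambda = 1e-4, standardize = FALSE)
      beta <- c(as.numeric(rfit$a0), as.numeric(rfit$beta))
    } else beta <- unname(coef(fit))
  } else {
    fit <- lm(y ~ X)
    beta <- unname(coef(fit))
    if (anyNA(beta)) { beta[is.na(beta)] <- 0; flagged <- TRUE }
  }
  new_stack_model(kind = "covariates_only", family = family,
                  intercept = beta[1],
                  cov_weights = setNames(beta[-1], colnames(X)),
                  score_weights = numeric(0),
                  flags = if (flagged) "ridge_fallback" else character(0))
}

resolve_family <- function(y, family) {
  if (family != "auto") return(family)
  if (all(y %in% c(0, 1))) "binomial" else "gaussian"
}

new_stack_model <- function(kind, family, intercept = 0,
                            cov_weights = numeric(0),
                            score_weights = numeric(0), booster = NULL,
                            stage1 = NULL, lambda = NA_real_,
                            flags = character(0), seed = NA_integer_) {
  structure(list(kind = kind, family = family, intercept = intercept,
                 cov_weights = cov_weights, score_weights = score_weights,
                 booster = booster, stage1 = stage1, lambda = lambda,
                 flags = flags, seed = seed),
            class = "stack_model")
}

#' Stack library scores and covariates with L1-penalized regression
#'
#' The multi-PGS linear model: an elastic-net fit (default pure lasso,
#' `alpha = 1`) over the standardized library scores plus the covariates,
#' with the covariates exempted from shrinkage via a penalty factor of 0
#' (scores get penalty factor 1). The penalty level is chosen by internal
#' cross-validation on the training data (binomial deviance for binary
#' outcomes, MSE for continuous), minimum-deviance rule. An all-zero score
#' weight vector is a valid outcome.
#'
#' @param library a `score_library` (columns standardized) or a plain
#'   numeric matrix of scores.
#' @param covariates data.frame/matrix of covariates.
#' @param y outcome.
#' @param family `"auto"`, `"binomial"` or `"gaussian"`.
#' @param alpha elastic-net mixing (1 = lasso, default).
#' @param inner_folds folds for the internal lambda CV (default 10).
#' @param penalty_grid optional lambda sequence.
#' @param seed integer seed (controls the internal CV fold split).
#' @return a `stack_model` of kind `"lasso"` with sparse `score_weights` and
#'   dense `cov_weights`.
#' @export
fit_lasso_stack <- function(library, covariates, y, family = "auto",
                            alpha = 1, inner_folds = 10, penalty_grid = NULL,
                            seed = 1) {
  S <- library_matrix(library)
  C <- as.matrix(covariates)
  stopifnot(nrow(S) == length(y), nrow(C) == length(y))
  family <- resolve_family(y, family)
  X <- cbind(C, S)
  pf <- c(rep(0, ncol(C)), rep(1, ncol(S)))
  cvfit <- with_seed(seed, glmnet::cv.glmnet(
    X, y, family = family, alpha = alpha, penalty.factor = pf,
    nfolds = inner_folds, lambda = penalty_grid, standardize = FALSE,
    type.measure = if (family == "binomial") "deviance" else "mse"))
  beta <- as.numeric(coef(cvfit, s = "lambda.min"))
  new_stack_model(kind = "lasso", family = family, intercept = beta[1],
                  cov_weights = setNames(beta[2:(1 + ncol(C))], colnames(C)),
                  score_weights = setNames(beta[-(1:(1 + ncol(C)))],
                                           colnames(S)),
                  lambda = cvfit$lambda.min, seed = seed)
}

library_matrix <- function(library) {
  if (inherits(library, "score_library")) library$scores
  else {
    stopifnot(is.matrix(library))
    library
  }
}

#' Stack library scores and covariates with gradient-boosted trees
#'
#' The non-linear multi-PGS: xgboost over \[scores + covariates\] with the
#' stated defaults `eta = 0.01`, `nrounds = 10`; logistic objective for
#' binary outcomes, squared error for continuous. Single-threaded for
#' reproducibility.
#'
#' @inheritParams fit_lasso_stack
#' @param eta learning rate.
#' @param nrounds boosting rounds.
#' @param covariates_only fit on covariates alone (used by the mixed model).
#' @return a `stack_model` of kind `"xgboost"`.
#' @export
fit_xgb_stack <- function(library, covariates, y, family = "auto",
                          eta = 0.01, nrounds = 10, seed = 1,
                          covariates_only = FALSE) {
  C <- as.matrix(covariates)
  X <- if (covariates_only) C else cbind(C, library_matrix(library))
  stopifnot(nrow(X) == length(y))
  family <- resolve_family(y, family)
  obj <- if (family == "binomial") "binary:logistic" else "reg:squarederror"
  dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y), nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(eta = eta, objective = obj, nthread = 1,
                  seed = child_seed(seed, 0L)),
    data = dtrain, nrounds = nrounds, verbose = 0)
  new_stack_model(kind = "xgboost", family = family, booster = booster,
                  cov_weights = setNames(numeric(ncol(C)), colnames(C)),
                  score_weights = numeric(0), seed = seed)
}

#' Mixed stack: non-linear covariates, linear scores
#'
#' Stage 1 fits gradient-boosted trees on the covariates only; stage 2 runs
#' the lasso stack over the library scores (penalty 1) plus the stage-1 risk
#' score (penalty 0). Captures non-linear covariate structure (e.g. a
#' sex-by-age interaction) while keeping the PGS combination linear and
#' interpretable. The stage-1 risk entering stage 2 is cross-fitted
#' (out-of-fold over `cf_folds` internal folds) so the lasso never sees
#' in-sample boosted predictions, which would otherwise be overweighted;
#' the stage-1 model kept for prediction time is refitted on all rows.
#'
#' @inheritParams fit_lasso_stack
#' @param eta,nrounds stage-1 xgboost settings.
#' @param cf_folds internal folds for cross-fitting the stage-1 risk.
#' @return a `stack_model` of kind `"mixed"` (stage-1 booster stored in
#'   `$stage1`).
#' @export
fit_mixed_stack <- function(library, covariates, y, family = "auto",
                            alpha = 1, eta = 0.01, nrounds = 10,
                            inner_folds = 10, cf_folds = 5, seed = 1) {
  family <- resolve_family(y, family)
  stage1 <- fit_xgb_stack(NULL, covariates, y, family = family, eta = eta,
                          nrounds = nrounds, seed = child_seed(seed, 3L),
                          covariates_only = TRUE)
  n <- length(y)
  cf <- make_folds(n, k = cf_folds,
                   y = if (family == "binomial") y else NULL,
                   seed = child_seed(seed, 4L))
  risk1 <- numeric(n)
  for (f in seq_len(cf_folds)) {
    trf <- which(cf != f)
    m_f <- fit_xgb_stack(NULL, covariates[trf, , drop = FALSE], y[trf],
                         family = family, eta = eta, nrounds = nrounds,
                         seed = child_seed(seed, 30L + f),
                         covariates_only = TRUE)
    risk1[cf == f] <- predict(m_f, library = NULL,
                              covariates = covariates[cf == f, ,
                                                      drop = FALSE])
  }
  risk_full <- predict(stage1, library = NULL, covariates = covariates)
  if (sd(risk_full) < 1e-12) {
    # degenerate stage 1: reduces to a lasso stack without covariates
    S <- library_matrix(library)
    m <- fit_lasso_stack(S, matrix(1, nrow(S), 1,
                                   dimnames = list(NULL, "const")), y,
                         family = family, alpha = alpha,
                         inner_folds = inner_folds, seed = seed)
    m$kind <- "mixed"; m$stage1 <- stage1
    m$flags <- c(m$flags, "constant_stage1")
    return(m)
  }
  m <- fit_lasso_stack(library, data.frame(xgb_cov = risk1), y,
                       family = family, alpha = alpha,
                       inner_folds = inner_folds, seed = seed)
  m$kind <- "mixed"
  m$stage1 <- stage1
  m
}

#' Simplify a fitted lasso stack to its large-weight scores
#'
#' Keeps the scores with `|weight| > threshold` (default 0.01) and refits the
#' lasso on that subset plus the covariates. With an empty selection the
#' covariates-only model is returned, flagged.
#'
#' @param model a fitted `stack_model` of kind `"lasso"`.
#' @param library,covariates,y the training data the model was fitted on.
#' @param threshold absolute-weight cutoff.
#' @param seed seed for the refit's internal CV.
#' @return a `stack_model` (kind `"lasso"`, flag `"simplified"`), with
#'   `$selected_tags`.
#' @export
simplify_stack <- function(model, library, covariates, y, threshold = 0.01,
                           seed = 1) {
  stopifnot(inherits(model, "stack_model"), model$kind == "lasso")
  sel <- names(model$score_weights)[abs(model$score_weights) > threshold]
  if (!length(sel)) {
    out <- fit_covariate_base(covariates, y, family = model$family)
    out$flags <- c(out$flags, "simplified", "empty_selection")
    out$selected_tags <- character(0)
    return(out)
  }
  S <- library_matrix(library)[, sel, drop = FALSE]
  out <- fit_lasso_stack(S, covariates, y, family = model$family, seed = seed)
  out$flags <- c(out$flags, "simplified")
  out$selected_tags <- sel
  out
}

#' Predict from a stack model
#'
#' Pure function of (model, features). For binary families the prediction is
#' the response-scale probability; continuous families return the linear
#' predictor.
#'
#' @param object a `stack_model`.
#' @param library a `score_library`/matrix aligned with training columns
#'   (ignored for covariates-only kind).
#' @param covariates covariate data.frame/matrix.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.stack_model <- function(object, library = NULL, covariates, ...) {
  C <- as.matrix(covariates)
  link <- switch(
    object$kind,
    covariates_only = object$intercept +
      as.numeric(C[, names(object$cov_weights), drop = FALSE] %*%
                   object$cov_weights),
    lasso = {
      S <- library_matrix(library)[, names(object$score_weights),
                                   drop = FALSE]
      object$intercept +
        as.numeric(C[, names(object$cov_weights), drop = FALSE] %*%
                     object$cov_weights) +
        as.numeric(S %*% object$score_weights)
    },
    mixed = {
      S <- library_matrix(library)[, names(object$score_weights),
                                   drop = FALSE]
      cov_part <- if ("xgb_cov" %in% names(object$cov_weights)) {
        risk1 <- predict(object$stage1, library = NULL, covariates = C)
        object$cov_weights[["xgb_cov"]] * risk1
      } else sum(object$cov_weights)  # degenerate stage 1: constant column
      object$intercept + cov_part + as.numeric(S %*% object$score_weights)
    },
    xgboost = {
      X <- if (is.null(library)) C else cbind(C, library_matrix(library))
      return(as.numeric(predict(object$booster, X)))
    },
    stop("unknown model kind: ", object$kind))
  if (object$family == "binomial") 1 / (1 + exp(-link)) else link
}

#' @exportS3Method base::print
print.stack_model <- function(x, ...) {
  nz <- sum(abs(x$score_weights) > 0)
  cat(sprintf("Stack model [%s, %s]: %d covariate(s), %d/%d nonzero score weight(s)\n",
              x$kind, x$family, length(x$cov_weights), nz,
              length(x$score_weights)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.stack_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$cov_weights,
    object$score_weights)
}

#' @exportS3Method base::summary
summary.stack_model <- function(object, ...) {
  sw <- object$score_weights
  top <- head(sw[order(-abs(sw))], 10)
  cat(sprintf("Stack model (%s, %s family)\n", object$kind, object$family))
  cat(sprintf("  nonzero score weights: %d of %d\n",
              sum(abs(sw) > 0), length(sw)))
  if (length(top)) {
    cat("  top |weight| scores:\n")
    for (i in seq_along(top))
      cat(sprintf("    %-20s % .4f\n", names(top)[i], top[i]))
  }
  invisible(object)
}

#' Serialize a linear stack model to JSON (tree kinds get a sidecar blob)
#'
#' @param model a `stack_model`.
#' @param path output `.json` path.
#' @return the path, invisibly.
#' @export
write_stack_model <- function(model, path) {
  desc <- list(kind = model$kind, family = model$family,
               intercept = model$intercept,
               cov_weights = as.list(model$cov_weights),
               score_weights = as.list(
                 model$score_weights[abs(model$score_weights) > 0]),
               lambda = model$lambda, flags = model$flags)
  if (model$kind %in% c("xgboost", "mixed")) {
    blob <- sub("\\.json$", ".xgb.bin", path)
    booster <- if (model$kind == "xgboost") model$booster
    else model$stage1$booster
    xgboost::xgb.save(booster, blob)
    desc$booster_file <- basename(blob)
  }
  writeLines(jsonlite::toJSON(desc, auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}
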