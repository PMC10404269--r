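#' Cross-validation fold assignment
#'
#' Deterministic k-fold partition given a seed; fold sizes differ by at most
#' one, and binary outcomes are stratified by case status so every fold sees
#' cases.
#'
#' @param n_ind number of individuals.
#' @param k number of folds (default 5).
#' @param y optional binary outcome for stratification.
#' @param seed integer seed.
#' @return integer vector of fold ids in 1..k.
#' @export
make_folds <- function(n_ind, k = 5, y = NULL, seed = 1) {
  stopifnot(n_ind >= k)
  with_seed(seed, {
    fold <- integer(n_ind)
    if (!is.null(y) && all(y %in% c(0, 1))) {
      if (sum(y == 1) < k || sum(y == 0) < k)
        stop("fewer cases (or controls) than folds")
      for (cls in c(0, 1)) {
        idx <- sample(which(y == cls))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold[sample.int(n_ind)] <- rep_len(seq_len(k), n_ind)
    }
    fold
  })
}

#' Covariate-adjusted variance explained
#'
#' `R2_adjusted = (R2_full - R2_cov) / (1 - R2_cov)`: the variance explained
#' by the full model after accounting for the covariates-only base model.
#'
#' @param r2_full,r2_cov observed-scale R2 of the full and base models.
#' @return adjusted R2.
#' @examples adjusted_r2(0.2, 0.1) # 0.1111...
#' @export
adjusted_r2 <- function(r2_full, r2_cov) {
  if (any(r2_cov >= 1)) stop("r2_cov = 1 leaves no variance to explain")
  bad <- r2_cov > r2_full
  if (any(bad)) {
    warning("r2_cov > r2_full; clamping to zero adjusted R2")
    r2_cov[bad] <- r2_full[bad]
  }
  (r2_full - r2_cov) / (1 - r2_cov)
}

#' Convert observed-scale R2 to the liability scale
#'
#' The ascertainment-corrected transformation for case-control data: with
#' threshold \eqn{t = \Phi^{-1}(1-K)}, \eqn{z = \phi(t)}, \eqn{m = z/K},
#' \eqn{C = K^2(1-K)^2 / (z^2 P(1-P))} and
#' \eqn{\theta = m (P-K)/(1-K) \, (m (P-K)/(1-K) - t)}:
#' \deqn{R^2_{liab} = C R^2_{obs} / (1 + C \theta R^2_{obs})}
#' where K is the population prevalence and P the sample case proportion.
#' With P = K (no ascertainment) \eqn{\theta = 0} and the formula reduces to
#' \eqn{C R^2_{obs}}.
#'
#' @param r2_obs observed-scale R2 from a linear regression of the 0/1
#'   outcome on the predictor.
#' @param K population prevalence in (0,1).
#' @param P sample case proportion in (0,1).
#' @return liability-scale R2.
#' @export
liability_r2 <- function(r2_obs, K, P) {
  stopifnot_scalar_prob(K, "K")
  stopifnot_scalar_prob(P, "P")
  t <- qnorm(1 - K)
  z <- dnorm(t)
  mz <- z / K
  C <- K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
  theta <- mz * (P - K) / (1 - K) * (mz * (P - K) / (1 - K) - t)
  C * r2_obs / (1 + C * theta * r2_obs)
}

#' Observed-scale R2 of a predictor
#'
#' Squared correlation from a linear regression of the outcome on the
#' predictor (the convention required by the liability conversion, applied
#' even to predictors trained with logistic loss). Returns 0 for a constant
#' predictor.
#'
#' @param pred predictor values.
#' @param y outcome.
#' @return R2 in \[0,1\].
#' @export
r2_linear <- function(pred, y) {
  if (sd(pred) < 1e-12 || sd(y) < 1e-12) return(0)
  cor(pred, y)^2
}

#' Rank-based AUC
#'
#' Mann-Whitney AUC: the probability a random case outranks a random
#' control, ties counted half.
#'
#' @param risk_score numeric scores.
#' @param y binary outcome (both classes present).
#' @return AUC in \[0,1\].
#' @export
auc <- function(risk_score, y) {
  stopifnot(all(y %in% c(0, 1)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(risk_score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Quintile log odds ratios versus the middle quintile
#'
#' Individuals are binned into quintiles of the (out-of-sample) risk score;
#' a logistic regression of the outcome on quintile indicators (reference:
#' 3rd quintile) plus covariates gives per-quintile log-ORs with standard
#' errors. A quintile with an empty case or control cell gets an infinite
#' estimate and is flagged (`degenerate`), its CI undefined.
#'
#' @param risk_score out-of-sample risk score.
#' @param y binary outcome.
#' @param covariates optional covariate data.frame/matrix.
#' @param reference `"middle"` (the 3rd quintile) or a quintile index 1-5.
#' @param n_groups number of score bins (default 5).
#' @return data.frame: quintile, log_or, se, ci_low, ci_high, degenerate.
#' @export
quintile_or <- function(risk_score, y, covariates = NULL,
                        reference = "middle", n_groups = 5) {
  stopifnot(all(y %in% c(0, 1)))
  ref <- if (identical(reference, "middle")) ceiling(n_groups / 2)
  else as.integer(reference)
  # stable rank-based binning; ties broken by original order
  rk <- rank(risk_score, ties.method = "first")
  q <- as.integer(cut(rk, breaks = quantile(rk, probs = seq(0, 1,
                                                            1 / n_groups)),
                      include.lowest = TRUE))
  qf <- factor(q, levels = c(ref, setdiff(seq_len(n_groups), ref)))
  degen <- vapply(seq_len(n_groups), function(g) {
    length(unique(y[q == g])) < 2
  }, logical(1))
  X <- if (is.null(covariates)) NULL else as.matrix(covariates)
  fit <- if (is.null(X)) suppressWarnings(glm(y ~ qf, family = binomial()))
  else suppressWarnings(glm(y ~ qf + X, family = binomial()))
  cf <- summary(fit)$coefficients
  out <- data.frame(quintile = seq_len(n_groups), log_or = 0, se = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_,
                    degenerate = degen)
  for (g in setdiff(seq_len(n_groups), ref)) {
    nm <- paste0("qf", g)
    if (nm %in% rownames(cf)) {
      out$log_or[g] <- cf[nm, 1]
      out$se[g] <- cf[nm, 2]
    }
  }
  out$log_or[degen & out$quintile != ref] <-
    ifelse(vapply(which(degen & out$quintile != ref), function(g)
      all(y[q == g] == 1), logical(1)), Inf, -Inf)
  ok <- !out$degenerate & out$quintile != ref
  out$ci_low[ok] <- out$log_or[ok] - 1.96 * out$se[ok]
  out$ci_high[ok] <- out$log_or[ok] + 1.96 * out$se[ok]
  attr(out, "reference") <- ref
  out
}

#' Percentile bootstrap confidence interval
#'
#' Resamples individuals with replacement `B` times, recomputes the
#' statistic, and returns the 2.5/97.5 percentile bounds around the
#' point estimate computed on the original data.
#'
#' @param data vector, matrix or data.frame of per-individual contributions
#'   (rows resampled).
#' @param stat_fn function of the resampled data returning a scalar.
#' @param B bootstrap replicates (default 10000).
#' @param seed integer seed.
#' @return list: `point`, `lo`, `hi`, `B`.
#' @export
bootstrap_ci <- function(data, stat_fn, B = 10000, seed = 1) {
  stopifnot(B >= 100)
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  take <- if (is.null(dim(data))) function(i) data[i]
  else function(i) data[i, , drop = FALSE]
  point <- stat_fn(data)
  stats <- with_seed(seed, vapply(seq_len(B), function(b) {
    stat_fn(take(sample.int(n, n, replace = TRUE)))
  }, numeric(1)))
  qs <- quantile(stats, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  list(point = point, lo = qs[1], hi = qs[2], B = B)
}

#' Recode two comorbid binary phenotypes as a case-case outcome
#'
#' Individuals with both disorders are excluded, as are controls of both;
#' A-only cases become 1, B-only cases become 0.
#'
#' @param pheno_A,pheno_B binary vectors on the same individuals.
#' @return list: `y` (0/1 vector on the retained individuals), `mask`
#'   (logical vector over the input individuals).
#' @export
recode_case_case <- function(pheno_A, pheno_B) {
  stopifnot(length(pheno_A) == length(pheno_B),
            all(pheno_A %in% c(0, 1)), all(pheno_B %in% c(0, 1)))
  mask <- xor(pheno_A == 1, pheno_B == 1)
  y <- pheno_A[mask]
  if (!any(y == 1) || !any(y == 0))
    stop("case-case recoding left a class empty")
  list(y = y, mask = mask)
}

#' Cross-validated evaluation of stacking models
#'
#' The evaluation loop: for each of `k` folds, the library is restandardized
#' on the training individuals, the requested models are fitted on the
#' training fold (including internal penalty selection), and test-fold
#' predictions are collected. Pooled out-of-sample predictions yield, per
#' model: observed-scale and liability-scale covariate-adjusted R2, AUC,
#' top-vs-middle quintile log-OR, and percentile bootstrap CIs for the
#' adjusted R2. The covariates-only base model is always fitted per fold for
#' the adjustment.
#'
#' @param library a `score_library`.
#' @param covariates covariate data.frame.
#' @param y outcome (binary 0/1 or continuous).
#' @param model_kinds subset of `c("lasso", "xgboost", "mixed")`; single
#'   library columns can be evaluated with [single_score_model()] passed via
#'   `extra_predictors`.
#' @param K_prevalence population prevalence for the liability conversion
#'   (binary outcomes; `NA` skips the conversion).
#' @param k number of folds.
#' @param B bootstrap replicates for the CIs (default 10000).
#' @param extra_predictors named list of functions
#'   `function(library_train_std, covariates, y, train_idx, test_idx)` that
#'   return test-fold predictions for additional baseline predictors (e.g. a
#'   single score or an externally weighted index).
#' @param leakage_safe standardize scores on the training fold only
#'   (default TRUE); FALSE reproduces whole-sample standardization.
#' @param seed integer seed (folds, model seeds, bootstraps).
#' @return `eval_report`: list with `table` (one row per model: r2_full,
#'   r2_cov, r2_adj_obs, r2_adj_liab, auc, top_or, CIs), `folds`,
#'   `predictions` (pooled out-of-sample), `quintiles` (per model),
#'   `models_by_fold`, `K`, `P`.
#' @export
cv_evaluate <- function(library, covariates, y,
                        model_kinds = c("lasso"),
                        K_prevalence = NA, k = 5, B = 10000,
                        extra_predictors = list(), leakage_safe = TRUE,
                        seed = 1) {
  n <- length(y)
  binary <- all(y %in% c(0, 1))
  folds <- make_folds(n, k = k, y = if (binary) y else NULL,
                      seed = child_seed(seed, 1L))
  model_names <- c(model_kinds, names(extra_predictors))
  preds <- matrix(NA_real_, n, length(model_names) + 1,
                  dimnames = list(NULL, c("covariates_only", model_names)))
  models_by_fold <- vector("list", k)

  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    lib_f <- if (leakage_safe) standardize_library(library, tr) else library
    cov_tr <- covariates[tr, , drop = FALSE]
    cov_te <- covariates[te, , drop = FALSE]
    lib_tr <- lib_f; lib_tr$scores <- lib_f$scores[tr, , drop = FALSE]
    lib_te <- lib_f; lib_te$scores <- lib_f$scores[te, , drop = FALSE]
    fitted <- list()

    base <- fit_covariate_base(cov_tr, y[tr])
    preds[te, "covariates_only"] <- predict(base, covariates = cov_te)
    fitted$covariates_only <- base

    for (kind in model_kinds) {
      mseed <- child_seed(seed, 10L * f + match(kind, model_kinds))
      mod <- switch(kind,
                    lasso = fit_lasso_stack(lib_tr, cov_tr, y[tr],
                                            seed = mseed),
                    xgboost = fit_xgb_stack(lib_tr, cov_tr, y[tr],
                                            seed = mseed),
                    mixed = fit_mixed_stack(lib_tr, cov_tr, y[tr],
                                            seed = mseed),
                    stop("unknown model kind: ", kind))
      preds[te, kind] <- predict(mod, library = lib_te, covariates = cov_te)
      fitted[[kind]] <- mod
    }
    for (nm in names(extra_predictors)) {
      preds[te, nm] <- extra_predictors[[nm]](lib_f, covariates, y, tr, te)
    }
    models_by_fold[[f]] <- fitted
  }

  P <- if (binary) mean(y) else NA_real_
  rows <- list(); quints <- list()
  r2_cov <- r2_linear(preds[, "covariates_only"], y)
  for (nm in model_names) {
    p <- preds[, nm]
    r2_full <- r2_linear(p, y)
    r2_adj <- adjusted_r2(r2_full, min(r2_cov, r2_full))
    if (binary && !is.na(K_prevalence)) {
      r2_full_l <- liability_r2(r2_full, K_prevalence, P)
      r2_cov_l <- liability_r2(min(r2_cov, r2_full), K_prevalence, P)
      r2_adj_liab <- adjusted_r2(r2_full_l, r2_cov_l)
    } else r2_adj_liab <- NA_real_
    ci <- bootstrap_ci(cbind(p = p, c = preds[, "covariates_only"], y = y),
                       function(d) adjusted_r2(
                         r2_linear(d[, "p"], d[, "y"]),
                         min(r2_linear(d[, "c"], d[, "y"]),
                             r2_linear(d[, "p"], d[, "y"]))),
                       B = B, seed = child_seed(seed, 500L + match(nm, model_names)))
    top_or <- NA_real_
    if (binary) {
      qt <- quintile_or(p, y, covariates = covariates)
      quints[[nm]] <- qt
      top_or <- qt$log_or[nrow(qt)]
    }
    rows[[nm]] <- data.frame(
      model = nm, r2_full = r2_full, r2_cov = r2_cov,
      r2_adj_obs = r2_adj, r2_adj_obs_lo = ci$lo, r2_adj_obs_hi = ci$hi,
      r2_adj_liab = r2_adj_liab,
      auc = if (binary) auc(p, y) else NA_real_,
      top_log_or = top_or, stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 folds = folds, predictions = preds, quintiles = quints,
                 models_by_fold = models_by_fold,
                 K = K_prevalence, P = P, n = n,
                 n_cases = if (binary) sum(y) else NA_integer_,
                 seed = seed),
            class = "eval_report")
}

#' Helper: single-score baseline predictor for [cv_evaluate()]
#'
#' Returns an extra-predictor function that predicts from one library column
#' plus covariates with an unpenalized GLM, the "single GWAS PGS" reference.
#'
#' @param tag library column name.
#' @return function usable in `extra_predictors`.
#' @export
single_score_model <- function(tag) {
  function(lib, covariates, y, tr, te) {
    S <- lib$scores[, tag, drop = FALSE]
    df_tr <- data.frame(covariates[tr, , drop = FALSE], score = S[tr, 1])
    base <- fit_covariate_base(df_tr, y[tr])
    df_te <- data.frame(covariates[te, , drop = FALSE], score = S[te, 1])
    predict(base, covariates = df_te)
  }
}

#' @exportS3Method base::print
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation report: n = %d%s, %d-fold CV\n", x$n,
              if (!is.na(x$n_cases)) sprintf(" (%d cases, P = %.3g)",
                                             x$n_cases, x$P) else "",
              max(x$folds)))
  if (!is.na(x$K)) cat(sprintf("  liability conversion with K = %g\n", x$K))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report as JSON plus a tidy TSV
#'
#' @param report an `eval_report`.
#' @param dir output directory.
#' @return dir, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(jsonlite::toJSON(list(
    table = report$table, K = report$K, P = report$P, n = report$n,
    n_cases = report$n_cases), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", na = "null"),
    file.path(dir, "eval_report.json"))
  long <- do.call(rbind, lapply(seq_len(nrow(report$table)), function(i) {
    r <- report$table[i, ]
    stats <- setdiff(names(r), "model")
    data.frame(model = r$model, statistic = stats,
               value = as.numeric(r[stats]), stringsAsFactors = FALSE)
  }))
  write.table(long, file.path(dir, "eval_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (length(report$quintiles)) {
    qt <- do.call(rbind, lapply(names(report$quintiles), function(nm)
      data.frame(model = nm, report$quintiles[[nm]])))
    write.table(qt, file.path(dir, "quintile_or.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
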