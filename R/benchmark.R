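#' Selection-index weights for a multi-trait summary-statistics predictor
#'
#' The wMT-SBLUP-style index: each standardized per-trait score enters with a
#' weight derived only from GWAS sample sizes, SNP-heritabilities and genetic
#' correlations — no individual-level tuning. The expected squared accuracy
#' of score i for its own trait is
#' \eqn{r_i^2 = h_i^2 / (1 + M_e / (n_i h_i^2))} with \eqn{M_e} the effective
#' number of independent markers. For standardized scores the index solves
#' \eqn{w = V^{-1} c} with \eqn{V_{ii} = 1},
#' \eqn{V_{ij} = r_g(i,j) r_i r_j} and
#' \eqn{c_i = r_g(i, T) r_i \sqrt{h_T^2}}. All intermediates are returned
#' for audit.
#'
#' @param params list/data.frame with per-trait `h2` and `n_gwas`, plus `rg`
#'   (trait x trait matrix) and optionally `M_e` (default 60000) and trait
#'   `tags`.
#' @param target_trait index (or tag) of the target trait.
#' @return list: `weights` (named vector over traits), `r2` (expected
#'   per-score accuracies), `V`, `c`, `M_e`, `pseudo_inverse` flag.
#' @export
wmt_weights <- function(params, target_trait) {
  h2 <- params$h2; n <- params$n_gwas
  rg <- params$rg; M_e <- params$M_e %||% 60000
  tags <- params$tags %||% paste0("trait", seq_along(h2))
  if (is.character(target_trait)) target_trait <- match(target_trait, tags)
  stopifnot(length(h2) == length(n), nrow(rg) == length(h2),
            target_trait >= 1, target_trait <= length(h2))
  if (h2[target_trait] <= 0) stop("target trait must have h2 > 0")
  r2 <- ifelse(h2 > 0, h2 / (1 + M_e / (n * pmax(h2, 1e-12))), 0)
  r <- sqrt(r2)
  V <- rg * outer(r, r)
  diag(V) <- 1
  cvec <- rg[, target_trait] * r * sqrt(h2[target_trait])
  pinv <- FALSE
  w <- tryCatch(solve(V, cvec), error = function(e) {
    pinv <<- TRUE
    sv <- svd(V)
    pos <- sv$d > max(sv$d) * 1e-10
    sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% cvec) / sv$d[pos])
  })
  w <- as.numeric(w)
  # a trait uncorrelated with the target and with every other trait cannot
  # carry information; zero it exactly to avoid numeric dust
  iso <- abs(rg[, target_trait]) < 1e-12 &
    vapply(seq_along(h2), function(i)
      all(abs(rg[i, -i]) < 1e-12), logical(1))
  w[iso & seq_along(w) != target_trait] <- 0
  list(weights = setNames(w, tags), r2 = setNames(r2, tags), V = V, c = cvec,
       M_e = M_e, target = tags[target_trait], pseudo_inverse = pinv)
}

#' Apply selection-index weights to standardized library scores
#'
#' @param library_scores matrix of standardized scores (columns named by
#'   trait tag) or a `score_library`.
#' @param weights named weight vector from [wmt_weights()] (or the full
#'   return value).
#' @return per-individual index score.
#' @export
wmt_predict <- function(library_scores, weights) {
  if (is.list(weights) && !is.null(weights$weights))
    weights <- weights$weights
  S <- library_matrix(library_scores)
  miss <- setdiff(names(weights), colnames(S))
  if (length(miss)) stop("scores missing from library: ",
                         paste(miss, collapse = ", "))
  as.numeric(S[, names(weights), drop = FALSE] %*% weights)
}

#' BLUP polygenic score from individual-level genotypes
#'
#' Exact ridge regression on standardized dosages — the infinitesimal-model
#' best linear unbiased predictor — with penalty
#' \eqn{\lambda = M (1-h^2)/(n h^2)}. When `h2_hint` is missing it is chosen
#' by cross-validation over a small grid. The dual (n x n kernel) solver is
#' used when n < M. Out-of-fold scores are returned so the evaluation stays
#' out-of-sample.
#'
#' @param cohort a `cohort_data` (or any object with `dosages` and `maf`).
#' @param y outcome for training (length n).
#' @param h2_hint assumed h2 for the penalty; `NULL` triggers the grid.
#' @param folds integer fold assignment (from [make_folds()]); scores for
#'   fold f are predicted by a model trained on the complement.
#' @param intercept_covariates optional covariates regressed out of y before
#'   the ridge fit (per training fold).
#' @return list: `scores` (out-of-fold per-individual), `effects`
#'   (per-variant standardized effects from the full-data fit), `h2_used`,
#'   `lambda`.
#' @export
blup_pgs <- function(cohort, y, h2_hint = NULL, folds = NULL,
                     intercept_covariates = NULL) {
  Xs <- standardized_dosages(cohort)
  n <- nrow(Xs); M <- ncol(Xs)
  stopifnot(length(y) == n)
  if (is.null(folds)) folds <- make_folds(n, 5, seed = 1)
  if (any(table(folds) < 2) || n < 2) stop("need at least 2 per fold")

  ridge_fit <- function(Xtr, ytr, lambda) {
    yc <- ytr - mean(ytr)
    if (nrow(Xtr) < ncol(Xtr)) {
      K <- tcrossprod(Xtr)
      alpha <- solve(K + lambda * diag(nrow(Xtr)), yc)
      as.numeric(crossprod(Xtr, alpha))
    } else {
      as.numeric(solve(crossprod(Xtr) + lambda * diag(ncol(Xtr)),
                       crossprod(Xtr, yc)))
    }
  }
  lambda_of <- function(h2, n_tr) M * (1 - h2) / (n_tr * h2)

  resid_y <- function(idx) {
    if (is.null(intercept_covariates)) return(y[idx])
    C <- as.matrix(intercept_covariates)[idx, , drop = FALSE]
    as.numeric(lm(y[idx] ~ C)$residuals)
  }

  if (is.null(h2_hint)) {
    grid <- c(0.05, 0.1, 0.2, 0.3, 0.5, 0.8)
    # pick h2 by correlation of out-of-fold scores with y
    perf <- vapply(grid, function(h2) {
      sc <- numeric(n)
      for (f in unique(folds)) {
        tr <- which(folds != f); te <- which(folds == f)
        b <- ridge_fit(Xs[tr, , drop = FALSE], resid_y(tr),
                       lambda_of(h2, length(tr)))
        sc[te] <- Xs[te, , drop = FALSE] %*% b
      }
      if (sd(sc) < 1e-12) 0 else cor(sc, y)
    }, numeric(1))
    h2_used <- grid[which.max(perf)]
  } else h2_used <- h2_hint

  scores <- numeric(n)
  for (f in unique(folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    b <- ridge_fit(Xs[tr, , drop = FALSE], resid_y(tr),
                   lambda_of(h2_used, length(tr)))
    scores[te] <- Xs[te, , drop = FALSE] %*% b
  }
  effects <- ridge_fit(Xs, resid_y(seq_len(n)), lambda_of(h2_used, n))
  list(scores = scores, effects = effects, h2_used = h2_used,
       lambda = lambda_of(h2_used, n), folds = folds)
}

#' Cross-trait LD-score regression slope as a genetic-correlation plug-in
#'
#' Thin estimator for pipeline completeness: regresses the z-score product
#' of two harmonized summary-statistics sets on the LD score; the slope
#' scaled by \eqn{M / \sqrt{n_1 n_2}} estimates the genetic covariance,
#' normalized by the single-trait LDSC h2 estimates.
#'
#' @param ss1,ss2 harmonized `sumstats` on the same panel (matched on
#'   `panel_index`).
#' @param panel the `ld_panel`.
#' @return list: `rg`, `gcov`, `h2_1`, `h2_2`.
#' @export
ldsc_rg <- function(ss1, ss2, panel) {
  d1 <- as.data.frame(ss1); d2 <- as.data.frame(ss2)
  common <- intersect(d1$panel_index, d2$panel_index)
  if (length(common) < 50) stop("need >= 50 overlapping variants")
  i1 <- match(common, d1$panel_index); i2 <- match(common, d2$panel_index)
  ell <- ld_scores(panel)[common]
  z1 <- d1$beta[i1] / d1$se[i1]; z2 <- d2$beta[i2] / d2$se[i2]
  n1 <- median(d1$n_eff); n2 <- median(d2$n_eff)
  M <- length(common)
  slope <- unname(coef(lm(I(z1 * z2) ~ ell))[2])
  gcov <- slope * M / sqrt(n1 * n2)
  h1 <- ldsc_h2(new_sumstats(d1[i1, ]), ell)$h2
  h2_ <- ldsc_h2(new_sumstats(d2[i2, ]), ell)$h2
  rg <- gcov / sqrt(h1 * h2_)
  list(rg = max(min(rg, 1), -1), gcov = gcov, h2_1 = h1, h2_2 = h2_)
}
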