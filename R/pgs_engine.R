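#' Per-variant LD scores from a panel
#'
#' \eqn{\ell_j = \sum_k r^2_{jk}} over the variant's block; includes the
#' self-correlation, so \eqn{\ell_j \ge 1}.
#'
#' @param panel an `ld_panel`.
#' @return numeric vector of length m.
#' @export
ld_scores <- function(panel) {
  out <- numeric(panel$m)
  for (b in panel$blocks) {
    out[b$from:b$to] <- rowSums(b$R^2)
  }
  out
}

#' SNP-heritability by LD-score regression
#'
#' Regresses per-variant chi-square statistics \eqn{(\beta_j/se_j)^2} on LD
#' scores with a free intercept; the slope times \eqn{M/n_{eff}} (median
#' n_eff across variants) estimates SNP-h2, clamped to \[0.001, 1\]. The
#' regression uses the standard heteroskedasticity weights
#' \eqn{1 / (\ell_j (1 + n h^2 \ell_j / M)^2)}, iterated from an initial
#' unweighted slope; per-variant chi-squares have variance growing with
#' their expectation, and the weights keep the estimator usable at small M.
#' Used to initialize the Gibbs sampler. With a degenerate design (all LD
#' scores equal) it falls back to the mean-chi-square estimator
#' \eqn{h^2 = (\bar{\chi^2} - 1) M / (n \bar\ell)} and flags it.
#'
#' @param sumstats harmonized `sumstats`.
#' @param ld_scores LD scores aligned with `sumstats` rows (e.g.
#'   `ld_scores(panel)[sumstats$panel_index]`).
#' @return list: `h2` (clamped), `slope`, `intercept`, `n_eff`,
#'   `fallback` (logical).
#' @export
ldsc_h2 <- function(sumstats, ld_scores) {
  ss <- as.data.frame(sumstats)
  stopifnot(nrow(ss) == length(ld_scores))
  if (nrow(ss) < 50) stop("need at least 50 variants for LD-score regression")
  chi2 <- (ss$beta / ss$se)^2
  n_eff <- median(ss$n_eff)
  M <- nrow(ss)
  fallback <- sd(ld_scores) < 1e-12
  if (fallback) {
    h2_raw <- (mean(chi2) - 1) * M / (n_eff * mean(ld_scores))
    slope <- NA_real_; intercept <- NA_real_
  } else {
    h2_w <- max(unname(coef(lm(chi2 ~ ld_scores))[2]) * M / n_eff, 0.01)
    for (it in 1:3) {
      pred <- 1 + n_eff * h2_w * ld_scores / M
      w <- 1 / (ld_scores * pmax(pred, 1)^2)
      fit <- lm(chi2 ~ ld_scores, weights = w)
      h2_w <- unname(coef(fit)[2]) * M / n_eff
    }
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    h2_raw <- h2_w
  }
  list(h2 = min(max(h2_raw, 0.001), 1), slope = slope,
       intercept = intercept, n_eff = n_eff, fallback = fallback,
       h2_raw = h2_raw)
}

#' Posterior-mean variant effects via multi-chain spike-and-slab Gibbs
#'
#' Runs the LDpred-auto-style sampler: each variant's residual marginal
#' effect is computed against the current effects through the block LD
#' matrices; the slab posterior has mean
#' `residual / (1 + M p / (n_eff h2))` and variance
#' `(1/n_eff) / (1 + M p / (n_eff h2))`; the inclusion probability comes from
#' the two-component Gaussian likelihood ratio; `p` is resampled from
#' `Beta(1 + #causal, 1 + M - #causal)` and `h2` recomputed as the quadratic
#' form `beta' R beta` over blocks. Chains start from a log-spaced grid of
#' `p` in \[1e-4, 0.9\] and the LDSC h2 estimate; a chain whose h2 trace
#' exceeds `max(dead_mult * h2_init, 1)` is marked dead. Post-burn-in
#' iterates are averaged per chain (Rao-Blackwellised over the conditional
#' means).
#'
#' The full-scale run configuration is 30 chains, 800 burn-in and 400
#' sampling iterations; the desk-scale default here is 10/200/100
#' (see the methods vignette).
#'
#' @param sumstats harmonized, QC'd `sumstats` (needs `panel_index`).
#' @param panel an `ld_panel`.
#' @param n_chains,burn_in,n_iter sampler configuration.
#' @param p_init_grid optional vector of per-chain initial `p`; default
#'   `n_chains` points log-spaced in \[1e-4, 0.9\].
#' @param h2_init optional initial h2; default the LDSC estimate.
#' @param fix_p,fix_h2 freeze a hyperparameter at its initial value
#'   (oracle/test hooks; `fix_p = TRUE` with `p_init_grid = 1` gives the
#'   infinitesimal model).
#' @param dead_mult dead-chain bound multiplier (default 3).
#' @param seed integer seed; chains are reproducible bit-for-bit.
#' @return `pgs_weights`: list with `beta` (posterior-mean standardized
#'   effects, kept chains averaged at this stage over *live* chains; run
#'   [filter_chains()] for the tutorial filter), `chain_beta` (m x chains),
#'   `p_trace`/`h2_trace`, `p_hat`, `h2_hat`, `dead`, `kept`, provenance.
#' @export
ldpred_auto <- function(sumstats, panel, n_chains = 10, burn_in = 200,
                        n_iter = 100, p_init_grid = NULL, h2_init = NULL,
                        fix_p = FALSE, fix_h2 = FALSE, dead_mult = 3,
                        seed = 1) {
  ss <- as.data.frame(sumstats)
  if (is.null(ss$panel_index)) stop("run harmonize() before ldpred_auto()")
  idx <- ss$panel_index
  m <- length(idx)
  n_eff <- median(ss$n_eff)
  # standardized-scale marginal effects from the scale-invariant z-statistic
  beta_hat <- (ss$beta / ss$se) / sqrt(ss$n_eff)

  # restrict panel blocks to surviving variants
  sub <- subset_blocks(panel, idx)
  if (is.null(p_init_grid))
    p_init_grid <- exp(seq(log(1e-4), log(0.9), length.out = n_chains))
  n_chains <- length(p_init_grid)
  if (is.null(h2_init)) {
    ells <- ld_scores(panel)[idx]
    h2_init <- if (m >= 50) ldsc_h2(sumstats, ells)$h2 else
      min(max((mean((beta_hat * sqrt(n_eff))^2) - 1) * m /
                (n_eff * mean(ells)), 0.001), 1)
  }
  # divergence bound: a legitimate chain's h2 never exceeds ~1 on the
  # standardized scale, so the floor at 1 only catches true explosions even
  # when the LDSC initialization underestimates
  bound <- max(dead_mult * h2_init, 1)

  fit <- with_seed(seed, {
    gibbs_auto_cpp(beta_hat, sub$R, sub$from, sub$to, n_eff,
                   as.numeric(p_init_grid), h2_init,
                   as.integer(burn_in), as.integer(n_iter),
                   fix_p, fix_h2, bound)
  })
  live <- !fit$dead
  if (!any(live))
    stop(structure(class = c("multipgs_chain_error", "error", "condition"),
                   list(message = "no_converged_chains", call = NULL,
                        reason = "no_converged_chains")))
  w <- structure(list(
    beta = rowMeans(fit$beta[, live, drop = FALSE]),
    chain_beta = fit$beta,
    p_trace = fit$p_trace, h2_trace = fit$h2_trace,
    p_hat = mean(fit$p_hat[live]), h2_hat = mean(fit$h2_hat[live]),
    chain_p_hat = fit$p_hat, chain_h2_hat = fit$h2_hat,
    dead = fit$dead, kept = live,
    panel_index = idx, rsid = ss$rsid, a1 = ss$a1,
    maf = panel$variants$maf[idx],
    n_eff = n_eff, m = m, h2_init = h2_init,
    trait = attr(sumstats, "meta")$trait %||% "trait",
    config = list(n_chains = n_chains, burn_in = burn_in, n_iter = n_iter,
                  fix_p = fix_p, fix_h2 = fix_h2, dead_mult = dead_mult,
                  seed = seed)),
    class = "pgs_weights")
  w
}

subset_blocks <- function(panel, idx) {
  stopifnot(!is.unsorted(idx), !anyDuplicated(idx))
  Rs <- list(); from <- integer(); to <- integer()
  pos <- 1L
  for (b in panel$blocks) {
    inb <- idx[idx >= b$from & idx <= b$to]
    if (!length(inb)) next
    local <- inb - b$from + 1L
    Rs[[length(Rs) + 1L]] <- b$R[local, local, drop = FALSE]
    from <- c(from, pos)
    to <- c(to, pos + length(inb) - 1L)
    pos <- pos + length(inb)
  }
  list(R = Rs, from = from, to = to)
}

#' @exportS3Method base::print
print.pgs_weights <- function(x, ...) {
  cat(sprintf("PGS weights for '%s': %d variants, n_eff = %g\n",
              x$trait, x$m, x$n_eff))
  cat(sprintf("  chains: %d run, %d live, %d kept; p_hat = %.3g, h2_hat = %.3g\n",
              length(x$dead), sum(!x$dead), sum(x$kept), x$p_hat, x$h2_hat))
  invisible(x)
}

#' Filter Gibbs chains by predictive scale and average the survivors
#'
#' Computes each live chain's predictive scale (the standard deviation of its
#' averaged effect-size vector) and keeps chains whose scale is at least
#' `band` times the 95th percentile of live-chain scales (the tutorial
#' heuristic for discarding under-converged chains). The final effect sizes
#' are the mean over kept chains. If nothing survives the band, the single
#' chain with the median h2 estimate is used and flagged.
#'
#' @param weights a `pgs_weights` object.
#' @param band scale band multiplier (default 0.95).
#' @return the `pgs_weights` with `beta`, `kept`, `p_hat`, `h2_hat` updated;
#'   `fallback_single_chain` flag set when the fallback fired.
#' @export
filter_chains <- function(weights, band = 0.95) {
  stopifnot(inherits(weights, "pgs_weights"))
  live <- which(!weights$dead)
  if (!length(live)) stop("no live chains to filter")
  scales <- apply(weights$chain_beta[, live, drop = FALSE], 2, sd)
  cutoff <- band * quantile(scales, 0.95, names = FALSE, type = 7)
  keep <- live[scales >= cutoff]
  fallback <- FALSE
  if (!length(keep)) {
    h2s <- weights$chain_h2_hat[live]
    keep <- live[which.min(abs(h2s - median(h2s)))]
    fallback <- TRUE
  }
  mask <- rep(FALSE, length(weights$dead))
  mask[keep] <- TRUE
  weights$kept <- mask
  weights$beta <- rowMeans(weights$chain_beta[, keep, drop = FALSE])
  weights$p_hat <- mean(weights$chain_p_hat[keep])
  weights$h2_hat <- mean(weights$chain_h2_hat[keep])
  weights$fallback_single_chain <- fallback
  weights$n_kept <- length(keep)
  weights
}

#' Project variant weights onto cohort genotypes
#'
#' `score_i = sum_j beta_j (x_ij - 2 maf_j) / sd_j` on the standardized
#' scale. Variants are matched by panel index; an empty intersection errors.
#'
#' @param weights a `pgs_weights` object.
#' @param cohort a `cohort_data` (same panel).
#' @return numeric vector of per-individual raw scores.
#' @export
project <- function(weights, cohort) {
  stopifnot(inherits(weights, "pgs_weights"), inherits(cohort, "cohort_data"))
  idx <- weights$panel_index
  if (!length(idx) || max(idx) > ncol(cohort$dosages))
    stop(structure(class = c("multipgs_parse_error", "error", "condition"),
                   list(message = "no variant overlap between weights and cohort",
                        call = NULL, reason = "no_overlap")))
  Xs <- standardized_dosages(cohort, idx)
  as.numeric(Xs %*% weights$beta)
}

#' Export PGS weights as a PLINK-score-compatible TSV
#'
#' Columns: rsid, a1, beta_standardized, beta_allelic (the standardized
#' effect divided by the Hardy-Weinberg dosage sd, usable with allele
#' counts).
#'
#' @param weights a `pgs_weights`.
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
write_weights <- function(weights, path) {
  sd_j <- sqrt(2 * weights$maf * (1 - weights$maf))
  df <- data.frame(rsid = weights$rsid, a1 = weights$a1,
                   beta_standardized = weights$beta,
                   beta_allelic = weights$beta / sd_j)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(trait = weights$trait, p_hat = weights$p_hat,
               h2_hat = weights$h2_hat, n_kept_chains = sum(weights$kept),
               n_variants = weights$m, n_eff = weights$n_eff)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             sub("\\.tsv$", ".json", path))
  invisible(path)
}
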