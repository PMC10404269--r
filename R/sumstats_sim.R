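#' Simulate GWAS summary statistics for one trait
#'
#' Generates marginal association results as an external GWAS would report
#' them: per-variant effect estimates on the allele-count scale, standard
#' errors, effect-allele frequency and effective sample size. Two modes:
#'
#' * `"direct"` (default, fast): per LD block the standardized marginal
#'   effects are drawn exactly from their sampling distribution,
#'   \eqn{\hat\beta = R\beta + e}, \eqn{e \sim MVN(0, R/n)}, with
#'   \eqn{se = 1/\sqrt{n}} on the standardized scale.
#' * `"cohort"` (slow oracle): an external cohort of `n_gwas` individuals is
#'   simulated from the same panel and architecture, and each variant is
#'   tested by single-SNP linear regression; used to validate the direct
#'   mode.
#'
#' In both modes the reported `beta` and `se` are converted to the
#' allele-count scale (`beta_allelic = beta_std / sd_j`,
#' `sd_j = sqrt(2 maf (1-maf))`), matching the convention of real
#' summary-statistics files; the z-statistic is scale-invariant.
#'
#' @param panel an `ld_panel`.
#' @param architecture a `trait_architecture`.
#' @param trait trait index (column of `beta_true`).
#' @param n_gwas GWAS sample size (>= 30).
#' @param mode `"direct"` or `"cohort"`.
#' @param freq_noise sd of Gaussian noise added to the reported allele
#'   frequency (clipped to (0.001, 0.999)); 0 reports the panel MAF exactly.
#' @param trait_label label stored in the file-level metadata.
#' @param seed integer seed.
#' @return A `sumstats` object (data.frame: rsid, chr, pos, a1, a0, beta, se,
#'   freq, n_eff; metadata in `attr(, "meta")`).
#' @export
simulate_sumstats <- function(panel, architecture, trait = 1, n_gwas,
                              mode = c("direct", "cohort"), freq_noise = 0.01,
                              trait_label = sprintf("trait%d", trait),
                              seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "ld_panel"),
            inherits(architecture, "trait_architecture"), n_gwas >= 30)
  if (trait < 1 || trait > architecture$n_traits)
    stop("trait index out of range")
  beta_true <- architecture$beta_true[, trait]
  m <- panel$m
  sd_j <- sqrt(2 * panel$variants$maf * (1 - panel$variants$maf))

  res <- with_seed(seed, {
    if (mode == "direct") {
      chols <- panel_chols(panel)
      bh <- numeric(m)
      for (b in seq_along(panel$blocks)) {
        idx <- panel$blocks[[b]]$from:panel$blocks[[b]]$to
        mu <- as.numeric(panel$blocks[[b]]$R %*% beta_true[idx])
        z <- rnorm(length(idx))
        bh[idx] <- mu + as.numeric(crossprod(chols[[b]], z)) / sqrt(n_gwas)
      }
      list(beta_std = bh, se_std = rep(1 / sqrt(n_gwas), m))
    } else {
      coh <- simulate_cohort(panel, architecture, n_ind = n_gwas,
                             trait_type = "continuous",
                             seed = child_seed(seed, 77L))
      y <- coh$phenotypes[[trait]]
      X <- coh$dosages
      n <- nrow(X)
      xm <- colMeans(X)
      xc2 <- colSums(X^2) - n * xm^2
      sxy <- as.numeric(crossprod(X, y - mean(y)))
      b_allelic <- sxy / xc2
      # residual variance of the marginal fit, per variant
      ssy <- sum((y - mean(y))^2)
      sse <- pmax(ssy - b_allelic * sxy, 0)
      se_allelic <- sqrt(sse / (n - 2) / xc2)
      sd_obs <- sqrt(xc2 / n)
      list(beta_std = b_allelic * sd_obs, se_std = se_allelic * sd_obs)
    }
  })
  freq <- panel$variants$maf
  if (freq_noise > 0) {
    freq <- with_seed(child_seed(seed, 13L),
                      pmin(pmax(freq + rnorm(m, 0, freq_noise), 0.001), 0.999))
  }
  df <- data.frame(rsid = panel$variants$id,
                   chr = panel$variants$chr,
                   pos = panel$variants$pos,
                   a1 = panel$variants$a1,
                   a0 = panel$variants$a0,
                   beta = res$beta_std / sd_j,
                   se = res$se_std / sd_j,
                   freq = freq,
                   n_eff = n_gwas,
                   stringsAsFactors = FALSE)
  new_sumstats(df, meta = list(trait = trait_label, source = "simulated",
                               mode = mode, n_gwas = n_gwas, seed = seed))
}

new_sumstats <- function(df, meta = list()) {
  stopifnot(all(c("rsid", "a1", "a0", "beta", "se") %in% names(df)))
  attr(df, "meta") <- meta
  class(df) <- c("sumstats", "data.frame")
  df
}

#' @exportS3Method base::print
print.sumstats <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("GWAS summary statistics: %d variants (trait: %s, source: %s)\n",
              nrow(x), meta$trait %||% "?", meta$source %||% "?"))
  print.data.frame(head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}
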