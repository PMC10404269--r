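# Shared fixtures, built in code and cached for the session.
# All sizes are desk-scale; seeds fixed so every test is reproducible.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

small_panel <- function() fixture("small_panel", function()
  simulate_panel(300, block_size = 30, rho = 0.5, seed = 101))

identity_panel <- function(m = 60) {
  simulate_panel(m, block_size = min(20, m), rho = 0, seed = 102)
}

small_arch <- function() fixture("small_arch", function()
  simulate_architecture(small_panel(), n_traits = 2, h2 = c(0.5, 0.4),
                        rg = 0.6, polygenicity = 0.1, seed = 103))

small_cohort <- function() fixture("small_cohort", function()
  simulate_cohort(small_panel(), small_arch(), n_ind = 800,
                  prevalence = 0.2, seed = 104))

# a harmonized, QC-passing sumstats object on the small panel
small_sumstats <- function() fixture("small_sumstats", function() {
  ss <- simulate_sumstats(small_panel(), small_arch(), trait = 1,
                          n_gwas = 20000, seed = 105)
  sd_qc(harmonize(ss, small_panel()), small_panel())
})

# random standardized score library with k named columns
random_library <- function(n, k, seed = 1) {
  set.seed(seed)
  S <- matrix(rnorm(n * k), n, k,
              dimnames = list(NULL, sprintf("s%02d", seq_len(k))))
  score_library(S)
}

toy_covariates <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(sex = rbinom(n, 1, 0.5), age = runif(n, 1, 35))
}

write_sim_gwas_file <- function(panel, arch, trait, n_gwas, path, seed) {
  ss <- simulate_sumstats(panel, arch, trait = trait, n_gwas = n_gwas,
                          seed = seed)
  write_sumstats(ss, path)
  path
}

# exact spike-and-slab posterior mean for a single LD block by enumeration
# of all 2^M causal configurations (fixed p and slab variance sigma2);
# independent oracle for the Gibbs sampler.
enumeration_posterior_mean <- function(beta_hat, R, n_eff, p, sigma2) {
  M <- length(beta_hat)
  post_mean <- numeric(M)
  log_w <- numeric(2^M)
  means <- vector("list", 2^M)
  for (code in 0:(2^M - 1)) {
    gamma <- as.logical(bitwAnd(code, 2^(0:(M - 1))))
    k <- sum(gamma)
    # marginal likelihood beta_hat ~ N(0, R_.g sigma2 R_.g' + R/n)
    Sigma <- R / n_eff
    if (k > 0) {
      Rg <- R[, gamma, drop = FALSE]
      Sigma <- Sigma + sigma2 * tcrossprod(Rg)
    }
    ld <- determinant(Sigma, logarithm = TRUE)$modulus
    quad <- as.numeric(crossprod(beta_hat, solve(Sigma, beta_hat)))
    log_w[code + 1] <- k * log(p) + (M - k) * log(1 - p) -
      0.5 * (ld + quad)
    mu <- numeric(M)
    if (k > 0) {
      A <- n_eff * R[gamma, gamma, drop = FALSE] + diag(1 / sigma2, k)
      mu[gamma] <- solve(A, n_eff * beta_hat[gamma])
    }
    means[[code + 1]] <- mu
  }
  w <- exp(log_w - max(log_w))
  w <- w / sum(w)
  for (i in seq_along(w)) post_mean <- post_mean + w[i] * means[[i]]
  post_mean
}

# liability-threshold simulation oracle: draw an ascertained case-control
# sample whose underlying liability R2 is r2l, regress y on the genetic
# score, return observed-scale R2. Exact truncated-normal sampling.
simulate_liability_r2_obs <- function(r2l, K, P, n, seed) {
  set.seed(seed)
  t <- qnorm(1 - K)
  n_case <- round(n * P)
  n_ctrl <- n - n_case
  u <- runif(n_case)
  l_case <- qnorm(pnorm(t) + u * (1 - pnorm(t)))
  u <- runif(n_ctrl)
  l_ctrl <- qnorm(u * pnorm(t))
  l <- c(l_case, l_ctrl)
  y <- rep(c(1, 0), c(n_case, n_ctrl))
  g <- r2l * l + rnorm(n, 0, sqrt(r2l * (1 - r2l)))
  summary(lm(y ~ g))$r.squared
}

# numeric-integration oracle for the top-vs-middle quintile odds ratio of a
# score with correlation rho to the liability, population quintiles,
# prevalence K (no ascertainment)
quintile_logor_oracle <- function(rho, K) {
  t <- qnorm(1 - K)
  p_case_in <- function(lo, hi) {
    integrate(function(s) dnorm(s) * pnorm((rho * s - t) / sqrt(1 - rho^2)),
              lo, hi, rel.tol = 1e-9)$value / (pnorm(hi) - pnorm(lo))
  }
  br <- qnorm(seq(0, 1, 0.2))
  p5 <- p_case_in(br[5], Inf)
  p3 <- p_case_in(br[3], br[4])
  log(p5 / (1 - p5)) - log(p3 / (1 - p3))
}
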