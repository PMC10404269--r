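test_that("LD scores match closed forms and brute-force summation", {
  expect_equal(ld_scores(identity_panel(30)), rep(1, 30))

  p2 <- simulate_panel(2, block_size = 2, rho = 0.5, seed = 1)
  expect_equal(ld_scores(p2), c(1.25, 1.25))

  p <- simulate_panel(100, block_size = 100, rho = 0.9, seed = 2)
  R <- p$blocks[[1]]$R
  brute <- vapply(1:100, function(j) sum(R[j, ]^2), numeric(1))
  expect_equal(ld_scores(p), brute)
})

test_that("LDSC h2 clamps at the floor for flat chi-squares and flags degenerate designs", {
  df <- data.frame(rsid = sprintf("rs%d", 1:100), chr = 1, pos = 1:100,
                   a1 = "A", a0 = "G", beta = 0.01, se = 0.01, freq = 0.3,
                   n_eff = 1e4)
  ss <- multipgs:::new_sumstats(df)
  est <- ldsc_h2(ss, seq(1, 3, length.out = 100))
  expect_equal(est$h2, 0.001)  # chi2 constant at 1 -> slope 0 -> floor

  est2 <- ldsc_h2(ss, rep(1.5, 100))
  expect_true(est2$fallback)
})

test_that("LDSC h2 tracks simulation truth", {
  panel <- simulate_panel(5000, 50, rho = c(0.2, 0.9), seed = 61)
  null_arch <- simulate_architecture(panel, 1, h2 = 0, polygenicity = 0.1,
                                     seed = 62)
  ss0 <- harmonize(simulate_sumstats(panel, null_arch, 1, 50000, seed = 63),
                   panel)
  est0 <- ldsc_h2(ss0, ld_scores(panel)[ss0$panel_index])
  expect_lte(est0$h2, 0.02)

  arch <- simulate_architecture(panel, 1, h2 = 0.5, polygenicity = 0.1,
                                seed = 64)
  ss <- harmonize(simulate_sumstats(panel, arch, 1, 50000, seed = 65), panel)
  est <- ldsc_h2(ss, ld_scores(panel)[ss$panel_index])
  expect_equal(est$h2, 0.5, tolerance = 0.2)
})

test_that("null summary statistics give zero posterior means in all chains", {
  panel <- identity_panel(40)
  df <- data.frame(rsid = panel$variants$id, chr = 1,
                   pos = panel$variants$pos,
                   a1 = panel$variants$a1, a0 = panel$variants$a0,
                   beta = 0, se = 0.01, freq = panel$variants$maf,
                   n_eff = 1e4)
  ss <- harmonize(multipgs:::new_sumstats(df), panel)
  w <- ldpred_auto(ss, panel, n_chains = 4, burn_in = 50, n_iter = 50,
                   seed = 1)
  expect_lt(max(abs(w$chain_beta[, !w$dead])), 1e-12)
  expect_lt(max(abs(w$beta)), 1e-12)
})

test_that("infinitesimal limit: identity LD with p = 1 equals closed-form shrinkage", {
  panel <- identity_panel(50)
  arch <- simulate_architecture(panel, 1, h2 = 0.4, polygenicity = 1,
                                seed = 2)
  ss <- harmonize(simulate_sumstats(panel, arch, 1, 8000, freq_noise = 0,
                                    seed = 3), panel)
  n <- 8000; M <- nrow(ss); h2 <- 0.4
  w <- ldpred_auto(ss, panel, p_init_grid = 1, h2_init = h2,
                   fix_p = TRUE, fix_h2 = TRUE,
                   burn_in = 20, n_iter = 30, seed = 4)
  beta_hat_std <- (ss$beta / ss$se) / sqrt(ss$n_eff)
  closed <- beta_hat_std / (1 + M / (n * h2))
  expect_equal(w$beta, closed, tolerance = 1e-6)
})

test_that("Gibbs posterior means match exhaustive enumeration on a 3-variant block", {
  panel <- simulate_panel(3, block_size = 3, rho = 0.6, seed = 5)
  R <- panel$blocks[[1]]$R
  n <- 2000; p <- 0.3; h2 <- 0.3
  sigma2 <- h2 / (3 * p)
  set.seed(6)
  beta_true <- c(0.3, 0, -0.2)
  beta_hat_std <- as.numeric(R %*% beta_true) +
    as.numeric(crossprod(chol(R), rnorm(3))) / sqrt(n)
  sd_j <- sqrt(2 * panel$variants$maf * (1 - panel$variants$maf))
  df <- data.frame(rsid = panel$variants$id, chr = 1,
                   pos = panel$variants$pos, a1 = panel$variants$a1,
                   a0 = panel$variants$a0, beta = beta_hat_std / sd_j,
                   se = 1 / (sqrt(n) * sd_j), freq = panel$variants$maf,
                   n_eff = n)
  ss <- harmonize(multipgs:::new_sumstats(df), panel)

  oracle <- enumeration_posterior_mean(beta_hat_std, R, n, p, sigma2)
  w <- ldpred_auto(ss, panel, p_init_grid = rep(p, 8), h2_init = h2,
                   fix_p = TRUE, fix_h2 = TRUE, burn_in = 500,
                   n_iter = 4000, seed = 7)
  mcse <- apply(w$chain_beta, 1, sd) / sqrt(ncol(w$chain_beta))
  expect_true(all(abs(w$beta - oracle) <= pmax(3 * mcse, 5e-4)))
})

test_that("shrinkage is monotone in the prior odds M p / (n h2)", {
  panel <- identity_panel(30)
  arch <- simulate_architecture(panel, 1, h2 = 0.5, polygenicity = 1,
                                seed = 8)
  ss <- harmonize(simulate_sumstats(panel, arch, 1, 5000, freq_noise = 0,
                                    seed = 9), panel)
  h2_grid <- c(0.8, 0.4, 0.2, 0.1, 0.05)  # decreasing h2 => more shrinkage
  norms <- vapply(h2_grid, function(h2) {
    w <- ldpred_auto(ss, panel, p_init_grid = 1, h2_init = h2,
                     fix_p = TRUE, fix_h2 = TRUE, burn_in = 10, n_iter = 20,
                     seed = 10)
    sum(abs(w$beta))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("estimated hyperparameters track simulation truth", {
  panel <- simulate_panel(2000, 50, rho = c(0.2, 0.9), seed = 71)
  p_true <- 0.05; h2_true <- 0.5
  arch <- simulate_architecture(panel, 1, h2 = h2_true,
                                polygenicity = p_true, seed = 72)
  ss <- sd_qc(harmonize(simulate_sumstats(panel, arch, 1, 50000, seed = 73),
                        panel), panel)
  w <- filter_chains(ldpred_auto(ss, panel, n_chains = 10, burn_in = 200,
                                 n_iter = 100, seed = 74))
  expect_equal(w$h2_hat, h2_true, tolerance = 0.1)
  expect_lt(abs(w$p_hat - p_true) / p_true, 1.0)
  expect_gte(sum(w$kept), 1)
})

test_that("chain filtering keeps consistent chains and excludes degenerate ones", {
  w <- structure(list(
    chain_beta = matrix(rep(c(0.1, -0.2, 0.3), 5), ncol = 5),
    chain_p_hat = rep(0.1, 5), chain_h2_hat = rep(0.3, 5),
    dead = rep(FALSE, 5), kept = rep(TRUE, 5),
    p_hat = 0.1, h2_hat = 0.3, beta = rep(0, 3), m = 3),
    class = "pgs_weights")
  f <- filter_chains(w)
  expect_true(all(f$kept))
  expect_equal(f$beta, c(0.1, -0.2, 0.3))

  w2 <- w
  w2$chain_beta[, 3] <- 0  # an artificially collapsed chain
  f2 <- filter_chains(w2)
  expect_false(f2$kept[3])
  expect_equal(sum(f2$kept), f2$n_kept)
  expect_equal(f2$beta, c(0.1, -0.2, 0.3))
})

test_that("projection is the standardized-dosage inner product", {
  panel <- small_panel()
  cohort <- small_cohort()
  ss <- small_sumstats()
  w <- ldpred_auto(ss, panel, n_chains = 4, burn_in = 50, n_iter = 50,
                   seed = 11)
  w0 <- w; w0$beta <- rep(0, w$m)
  expect_equal(project(w0, cohort), rep(0, nrow(cohort$dosages)))

  w1 <- w0
  w1$beta[5] <- 1
  j <- w1$panel_index[5]
  xs <- (cohort$dosages[, j] - 2 * cohort$maf[j]) /
    sqrt(2 * cohort$maf[j] * (1 - cohort$maf[j]))
  expect_equal(project(w1, cohort), xs)

  sc <- project(w, cohort)
  expect_gt(cor(sc, cohort$genetic_values[, 1]), 0.3)
  expect_lte(cor(sc, cohort$genetic_values[, 1])^2, 1)
})

test_that("prediction accuracy grows with GWAS sample size", {
  panel <- simulate_panel(1000, 50, 0.5, seed = 81)
  arch <- simulate_architecture(panel, 1, h2 = 0.5, polygenicity = 0.05,
                                seed = 82)
  cohort <- simulate_cohort(panel, arch, 2000, trait_type = "continuous",
                            seed = 83)
  cors <- vapply(c(5000, 20000, 80000), function(n) {
    ss <- sd_qc(harmonize(simulate_sumstats(panel, arch, 1, n,
                                            seed = 84 + n %% 97), panel),
                panel)
    w <- filter_chains(ldpred_auto(ss, panel, n_chains = 6, burn_in = 150,
                                   n_iter = 75, seed = 85))
    cor(project(w, cohort), cohort$genetic_values[, 1])
  }, numeric(1))
  expect_true(all(diff(cors) > -0.02))  # monotone up to sampling error
  expect_gt(cors[3], cors[1])
})

test_that("the sampler is reproducible under a fixed seed", {
  ss <- small_sumstats()
  panel <- small_panel()
  w1 <- ldpred_auto(ss, panel, n_chains = 4, burn_in = 50, n_iter = 50,
                    seed = 12)
  w2 <- ldpred_auto(ss, panel, n_chains = 4, burn_in = 50, n_iter = 50,
                    seed = 12)
  expect_identical(w1$chain_beta, w2$chain_beta)
  expect_identical(w1$h2_trace, w2$h2_trace)
})
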