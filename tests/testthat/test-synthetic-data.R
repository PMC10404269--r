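test_that("panel blocks have the AR(1) structure and are PSD", {
  p0 <- simulate_panel(10, block_size = 5, rho = 0, seed = 1)
  expect_length(p0$blocks, 2)
  for (b in p0$blocks) expect_equal(b$R, diag(5))

  p <- simulate_panel(6, block_size = 3, rho = 0.5, seed = 1)
  expect_equal(p$blocks[[1]]$R[1, 2], 0.5)
  expect_equal(p$blocks[[1]]$R[1, 3], 0.25)
  expect_equal(p$blocks[[1]]$R, t(p$blocks[[1]]$R))

  for (seed in 1:3) {
    pp <- simulate_panel(120, block_size = 40, rho = -0.8, seed = seed)
    for (b in pp$blocks) {
      ev <- eigen(b$R, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), 0)
      expect_equal(unname(diag(b$R)), rep(1, nrow(b$R)))
    }
  }
  expect_true(all(p$variants$maf > 0 & p$variants$maf <= 0.5))
})

test_that("block index ranges partition the variant list", {
  p <- simulate_panel(137, block_size = 25, rho = 0.3, seed = 7)
  idx <- unlist(lapply(p$blocks, function(b) b$from:b$to))
  expect_equal(idx, 1:137)
})

test_that("architecture hits target h2 exactly under the panel LD", {
  panel <- small_panel()
  arch <- small_arch()
  for (t in 1:2) {
    qf <- multipgs:::panel_quadform(panel, arch$beta_true[, t])
    expect_equal(qf, arch$h2[t], tolerance = 1e-10)
  }
  a0 <- simulate_architecture(panel, 2, h2 = c(0, 0.5), rg = 0.5,
                              polygenicity = 0.1, seed = 1)
  expect_true(all(a0$beta_true[, 1] == 0))
})

test_that("architecture rejects a non-PSD genetic correlation", {
  rg <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(simulate_architecture(small_panel(), 3, h2 = 0.3, rg = rg,
                                     polygenicity = 0.2, seed = 1),
               "positive semi-definite")
})

test_that("independent traits have uncorrelated effects at large m", {
  panel <- simulate_panel(10000, block_size = 50, rho = 0.4, seed = 11)
  arch <- simulate_architecture(panel, 2, h2 = 0.5, rg = diag(2),
                                polygenicity = 0.3, seed = 12)
  shared <- arch$causal[, 1] & arch$causal[, 2]
  r <- cor(arch$beta_true[shared, 1], arch$beta_true[shared, 2])
  expect_lt(abs(r), 0.05)
})

test_that("realized genetic correlation matches the target at m = 10,000", {
  panel <- simulate_panel(10000, block_size = 50, rho = 0.4, seed = 13)
  arch <- simulate_architecture(panel, 2, h2 = 0.5, rg = 0.8,
                                polygenicity = 0.1, seed = 14)
  # genetic correlation of population-level genetic values under analytic LD
  cross <- 0
  for (b in panel$blocks) {
    i <- b$from:b$to
    cross <- cross + crossprod(arch$beta_true[i, 1],
                               b$R %*% arch$beta_true[i, 2])
  }
  q1 <- multipgs:::panel_quadform(panel, arch$beta_true[, 1])
  q2 <- multipgs:::panel_quadform(panel, arch$beta_true[, 2])
  rg_real <- as.numeric(cross) / sqrt(q1 * q2)
  expect_equal(rg_real, 0.8, tolerance = 0.05)
})

test_that("realized heritability in a simulated cohort is near target", {
  panel <- simulate_panel(5000, block_size = 50, rho = 0.4, seed = 15)
  arch <- simulate_architecture(panel, 1, h2 = 0.4, polygenicity = 0.1,
                                seed = 16)
  coh <- simulate_cohort(panel, arch, n_ind = 5000,
                         trait_type = "continuous", seed = 17)
  expect_equal(var(coh$genetic_values[, 1]), 0.4, tolerance = 0.03)
})

test_that("null sumstats have unit mean chi-square; signal inflates per LDSC", {
  panel <- simulate_panel(2000, block_size = 50, rho = 0.5, seed = 21)
  null_arch <- simulate_architecture(panel, 1, h2 = 0, polygenicity = 0.1,
                                     seed = 22)
  n_gwas <- 10000
  ss <- simulate_sumstats(panel, null_arch, 1, n_gwas, seed = 23)
  chi2 <- (ss$beta / ss$se)^2
  # mean of m chi-square(1)-ish values: se of mean ~ sqrt(2/m)
  expect_lt(abs(mean(chi2) - 1), 3 * sqrt(2 / panel$m))

  arch <- simulate_architecture(panel, 1, h2 = 0.5, polygenicity = 0.1,
                                seed = 24)
  ss2 <- simulate_sumstats(panel, arch, 1, n_gwas, seed = 25)
  chi2_sig <- (ss2$beta / ss2$se)^2
  expected <- 1 + n_gwas * 0.5 * mean(ld_scores(panel)) / panel$m
  expect_equal(mean(chi2_sig), expected, tolerance = 0.15)
})

test_that("direct and cohort sumstats modes agree statistically", {
  panel <- simulate_panel(500, block_size = 50, rho = 0.5, seed = 31)
  arch <- simulate_architecture(panel, 1, h2 = 0.5, polygenicity = 0.1,
                                seed = 32)
  n <- 5000
  sd_j <- sqrt(2 * panel$variants$maf * (1 - panel$variants$maf))
  d <- simulate_sumstats(panel, arch, 1, n, mode = "direct", seed = 33)
  c_ <- simulate_sumstats(panel, arch, 1, n, mode = "cohort", seed = 34)
  chi_d <- mean((d$beta / d$se)^2)
  chi_c <- mean((c_$beta / c_$se)^2)
  # both are means of ~m noncentral chi-squares around the same expectation
  expect_equal(chi_d, chi_c, tolerance = 0.15 * chi_d)
  # standardized effects correlate strongly with the LD-smeared truth
  mu <- multipgs:::panel_Rv(panel, arch$beta_true[, 1])
  expect_gt(cor(d$beta * sd_j, mu), 0.7)
  expect_gt(cor(c_$beta * sd_j, mu), 0.7)
})

test_that("cohort case fraction, dosage margins and null-PGS behave", {
  panel <- simulate_panel(200, block_size = 40, rho = 0.5, seed = 41)
  arch <- simulate_architecture(panel, 1, h2 = 0.3, polygenicity = 0.2,
                                seed = 42)
  K <- 0.1
  n <- 50000
  coh <- simulate_cohort(panel, arch, n_ind = n, prevalence = K, seed = 43)
  expect_lt(abs(mean(coh$phenotypes[[1]]) - K), 3 * sqrt(K * (1 - K) / n))
  # Hardy-Weinberg margins
  expect_lt(max(abs(colMeans(coh$dosages) - 2 * panel$variants$maf)), 0.02)

  null_arch <- simulate_architecture(panel, 1, h2 = 0, polygenicity = 0.2,
                                     seed = 44)
  coh0 <- simulate_cohort(panel, null_arch, n_ind = 5000, prevalence = 0.3,
                          seed = 45)
  score <- rowSums(multipgs:::standardized_dosages(coh0)[, 1:50])
  expect_lt(abs(cor(score, coh0$phenotypes[[1]])), 0.05)
})

test_that("case oversampling reaches the target and rejects impossible targets", {
  panel <- small_panel()
  arch <- small_arch()
  coh <- simulate_cohort(panel, arch, n_ind = 20000, prevalence = 0.05,
                         ascertainment = list(type = "case_oversample",
                                              target_P = 0.5),
                         seed = 46)
  expect_equal(coh$case_proportion[1], 0.5, tolerance = 0.02)
  expect_equal(coh$case_proportion[1], mean(coh$phenotypes[[1]]))
  expect_error(
    simulate_cohort(panel, arch, n_ind = 5000, prevalence = 0.3,
                    ascertainment = list(type = "case_oversample",
                                         target_P = 0.05),
                    seed = 47),
    "target_P")
})

test_that("fixed seeds give bit-identical simulation output", {
  p1 <- simulate_panel(150, 30, 0.5, seed = 9)
  p2 <- simulate_panel(150, 30, 0.5, seed = 9)
  expect_identical(p1, p2)
  a1 <- simulate_architecture(p1, 2, 0.4, 0.5, 0.1, seed = 9)
  a2 <- simulate_architecture(p2, 2, 0.4, 0.5, 0.1, seed = 9)
  expect_identical(a1, a2)
  s1 <- simulate_sumstats(p1, a1, 1, 5000, seed = 9)
  s2 <- simulate_sumstats(p2, a2, 1, 5000, seed = 9)
  expect_identical(s1, s2)
  c1 <- simulate_cohort(p1, a1, 500, seed = 9)
  c2 <- simulate_cohort(p2, a2, 500, seed = 9)
  expect_identical(c1, c2)
})

test_that("cohort round-trips through PLINK bed/bim/fam", {
  panel <- identity_panel(40)
  arch <- simulate_architecture(panel, 1, 0.5, polygenicity = 0.3, seed = 1)
  coh <- simulate_cohort(panel, arch, n_ind = 37, seed = 2)
  prefix <- file.path(tempfile("plink"), "coh")
  write_plink(coh, panel, prefix)
  back <- read_plink(prefix)
  expect_equal(back$dosages, unname(coh$dosages))
  expect_equal(back$bim$id, panel$variants$id)
  expect_equal(nrow(back$fam), 37)
})
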