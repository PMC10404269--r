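#' Simulate a multi-trait genetic architecture
#'
#' Draws standardized-scale true effect sizes for one or more genetically
#' correlated traits on a simulated LD panel. Causal sets are coupled through
#' a shared latent uniform per variant: variant j is causal for trait t when
#' u_j < polygenicity_t, so causal sets are nested and the overlap between
#' traits i and j is min(p_i, p_j). At shared causal variants, effects are
#' jointly Gaussian with an effect-size correlation chosen so the *genetic*
#' correlation matches `rg`: under nested causal sets,
#' rg_ij = rho_eff_ij * min(p_i, p_j) / sqrt(p_i * p_j), hence
#' rho_eff_ij = rg_ij * sqrt(p_i * p_j) / min(p_i, p_j) (must stay in
#' \[-1,1\]).
#' Effects are rescaled per trait so the genetic variance under the panel's
#' LD, sum over blocks of beta' R beta, equals the target h2 exactly.
#'
#' @param panel an `ld_panel`.
#' @param n_traits number of traits.
#' @param h2 per-trait SNP heritability in \[0,1\] (recycled).
#' @param rg genetic-correlation matrix (n_traits x n_traits), symmetric PSD
#'   with unit diagonal; a scalar is expanded to an exchangeable matrix.
#' @param polygenicity per-trait proportion of causal variants in (0,1\]
#'   (recycled).
#' @param seed integer seed.
#' @return `trait_architecture`: list with `beta_true` (m x n_traits matrix,
#'   standardized scale), `causal` (logical matrix), `h2`, `rg`,
#'   `polygenicity`.
#' @export
simulate_architecture <- function(panel, n_traits = 1, h2 = 0.5, rg = NULL,
                                  polygenicity = 0.01, seed = 1) {
  stopifnot(inherits(panel, "ld_panel"), n_traits >= 1)
  h2 <- rep_len(h2, n_traits)
  polygenicity <- rep_len(polygenicity, n_traits)
  stopifnot(all(h2 >= 0 & h2 <= 1), all(polygenicity > 0 & polygenicity <= 1))
  if (is.null(rg)) rg <- diag(n_traits)
  if (is.matrix(rg) && nrow(rg) == 1L) rg <- rg[1, 1]
  if (!is.matrix(rg)) {
    rg <- matrix(rg, n_traits, n_traits)
    diag(rg) <- 1
  }
  stopifnot(nrow(rg) == n_traits, ncol(rg) == n_traits)
  if (max(abs(rg - t(rg))) > 1e-8 || any(abs(diag(rg) - 1) > 1e-8))
    stop("`rg` must be symmetric with unit diagonal")
  ev <- eigen((rg + t(rg)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("`rg` is not positive semi-definite")

  # effect-size correlation needed at shared causals given nested causal sets
  rho_eff <- rg
  for (i in seq_len(n_traits)) for (j in seq_len(n_traits)) if (i != j) {
    adj <- sqrt(polygenicity[i] * polygenicity[j]) /
      min(polygenicity[i], polygenicity[j])
    rho_eff[i, j] <- rg[i, j] * adj
  }
  if (max(abs(rho_eff)) > 1 + 1e-12)
    stop("requested rg not attainable with these polygenicities ",
         "(implied effect correlation exceeds 1)")
  ev2 <- eigen((rho_eff + t(rho_eff)) / 2, symmetric = TRUE)
  ev2$values <- pmax(ev2$values, 0)
  L <- ev2$vectors %*% diag(sqrt(ev2$values), n_traits)

  m <- panel$m
  with_seed(seed, {
    u <- runif(m)
    causal <- outer(u, polygenicity, "<")
    raw <- matrix(rnorm(m * n_traits), m, n_traits) %*% t(L)
    beta <- raw * causal
    for (t in seq_len(n_traits)) {
      if (h2[t] == 0 || !any(causal[, t])) {
        beta[, t] <- 0
        next
      }
      v <- panel_quadform(panel, beta[, t])
      if (v > 0) beta[, t] <- beta[, t] * sqrt(h2[t] / v)
    }
    structure(list(beta_true = beta, causal = causal, h2 = h2, rg = rg,
                   polygenicity = polygenicity, n_traits = n_traits,
                   seed = seed),
              class = "trait_architecture")
  })
}

#' @exportS3Method base::print
print.trait_architecture <- function(x, ...) {
  cat(sprintf("Trait architecture: %d trait(s), %d variants\n",
              x$n_traits, nrow(x$beta_true)))
  cat("  h2:", paste(signif(x$h2, 3), collapse = ", "), "\n")
  cat("  polygenicity:", paste(signif(x$polygenicity, 3), collapse = ", "),
      "\n")
  invisible(x)
}
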