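#' Simulate an individual-level cohort under the liability-threshold model
#'
#' Genotype dosages are drawn by Gaussian-copula thresholding: per LD block a
#' latent MVN vector per haplotype (the panel's analytic correlation matrix),
#' thresholded at the 1-maf normal quantile, summed over two haplotypes. This
#' preserves Hardy-Weinberg marginals exactly (dosage mean 2*maf) and block LD
#' approximately. The liability of each binary trait is
#' genetic value + covariate effects + Gaussian residual scaled so the total
#' liability variance is 1; an individual is a case when liability exceeds
#' the threshold \eqn{\Phi^{-1}(1-K)} for prevalence K. Optional
#' case-oversampling emulates a case-cohort design: all cases are kept and
#' controls are subsampled until the case fraction reaches `target_P`.
#'
#' @param panel an `ld_panel`.
#' @param architecture a `trait_architecture`.
#' @param n_ind number of individuals before ascertainment.
#' @param prevalence per binary trait, population prevalence K in (0,1)
#'   (recycled over traits).
#' @param trait_type `"binary"` or `"continuous"`, recycled over traits.
#' @param ascertainment `NULL`/"none", or `list(type = "case_oversample",
#'   target_P = , trait = 1)`; `target_P` must be >= the trait's prevalence.
#' @param covariate_model list with optional elements `beta_sex`, `beta_age`,
#'   `beta_sexage` (liability-scale effects of standardized sex, age and
#'   their interaction) and `n_pcs` (default 20; PCs are standard-normal
#'   noise, the homogeneous-sample case).
#' @param seed integer seed.
#' @return `cohort_data`: list with `dosages` (n x m integer matrix in
#'   \{0,1,2\}), `phenotypes` (data.frame, one column per trait),
#'   `covariates` (data.frame: sex, age, PC1..), `genetic_values`
#'   (n x n_traits), `prevalence`, `case_proportion`, `maf`, `trait_type`.
#' @export
simulate_cohort <- function(panel, architecture, n_ind,
                            prevalence = 0.1, trait_type = "binary",
                            ascertainment = NULL,
                            covariate_model = list(), seed = 1) {
  stopifnot(inherits(panel, "ld_panel"),
            inherits(architecture, "trait_architecture"), n_ind >= 2)
  nt <- architecture$n_traits
  trait_type <- rep_len(trait_type, nt)
  prevalence <- rep_len(prevalence, nt)
  stopifnot(all(prevalence > 0 & prevalence < 1))
  if (is.character(ascertainment) && identical(ascertainment, "none"))
    ascertainment <- NULL

  maf <- panel$variants$maf
  sd_j <- sqrt(2 * maf * (1 - maf))
  cm <- modifyList(list(beta_sex = 0, beta_age = 0, beta_sexage = 0,
                        n_pcs = 20L), covariate_model)

  with_seed(seed, {
    X <- matrix(0L, n_ind, panel$m)
    chols <- panel_chols(panel)
    for (b in seq_along(panel$blocks)) {
      idx <- panel$blocks[[b]]$from:panel$blocks[[b]]$to
      thr <- qnorm(1 - maf[idx])
      h1 <- matrix(rnorm(n_ind * length(idx)), n_ind) %*% chols[[b]]
      h2 <- matrix(rnorm(n_ind * length(idx)), n_ind) %*% chols[[b]]
      X[, idx] <- (sweep(h1, 2, thr, ">") + sweep(h2, 2, thr, ">"))
    }
    storage.mode(X) <- "integer"

    # standardized genetic values, using the panel's analytic moments
    G <- sweep(sweep(X, 2, 2 * maf, "-"), 2, sd_j, "/") %*%
      architecture$beta_true

    sex <- rbinom(n_ind, 1, 0.5)
    age <- runif(n_ind, 1, 35)           # birth-cohort-style age span
    sex_c <- sex - 0.5
    age_c <- as.numeric(scale(age))
    cov_eff <- cm$beta_sex * sex_c * 2 + cm$beta_age * age_c +
      cm$beta_sexage * (sex_c * 2) * age_c
    var_cov <- var(cov_eff)
    pcs <- matrix(rnorm(n_ind * cm$n_pcs), n_ind)
    colnames(pcs) <- paste0("PC", seq_len(cm$n_pcs))

    phen <- vector("list", nt)
    for (t in seq_len(nt)) {
      h2t <- architecture$h2[t]
      resid_var <- 1 - h2t - var_cov
      if (resid_var < 0)
        stop("h2 + covariate variance exceeds 1; liability not normalizable")
      liab <- G[, t] + cov_eff + rnorm(n_ind, 0, sqrt(resid_var))
      phen[[t]] <- if (trait_type[t] == "binary") {
        as.integer(liab > qnorm(1 - prevalence[t]))
      } else liab
    }
    phenotypes <- as.data.frame(setNames(phen, paste0(
      "trait", seq_len(nt))))
    covariates <- data.frame(sex = sex, age = age, pcs)

    keep <- seq_len(n_ind)
    if (!is.null(ascertainment)) {
      stopifnot(identical(ascertainment$type, "case_oversample"))
      at <- ascertainment$trait %||% 1L
      stopifnot(trait_type[at] == "binary")
      targ <- ascertainment$target_P
      stopifnot_scalar_prob(targ, "target_P")
      cases <- which(phenotypes[[at]] == 1L)
      ctrls <- which(phenotypes[[at]] == 0L)
      if (targ < length(cases) / n_ind)
        stop("target_P below the realized case fraction; case oversampling ",
             "cannot reach it without subsampling cases")
      n_ctrl <- round(length(cases) * (1 - targ) / targ)
      if (n_ctrl > length(ctrls)) n_ctrl <- length(ctrls)
      keep <- sort(c(cases, sample(ctrls, n_ctrl)))
    }

    phenotypes <- phenotypes[keep, , drop = FALSE]
    rownames(phenotypes) <- NULL
    case_prop <- vapply(seq_len(nt), function(t) {
      if (trait_type[t] == "binary") mean(phenotypes[[t]]) else NA_real_
    }, numeric(1))

    structure(list(dosages = X[keep, , drop = FALSE],
                   phenotypes = phenotypes,
                   covariates = {
                     cv <- covariates[keep, , drop = FALSE]
                     rownames(cv) <- NULL
                     cv
                   },
                   genetic_values = G[keep, , drop = FALSE],
                   prevalence = prevalence,
                   case_proportion = case_prop,
                   maf = maf, trait_type = trait_type,
                   variant_ids = panel$variants$id, seed = seed),
              class = "cohort_data")
  })
}

#' @exportS3Method base::print
print.cohort_data <- function(x, ...) {
  cat(sprintf("Cohort: %d individuals x %d variants; %d trait(s)\n",
              nrow(x$dosages), ncol(x$dosages), ncol(x$phenotypes)))
  for (t in seq_along(x$trait_type)) {
    if (x$trait_type[t] == "binary")
      cat(sprintf("  %s: binary, K = %.3g, observed case fraction P = %.3g\n",
                  names(x$phenotypes)[t], x$prevalence[t],
                  x$case_proportion[t]))
    else cat(sprintf("  %s: continuous\n", names(x$phenotypes)[t]))
  }
  invisible(x)
}

# Standardize dosages with the panel's analytic moments (2*maf and HW sd).
standardized_dosages <- function(cohort, cols = NULL) {
  X <- cohort$dosages
  maf <- cohort$maf
  if (!is.null(cols)) {
    X <- X[, cols, drop = FALSE]
    maf <- maf[cols]
  }
  sweep(sweep(X, 2, 2 * maf, "-"), 2, sqrt(2 * maf * (1 - maf)), "/")
}

#' Export a cohort to PLINK bed/bim/fam plus phenotype/covariate TSVs
#'
#' Writes the standard PLINK 1 binary genotype triplet (SNP-major .bed with
#' the 0x6c 0x1b 0x01 magic) and FID/IID-keyed phenotype and covariate
#' tables. Dosages are exact (no missingness is generated by the simulator).
#'
#' @param cohort a `cohort_data`.
#' @param panel the `ld_panel` the cohort was simulated from.
#' @param prefix output path prefix (directory created if needed).
#' @return the prefix, invisibly.
#' @export
write_plink <- function(cohort, panel, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  n <- nrow(cohort$dosages)
  m <- ncol(cohort$dosages)
  v <- panel$variants
  write.table(data.frame(v$chr, v$id, 0, v$pos, v$a1, v$a0),
              paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  iid <- sprintf("ind%06d", seq_len(n))
  write.table(data.frame(iid, iid, 0, 0, cohort$covariates$sex + 1L, -9),
              paste0(prefix, ".fam"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  # PLINK bed codes (allele-1 dosage): 2 -> 00, 1 -> 10, 0 -> 11
  code <- c(`0` = 3L, `1` = 2L, `2` = 0L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  bytes_per_snp <- ceiling(n / 4)
  for (j in seq_len(m)) {
    g <- code[as.character(cohort$dosages[, j])]
    g <- c(g, integer(bytes_per_snp * 4 - n))
    gm <- matrix(g, nrow = 4)
    writeBin(as.raw(gm[1, ] + 4L * gm[2, ] + 16L * gm[3, ] + 64L * gm[4, ]),
             con)
  }
  pheno <- data.frame(FID = iid, IID = iid, cohort$phenotypes)
  covar <- data.frame(FID = iid, IID = iid, cohort$covariates)
  write.table(pheno, paste0(prefix, ".pheno.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(covar, paste0(prefix, ".covar.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}

#' Read genotypes back from a PLINK .bed triplet
#'
#' Minimal SNP-major reader used for round-trip checks of [write_plink()].
#'
#' @param prefix path prefix of the .bed/.bim/.fam triplet.
#' @return list with `dosages` (n x m integer), `bim`, `fam` data.frames.
#' @export
read_plink <- function(prefix) {
  bim <- read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE,
                    col.names = c("chr", "id", "cm", "pos", "a1", "a0"))
  fam <- read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE,
                    col.names = c("FID", "IID", "pat", "mat", "sex", "pheno"))
  n <- nrow(fam); m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + bytes_per_snp * m)
  stopifnot(identical(raw[1:3], as.raw(c(0x6c, 0x1b, 0x01))))
  body <- as.integer(raw[-(1:3)])
  two_bit <- function(x, k) bitwAnd(bitwShiftR(x, 2L * k), 3L)
  decode <- c(`0` = 2L, `2` = 1L, `3` = 0L, `1` = NA_integer_)
  X <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    b <- body[((j - 1) * bytes_per_snp + 1):(j * bytes_per_snp)]
    g <- as.vector(t(matrix(c(two_bit(b, 0L), two_bit(b, 1L),
                              two_bit(b, 2L), two_bit(b, 3L)),
                            ncol = 4)))
    X[, j] <- decode[as.character(g[seq_len(n)])]
  }
  list(dosages = X, bim = bim, fam = fam)
}
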