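#' Default desk-scale pipeline configuration
#'
#' All tunable parameters of the end-to-end workflow in one nested list:
#' panel size, architecture, GWAS sample sizes, cohort design, QC
#' thresholds, sampler settings, stacking models and evaluation options.
#' Matches the bundled `inst/extdata/demo_config.yaml`. Every threshold used
#' anywhere in the pipeline appears here; nothing is hard-coded downstream.
#'
#' @param overrides nested list merged over the defaults.
#' @return config list.
#' @export
default_config <- function(overrides = list()) {
  cfg <- list(
    seed = 42,
    panel = list(m = 2000, block_size = 50, rho = c(0.2, 0.9),
                 maf_range = c(0.05, 0.5)),
    architecture = list(n_traits = 20, h2 = 0.5, rg_target_aux = 0.5,
                        rg_aux_aux = 0.3, polygenicity = 0.05),
    gwas = list(n_target = 1000, n_aux = 50000, freq_noise = 0.01),
    cohort = list(n_ind = 4000, prevalence = 0.2, trait_type = "binary",
                  ascertainment = "none",
                  covariate_model = list(beta_sex = 0.05, beta_age = 0.05,
                                         beta_sexage = 0, n_pcs = 20)),
    qc = list(min_snps_frac = 0.5,
              thresholds = list(t_low = 0.5, t_high = 1.1,
                                t_abs = 0.05, t_ref = 0.05)),
    sampler = list(n_chains = 10, burn_in = 200, n_iter = 100,
                   chain_band = 0.95, dead_mult = 3),
    stack = list(models = c("lasso", "xgboost", "mixed"),
                 simplify_threshold = 0.01),
    evaluate = list(k_folds = 5, B = 10000),
    benchmark = list(wmt = TRUE, blup = TRUE, blup_h2_hint = 0.5,
                     M_e = NA),
    leave_target_out = TRUE)
  modifyList(cfg, overrides)
}

#' Read a pipeline configuration from YAML
#'
#' Values in the file override [default_config()]; the result round-trips
#' losslessly through [yaml::write_yaml].
#'
#' @param path YAML file.
#' @return config list.
#' @export
read_config <- function(path) {
  default_config(yaml::read_yaml(path))
}

#' Run the full multi-PGS workflow at desk scale
#'
#' Wires simulate, QC, derive, build, stack, evaluate and benchmark into one
#' reproducible run: simulates an LD panel and a genetically correlated
#' multi-trait architecture in which trait 1 is the target (small own GWAS)
#' and the rest are auxiliaries (large GWAS); writes per-trait GWAS
#' summary-statistics files; builds the PGS library through the full
#' parse/harmonize/QC/Gibbs/projection path; fits the stacking models; and
#' evaluates everything with cross-validated, liability-adjusted statistics
#' against the single own-trait PGS, the selection-index (wMT) predictor and
#' a BLUP PGS. Artifacts (canonical sumstats, weights, library, reports,
#' logs) are written under `out_dir` with an md5 checksum manifest.
#'
#' @param config list from [default_config()]/[read_config()].
#' @param out_dir artifact directory (created).
#' @return list: `report` (`eval_report`), `report_lto` (leave-target-out),
#'   `comparison` (from [compare_report()]), `library`, `panel`, paths.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("mpgs")) {
  cfg <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  log <- list()

  panel <- simulate_panel(cfg$panel$m, cfg$panel$block_size, cfg$panel$rho,
                          as.numeric(cfg$panel$maf_range),
                          seed = child_seed(seed, 1L))
  nt <- cfg$architecture$n_traits
  rg <- matrix(cfg$architecture$rg_aux_aux, nt, nt)
  rg[1, ] <- rg[, 1] <- cfg$architecture$rg_target_aux
  diag(rg) <- 1
  arch <- simulate_architecture(panel, nt, h2 = cfg$architecture$h2, rg = rg,
                                polygenicity = cfg$architecture$polygenicity,
                                seed = child_seed(seed, 2L))

  ss_dir <- file.path(out_dir, "sumstats")
  dir.create(ss_dir, showWarnings = FALSE)
  n_gwas <- c(cfg$gwas$n_target, rep(cfg$gwas$n_aux, nt - 1))
  tags <- c("target", sprintf("aux%02d", seq_len(nt - 1)))
  paths <- character(nt)
  for (t in seq_len(nt)) {
    ss <- simulate_sumstats(panel, arch, trait = t, n_gwas = n_gwas[t],
                            freq_noise = cfg$gwas$freq_noise,
                            trait_label = tags[t],
                            seed = child_seed(seed, 10L + t))
    paths[t] <- file.path(ss_dir, paste0(tags[t], ".tsv.gz"))
    write_sumstats(ss, paths[t])
  }
  manifest <- data.frame(path = paths, trait = tags,
                         stringsAsFactors = FALSE)
  # persisted manifest uses paths relative to out_dir so reruns into
  # different directories produce identical artifacts
  write.table(data.frame(path = file.path("sumstats", basename(paths)),
                         trait = tags),
              file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  cohort <- simulate_cohort(panel, arch, n_ind = cfg$cohort$n_ind,
                            prevalence = cfg$cohort$prevalence,
                            trait_type = cfg$cohort$trait_type,
                            ascertainment = cfg$cohort$ascertainment,
                            covariate_model = cfg$cohort$covariate_model,
                            seed = child_seed(seed, 3L))
  y <- cohort$phenotypes[[1]]
  covariates <- cohort$covariates

  lib <- build_library(manifest, panel, cohort, config = list(
    min_snps = floor(panel$m * cfg$qc$min_snps_frac),
    sd_qc_thresholds = cfg$qc$thresholds,
    n_chains = cfg$sampler$n_chains, burn_in = cfg$sampler$burn_in,
    n_iter = cfg$sampler$n_iter, chain_band = cfg$sampler$chain_band,
    seed = child_seed(seed, 4L)))
  write_library(lib, file.path(out_dir, "library"))
  log$library <- lib$log

  extra <- list(single = single_score_model("target"))
  if (isTRUE(cfg$benchmark$wmt)) {
    M_e <- cfg$benchmark$M_e
    if (is.null(M_e) || is.na(M_e)) M_e <- panel$m / mean(ld_scores(panel))
    params <- list(h2 = arch$h2, n_gwas = n_gwas, rg = arch$rg, M_e = M_e,
                   tags = tags)
    ww <- wmt_weights(params, target_trait = 1)
    writeLines(jsonlite::toJSON(ww[c("weights", "r2", "M_e", "target")],
                                auto_unbox = TRUE, digits = NA),
               file.path(out_dir, "wmt_weights.json"))
    extra$wmt <- function(lib, covs, yy, tr, te) {
      idx <- wmt_predict(lib, ww)
      df_tr <- data.frame(covs[tr, , drop = FALSE], score = idx[tr])
      base <- fit_covariate_base(df_tr, yy[tr])
      predict(base, covariates = data.frame(covs[te, , drop = FALSE],
                                            score = idx[te]))
    }
  }
  if (isTRUE(cfg$benchmark$blup)) {
    extra$blup <- function(lib, covs, yy, tr, te) {
      Xs <- standardized_dosages(cohort)
      lam <- ncol(Xs) * (1 - cfg$benchmark$blup_h2_hint) /
        (length(tr) * cfg$benchmark$blup_h2_hint)
      ytr <- yy[tr] - mean(yy[tr])
      K <- tcrossprod(Xs[tr, , drop = FALSE])
      alpha <- solve(K + lam * diag(length(tr)), ytr)
      b <- as.numeric(crossprod(Xs[tr, , drop = FALSE], alpha))
      sc <- as.numeric(Xs %*% b)
      df_tr <- data.frame(covs[tr, , drop = FALSE], score = sc[tr])
      base <- fit_covariate_base(df_tr, yy[tr])
      predict(base, covariates = data.frame(covs[te, , drop = FALSE],
                                            score = sc[te]))
    }
  }

  K_prev <- if (cfg$cohort$trait_type[1] == "binary")
    cfg$cohort$prevalence[1] else NA
  report <- cv_evaluate(lib, covariates, y,
                        model_kinds = cfg$stack$models,
                        K_prevalence = K_prev,
                        k = cfg$evaluate$k_folds, B = cfg$evaluate$B,
                        extra_predictors = extra,
                        seed = child_seed(seed, 5L))
  write_eval_report(report, file.path(out_dir, "report"))

  report_lto <- NULL
  if (isTRUE(cfg$leave_target_out)) {
    lib936 <- exclude_scores(lib, "target")
    report_lto <- cv_evaluate(lib936, covariates, y,
                              model_kinds = "lasso",
                              K_prevalence = K_prev,
                              k = cfg$evaluate$k_folds, B = cfg$evaluate$B,
                              seed = child_seed(seed, 5L))
    write_eval_report(report_lto, file.path(out_dir, "report_lto"))
  }

  comparison <- compare_report(report, baseline = "single")
  write.table(comparison, file.path(out_dir, "comparison.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  writeLines(yaml::as.yaml(cfg), file.path(out_dir, "config.yaml"))
  arts <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  arts <- arts[!grepl("checksums", arts)]
  checks <- file_checksums(sort(arts))
  write.table(checks, file.path(out_dir, "checksums.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  list(report = report, report_lto = report_lto, comparison = comparison,
       library = lib, panel = panel, cohort = cohort, arch = arch,
       out_dir = out_dir, checksums = checks)
}

#' Tabulate model comparison against a baseline predictor
#'
#' One row per model: adjusted R2 with CI, fold-change of adjusted R2 over
#' the baseline, and a flag for whether the 95% bootstrap CIs overlap the
#' baseline's.
#'
#' @param report an `eval_report` with at least two models.
#' @param baseline model name to compare against.
#' @return data.frame: model, r2_adj_obs, ci, fold_change, ci_overlap.
#' @export
compare_report <- function(report, baseline) {
  tab <- report$table
  if (!baseline %in% tab$model)
    stop("baseline model '", baseline, "' not in report; available: ",
         paste(tab$model, collapse = ", "))
  if (nrow(tab) < 2) stop("need at least two models to compare")
  b <- tab[tab$model == baseline, ]
  fold <- tab$r2_adj_obs / b$r2_adj_obs
  fold[!is.finite(fold)] <- NA_real_
  data.frame(model = tab$model,
             r2_adj_obs = tab$r2_adj_obs,
             r2_adj_lo = tab$r2_adj_obs_lo,
             r2_adj_hi = tab$r2_adj_obs_hi,
             fold_change_vs_baseline = fold,
             undefined_fold_change = b$r2_adj_obs == 0,
             ci_overlap_baseline = pmin(tab$r2_adj_obs_hi, b$r2_adj_obs_hi) >=
               pmax(tab$r2_adj_obs_lo, b$r2_adj_obs_lo),
             stringsAsFactors = FALSE)
}
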