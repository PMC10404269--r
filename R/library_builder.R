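#' Build a standardized PGS library from a manifest of summary-statistics files
#'
#' Runs the full per-file pipeline — parse, harmonize, SD-QC, minimum-SNP
#' gate, spike-and-slab Gibbs derivation, chain filtering, projection onto
#' the cohort — over every file in the manifest, then assembles the
#' individuals x scores matrix with per-score metadata. File failures
#' (unparseable, no overlap, gate failure, no converged chains) are logged
#' with a reason and skipped, never fatal. Columns are standardized to mean 0
#' and variance 1 on the standardization subset (default: all individuals;
#' in cross-validated evaluation the training fold — see
#' [standardize_library()]).
#'
#' @param manifest data.frame with columns `path` (file) and `trait` (tag);
#'   alternatively a list of in-memory `sumstats` objects (named by tag).
#' @param panel an `ld_panel`.
#' @param cohort a `cohort_data`.
#' @param config list overriding defaults: `min_snps` (gate; default
#'   0.5 * panel m for desk runs), `sd_qc_thresholds`, `n_chains`, `burn_in`,
#'   `n_iter`, `chain_band`, `seed`.
#' @return `score_library`: list with `scores` (n x k standardized matrix),
#'   `meta` (per-score data.frame: tag, source, n_eff, p_hat, h2_hat,
#'   n_variants, qc_status), `std` (per-score mean/sd and subset used),
#'   `log` (per-file stage counts and failures).
#' @export
build_library <- function(manifest, panel, cohort, config = list()) {
  cfg <- modifyList(list(min_snps = floor(panel$m / 2),
                         sd_qc_thresholds = list(),
                         n_chains = 10, burn_in = 200, n_iter = 100,
                         chain_band = 0.95, seed = 1,
                         n_eff_default = NULL), config)
  items <- if (is.data.frame(manifest)) {
    stopifnot(all(c("path", "trait") %in% names(manifest)),
              nrow(manifest) >= 1)
    lapply(seq_len(nrow(manifest)), function(i)
      list(tag = manifest$trait[i], path = manifest$path[i], ss = NULL))
  } else {
    stopifnot(is.list(manifest), length(manifest) >= 1)
    tags <- names(manifest) %||% sprintf("score%03d", seq_along(manifest))
    lapply(seq_along(manifest), function(i)
      list(tag = tags[i], path = NA_character_, ss = manifest[[i]]))
  }

  n <- nrow(cohort$dosages)
  cols <- list(); meta <- list(); log <- list()
  for (i in seq_along(items)) {
    it <- items[[i]]
    rec <- list(tag = it$tag, status = "ok", reason = NA_character_,
                n_parsed = NA_integer_, n_harmonized = NA_integer_,
                n_qc = NA_integer_, n_kept_chains = NA_integer_)
    score <- tryCatch({
      ss <- if (is.null(it$ss))
        parse_sumstats(it$path, trait_label = it$tag,
                       n_eff_default = cfg$n_eff_default)
      else it$ss
      rec$n_parsed <- nrow(ss)
      ss <- harmonize(ss, panel)
      rec$n_harmonized <- nrow(ss)
      ss <- sd_qc(ss, panel, cfg$sd_qc_thresholds)
      rec$n_qc <- nrow(ss)
      if (!qc_gate(ss, cfg$min_snps))
        stop(structure(class = c("multipgs_parse_error", "error", "condition"),
                       list(message = "failed min-SNP gate", call = NULL,
                            reason = "qc_gate")))
      w <- ldpred_auto(ss, panel, n_chains = cfg$n_chains,
                       burn_in = cfg$burn_in, n_iter = cfg$n_iter,
                       seed = child_seed(cfg$seed, 100L + i))
      w <- filter_chains(w, band = cfg$chain_band)
      rec$n_kept_chains <- w$n_kept
      rec$p_hat <- w$p_hat; rec$h2_hat <- w$h2_hat
      rec$n_eff <- w$n_eff; rec$n_variants <- w$m
      project(w, cohort)
    }, error = function(e) {
      rec$status <<- "failed"
      rec$reason <<- if (!is.null(e$reason)) e$reason else conditionMessage(e)
      NULL
    })
    if (!is.null(score)) {
      if (sd(score) < 1e-8) {
        rec$status <- "failed"; rec$reason <- "constant_score"
      } else {
        cols[[it$tag]] <- score
        meta[[it$tag]] <- data.frame(
          tag = it$tag,
          source = if (is.na(it$path)) "memory" else basename(it$path),
          n_eff = rec$n_eff, p_hat = rec$p_hat, h2_hat = rec$h2_hat,
          n_variants = rec$n_variants, n_kept_chains = rec$n_kept_chains,
          qc_status = "pass", stringsAsFactors = FALSE)
      }
    }
    log[[i]] <- rec
  }
  if (!length(cols))
    stop(structure(class = c("multipgs_parse_error", "error", "condition"),
                   list(message = "no scores survived the library build",
                        call = NULL, reason = "empty_library")))
  scores <- do.call(cbind, cols)
  lib <- structure(list(scores = scores,
                        meta = do.call(rbind, meta),
                        std = NULL,
                        log = log),
                   class = "score_library")
  standardize_library(lib, subset = seq_len(n))
}

#' Construct a score library from an existing matrix
#'
#' Convenience constructor used when per-individual scores were computed
#' elsewhere (or simulated); standardizes columns like [build_library()].
#'
#' @param scores numeric matrix, individuals x scores, with column names.
#' @param meta optional per-score data.frame (`tag` column required).
#' @param standardize standardize columns (default TRUE).
#' @return a `score_library`.
#' @export
score_library <- function(scores, meta = NULL, standardize = TRUE) {
  stopifnot(is.matrix(scores), !is.null(colnames(scores)))
  if (is.null(meta))
    meta <- data.frame(tag = colnames(scores), source = "matrix",
                       n_eff = NA_real_, p_hat = NA_real_, h2_hat = NA_real_,
                       n_variants = NA_integer_, n_kept_chains = NA_integer_,
                       qc_status = "pass", stringsAsFactors = FALSE)
  stopifnot(identical(meta$tag, colnames(scores)))
  lib <- structure(list(scores = scores, meta = meta, std = NULL,
                        log = list()), class = "score_library")
  if (standardize) standardize_library(lib, seq_len(nrow(scores))) else lib
}

#' Standardize library columns on a subset of individuals
#'
#' Means and sds are computed on `subset` (e.g. a training fold) and applied
#' to every row, so evaluation on the complement never leaks test-set
#' moments. Near-constant columns (sd < 1e-8 on the subset) are dropped with
#' a logged reason.
#'
#' @param library a `score_library`.
#' @param subset integer indices of the standardization subset.
#' @return the library with `scores` restandardized and `std` recording the
#'   parameters and subset.
#' @export
standardize_library <- function(library, subset) {
  raw <- if (is.null(library$std)) library$scores else
    sweep(sweep(library$scores, 2, library$std$sd, "*"), 2,
          library$std$mean, "+")
  mu <- colMeans(raw[subset, , drop = FALSE])
  sg <- apply(raw[subset, , drop = FALSE], 2, sd)
  keep <- sg >= 1e-8
  if (!all(keep)) {
    library$log <- c(library$log, list(list(
      status = "dropped_constant", tags = colnames(raw)[!keep])))
  }
  raw <- raw[, keep, drop = FALSE]
  mu <- mu[keep]; sg <- sg[keep]
  library$scores <- sweep(sweep(raw, 2, mu, "-"), 2, sg, "/")
  library$meta <- library$meta[keep, , drop = FALSE]
  library$std <- list(mean = mu, sd = sg, subset = subset)
  library
}

#' Remove scores from a library by tag
#'
#' Used for leave-target-out experiments: drop the target outcome's own
#' score(s) and refit the stack on what remains.
#'
#' @param library a `score_library`.
#' @param tags character vector of score tags to remove.
#' @return a new `score_library` without those columns; the input is
#'   untouched.
#' @export
exclude_scores <- function(library, tags) {
  if (!length(tags)) return(library)
  missing <- setdiff(tags, library$meta$tag)
  if (length(missing))
    stop("tag(s) not in library: ", paste(missing, collapse = ", "),
         "; available: ", paste(library$meta$tag, collapse = ", "))
  keep <- !(library$meta$tag %in% tags)
  library$scores <- library$scores[, keep, drop = FALSE]
  library$meta <- library$meta[keep, , drop = FALSE]
  if (!is.null(library$std)) {
    library$std$mean <- library$std$mean[keep]
    library$std$sd <- library$std$sd[keep]
  }
  library
}

#' @exportS3Method base::print
print.score_library <- function(x, ...) {
  cat(sprintf("PGS library: %d individuals x %d scores\n",
              nrow(x$scores), ncol(x$scores)))
  fails <- Filter(function(r) identical(r$status, "failed"), x$log)
  if (length(fails))
    cat(sprintf("  %d file(s) failed: %s\n", length(fails),
                paste(vapply(fails, function(r)
                  sprintf("%s (%s)", r$tag, r$reason), ""), collapse = ", ")))
  invisible(x)
}

#' Persist / load a score library
#'
#' Matrix in an RDS array store plus a metadata TSV; also exportable in long
#' format (IID, score_tag, value).
#'
#' @param library a `score_library`.
#' @param dir directory.
#' @param long also write `library_long.tsv` (default FALSE).
#' @return `write_library`: dir, invisibly; `read_library`: a
#'   `score_library`.
#' @export
write_library <- function(library, dir, long = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(library$scores, file.path(dir, "scores.rds"))
  write.table(library$meta, file.path(dir, "meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  saveRDS(library[c("std", "log")], file.path(dir, "std.rds"))
  if (long) {
    lf <- data.frame(IID = rep(seq_len(nrow(library$scores)),
                               ncol(library$scores)),
                     score_tag = rep(colnames(library$scores),
                                     each = nrow(library$scores)),
                     value = as.vector(library$scores))
    write.table(lf, file.path(dir, "library_long.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_library
#' @export
read_library <- function(dir) {
  extra <- readRDS(file.path(dir, "std.rds"))
  structure(list(scores = readRDS(file.path(dir, "scores.rds")),
                 meta = read.table(file.path(dir, "meta.tsv"), header = TRUE,
                                   sep = "\t", stringsAsFactors = FALSE),
                 std = extra$std, log = extra$log),
            class = "score_library")
}
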