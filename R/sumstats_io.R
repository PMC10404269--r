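#' Read the GWAS column-name alias library
#'
#' Heterogeneous summary-statistics files name the same quantities in many
#' ways; a column map lists, per canonical field, the accepted header aliases
#' in priority order. The default map ships with the package as an editable
#' YAML file.
#'
#' @param path YAML file; default is the bundled alias library.
#' @return A named list of character vectors, class `column_map`.
#' @export
read_column_map <- function(path = system.file("extdata",
                                               "column_aliases.yaml",
                                               package = "multipgs")) {
  cm <- yaml::read_yaml(path)
  cm <- lapply(cm, function(x) tolower(as.character(x)))
  all_alias <- unlist(cm, use.names = FALSE)
  if (anyDuplicated(all_alias))
    stop("alias lists must be disjoint across canonical fields; duplicated: ",
         paste(unique(all_alias[duplicated(all_alias)]), collapse = ", "))
  structure(cm, class = "column_map")
}

default_column_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_column_map()
    cache
  }
})

sniff_delim <- function(header_line) {
  counts <- c("\t" = lengths(regmatches(header_line,
                                        gregexpr("\t", header_line))),
              "," = lengths(regmatches(header_line,
                                       gregexpr(",", header_line))),
              " " = lengths(regmatches(header_line,
                                       gregexpr(" +", header_line))))
  names(counts) <- c("\t", ",", " ")
  if (max(counts) == 0) stop("could not detect a delimiter in header")
  names(counts)[which.max(counts)]
}

#' Parse a GWAS summary-statistics file into canonical form
#'
#' Maps heterogeneous headers to canonical fields via the alias library,
#' converts odds ratios to log-odds betas (`beta = ln(OR)`), derives betas
#' from Z-scores when a standard error is present (`beta = z * se`), computes
#' the effective sample size from case/control counts when no total N column
#' exists, and drops rows with missing or non-finite mandatory fields
#' (rsid, a1, a0, beta, se), counting every drop. Tab-, comma- and
#' space-delimited files are auto-detected; gzip is transparent.
#'
#' @param path file path (optionally `.gz`).
#' @param column_map a `column_map`; default the bundled library.
#' @param n_eff_default effective sample size to use when the file carries
#'   no N information (otherwise an error).
#' @param trait_label,source_tag metadata stored on the result.
#' @return A `sumstats` object; `attr(,"meta")$parse_log` records row counts.
#'   Rejection (no usable effect column, zero parsable rows) signals an error
#'   of class `multipgs_parse_error` with a `reason` field
#'   (`"no_effect_column"`, `"empty_after_parse"`).
#' @export
parse_sumstats <- function(path, column_map = default_column_map(),
                           n_eff_default = NULL,
                           trait_label = basename(path),
                           source_tag = "file") {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  header_line <- readLines(con, n = 1)
  close(con)
  delim <- sniff_delim(header_line)
  # read everything as character: allele columns like "T" must never be
  # sniffed into logicals
  raw <- read.table(path, header = TRUE, sep = if (delim == " ") "" else delim,
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = FALSE, colClasses = "character")
  names(raw) <- tolower(names(raw))

  pick <- function(field) {
    hit <- intersect(column_map[[field]], names(raw))
    if (length(hit)) raw[[hit[1]]] else NULL
  }
  rsid <- pick("rsid"); a1 <- pick("a1"); a0 <- pick("a0")
  beta <- pick("beta"); or_col <- pick("or"); z <- pick("z"); se <- pick("se")

  reject <- function(reason) {
    stop(structure(class = c("multipgs_parse_error", "error", "condition"),
                   list(message = sprintf("%s: %s", basename(path), reason),
                        call = NULL, reason = reason)))
  }
  effect_type <- "beta"
  if (is.null(beta)) {
    if (!is.null(or_col)) {
      beta <- log(as.numeric(or_col)); effect_type <- "or"
    } else if (!is.null(z) && !is.null(se)) {
      beta <- as.numeric(z) * as.numeric(se); effect_type <- "z"
    } else reject("no_effect_column")
  } else beta <- as.numeric(beta)
  if (is.null(se)) reject("no_effect_column")
  if (is.null(rsid) || is.null(a1) || is.null(a0))
    reject("no_effect_column")

  n <- pick("n")
  if (is.null(n)) {
    nca <- pick("n_cases"); nco <- pick("n_controls")
    if (!is.null(nca) && !is.null(nco)) {
      n <- compute_n_eff(as.numeric(nca), as.numeric(nco))
    } else if (!is.null(n_eff_default)) {
      n <- rep(n_eff_default, nrow(raw))
    } else stop(basename(path), ": no sample-size column and no ",
                "`n_eff_default` supplied")
  }

  df <- data.frame(rsid = as.character(rsid),
                   chr = if (!is.null(pick("chr")))
                     as.integer(gsub("^chr", "", as.character(pick("chr"))))
                   else NA_integer_,
                   pos = if (!is.null(pick("pos"))) as.integer(pick("pos"))
                   else NA_integer_,
                   a1 = toupper(as.character(a1)),
                   a0 = toupper(as.character(a0)),
                   beta = beta,
                   se = as.numeric(se),
                   freq = if (!is.null(pick("freq"))) as.numeric(pick("freq"))
                   else NA_real_,
                   n_eff = as.numeric(n),
                   stringsAsFactors = FALSE)
  n_in <- nrow(df)
  ok <- !is.na(df$rsid) & nzchar(df$rsid) & !is.na(df$a1) & !is.na(df$a0) &
    is.finite(df$beta) & is.finite(df$se) & df$se > 0 & is.finite(df$n_eff) &
    df$n_eff > 0
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0) reject("empty_after_parse")
  # duplicated ids: keep the highest-information (smallest se) record
  if (anyDuplicated(df$rsid)) {
    df <- df[order(df$rsid, df$se), ]
    df <- df[!duplicated(df$rsid), ]
    df <- df[order(df$pos, df$rsid), ]
  }
  rownames(df) <- NULL
  new_sumstats(df, meta = list(
    trait = trait_label, source = source_tag, effect_type = effect_type,
    parse_log = list(n_in = n_in, n_dropped_invalid = n_in - nrow(df),
                     n_out = nrow(df))))
}

#' Effective sample size of a case-control GWAS
#'
#' `n_eff = 4 / (1/n_cases + 1/n_controls)`, the standard equivalent
#' balanced-design size; equals `2 * n` for a balanced study and is bounded
#' above by `4 * n_cases`.
#'
#' @param n_cases,n_controls positive counts (vectorized).
#' @return numeric vector of effective sample sizes.
#' @examples compute_n_eff(1000, 1000) # 2000
#' @export
compute_n_eff <- function(n_cases, n_controls) {
  if (any(n_cases <= 0) || any(n_controls <= 0))
    stop("case and control counts must be positive")
  4 / (1 / n_cases + 1 / n_controls)
}

is_ambiguous <- function(a1, a0) {
  flip <- chartr("ACGT", "TGCA", a1)
  a0 == flip
}

#' Harmonize summary statistics to an LD panel
#'
#' Matches variants to the panel by id (falling back to chromosome+position+
#' allele pair for id-less rows), aligns the effect allele with the panel's
#' counted allele (flipping the beta sign and the frequency when the alleles
#' are swapped), drops strand-ambiguous (A/T, C/G) variants, and drops
#' anything unmatched. The result carries the panel's variant order and a
#' `harmonize_log` of every action, so harmonizing twice is a no-op.
#'
#' @param sumstats a `sumstats` object.
#' @param panel an `ld_panel`.
#' @return harmonized `sumstats` with `panel_index` column (row in the panel
#'   variant table). Errors with class `multipgs_parse_error`
#'   (reason `"no_overlap"`) when nothing survives.
#' @export
harmonize <- function(sumstats, panel) {
  v <- panel$variants
  ss <- as.data.frame(sumstats)
  n_in <- nrow(ss)
  amb <- is_ambiguous(ss$a1, ss$a0)
  ss <- ss[!amb, , drop = FALSE]

  idx <- match(ss$rsid, v$id)
  no_id <- is.na(idx) & !is.na(ss$chr) & !is.na(ss$pos)
  if (any(no_id)) {
    key_panel <- paste(v$chr, v$pos)
    idx[no_id] <- match(paste(ss$chr[no_id], ss$pos[no_id]), key_panel)
  }
  matched <- !is.na(idx)
  ss <- ss[matched, , drop = FALSE]
  idx <- idx[matched]

  same <- ss$a1 == v$a1[idx] & ss$a0 == v$a0[idx]
  swapped <- ss$a1 == v$a0[idx] & ss$a0 == v$a1[idx]
  # strand-flipped representations of the same pair
  fl <- function(x) chartr("ACGT", "TGCA", x)
  same_strand <- fl(ss$a1) == v$a1[idx] & fl(ss$a0) == v$a0[idx]
  swapped_strand <- fl(ss$a1) == v$a0[idx] & fl(ss$a0) == v$a1[idx]
  keep <- same | swapped | same_strand | swapped_strand
  do_flip <- swapped | swapped_strand

  ss <- ss[keep, , drop = FALSE]
  idx <- idx[keep]
  do_flip <- do_flip[keep]
  if (nrow(ss) < 1)
    stop(structure(class = c("multipgs_parse_error", "error", "condition"),
                   list(message = "no variants overlap the panel",
                        call = NULL, reason = "no_overlap")))
  ss$beta[do_flip] <- -ss$beta[do_flip]
  ss$freq[do_flip] <- 1 - ss$freq[do_flip]
  ss$a1 <- v$a1[idx]
  ss$a0 <- v$a0[idx]
  ss$chr <- v$chr[idx]
  ss$pos <- v$pos[idx]
  ord <- order(idx)
  ss <- ss[ord, , drop = FALSE]
  idx <- idx[ord]
  ss$panel_index <- idx
  rownames(ss) <- NULL
  meta <- attr(sumstats, "meta")
  meta$harmonize_log <- list(
    n_in = n_in, n_ambiguous = sum(amb), n_unmatched = sum(!matched),
    n_allele_mismatch = sum(!keep), n_flipped = sum(do_flip),
    n_out = nrow(ss))
  new_sumstats(ss, meta = meta)
}

#' Standard-deviation QC of summary statistics against the panel
#'
#' Compares, per variant, the genotype standard deviation implied by the
#' reported standard error, `sd_ss = 1 / (se * sqrt(n_eff))` (phenotype-sd
#' units; case-control files use the effective sample size), with the
#' Hardy-Weinberg expectation from the panel MAF,
#' `sd_ref = sqrt(2 maf (1-maf))`. A variant is dropped when
#' `sd_ss < t_low * sd_ref`, `sd_ss > t_high * sd_ref`, `sd_ss < t_abs`
#' or `sd_ref < t_ref`. Inflated standard errors (mis-reported N, bad
#' imputation, trait-scale mixups) show up as sd_ss far below sd_ref.
#'
#' @param sumstats harmonized `sumstats` (needs `panel_index`).
#' @param panel an `ld_panel`.
#' @param thresholds named list overriding `t_low = 0.5`, `t_high = 1.1`,
#'   `t_abs = 0.05`, `t_ref = 0.05`.
#' @return filtered `sumstats`; `attr(,"meta")$sd_qc` holds drop counts and
#'   the full diagnostics table (`sd_ss`, `sd_ref`, `dropped`) for the QC
#'   scatter plot.
#' @export
sd_qc <- function(sumstats, panel, thresholds = list()) {
  th <- modifyList(list(t_low = 0.5, t_high = 1.1, t_abs = 0.05,
                        t_ref = 0.05), thresholds)
  ss <- as.data.frame(sumstats)
  if (is.null(ss$panel_index))
    stop("run harmonize() before sd_qc()")
  maf <- panel$variants$maf[ss$panel_index]
  sd_ref <- sqrt(2 * maf * (1 - maf))
  sd_ss <- 1 / (ss$se * sqrt(ss$n_eff))
  drop <- sd_ss < th$t_low * sd_ref | sd_ss > th$t_high * sd_ref |
    sd_ss < th$t_abs | sd_ref < th$t_ref
  diag_tab <- data.frame(rsid = ss$rsid, sd_ss = sd_ss, sd_ref = sd_ref,
                         dropped = drop)
  out <- ss[!drop, , drop = FALSE]
  rownames(out) <- NULL
  meta <- attr(sumstats, "meta")
  meta$sd_qc <- list(n_in = nrow(ss), n_dropped = sum(drop),
                     n_out = nrow(out), thresholds = th,
                     diagnostics = diag_tab)
  new_sumstats(out, meta = meta)
}

#' Minimum-SNP gate after QC
#'
#' A file is usable only if strictly more than `min_snps` variants survive
#' QC (genome-scale default 200,000; scale it down with the panel for
#' desk-size runs).
#'
#' @param sumstats QC'd `sumstats`.
#' @param min_snps integer threshold.
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
qc_gate <- function(sumstats, min_snps = 200000) {
  nrow(sumstats) > min_snps
}

#' Write / read canonical summary statistics
#'
#' Fixed column order (rsid, chr, pos, a1, a0, beta, se, freq, n_eff),
#' tab-delimited; round-trips all mandatory fields losslessly.
#'
#' @param sumstats a `sumstats` object.
#' @param path output TSV path (`.gz` supported).
#' @return `write_sumstats`: the path, invisibly. `read_sumstats`: a
#'   `sumstats` object.
#' @export
write_sumstats <- function(sumstats, path) {
  cols <- c("rsid", "chr", "pos", "a1", "a0", "beta", "se", "freq", "n_eff")
  df <- as.data.frame(sumstats)[, cols]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  new_sumstats(df, meta = list(trait = basename(path), source = "canonical"))
}
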