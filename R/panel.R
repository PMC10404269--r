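#' Simulate a block-diagonal LD reference panel
#'
#' Generates a stand-in for an external linkage-disequilibrium reference:
#' a variant table (id, chromosome, 1-based position, alleles, minor allele
#' frequency) plus a list of per-block correlation matrices. Within each block
#' the correlation is AR(1): \eqn{r_{jk} = \rho^{|j-k|}}, which is symmetric
#' positive definite for \eqn{|\rho| < 1}, so downstream solvers never meet a
#' non-PSD matrix. Blocks partition the variant list and are mutually
#' independent, mirroring how independent LD blocks are used as reference
#' panels for summary-statistics methods.
#'
#' @param m_variants total number of variants (>= block_size).
#' @param block_size number of variants per block; the last block absorbs the
#'   remainder.
#' @param rho AR(1) correlation parameter, |rho| < 1. A length-2 vector gives
#'   heterogeneous LD: each block draws its own rho uniformly from
#'   `[rho[1], rho[2]]` (deterministic given `seed`), producing the spread of
#'   LD scores real panels show across the genome.
#' @param maf_range length-2 numeric; MAFs drawn uniformly in this range,
#'   which must lie within (0, 0.5].
#' @param seed integer seed; fixed seed gives bit-identical panels.
#' @return An object of class `ld_panel`: list with `variants` (data.frame:
#'   id, chr, pos, a1, a0, maf), `blocks` (list of `(from, to, R)`), and `m`.
#' @examples
#' p <- simulate_panel(100, block_size = 20, rho = 0.7, seed = 1)
#' sapply(p$blocks, function(b) min(eigen(b$R, symmetric = TRUE,
#'                                         only.values = TRUE)$values))
#' @export
simulate_panel <- function(m_variants, block_size = 50, rho = 0.5,
                           maf_range = c(0.05, 0.5), seed = 1) {
  stopifnot(m_variants >= block_size, block_size >= 1, all(abs(rho) < 1),
            length(rho) %in% 1:2,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  m <- as.integer(m_variants)
  starts <- seq(1L, m, by = as.integer(block_size))
  ends <- c(starts[-1] - 1L, m)
  # merge a trailing stub into the previous block
  if (length(starts) > 1 && (ends[length(ends)] - starts[length(starts)] + 1L) <
      block_size / 2) {
    starts <- starts[-length(starts)]
    ends <- ends[-(length(ends) - 1L)]
  }
  rhos <- if (length(rho) == 2)
    with_seed(child_seed(seed, 7L), runif(length(starts), rho[1], rho[2]))
  else rep(rho, length(starts))
  blocks <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    sz <- ends[b] - starts[b] + 1L
    R <- rhos[b] ^ abs(outer(seq_len(sz), seq_len(sz), "-"))
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("block correlation matrix is not PSD")
    blocks[[b]] <- list(from = starts[b], to = ends[b], R = R)
  }
  variants <- with_seed(seed, {
    maf <- runif(m, maf_range[1], maf_range[2])
    bases <- c("A", "C", "G", "T")
    a1 <- sample(bases, m, replace = TRUE)
    # avoid strand-ambiguous pairs in the panel itself
    a0 <- vapply(a1, function(x) {
      sample(setdiff(bases, c(x, chartr("ACGT", "TGCA", x))), 1L)
    }, character(1))
    data.frame(id = sprintf("rs%06d", seq_len(m)),
               chr = rep(1L, m),
               pos = seq_len(m) * 1000L,
               a1 = a1, a0 = a0, maf = maf,
               stringsAsFactors = FALSE)
  })
  structure(list(variants = variants, blocks = blocks, m = m,
                 rho = rho, seed = seed),
            class = "ld_panel")
}

#' @exportS3Method base::print
print.ld_panel <- function(x, ...) {
  cat(sprintf("LD panel: %d variants in %d block(s), AR(1) rho = %g\n",
              x$m, length(x$blocks), x$rho))
  invisible(x)
}

# Block-wise matrix-vector product R %*% v over the whole panel.
panel_Rv <- function(panel, v) {
  out <- numeric(panel$m)
  for (b in panel$blocks) {
    idx <- b$from:b$to
    out[idx] <- as.numeric(b$R %*% v[idx])
  }
  out
}

# Quadratic form v' R v summed over blocks (genetic variance under LD).
panel_quadform <- function(panel, v) {
  s <- 0
  for (b in panel$blocks) {
    idx <- b$from:b$to
    s <- s + as.numeric(crossprod(v[idx], b$R %*% v[idx]))
  }
  s
}

# Cholesky factors of the blocks, cached on first use.
panel_chols <- function(panel) {
  if (!is.null(panel$.chols)) return(panel$.chols)
  lapply(panel$blocks, function(b) chol(b$R))
}

#' Write / read an LD panel
#'
#' The variant table is a TSV mirroring PLINK `.bim` columns
#' (chr, id, cm, pos, a1, a0) plus maf; block matrices go to an RDS array
#' store next to it.
#'
#' @param panel an `ld_panel`.
#' @param dir output directory (created if needed).
#' @return `write_panel` returns `dir` invisibly; `read_panel` an `ld_panel`.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- panel$variants
  bim <- data.frame(chr = v$chr, id = v$id, cm = 0, pos = v$pos,
                    a1 = v$a1, a0 = v$a0, maf = v$maf)
  write.table(bim, file.path(dir, "variants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  saveRDS(panel$blocks, file.path(dir, "blocks.rds"))
  writeLines(jsonlite::toJSON(list(m = panel$m, rho = panel$rho,
                                   seed = panel$seed), auto_unbox = TRUE),
             file.path(dir, "panel.json"))
  invisible(dir)
}

#' @rdname write_panel
#' @export
read_panel <- function(dir) {
  bim <- read.table(file.path(dir, "variants.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  meta <- jsonlite::fromJSON(file.path(dir, "panel.json"))
  structure(list(
    variants = data.frame(id = bim$id, chr = bim$chr, pos = bim$pos,
                          a1 = bim$a1, a0 = bim$a0, maf = bim$maf,
                          stringsAsFactors = FALSE),
    blocks = readRDS(file.path(dir, "blocks.rds")),
    m = meta$m, rho = meta$rho, seed = meta$seed), class = "ld_panel")
}
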