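#' @useDynLib multipgs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor dnorm integrate lm pnorm predict qnorm quantile
#'   rbeta rbinom rnorm runif sd var median glm binomial gaussian
#'   complete.cases setNames
#' @importFrom utils read.table write.table head modifyList
NULL

# Child-seed derivation: one master seed, fixed offsets per operation so that
# independent stages never share an RNG stream. Kept below 2^31 - 1.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647L)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_prob <- function(x, name, lo = 0, hi = 1,
                                  open_lo = TRUE, open_hi = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lo) x > lo else x >= lo) &&
    (if (open_hi) x < hi else x <= hi)
  if (!ok) stop(sprintf("`%s` must be a scalar in %s%g, %g%s", name,
                        if (open_lo) "(" else "[", lo, hi,
                        if (open_hi) ")" else "]"), call. = FALSE)
  invisible(x)
}

# Checksums for the pipeline manifest; text files get md5 of contents.
file_checksums <- function(paths) {
  sums <- tools::md5sum(paths)
  data.frame(file = basename(paths), md5 = unname(sums),
             stringsAsFactors = FALSE)
}
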