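#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a global seed
#'
#' All randomized stages consume seeds derived from one global seed by fixed
#' small offsets, so a single `--seed` reproduces a whole run. Kept below
#' 2^31 - 1.
#' @param seed integer global seed
#' @param offset integer stage offset
#' @return integer seed
#' @export
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647)
}

# per-site cM weights: adjacent-midpoint gaps, summing exactly to
# cM[last] - cM[first] for each chromosome
site_weights <- function(cM) {
  n <- length(cM)
  if (n == 1L) return(0)
  mid <- (cM[-1] + cM[-n]) / 2
  c(mid[1] - cM[1], diff(mid), cM[n] - mid[n - 1])
}

# total length of the intersection of two sets of disjoint intervals,
# given as two-column matrices [start, end)
interval_intersect_length <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  tot <- 0
  i <- 1L; j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    lo <- max(a[i, 1], b[j, 1])
    hi <- min(a[i, 2], b[j, 2])
    if (hi > lo) tot <- tot + (hi - lo)
    if (a[i, 2] <= b[j, 2]) i <- i + 1L else j <- j + 1L
  }
  tot
}

# run a block of code under a local RNG state with the given seed, restoring
# the caller's RNG afterwards
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
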