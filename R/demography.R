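#' Coalescence probability per generation under a diploid Ne trajectory
#'
#' For a pair of haplotype lineages, `P(g) = 1/(2 Ne(g)) *
#' prod_{h<g} (1 - 1/(2 Ne(h)))`: the probability that the pair first
#' coalesces exactly g generations ago.
#'
#' @param ne vector of diploid effective sizes for generations 1..G (a
#'   scalar is recycled).
#' @param G number of generations.
#' @return list with `p` (length G) and `residual` (mass beyond G);
#'   `sum(p) + residual == 1`.
#' @export
coalescence_pmf <- function(ne, G = length(ne)) {
  ne <- rep_len(ne, G)
  if (any(ne <= 0)) stopf("Ne must be positive")
  rate <- 1 / (2 * ne)
  if (any(rate > 1)) stopf("Ne must be >= 0.5")
  surv <- cumprod(1 - rate)
  p <- rate * c(1, head(surv, -1L))
  list(p = p, residual = surv[G])
}

#' Expected IBD segment-length spectrum per haplotype pair
#'
#' Under the Haldane model, a segment inherited from a coalescence g
#' generations ago has exponential length with rate 2g per Morgan. The
#' expected number of segments of length >= u Morgans per haplotype pair is
#' `sum_g P(g) * 2 g L * exp(-2 g u)` on an infinite-chromosome
#' approximation. When chromosome lengths are supplied a refined model is
#' used: chromosome ends are accounted for, and segment terminations are
#' thinned by the total coalescence mass `cbar = sum_g P(g)` — a
#' recombination breakpoint ends an observed segment only when the detached
#' lineage fails to re-coalesce within the horizon, so maximal shared
#' segments are fewer and longer than per-coalescence episodes:
#' `sum_g P(g) * sum_c exp(-lam_g u) (lam_g (Lc - u) + 1)` with
#' `lam_g = 2 g (1 - cbar)`.
#'
#' @param ne Ne trajectory (vector, generations 1..G, or scalar).
#' @param L total genome length in Morgans (ignored when `chrom_lengths`
#'   given).
#' @param bins_cM increasing bin edges in cM (first edge is the detection
#'   threshold); a final open bin to infinity is added.
#' @param G number of generations of ancestry contributing (coalescences
#'   beyond G are excluded, matching a panel whose founders are unrelated).
#' @param chrom_lengths optional per-chromosome lengths in Morgans.
#' @return list with `edges_cM`, `expected` (per haplotype pair, one value
#'   per bin including the open tail bin) and `tail` function
#'   (`tail(u_morgans)` = expected count of segments >= u).
#' @export
expected_spectrum <- function(ne, L = NULL, bins_cM = c(4, 6, 8, 10, 12, 16, 20, 30),
                              G = length(ne), chrom_lengths = NULL) {
  pmf <- coalescence_pmf(ne, G)
  g <- seq_len(G)
  cbar <- sum(pmf$p)
  lam <- 2 * g * (1 - cbar)
  tail_fun <- function(u) {
    if (any(u < 0)) stopf("u must be non-negative")
    vapply(u, function(ui) {
      if (is.null(chrom_lengths)) {
        sum(pmf$p * 2 * g * L * exp(-2 * g * ui))
      } else {
        per_chr <- vapply(chrom_lengths, function(Lc) {
          if (ui >= Lc) return(0)
          sum(pmf$p * exp(-lam * ui) * (lam * (Lc - ui) + 1))
        }, numeric(1L))
        sum(per_chr)
      }
    }, numeric(1L))
  }
  edges <- sort(bins_cM) / 100
  tails <- tail_fun(edges)
  expected <- c(-diff(tails), tails[length(tails)])
  list(edges_cM = sort(bins_cM), expected = expected, tail = tail_fun)
}

#' Observed IBD segment-length spectrum
#'
#' Bins within-group segment lengths (> the first edge) for Ne fitting. The
#' segment table and individual list are retained so that bootstrap
#' resampling of individuals can recompute the spectrum.
#'
#' @param segments segment data.frame with `id_a`, `id_b`, `length_cM`.
#' @param individuals ids of the analyzed individuals (defines the number of
#'   haplotype pairs `2 n (n - 1)`).
#' @param bins_cM increasing bin edges in cM, first edge >= the selection
#'   threshold (default 4 cM); an open tail bin is added.
#' @param chrom_lengths_cM per-chromosome map lengths in cM.
#' @return object of class `segment_spectrum`.
#' @export
segment_spectrum <- function(segments, individuals,
                             bins_cM = c(4, 6, 8, 10, 12, 16, 20, 30),
                             chrom_lengths_cM = NULL) {
  edges <- sort(bins_cM)
  segments <- segments[segments$length_cM >= edges[1L] &
                         as.character(segments$id_a) != as.character(segments$id_b), ,
                       drop = FALSE]
  n <- length(individuals)
  counts <- bin_counts(segments$length_cM, edges)
  seg_cols <- intersect(c("id_a", "id_b", "length_cM", "chrom", "start_cM", "end_cM"),
                        names(segments))
  structure(list(edges_cM = edges, counts = counts,
                 n_individuals = n, n_pairs = 2 * n * (n - 1),
                 segments = segments[, seg_cols],
                 individuals = as.character(individuals),
                 chrom_lengths_cM = chrom_lengths_cM,
                 L_morgans = if (is.null(chrom_lengths_cM)) NULL
                             else sum(chrom_lengths_cM) / 100),
            class = "segment_spectrum")
}

bin_counts <- function(len, edges, w = NULL) {
  idx <- findInterval(len, edges)
  if (is.null(w)) w <- rep(1, length(len))
  out <- tapply(w, factor(idx, levels = seq_along(edges)), sum)
  as.numeric(ifelse(is.na(out), 0, out))
}

ne_knots <- function(G, every) {
  k <- ceiling(G / every)
  rep(seq_len(k), each = every)[seq_len(G)]
}

fit_ne_point <- function(counts, n_pairs, edges_cM, G, knot_every, smoothing,
                         L, chrom_lengths, ne_bounds) {
  knot_of <- ne_knots(G, knot_every)
  nk <- max(knot_of)
  total <- max(sum(counts), 1)
  obj <- function(theta) {
    ne <- 10^theta[knot_of]
    sp <- expected_spectrum(ne, L = L, bins_cM = edges_cM, G = G,
                            chrom_lengths = chrom_lengths)
    e <- pmax(sp$expected * n_pairs, 1e-12)
    o <- counts
    dev <- 2 * sum(e - o + ifelse(o > 0, o * log(o / e), 0))
    dev / total + smoothing * sum(diff(theta)^2)
  }
  fit <- optim(rep(3, nk), obj, method = "L-BFGS-B",
               lower = log10(ne_bounds[1L]), upper = log10(ne_bounds[2L]),
               control = list(maxit = 300L))
  10^fit$par[knot_of]
}

#' Fit a recent Ne trajectory to an IBD segment-length spectrum
#'
#' Minimizes the Poisson deviance between observed per-bin segment counts
#' and the expectation from [expected_spectrum()] over a piecewise-constant
#' log10-Ne trajectory (knots every `knot_every` generations), with a
#' squared-difference smoothness penalty on adjacent knots. The deviance is
#' normalized by the total observed count so the point estimate is invariant
#' to rescaling counts and pair numbers together. Confidence bands come from
#' resampling individuals with replacement and refitting.
#'
#' @param spectrum a [segment_spectrum()].
#' @param G number of generations to fit (default 50).
#' @param n_bootstrap bootstrap replicates (default 100; 0 disables bands).
#' @param smoothing penalty weight on adjacent squared log10-Ne differences
#'   (default 0.02).
#' @param seed integer seed for the bootstrap.
#' @param knot_every knot spacing in generations (default 5).
#' @param ne_bounds allowed diploid Ne range (default `c(10, 1e8)`).
#' @param bootstrap_unit what a bootstrap replicate resamples:
#'   `"both"` (default) resamples individuals with replacement and, jointly,
#'   genomic blocks of `block_cM`; `"individuals"` resamples individuals
#'   only; `"blocks"` genomic blocks only. Individual resampling captures
#'   sampling noise; block resampling additionally captures the correlated
#'   variation of the realized genealogy along the genome, which
#'   individual resampling alone understates.
#' @param block_cM genomic block length for block resampling (default 10).
#' @return object of class `ne_trajectory`: data.frame `trajectory`
#'   (`gen`, `Ne`, `lo95`, `hi95`) plus fit metadata.
#' @export
fit_ne <- function(spectrum, G = 50L, n_bootstrap = 100L, smoothing = 0.02,
                   seed = 1L, knot_every = 5L, ne_bounds = c(10, 1e8),
                   bootstrap_unit = c("both", "individuals", "blocks"),
                   block_cM = 10) {
  stopifnot(inherits(spectrum, "segment_spectrum"))
  bootstrap_unit <- match.arg(bootstrap_unit)
  if (sum(spectrum$counts) == 0) stopf("no segments above threshold")
  chrom_lengths <- if (is.null(spectrum$chrom_lengths_cM)) NULL
                   else spectrum$chrom_lengths_cM / 100
  L <- spectrum$L_morgans
  point <- fit_ne_point(spectrum$counts, spectrum$n_pairs, spectrum$edges_cM,
                        G, knot_every, smoothing, L, chrom_lengths, ne_bounds)
  lo <- hi <- rep(NA_real_, G)
  if (n_bootstrap > 0L) {
    if (is.null(spectrum$segments) || is.null(spectrum$individuals))
      stopf("spectrum lacks segment-level data needed for the bootstrap")
    seg <- spectrum$segments
    ids <- spectrum$individuals
    n <- length(ids)
    ia <- match(as.character(seg$id_a), ids)
    ib <- match(as.character(seg$id_b), ids)
    use_blocks <- bootstrap_unit %in% c("both", "blocks")
    use_indiv <- bootstrap_unit %in% c("both", "individuals")
    if (use_blocks) {
      if (!all(c("chrom", "start_cM", "end_cM") %in% names(seg)) ||
          is.null(spectrum$chrom_lengths_cM))
        stopf("block bootstrap needs segment positions and chromosome lengths")
      chrom_ids <- seq_along(spectrum$chrom_lengths_cM)
      nblk_per <- pmax(1L, floor(spectrum$chrom_lengths_cM / block_cM))
      blk0 <- c(0L, cumsum(nblk_per))
      ci <- as.integer(factor(seg$chrom, levels = sort(unique(seg$chrom))))
      mid <- (seg$start_cM + seg$end_cM) / 2
      within <- pmin(floor(mid / block_cM), nblk_per[ci] - 1L)
      seg_blk <- blk0[ci] + within + 1L
      B <- sum(nblk_per)
    }
    boots <- with_seed(derive_seed(seed, 7L), {
      replicate(n_bootstrap, {
        w <- rep(1, nrow(seg))
        np <- spectrum$n_pairs
        if (use_indiv) {
          m <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
          w <- m[ia] * m[ib]
          np <- 2 * (n^2 - sum(m^2))
        }
        if (use_blocks) {
          wb <- tabulate(sample.int(B, B, replace = TRUE), nbins = B)
          w <- w * wb[seg_blk]
        }
        cb <- bin_counts(seg$length_cM, spectrum$edges_cM, w)
        if (sum(cb) == 0 || np <= 0) return(rep(NA_real_, G))
        fit_ne_point(cb, np, spectrum$edges_cM, G, knot_every, smoothing,
                     L, chrom_lengths, ne_bounds)
      })
    })
    lo <- apply(boots, 1L, quantile, probs = 0.025, na.rm = TRUE)
    hi <- apply(boots, 1L, quantile, probs = 0.975, na.rm = TRUE)
  }
  structure(list(trajectory = data.frame(gen = seq_len(G), Ne = point,
                                         lo95 = pmin(lo, point),
                                         hi95 = pmax(hi, point)),
                 spectrum = spectrum, smoothing = smoothing,
                 knot_every = knot_every, n_bootstrap = n_bootstrap),
            class = "ne_trajectory")
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat("Ne trajectory (diploid):\n")
  print(summary_ne(x), row.names = FALSE)
  invisible(x)
}

#' Summary table of an Ne trajectory at reporting generations
#' @param traj an `ne_trajectory`.
#' @param gens generations to report (default 5, 15, 30).
#' @return data.frame with `gen`, `Ne`, `lo95`, `hi95`.
#' @export
summary_ne <- function(traj, gens = c(5L, 15L, 30L)) {
  traj$trajectory[traj$trajectory$gen %in% gens, , drop = FALSE]
}

#' Write an Ne trajectory as TSV
#' @param traj an `ne_trajectory`.
#' @param path output path.
#' @param summary_path optional path for the reporting-generation summary.
#' @param gens reporting generations.
#' @export
write_ne <- function(traj, path, summary_path = NULL, gens = c(5L, 15L, 30L)) {
  write.table(traj$trajectory, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path))
    write.table(summary_ne(traj, gens), summary_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(path)
}
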