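#' ROH scan parameters
#'
#' Defaults mirror the standard PLINK sliding-window scan: 50-SNP windows
#' with at most 1 heterozygote and 5 missing calls, runs of at least 50 SNPs
#' and 1500 kb, maximum inter-SNP gap 1000 kb, density at least one SNP per
#' 50 kb, and a window hit-rate threshold of 0.05.
#' @param window_snp,window_het_max,window_missing_max,min_snp,min_kb,max_gap_kb,min_density_kb_per_snp,window_hit_threshold scan parameters.
#' @return object of class `roh_params`.
#' @export
roh_params <- function(window_snp = 50L, window_het_max = 1L,
                       window_missing_max = 5L, min_snp = 50L, min_kb = 1500,
                       max_gap_kb = 1000, min_density_kb_per_snp = 50,
                       window_hit_threshold = 0.05) {
  p <- list(window_snp = as.integer(window_snp),
            window_het_max = as.integer(window_het_max),
            window_missing_max = as.integer(window_missing_max),
            min_snp = as.integer(min_snp), min_kb = min_kb,
            max_gap_kb = max_gap_kb,
            min_density_kb_per_snp = min_density_kb_per_snp,
            window_hit_threshold = window_hit_threshold)
  if (any(unlist(p) <= 0)) stopf("all ROH parameters must be positive")
  structure(p, class = "roh_params")
}

roll_sum <- function(x, w) {
  cs <- c(0, cumsum(x))
  cs[(w + 1L):length(cs)] - cs[seq_len(length(cs) - w)]
}

detect_roh_one <- function(g, bp, params) {
  S <- length(g)
  W <- params$window_snp
  if (S < W) return(NULL)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  pass <- roll_sum(het, W) <= params$window_het_max &
    roll_sum(mis, W) <= params$window_missing_max
  # hit rate per SNP: passing windows containing it / windows containing it
  nw <- S - W + 1L
  cp <- c(0, cumsum(pass))
  lo <- pmax(seq_len(S) - W + 1L, 1L)
  hi <- pmin(seq_len(S), nw)
  covered <- hi >= lo
  npass <- ifelse(covered, cp[hi + 1L] - cp[lo], 0)
  ncov <- ifelse(covered, hi - lo + 1L, 0L)
  cand <- covered & (npass / pmax(ncov, 1L)) >= params$window_hit_threshold
  if (!any(cand)) return(NULL)
  # maximal candidate runs, split at gaps > max_gap_kb
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (i in which(r$values)) {
    idx <- starts[i]:ends[i]
    brk <- which(diff(bp[idx]) > params$max_gap_kb * 1000)
    sub_start <- c(idx[1L], idx[brk + 1L])
    sub_end <- c(idx[brk], idx[length(idx)])
    for (j in seq_along(sub_start)) {
      a <- sub_start[j]; b <- sub_end[j]
      n_snp <- b - a + 1L
      kb <- (bp[b] - bp[a]) / 1000
      if (n_snp >= params$min_snp && kb >= params$min_kb &&
          kb / n_snp <= params$min_density_kb_per_snp) {
        segs[[length(segs) + 1L]] <- c(a, b, n_snp)
      }
    }
  }
  if (!length(segs)) return(NULL)
  do.call(rbind, segs)
}

#' Detect runs of homozygosity
#'
#' Sliding-window scan: every `window_snp`-SNP window with at most
#' `window_het_max` heterozygotes and `window_missing_max` missing calls
#' passes; each SNP's hit rate is the fraction of windows containing it that
#' pass; SNPs at or above `window_hit_threshold` are run candidates; maximal
#' candidate runs (split at inter-SNP gaps over `max_gap_kb`) are reported
#' when they reach `min_snp` SNPs, `min_kb` kb and a density of at least one
#' SNP per `min_density_kb_per_snp` kb.
#'
#' @param genotypes S x N matrix of 0/1/2 genotypes (NA = missing) or the
#'   list returned by [panel_genotypes()].
#' @param sites data.frame with `chrom` and `bp` (sorted within chromosome);
#'   taken from `genotypes` when it is a [panel_genotypes()] list.
#' @param params a [roh_params()].
#' @return data.frame: `id`, `chrom`, `start_bp`, `end_bp`, `n_snp`, `kb`.
#' @export
detect_roh <- function(genotypes, sites = NULL, params = roh_params()) {
  if (is.list(genotypes) && !is.null(genotypes$geno)) {
    sites <- genotypes$sites
    genotypes <- genotypes$geno
  }
  stopifnot(!is.null(sites), nrow(sites) == nrow(genotypes))
  ids <- colnames(genotypes) %||% as.character(seq_len(ncol(genotypes)))
  out <- list()
  for (ch in unique(sites$chrom)) {
    rows <- which(sites$chrom == ch)
    bp <- sites$bp[rows]
    if (is.unsorted(bp)) stopf("unsorted positions on chromosome %s", ch)
    for (ind in seq_len(ncol(genotypes))) {
      m <- detect_roh_one(genotypes[rows, ind], bp, params)
      if (is.null(m)) next
      out[[length(out) + 1L]] <- data.frame(
        id = ids[ind], chrom = ch,
        start_bp = bp[m[, 1L]], end_bp = bp[m[, 2L]],
        n_snp = m[, 3L], kb = (bp[m[, 2L]] - bp[m[, 1L]]) / 1000)
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(id = character(0), chrom = integer(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_snp = integer(0), kb = numeric(0))
  out
}

#' ROH-based inbreeding coefficient F_ROH
#'
#' Fraction of the genome covered by ROH strictly longer than `min_bp`
#' (1.5 Mb). The default denominator is the autosomal human genome length
#' used for biobank-scale data (2,879,248,291 bp); for simulated panels pass
#' the simulated genome length.
#'
#' @param segments from [detect_roh()].
#' @param genome_bp genome length denominator in bp.
#' @param ids optional individual ids to report (zeros when absent from
#'   `segments`).
#' @param min_bp minimum ROH length counted, strict (default 1.5e6).
#' @return named numeric vector of F_ROH values.
#' @export
f_roh <- function(segments, genome_bp = 2879248291, ids = NULL, min_bp = 1.5e6) {
  len <- segments$end_bp - segments$start_bp
  keep <- len > min_bp
  agg <- tapply(len[keep], segments$id[keep], sum)
  if (is.null(ids)) ids <- sort(unique(as.character(segments$id)))
  out <- setNames(rep(0, length(ids)), ids)
  hit <- intersect(names(agg), ids)
  out[hit] <- agg[hit] / genome_bp
  out
}

#' F_SNP from homozygosity counts
#'
#' The excess-homozygosity ratio `(O_HOM - E_HOM) / (N - E_HOM)`: 0 when the
#' observed homozygote count matches the Hardy-Weinberg expectation, 1 when
#' every site is homozygous.
#' @param o_hom observed homozygous site count.
#' @param e_hom expected homozygous count under HWE.
#' @param n number of sites.
#' @return the inbreeding coefficient (NA when `n == e_hom`).
#' @export
f_snp_value <- function(o_hom, e_hom, n) {
  ifelse(abs(n - e_hom) < 1e-12, NA_real_, (o_hom - e_hom) / (n - e_hom))
}

#' SNP-based inbreeding coefficient F_SNP
#'
#' Excess homozygosity in the current generation:
#' `F_SNP = (O_HOM - E_HOM) / (N - E_HOM)`, with `E_HOM =
#' sum_i (1 - 2 p_i (1 - p_i) n_i / (n_i - 1))` over the group's polymorphic
#' sites, `p_i` the within-group allele frequency and `n_i` the allele-copy
#' count. 0 indicates random mating, > 0 inbreeding, < 0 inbreeding
#' avoidance. Frequencies are computed within the supplied cluster groups.
#'
#' @param genotypes S x N 0/1/2 matrix (NA = missing) or
#'   [panel_genotypes()] list.
#' @param group_assignment named vector individual -> group (defaults to one
#'   group).
#' @return data.frame: `id`, `group`, `F_SNP`, `O_HOM`, `E_HOM`, `N`.
#' @export
f_snp <- function(genotypes, group_assignment = NULL) {
  if (is.list(genotypes) && !is.null(genotypes$geno)) genotypes <- genotypes$geno
  ids <- colnames(genotypes) %||% as.character(seq_len(ncol(genotypes)))
  if (is.null(group_assignment))
    group_assignment <- setNames(rep("all", length(ids)), ids)
  grp <- group_assignment[ids]
  if (anyNA(grp)) stopf("every individual needs a group")
  res <- vector("list", length(ids))
  for (g in unique(grp)) {
    members <- which(grp == g)
    sub <- genotypes[, members, drop = FALSE]
    n_i <- 2 * rowSums(!is.na(sub))
    p_i <- rowSums(sub, na.rm = TRUE) / n_i
    poly <- n_i >= 2 & p_i > 0 & p_i < 1
    e_site <- 1 - 2 * p_i * (1 - p_i) * n_i / (n_i - 1)
    for (m in members) {
      use <- poly & !is.na(genotypes[, m])
      N <- sum(use)
      E <- sum(e_site[use])
      O <- sum(genotypes[use, m] != 1L)
      res[[m]] <- data.frame(id = ids[m], group = g, F_SNP = f_snp_value(O, E, N),
                             O_HOM = O, E_HOM = E, N = N)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write ROH and inbreeding tables
#' @param roh from [detect_roh()].
#' @param inb data.frame joining [f_roh()] and [f_snp()] output.
#' @param dir output directory.
#' @export
write_inbreeding <- function(roh, inb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(roh, file.path(dir, "roh.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(inb, file.path(dir, "inbreeding.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
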