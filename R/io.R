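#' Read a phased VCF into a haplotype panel
#'
#' Biallelic records only (multi-allelic sites are skipped with a warning);
#' all genotypes must be phased (`|` separator) — an unphased record is an
#' error naming the offending site. Genetic positions come from a map file
#' via [genetic_positions()], or default to bp / 1e6 (1 cM = 1 Mb) when no
#' map is given.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param map_path optional genetic map (PLINK `.map` or 3-column
#'   chrom/bp/cM).
#' @return a [haplotype_panel()].
#' @export
read_phased_vcf <- function(path, map_path = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("read_phased_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    warnf("%d multi-allelic record(s) skipped", sum(multi))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- t(as.matrix(gt))
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  if (anyNA(gt)) stopf("missing genotypes are not supported in phased input")
  unphased <- grepl("/", gt, fixed = TRUE)
  if (any(unphased)) {
    i <- which(unphased)[1L]
    r <- (i - 1L) %% nrow(gt) + 1L
    cc <- (i - 1L) %/% nrow(gt) + 1L
    stopf("unphased genotype at %s:%s (sample %s)",
          fix[r, "CHROM"], fix[r, "POS"], colnames(gt)[cc])
  }
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  H <- 2L * ncol(gt)
  alleles <- matrix(0L, nrow(gt), H)
  alleles[, seq(1L, H, 2L)] <- as.integer(a1)
  alleles[, seq(2L, H, 2L)] <- as.integer(a2)
  chrom <- fix[, "CHROM"]
  bp <- as.integer(fix[, "POS"])
  cM <- if (is.null(map_path)) bp / 1e6
        else genetic_positions(map_path, chrom, bp)
  haplotype_panel(alleles, data.frame(chrom = chrom, bp = bp, cM = cM),
                  indiv = colnames(gt))
}

#' Genetic positions from a recombination map
#'
#' Linear interpolation of cM between flanking map points, with constant
#' extrapolation beyond the map ends, per chromosome.
#'
#' @param map a file path or data.frame; either PLINK `.map` layout
#'   (chrom, id, cM, bp) or 3 columns (chrom, bp, cM), rows increasing in bp
#'   within chromosome.
#' @param site_chrom,site_bp query site coordinates.
#' @return numeric cM positions.
#' @export
genetic_positions <- function(map, site_chrom, site_bp) {
  if (!is.data.frame(map)) map <- read.table(map, header = FALSE)
  if (ncol(map) >= 4L) map <- data.frame(chrom = map[[1L]], bp = map[[4L]], cM = map[[3L]])
  else map <- data.frame(chrom = map[[1L]], bp = map[[2L]], cM = map[[3L]])
  out <- numeric(length(site_bp))
  for (ch in unique(site_chrom)) {
    sub <- map[map$chrom == ch, , drop = FALSE]
    if (!nrow(sub)) stopf("chromosome %s absent from genetic map", ch)
    idx <- site_chrom == ch
    if (nrow(sub) == 1L) out[idx] <- sub$cM
    else out[idx] <- approx(sub$bp, sub$cM, xout = site_bp[idx], rule = 2L)$y
  }
  out
}

# Hardy-Weinberg exact test (Wigginton et al.), two-sided p from the
# conditional distribution of heterozygote counts
hwe_exact_p <- function(n_het, n_hom_min, n_hom_maj) {
  n <- n_het + n_hom_min + n_hom_maj
  if (n == 0L) return(1)
  rare <- 2L * n_hom_min + n_het
  probs <- numeric(rare + 1L)
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2L != rare %% 2L) mid <- mid + 1L
  probs[mid + 1L] <- 1
  h <- mid
  while (h >= 2L) {
    probs[h - 1L] <- probs[h + 1L] * h * (h - 1) /
      (4 * ((rare - h) / 2 + 1) * ((2 * n - rare - h) / 2 + 1))
    h <- h - 2L
  }
  h <- mid
  while (h + 2L <= rare) {
    probs[h + 3L] <- probs[h + 1L] * 4 * ((rare - h) / 2) * ((2 * n - rare - h) / 2) /
      ((h + 2) * (h + 1))
    h <- h + 2L
  }
  probs <- probs / sum(probs)
  min(1, sum(probs[probs <= probs[n_het + 1L] + 1e-12]))
}

#' QC parameters
#' @param max_site_missing,min_maf,min_hwe_p,max_indiv_missing,drop_strand_ambiguous site and individual filters.
#' @return object of class `qc_params`.
#' @export
qc_params <- function(max_site_missing = 0.05, min_maf = 0.02,
                      min_hwe_p = 1e-6, max_indiv_missing = 0.05,
                      drop_strand_ambiguous = TRUE) {
  structure(list(max_site_missing = max_site_missing, min_maf = min_maf,
                 min_hwe_p = min_hwe_p, max_indiv_missing = max_indiv_missing,
                 drop_strand_ambiguous = drop_strand_ambiguous),
            class = "qc_params")
}

#' Site and individual quality control
#'
#' Drops strand-ambiguous (A/T, G/C) sites, sites failing missingness, MAF
#' or Hardy-Weinberg exact-test thresholds, and individuals exceeding the
#' missingness bound. Reports counts per removal reason.
#'
#' @param genotypes S x N 0/1/2 matrix with NA for missing.
#' @param sites data.frame with at least `chrom`, `bp`; `ref`/`alt` columns
#'   enable the strand-ambiguity filter.
#' @param params a [qc_params()].
#' @return list: `geno`, `sites`, `keep_indiv`, `report`.
#' @export
qc_filter <- function(genotypes, sites, params = qc_params()) {
  S <- nrow(genotypes)
  drop_amb <- rep(FALSE, S)
  if (params$drop_strand_ambiguous && all(c("ref", "alt") %in% names(sites))) {
    pair <- paste0(sites$ref, sites$alt)
    drop_amb <- pair %in% c("AT", "TA", "GC", "CG")
  }
  miss <- rowMeans(is.na(genotypes))
  p <- rowMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  hwe <- vapply(seq_len(S), function(i) {
    g <- genotypes[i, ]
    g <- g[!is.na(g)]
    n_het <- sum(g == 1L)
    nalt <- sum(g == 2L); nref <- sum(g == 0L)
    hwe_exact_p(n_het, min(nalt, nref), max(nalt, nref))
  }, numeric(1L))
  drop_miss <- miss > params$max_site_missing
  drop_maf <- maf < params$min_maf
  drop_hwe <- hwe < params$min_hwe_p
  keep_site <- !(drop_amb | drop_miss | drop_maf | drop_hwe)
  g2 <- genotypes[keep_site, , drop = FALSE]
  imiss <- colMeans(is.na(g2))
  keep_indiv <- imiss <= params$max_indiv_missing
  report <- c(strand_ambiguous = sum(drop_amb),
              site_missingness = sum(drop_miss & !drop_amb),
              maf = sum(drop_maf & !drop_amb & !drop_miss),
              hwe = sum(drop_hwe & !drop_amb & !drop_miss & !drop_maf),
              individuals = sum(!keep_indiv))
  list(geno = g2[, keep_indiv, drop = FALSE],
       sites = sites[keep_site, , drop = FALSE],
       keep_indiv = keep_indiv, report = report)
}

#' Greedy LD pruning
#'
#' Sliding windows of `window_snp` sites advanced by `step`; within each
#' window, for every pair with squared Pearson correlation above `r2_max`
#' the later site is removed. Deterministic.
#'
#' @param genotypes S x N 0/1/2 matrix (NA allowed; pairwise-complete
#'   correlations).
#' @param window_snp,step,r2_max pruning parameters (PLINK-style defaults
#'   1000, 50, 0.2).
#' @return integer vector of retained site indices.
#' @export
ld_prune <- function(genotypes, window_snp = 1000L, step = 50L, r2_max = 0.2) {
  S <- nrow(genotypes)
  keep <- rep(TRUE, S)
  starts <- seq(1L, max(S - 1L, 1L), by = step)
  X <- t(genotypes)
  for (w0 in starts) {
    idx <- which(keep)[which(keep) >= w0 & which(keep) < w0 + window_snp]
    if (length(idx) < 2L) next
    cc <- suppressWarnings(cor(X[, idx, drop = FALSE],
                               use = "pairwise.complete.obs"))
    cc[is.na(cc)] <- 0
    for (i in seq_along(idx)) {
      if (!keep[idx[i]]) next
      for (j in seq_along(idx)) {
        if (j <= i || !keep[idx[j]]) next
        if (cc[i, j]^2 > r2_max) keep[idx[j]] <- FALSE
      }
    }
  }
  which(keep)
}

#' Variance-standardized genotype PCA
#'
#' Sites are centered by `2 p` and scaled by `sqrt(2 p (1 - p))` (missing
#' values imputed to the site mean; monomorphic sites dropped with a
#' warning); the top `k` components come from the eigendecomposition of the
#' individual-by-individual covariance. Coordinates are eigenvectors scaled
#' by the singular values.
#'
#' @param genotypes S x N 0/1/2 matrix.
#' @param k number of components.
#' @return N x k coordinate matrix.
#' @export
allele_pca <- function(genotypes, k = 2L) {
  p <- rowMeans(genotypes, na.rm = TRUE) / 2
  mono <- p <= 0 | p >= 1 | is.na(p)
  if (any(mono)) warnf("%d monomorphic site(s) dropped", sum(mono))
  g <- genotypes[!mono, , drop = FALSE]
  p <- p[!mono]
  if (!nrow(g)) stopf("no polymorphic sites")
  X <- (g - 2 * p) / sqrt(2 * p * (1 - p))
  X[is.na(X)] <- 0
  N <- ncol(X)
  if (k > N) stopf("k must not exceed the number of individuals")
  cv <- crossprod(X) / nrow(X)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values[seq_len(k)], 0)
  coords <- eg$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k, k)
  rownames(coords) <- colnames(genotypes)
  colnames(coords) <- paste0("PC", seq_len(k))
  coords
}
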