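#' Phased haplotype panel
#'
#' The substrate of painting, IBD detection and ROH scanning: binary alleles
#' for H haplotypes at S sites with physical (bp) and genetic (cM)
#' coordinates. Haplotypes are stored as columns in individual order
#' (individual i occupies columns 2i-1 and 2i).
#'
#' @param alleles S x H integer matrix of 0/1 alleles (sites in rows).
#' @param sites data.frame with columns `chrom`, `bp`, `cM`; `cM` must be
#'   non-decreasing within each chromosome.
#' @param indiv character vector of N = H/2 individual ids.
#' @param labels optional per-individual grouping labels.
#' @return object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, sites, indiv, labels = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  H <- ncol(alleles)
  if (H %% 2L != 0L) stopf("number of haplotypes must be even")
  if (length(indiv) != H %/% 2L) stopf("need one individual id per haplotype pair")
  if (nrow(sites) != nrow(alleles)) stopf("sites table must match allele rows")
  if (!all(alleles %in% c(0L, 1L))) stopf("alleles must be 0/1")
  for (ch in unique(sites$chrom)) {
    cm <- sites$cM[sites$chrom == ch]
    if (is.unsorted(cm)) stopf("site cM positions must be non-decreasing within chromosome %s", ch)
  }
  structure(list(alleles = alleles,
                 sites = as.data.frame(sites),
                 indiv = as.character(indiv),
                 labels = labels),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes (%d individuals), %d sites, %d chromosome(s), %.1f cM\n",
              ncol(x$alleles), length(x$indiv), nrow(x$alleles),
              length(unique(x$sites$chrom)), total_map_length(x)))
  invisible(x)
}

# total genetic map length in cM: sum over chromosomes of cM span between
# first and last site
total_map_length <- function(panel) {
  sum(tapply(panel$sites$cM, panel$sites$chrom, function(v) max(v) - min(v)))
}

# 0-based individual index per haplotype column
panel_hap_indiv <- function(panel) rep(seq_along(panel$indiv), each = 2L) - 1L

#' Diploid genotypes from a phased panel
#'
#' @param panel a [haplotype_panel()].
#' @return list with `geno` (S x N matrix of 0/1/2 alternate-allele counts),
#'   `sites`, `indiv`.
#' @export
panel_genotypes <- function(panel) {
  H <- ncol(panel$alleles)
  g <- panel$alleles[, seq(1L, H, 2L), drop = FALSE] +
    panel$alleles[, seq(2L, H, 2L), drop = FALSE]
  colnames(g) <- panel$indiv
  list(geno = g, sites = panel$sites, indiv = panel$indiv)
}

#' Write a panel as a phased VCF
#'
#' Minimal VCFv4.2 with phased `|`-separated GT fields, one biallelic record
#' per site (REF=A, ALT=C placeholders for simulated data).
#' @param panel a [haplotype_panel()].
#' @param path output path.
#' @export
write_phased_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=hapsharing",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$indiv), collapse = "\t")), con)
  H <- ncol(panel$alleles)
  gt <- matrix(paste(panel$alleles[, seq(1L, H, 2L), drop = FALSE],
                     panel$alleles[, seq(2L, H, 2L), drop = FALSE], sep = "|"),
               nrow = nrow(panel$alleles))
  body <- cbind(panel$sites$chrom, panel$sites$bp,
                paste0("snp", seq_len(nrow(panel$alleles))),
                "A", "C", ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write a PLINK-style genetic map
#'
#' Four columns: chromosome, snp id, position in cM, position in bp.
#' @param panel a [haplotype_panel()].
#' @param path output path.
#' @export
write_plink_map <- function(panel, path) {
  write.table(data.frame(chrom = panel$sites$chrom,
                         id = paste0("snp", seq_len(nrow(panel$sites))),
                         cM = panel$sites$cM, bp = panel$sites$bp),
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write ground-truth IBD segments as TSV
#' @param truth data.frame from [truth_ibd()].
#' @param path output path.
#' @export
write_truth_ibd <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-individual labels as TSV
#' @param panel a [haplotype_panel()] with labels, or a named vector.
#' @param path output path.
#' @export
write_labels <- function(panel, path) {
  if (inherits(panel, "haplotype_panel")) {
    df <- data.frame(id = panel$indiv, label = panel$labels %||% NA)
  } else {
    df <- data.frame(id = names(panel), label = as.vector(panel))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
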