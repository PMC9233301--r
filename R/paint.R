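#' Painting configuration
#'
#' @param chunks_per_region compatibility default carried in the output
#'   metadata (100, matching the ChromoPainter-style convention); chunk
#'   counts are not rescaled by it.
#' @param tie_break how a site is attributed when several donors achieve the
#'   longest covering match: `"seeded-random"` (default; a deterministic
#'   seeded hash picks among the tied donors, unbiased in expectation and
#'   reproducible) or `"split-equally"` (the site's length and the chunk
#'   count are shared equally among tied donors).
#' @param seed integer seed for the tie-break hash.
#' @return object of class `paint_config`.
#' @export
paint_config <- function(chunks_per_region = 100L,
                         tie_break = c("seeded-random", "split-equally"),
                         seed = 1L) {
  if (chunks_per_region < 1L) stopf("chunks_per_region must be >= 1")
  structure(list(chunks_per_region = as.integer(chunks_per_region),
                 tie_break = match.arg(tie_break),
                 seed = as.integer(seed)),
            class = "paint_config")
}

#' Set-maximal matches of one haplotype against a panel
#'
#' Returns every maximal identical interval between the target haplotype and
#' any other haplotype that is not contained, over the donor set, in a
#' strictly longer identical interval with another donor. Both haplotypes of
#' the target's own individual are excluded as donors. Matches are computed
#' per chromosome and never span chromosome boundaries.
#'
#' @param panel a [haplotype_panel()].
#' @param target_hap haplotype column index (1-based).
#' @return data.frame: `donor_hap` (1-based column), `start_site` (1-based),
#'   `end_site` (exclusive), `chrom`.
#' @export
maximal_matches <- function(panel, target_hap) {
  H <- ncol(panel$alleles)
  if (H < 4L) stopf("need >=2 other individuals")
  if (target_hap < 1L || target_hap > H) stopf("target_hap out of range")
  hi <- panel_hap_indiv(panel)
  eligible <- which(hi != hi[target_hap]) - 1L
  out <- lapply(unique(panel$sites$chrom), function(ch) {
    rows <- which(panel$sites$chrom == ch)
    m <- cpp_set_maximal(panel$alleles[rows, , drop = FALSE],
                         target_hap - 1L, eligible)
    if (!nrow(m)) return(NULL)
    data.frame(donor_hap = m[, 1L] + 1L,
               start_site = rows[1L] + m[, 2L],
               end_site = rows[1L] + m[, 3L],
               chrom = ch)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(out))
    out <- data.frame(donor_hap = integer(0), start_site = integer(0),
                      end_site = integer(0), chrom = integer(0))
  out[order(out$donor_hap, out$start_site), , drop = FALSE]
}

#' PBWT chunk painting of a panel
#'
#' Tiles each recipient haplotype into chunks: at every site the donor is the
#' haplotype with the longest identical interval covering that site; a chunk
#' is a maximal run of sites attributed to the same donor individual. Chunk
#' counts and genetic lengths (cM) are aggregated donor-haplotype to
#' donor-individual and recipient-haplotype to recipient-individual, and
#' summed over chromosomes into genome-wide coancestry matrices. Site
#' lengths are adjacent-midpoint cM weights, so each recipient row of the
#' chunklengths matrix sums exactly to 2 x the total map length.
#'
#' @param panel a [haplotype_panel()].
#' @param config a [paint_config()].
#' @return object of class `coancestry`: `chunkcounts` and `chunklengths`
#'   N x N matrices (rows = recipients, zero diagonal), `ids`,
#'   `map_length_cM`, `config`.
#' @export
paint_panel <- function(panel, config = paint_config()) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(config, "paint_config"))
  H <- ncol(panel$alleles)
  if (H < 4L) stopf("need >=2 other individuals")
  N <- H %/% 2L
  counts <- matrix(0, N, N, dimnames = list(panel$indiv, panel$indiv))
  lengths <- matrix(0, N, N, dimnames = list(panel$indiv, panel$indiv))
  hi <- panel_hap_indiv(panel)
  tie_mode <- if (config$tie_break == "seeded-random") 0L else 1L
  for (ch in unique(panel$sites$chrom)) {
    rows <- which(panel$sites$chrom == ch)
    if (length(rows) < 2L) {
      warnf("chromosome %s has < 2 sites; skipped", ch)
      next
    }
    w <- site_weights(panel$sites$cM[rows])
    cpp_paint_chrom(panel$alleles[rows, , drop = FALSE], hi, w,
                    counts, lengths, tie_mode, config$seed)
  }
  structure(list(chunkcounts = counts, chunklengths = lengths,
                 ids = panel$indiv, map_length_cM = total_map_length(panel),
                 config = config),
            class = "coancestry")
}

#' @export
print.coancestry <- function(x, ...) {
  cat(sprintf("coancestry: %d individuals, map length %.1f cM, mean chunk count %.2f\n",
              length(x$ids), x$map_length_cM, mean(rowSums(x$chunkcounts))))
  invisible(x)
}

#' PCA of a coancestry matrix
#'
#' Rows are normalized to sum 1, column means subtracted, and the singular
#' value decomposition taken; the first `k` left singular vectors scaled by
#' their singular values are returned. Component signs are fixed so that each
#' component's largest-magnitude loading is positive.
#'
#' @param coancestry a `coancestry` object or a square matrix.
#' @param k number of components (1 <= k <= N).
#' @param which `"chunkcounts"` (default, as used for structure PCA) or
#'   `"chunklengths"`.
#' @return N x k coordinate matrix with individual ids as row names.
#' @export
coancestry_pca <- function(coancestry, k = 2L, which = c("chunkcounts", "chunklengths")) {
  X <- if (inherits(coancestry, "coancestry")) coancestry[[match.arg(which)]]
       else as.matrix(coancestry)
  N <- nrow(X)
  if (k > N) stopf("k must not exceed the number of individuals")
  if (k < 1L) stopf("k must be >= 1")
  rs <- rowSums(X)
  rs[rs == 0] <- 1
  Xn <- sweep(X, 1L, rs, "/")
  Xc <- sweep(Xn, 2L, colMeans(Xn), "-")
  sv <- svd(Xc, nu = k, nv = k)
  coords <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(X)
  colnames(coords) <- paste0("PC", seq_len(k))
  coords
}

#' Write coancestry matrices as labelled square TSVs
#'
#' fineSTRUCTURE-compatible layout: header row and first column carry
#' individual ids.
#' @param coancestry a `coancestry` object.
#' @param dir output directory (created if needed).
#' @return paths of the two files, invisibly.
#' @export
write_coancestry <- function(coancestry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "chunkcounts.tsv")
  p2 <- file.path(dir, "chunklengths.tsv")
  write.table(coancestry$chunkcounts, p1, sep = "\t", quote = FALSE, col.names = NA)
  write.table(coancestry$chunklengths, p2, sep = "\t", quote = FALSE, col.names = NA)
  invisible(c(p1, p2))
}
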