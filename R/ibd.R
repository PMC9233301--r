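#' Detect IBD segments on a phased panel
#'
#' Reports every maximal pairwise identical haplotype interval of genetic
#' length at least `min_cM`, via a PBWT long-match scan (prefix/divergence
#' arrays) per chromosome. On error-free data these are exactly the maximal
#' allele-identity runs. Matches between the two haplotypes of one
#' individual are excluded. Segment genetic length is `cM(last site) -
#' cM(first site)` of the identical run.
#'
#' @param panel a [haplotype_panel()].
#' @param min_cM minimum reported genetic length (default 1 cM).
#' @return data.frame of segments: `id_a`, `hap_a`, `id_b`, `hap_b`,
#'   `chrom`, `start_bp`, `end_bp`, `length_cM`, `start_cM`, `end_cM`, plus
#'   internal site indices `start_site`/`end_site` (global, 1-based
#'   inclusive) used by [merge_ibd()]. Pair order is canonical
#'   (individual index a < b).
#' @export
detect_ibd <- function(panel, min_cM = 1) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (min_cM <= 0) stopf("min_cM must be positive")
  hi <- panel_hap_indiv(panel)
  out <- list()
  for (ch in unique(panel$sites$chrom)) {
    rows <- which(panel$sites$chrom == ch)
    cM <- panel$sites$cM[rows]
    if (is.unsorted(cM)) stopf("unsorted cM positions on chromosome %s", ch)
    S <- length(rows)
    # smallest possible number of sites spanning min_cM anywhere on this
    # chromosome: a run of genetic length >= min_cM has at least L0 sites
    reach <- findInterval(cM + min_cM, cM, left.open = TRUE) + 1L
    feas <- reach <= S
    if (!any(feas)) next
    L0 <- min(reach[feas] - which(feas) + 1L)
    m <- cpp_long_matches(panel$alleles[rows, , drop = FALSE], max(L0, 2L))
    if (!nrow(m)) next
    s1 <- m[, 3L] + 1L
    s2 <- m[, 4L]
    span <- cM[s2] - cM[s1]
    keep <- span >= min_cM & hi[m[, 1L] + 1L] != hi[m[, 2L] + 1L]
    if (!any(keep)) next
    h1 <- m[keep, 1L] + 1L
    h2 <- m[keep, 2L] + 1L
    swap <- h1 > h2
    tmp <- h1[swap]; h1[swap] <- h2[swap]; h2[swap] <- tmp
    i1 <- (h1 + 1L) %/% 2L
    i2 <- (h2 + 1L) %/% 2L
    out[[length(out) + 1L]] <- data.frame(
      id_a = panel$indiv[i1], hap_a = (h1 - 1L) %% 2L + 1L,
      id_b = panel$indiv[i2], hap_b = (h2 - 1L) %% 2L + 1L,
      chrom = ch,
      start_bp = panel$sites$bp[rows[s1[keep]]],
      end_bp = panel$sites$bp[rows[s2[keep]]],
      length_cM = span[keep],
      start_cM = cM[s1[keep]], end_cM = cM[s2[keep]],
      start_site = rows[s1[keep]], end_site = rows[s2[keep]]
    )
  }
  out <- do.call(rbind, out)
  if (is.null(out)) out <- empty_segments()
  out[order(out$id_a, out$hap_a, out$id_b, out$hap_b, out$chrom, out$start_cM), ,
      drop = FALSE]
}

empty_segments <- function() {
  data.frame(id_a = character(0), hap_a = integer(0), id_b = character(0),
             hap_b = integer(0), chrom = integer(0), start_bp = integer(0),
             end_bp = integer(0), length_cM = numeric(0), start_cM = numeric(0),
             end_cM = numeric(0), start_site = integer(0), end_site = integer(0))
}

#' Merge IBD segments across short, near-concordant gaps
#'
#' Genotyping and phase errors split true IBD segments into adjacent
#' detected pieces. Adjacent segments of the same haplotype pair and
#' chromosome are merged when the intervening gap is shorter than
#' `max_gap_cM` and contains at most `max_discordant` discordant sites
#' (sites where the two haplotypes carry different alleles), applied
#' transitively left to right.
#'
#' @param segments from [detect_ibd()] (site index columns required).
#' @param panel the [haplotype_panel()] the segments were detected on.
#' @param max_gap_cM gap bound, strict (default 0.6 cM).
#' @param max_discordant maximum discordant sites in the gap (default 1).
#' @return merged segment data.frame in the same layout.
#' @export
merge_ibd <- function(segments, panel, max_gap_cM = 0.6, max_discordant = 1L) {
  if (!nrow(segments)) return(segments)
  stopifnot(inherits(panel, "haplotype_panel"))
  key <- paste(segments$id_a, segments$hap_a, segments$id_b, segments$hap_b,
               segments$chrom, sep = "\r")
  ord <- order(key, segments$start_cM)
  segments <- segments[ord, , drop = FALSE]
  key <- key[ord]
  ia <- match(segments$id_a, panel$indiv)
  ib <- match(segments$id_b, panel$indiv)
  col_a <- 2L * ia - 2L + segments$hap_a
  col_b <- 2L * ib - 2L + segments$hap_b
  keep <- rep(TRUE, nrow(segments))
  cur <- 1L
  for (r in seq_len(nrow(segments))[-1L]) {
    if (key[r] == key[cur]) {
      gap <- segments$start_cM[r] - segments$end_cM[cur]
      if (gap < max_gap_cM) {
        gs <- segments$end_site[cur] + 1L
        ge <- segments$start_site[r] - 1L
        ndisc <- if (ge < gs) 0L else
          sum(panel$alleles[gs:ge, col_a[r]] != panel$alleles[gs:ge, col_b[r]])
        if (ndisc <= max_discordant) {
          segments$end_site[cur] <- segments$end_site[r]
          segments$end_bp[cur] <- segments$end_bp[r]
          segments$end_cM[cur] <- segments$end_cM[r]
          segments$length_cM[cur] <- segments$end_cM[cur] - segments$start_cM[cur]
          keep[r] <- FALSE
          next
        }
      }
    }
    cur <- r
  }
  segments[keep, , drop = FALSE]
}

#' Within-cluster IBD sharing summary
#'
#' For every individual, the mean total IBD length (cM) and mean segment
#' count over all other members of its cluster; partners with no shared
#' segment contribute zeros. Individuals in singleton clusters are flagged
#' with missing values.
#'
#' @param segments segment data.frame (detected or truth-derived) with
#'   `id_a`, `id_b`, `length_cM`.
#' @param assignment named vector (individual -> cluster) or `cluster_tree`.
#' @return data.frame: `id`, `cluster`, `mean_total_cM`, `mean_n_segments`.
#' @export
sharing_summary <- function(segments, assignment) {
  assignment <- resolve_assignment(assignment)
  ids <- names(assignment)
  tot <- setNames(rep(0, length(ids)), ids)
  cnt <- setNames(rep(0, length(ids)), ids)
  if (nrow(segments)) {
    same <- !is.na(assignment[as.character(segments$id_a)]) &
      !is.na(assignment[as.character(segments$id_b)]) &
      assignment[as.character(segments$id_a)] ==
        assignment[as.character(segments$id_b)] &
      as.character(segments$id_a) != as.character(segments$id_b)
    seg <- segments[same, , drop = FALSE]
    if (nrow(seg)) {
      add <- function(v, key, val) {
        s <- tapply(val, key, sum)
        v[names(s)] <- v[names(s)] + s
        v
      }
      tot <- add(tot, as.character(seg$id_a), seg$length_cM)
      tot <- add(tot, as.character(seg$id_b), seg$length_cM)
      cnt <- add(cnt, as.character(seg$id_a), rep(1, nrow(seg)))
      cnt <- add(cnt, as.character(seg$id_b), rep(1, nrow(seg)))
    }
  }
  size <- table(assignment)[assignment]
  npart <- as.numeric(size) - 1
  res <- data.frame(id = ids, cluster = unname(assignment),
                    mean_total_cM = ifelse(npart > 0, tot / npart, NA_real_),
                    mean_n_segments = ifelse(npart > 0, cnt / npart, NA_real_))
  rownames(res) <- NULL
  res
}

#' Mann-Whitney U rank test
#'
#' Two-sided Mann-Whitney U; exact p when `m * n <= 200` and there are no
#' ties, otherwise the normal approximation with tie and continuity
#' correction.
#' @param values_a,values_b numeric vectors (non-empty).
#' @return list with `U` (statistic for the first group) and `p`.
#' @export
rank_test <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) stopf("both groups must be non-empty")
  exact <- length(values_a) * length(values_b) <= 200 &&
    !any(duplicated(c(values_a, values_b)))
  wt <- suppressWarnings(wilcox.test(values_a, values_b, exact = exact,
                                     correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Length-weighted precision and recall of detected IBD against truth
#'
#' Intervals are compared per haplotype pair and chromosome in cM
#' coordinates. Precision = overlapping length / total detected length;
#' recall = overlapping length / total truth length. Both tables are
#' filtered to segments of length >= `min_cM` first; truth self-pairs
#' (autozygosity) are dropped since detection excludes them.
#'
#' @param detected from [detect_ibd()]/[merge_ibd()] (needs `start_cM`,
#'   `end_cM`).
#' @param truth from [truth_ibd()].
#' @param min_cM evaluation length threshold.
#' @return list with `precision`, `recall`, `detected_cM`, `truth_cM`.
#' @export
ibd_accuracy <- function(detected, truth, min_cM = 2) {
  truth <- truth[as.character(truth$id_a) != as.character(truth$id_b) &
                   truth$end_cM - truth$start_cM >= min_cM, , drop = FALSE]
  detected <- detected[detected$end_cM - detected$start_cM >= min_cM, , drop = FALSE]
  keyfun <- function(d) paste(d$id_a, d$hap_a, d$id_b, d$hap_b, d$chrom, sep = "\r")
  dk <- split(seq_len(nrow(detected)), keyfun(detected))
  tk <- split(seq_len(nrow(truth)), keyfun(truth))
  olap <- 0
  for (k in intersect(names(dk), names(tk))) {
    a <- detected[dk[[k]], c("start_cM", "end_cM"), drop = FALSE]
    b <- truth[tk[[k]], c("start_cM", "end_cM"), drop = FALSE]
    a <- as.matrix(a[order(a$start_cM), , drop = FALSE])
    b <- as.matrix(b[order(b$start_cM), , drop = FALSE])
    olap <- olap + interval_intersect_length(a, b)
  }
  dl <- sum(detected$end_cM - detected$start_cM)
  tl <- sum(truth$end_cM - truth$start_cM)
  list(precision = if (dl > 0) olap / dl else NA_real_,
       recall = if (tl > 0) olap / tl else NA_real_,
       detected_cM = dl, truth_cM = tl)
}

#' Write IBD segments as TSV
#'
#' Columns mirror refinedIBD-style output: sample1, hap1, sample2, hap2,
#' chrom, start_bp, end_bp, length_cM.
#' @param segments segment data.frame.
#' @param path output path.
#' @export
write_ibd <- function(segments, path) {
  write.table(segments[, c("id_a", "hap_a", "id_b", "hap_b", "chrom",
                           "start_bp", "end_bp", "length_cM")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
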