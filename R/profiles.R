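resolve_assignment <- function(assignment) {
  if (inherits(assignment, "cluster_tree")) assignment <- assignment$assignment
  if (is.null(names(assignment))) stopf("assignment must be named by individual id")
  assignment
}

#' Copying vectors of clusters
#'
#' For each cluster, averages its members' chunklength rows, sums the
#' columns by donor cluster and normalizes to 1: the cluster's profile of
#' haplotype material copied from each donor cluster.
#'
#' @param chunklengths a `coancestry` object or N x N matrix with individual
#'   ids as dimnames.
#' @param assignment named vector (individual -> cluster) or a
#'   `cluster_tree`.
#' @return K x K matrix; row g is the copying vector of cluster g.
#' @export
copying_vectors <- function(chunklengths, assignment) {
  M <- if (inherits(chunklengths, "coancestry")) chunklengths$chunklengths
       else as.matrix(chunklengths)
  assignment <- resolve_assignment(assignment)
  ids <- rownames(M) %||% as.character(seq_len(nrow(M)))
  cl <- assignment[ids]
  if (anyNA(cl)) stopf("every individual must be assigned to a cluster")
  clusters <- sort(unique(cl))
  agg <- matrix(0, length(clusters), length(clusters),
                dimnames = list(clusters, clusters))
  for (g in clusters) {
    members <- which(cl == g)
    if (!length(members)) stopf("empty cluster %s", g)
    row <- colMeans(M[members, , drop = FALSE])
    agg[g, ] <- tapply(row, cl, sum)[clusters]
  }
  sweep(agg, 1L, rowSums(agg), "/")
}

# cluster-level mean donation matrix: entry (g, h) is the mean over cluster-g
# individuals of total chunklength received from cluster-h donors
cluster_donation_matrix <- function(M, cl, clusters) {
  Z <- matrix(0, length(clusters), length(clusters),
              dimnames = list(clusters, clusters))
  for (g in clusters) {
    row <- colMeans(M[which(cl == g), , drop = FALSE])
    Z[g, ] <- tapply(row, cl, sum)[clusters]
  }
  Z
}

#' Non-negative least-squares haplotype-sharing profile
#'
#' Models a target cluster's mean copying from every other ("source")
#' cluster as a non-negative mixture of the source clusters' own copying
#' profiles: solves `min || xbar - t(Y) beta ||^2` subject to `beta >= 0`,
#' where `xbar` is the target's mean donated chunklength from each source
#' and `Y[k, l]` is the mean chunklength cluster-k individuals receive from
#' cluster l (source rows/columns only; the diagonal is retained). `beta` is
#' renormalized to sum 1 and interpreted as the average proportion of the
#' target's haplotypes best represented by each source.
#'
#' @param chunklengths a `coancestry` object or matrix.
#' @param assignment named vector or `cluster_tree`.
#' @param target_cluster the target cluster label.
#' @return object of class `sharing_profile`: `target`, `beta` (named,
#'   non-negative, sums to 1).
#' @export
nnls_profile <- function(chunklengths, assignment, target_cluster) {
  M <- if (inherits(chunklengths, "coancestry")) chunklengths$chunklengths
       else as.matrix(chunklengths)
  assignment <- resolve_assignment(assignment)
  ids <- rownames(M) %||% as.character(seq_len(nrow(M)))
  cl <- assignment[ids]
  clusters <- sort(unique(cl))
  if (length(clusters) < 2L) stopf("need >= 2 clusters")
  if (!target_cluster %in% clusters) stopf("unknown target cluster %s", target_cluster)
  sources <- setdiff(clusters, target_cluster)
  Z <- cluster_donation_matrix(M, cl, clusters)
  xbar <- Z[target_cluster, sources]
  Y <- Z[sources, sources, drop = FALSE]
  if (all(Y == 0) || qr(Y)$rank < length(sources)) stopf("degenerate source system")
  fit <- pracma::lsqnonneg(t(Y), as.numeric(xbar))
  beta <- fit$x
  if (sum(beta) <= 0) stopf("degenerate source system")
  beta <- beta / sum(beta)
  structure(list(target = target_cluster, beta = setNames(beta, sources)),
            class = "sharing_profile")
}

#' @export
print.sharing_profile <- function(x, ...) {
  cat(sprintf("sharing profile for cluster %s:\n", x$target))
  print(round(x$beta, 4))
  invisible(x)
}

#' All-cluster nnls profiles as a heat table
#' @param chunklengths a `coancestry` object or matrix.
#' @param assignment named vector or `cluster_tree`.
#' @return K x K matrix of beta proportions (zero diagonal).
#' @export
nnls_profiles <- function(chunklengths, assignment) {
  assignment <- resolve_assignment(assignment)
  clusters <- sort(unique(assignment))
  B <- matrix(0, length(clusters), length(clusters),
              dimnames = list(clusters, clusters))
  for (g in clusters) {
    pr <- nnls_profile(chunklengths, assignment, g)
    B[g, names(pr$beta)] <- pr$beta
  }
  B
}

#' Total variation distance between copying vectors
#'
#' `0.5 * sum(|a - b|)`: the maximum difference the two clusters' copying
#' profiles assign to any set of donor clusters. 0 for identical profiles,
#' 1 for disjoint support.
#' @param a,b equal-length non-negative vectors, each summing to 1.
#' @return value in `[0, 1]`.
#' @export
tvd <- function(a, b) {
  if (length(a) != length(b)) stopf("length mismatch")
  0.5 * sum(abs(a - b))
}

#' Pairwise TVD matrix between cluster copying vectors
#' @param cv matrix from [copying_vectors()].
#' @return symmetric K x K matrix.
#' @export
tvd_matrix <- function(cv) {
  K <- nrow(cv)
  out <- matrix(0, K, K, dimnames = dimnames(cv))
  for (i in seq_len(K)) for (j in seq_len(K))
    out[i, j] <- tvd(cv[i, ], cv[j, ])
  out
}

#' Hudson's Fst (ratio of averages)
#'
#' Per-site numerator `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' denominator `p1(1-p2) + p2(1-p1)`; Fst is the sum of numerators over the
#' sum of denominators across sites (ratio of averages, the standard
#' recommendation for multi-site estimates). Sites monomorphic in both
#' groups are skipped.
#'
#' @param x a [haplotype_panel()] (with `group_a`/`group_b` giving
#'   individual ids or indices), or a data.frame with columns `p1`, `n1`,
#'   `p2`, `n2` of per-site allele frequencies and allele-copy counts.
#' @param group_a,group_b individual ids (or indices) of the two groups when
#'   `x` is a panel.
#' @return Fst estimate (can be slightly negative for undifferentiated
#'   groups).
#' @export
hudson_fst <- function(x, group_a = NULL, group_b = NULL) {
  if (inherits(x, "haplotype_panel")) {
    ia <- if (is.numeric(group_a)) group_a else match(group_a, x$indiv)
    ib <- if (is.numeric(group_b)) group_b else match(group_b, x$indiv)
    if (anyNA(ia) || anyNA(ib)) stopf("unknown individuals in groups")
    ha <- as.vector(rbind(2L * ia - 1L, 2L * ia))
    hb <- as.vector(rbind(2L * ib - 1L, 2L * ib))
    tab <- data.frame(p1 = rowMeans(x$alleles[, ha, drop = FALSE]),
                      n1 = length(ha),
                      p2 = rowMeans(x$alleles[, hb, drop = FALSE]),
                      n2 = length(hb))
  } else tab <- as.data.frame(x)
  if (any(tab$n1 <= 1) || any(tab$n2 <= 1)) stopf("need >= 2 allele copies per group per site")
  mono <- (tab$p1 == 0 & tab$p2 == 0) | (tab$p1 == 1 & tab$p2 == 1)
  tab <- tab[!mono, , drop = FALSE]
  if (!nrow(tab)) stopf("no polymorphic sites")
  num <- (tab$p1 - tab$p2)^2 -
    tab$p1 * (1 - tab$p1) / (tab$n1 - 1) -
    tab$p2 * (1 - tab$p2) / (tab$n2 - 1)
  den <- tab$p1 * (1 - tab$p2) + tab$p2 * (1 - tab$p1)
  sum(num) / sum(den)
}

#' Pairwise Hudson Fst between clusters
#' @param panel a [haplotype_panel()].
#' @param assignment named vector or `cluster_tree`.
#' @return symmetric K x K matrix.
#' @export
fst_matrix <- function(panel, assignment) {
  assignment <- resolve_assignment(assignment)
  cl <- assignment[panel$indiv]
  clusters <- sort(unique(cl))
  out <- matrix(0, length(clusters), length(clusters),
                dimnames = list(clusters, clusters))
  for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
    if (j <= i) next
    f <- hudson_fst(panel, which(cl == clusters[i]), which(cl == clusters[j]))
    out[i, j] <- out[j, i] <- f
  }
  out
}

#' Write profile tables
#'
#' Per-cluster nnls beta heat-table plus pairwise TVD and Fst matrices as
#' labelled square TSVs.
#' @param beta matrix from [nnls_profiles()].
#' @param tvd_m matrix from [tvd_matrix()]; optional.
#' @param fst_m matrix from [fst_matrix()]; optional.
#' @param dir output directory.
#' @export
write_profiles <- function(beta, tvd_m = NULL, fst_m = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(beta, file.path(dir, "nnls_profiles.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  if (!is.null(tvd_m))
    write.table(tvd_m, file.path(dir, "tvd.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)
  if (!is.null(fst_m))
    write.table(fst_m, file.path(dir, "fst.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)
  invisible(dir)
}
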