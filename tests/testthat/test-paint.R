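test_that("set-maximal matches match brute-force enumeration", {
  # crafted panel: haplotypes 0101, 0100, 1101, 0000, each duplicated into a
  # diploid individual so self-exclusion removes exact copies only
  h <- cbind(c(0L, 1L, 0L, 1L), c(0L, 1L, 0L, 0L), c(1L, 1L, 0L, 1L), c(0L, 0L, 0L, 0L))
  alleles <- h[, rep(1:4, each = 2L)]
  panel <- haplotype_panel(alleles,
                           data.frame(chrom = 1L, bp = 1:4, cM = (1:4) / 10),
                           indiv = paste0("i", 1:4))
  m <- maximal_matches(panel, 1L)
  got <- m[, c("donor_hap", "start_site", "end_site")]
  rownames(got) <- NULL
  expect_equal(got,
               data.frame(donor_hap = c(3L, 4L, 5L, 6L),
                          start_site = c(1L, 1L, 2L, 2L),
                          end_site = c(4L, 4L, 5L, 5L)))

  # all-identical panel: every other individual's haplotypes match [1, S+1)
  ident <- haplotype_panel(matrix(1L, 6, 8),
                           data.frame(chrom = 1L, bp = 1:6, cM = (1:6) / 10),
                           indiv = paste0("i", 1:4))
  mi <- maximal_matches(ident, 1L)
  expect_equal(nrow(mi), 6L)
  expect_true(all(mi$start_site == 1L & mi$end_site == 7L))

  # target differing everywhere from all others: no matches
  A <- matrix(0L, 5, 6)
  A[, 1:2] <- 1L
  dif <- haplotype_panel(A, data.frame(chrom = 1L, bp = 1:5, cM = (1:5) / 10),
                         indiv = paste0("i", 1:3))
  expect_equal(nrow(maximal_matches(dif, 1L)), 0L)

  expect_error(maximal_matches(haplotype_panel(matrix(0L, 3, 2),
                                               data.frame(chrom = 1, bp = 1:3, cM = 1:3),
                                               "x"), 1L),
               "other individuals")
})

test_that("set-maximal matches agree with an independent containment filter on random panels", {
  for (sd in 1:8) {
    panel <- random_panel(4L, 40L, seed = sd)
    hi <- rep(seq_len(4L), each = 2L)
    for (t in c(1L, 4L)) {
      got <- maximal_matches(panel, t)
      # oracle: all maximal runs per eligible donor, drop strict containment
      runs <- do.call(rbind, lapply(which(hi != hi[t]), function(d) {
        r <- r_ident_runs(panel$alleles[, t], panel$alleles[, d])
        if (nrow(r)) cbind(d, r)
      }))
      keep <- vapply(seq_len(nrow(runs)), function(i) {
        !any(runs[, 2L] <= runs[i, 2L] & runs[, 3L] >= runs[i, 3L] &
               (runs[, 3L] - runs[, 2L]) > (runs[i, 3L] - runs[i, 2L]))
      }, logical(1L))
      oracle <- runs[keep, , drop = FALSE]
      oracle <- oracle[order(oracle[, 1L], oracle[, 2L]), , drop = FALSE]
      expect_equal(unname(as.matrix(got[, c("donor_hap", "start_site", "end_site")])),
                   unname(cbind(oracle[, 1L], oracle[, 2L], oracle[, 3L] + 1L)))
    }
  }
})

test_that("painting a recipient identical to one donor gives that donor everything", {
  S <- 40L
  x <- rep(0L, S); y <- rep(1L, S)
  alleles <- cbind(x, x, x, y, y, y, y, y)
  panel <- haplotype_panel(alleles,
                           data.frame(chrom = 1L, bp = seq_len(S), cM = seq_len(S) / 10),
                           indiv = paste0("i", 1:4))
  co <- paint_panel(panel, paint_config(seed = 1L))
  expect_equal(unname(co$chunkcounts["i1", "i2"]), 2)
  expect_equal(unname(co$chunklengths["i1", "i2"]), 2 * co$map_length_cM)
  expect_equal(unname(co$chunklengths["i1", c("i3", "i4")]), c(0, 0))
})

test_that("painting equals the site-by-site greedy oracle and conserves row sums", {
  for (sd in 1:12) {
    n_ind <- sample(3:5, 1L)
    S <- sample(30:100, 1L)
    panel <- random_panel(n_ind, S, seed = 100L + sd)
    co <- paint_panel(panel, paint_config(seed = sd))
    oracle <- r_paint_oracle(panel$alleles, hapsharing:::panel_hap_indiv(panel),
                             panel$sites$cM, seed = sd)
    expect_equal(unname(co$chunkcounts), oracle$counts)
    expect_equal(unname(co$chunklengths), oracle$lengths)
    expect_equal(unname(rowSums(co$chunklengths)),
                 rep(2 * co$map_length_cM, n_ind))
    expect_true(all(diag(co$chunkcounts) == 0))
  }
  # multi-chromosome row conservation, both tie-break modes
  panel <- random_panel(5L, 60L, seed = 7L, chroms = 3L)
  for (tb in c("seeded-random", "split-equally")) {
    co <- paint_panel(panel, paint_config(tie_break = tb, seed = 2L))
    expect_equal(unname(rowSums(co$chunklengths)),
                 rep(2 * co$map_length_cM, 5L), tolerance = 1e-10)
  }
})

test_that("more within-group truth IBD implies more within-group painting", {
  cfg <- sim_config(3L, 25L, 10L,
                    chromosomes = data.frame(length_cM = 60, n_sites = 1000L),
                    seed = 12L)
  sim <- simulate_panel(cfg)
  tr <- truth_ibd(sim$mosaic, min_cM = 1)
  tr <- tr[tr$id_a != tr$id_b, ]
  lab <- sim$mosaic$subpop
  same_t <- lab[match(tr$id_a, sim$mosaic$indiv)] == lab[match(tr$id_b, sim$mosaic$indiv)]
  n_same_pairs <- sum(choose(table(lab), 2L))
  n_diff_pairs <- choose(length(lab), 2L) - n_same_pairs
  truth_within <- sum(tr$end_cM[same_t] - tr$start_cM[same_t]) / n_same_pairs
  truth_between <- sum(tr$end_cM[!same_t] - tr$start_cM[!same_t]) / n_diff_pairs
  co <- paint_panel(sim$panel, paint_config(seed = 3L))
  same_p <- outer(lab, lab, "==")
  diag(same_p) <- NA
  paint_within <- mean(co$chunklengths[same_p & !is.na(same_p)])
  paint_between <- mean(co$chunklengths[!same_p & !is.na(same_p)])
  expect_gt(truth_within, truth_between)
  expect_gt(paint_within, paint_between)
})

test_that("coancestry PCA handles degenerate, block and full-rank inputs", {
  X <- matrix(rep(c(0, 2, 7, 1, 4, 4, 9, 3, 5, 5), each = 10L), 10, 10)
  p0 <- coancestry_pca(X, k = 2L)  # identical rows: no variance left
  expect_true(all(abs(p0) < 1e-8))

  set.seed(1)
  B <- matrix(0.1 / 9, 20, 20)
  B[1:10, 1:10] <- 0.9 / 9
  B[11:20, 11:20] <- 0.9 / 9
  B <- B + matrix(runif(400, 0, 0.005), 20)
  diag(B) <- 0
  p1 <- coancestry_pca(B, k = 2L)[, 1L]
  expect_true(max(p1[1:10]) < min(p1[11:20]) || min(p1[1:10]) > max(p1[11:20]))

  pk <- coancestry_pca(B, k = 19L)
  expect_true(all(is.finite(pk)))
  expect_error(coancestry_pca(B, k = 21L), "exceed")
})
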