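test_that("detection reports maximal identical runs above the cM threshold", {
  # two identical haplotypes in different individuals: one full-length segment
  S <- 120L
  set.seed(1)
  x <- rbinom(S, 1L, 0.5)
  f1 <- (x + rep_len(c(1L, 0L, 1L), S)) %% 2L
  f2 <- (x + rep_len(c(1L, 1L, 0L), S)) %% 2L
  cM <- seq(0, 100, length.out = S)
  panel <- haplotype_panel(cbind(x, f1, x, f2),
                           data.frame(chrom = 1L, bp = round(cM * 1e4) + 1L, cM = cM),
                           indiv = c("A", "B"))
  segs <- detect_ibd(panel, 1)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$length_cM, 100)
  expect_equal(c(segs$id_a, segs$hap_a, segs$id_b, segs$hap_b), c("A", "1", "B", "1"))

  # a 0.9 cM maximal run is not reported at the default 1 cM threshold,
  # but is at a lower one
  cM2 <- seq(0, by = 0.1, length.out = 30L)
  p2 <- two_run_panel(cM2, disc_idx = c(10L, 21L))  # identical run sites 11..20: 0.9 cM
  expect_equal(nrow(detect_ibd(p2, 1)), 0L)
  expect_true(any(abs(detect_ibd(p2, 0.9)$length_cM - 0.9) < 1e-9))
})

test_that("detection equals a brute-force run oracle on small panels", {
  for (sd in 1:20) {
    panel <- random_panel(n_ind = sample(3:5, 1L), S = sample(60:150, 1L),
                          seed = 300L + sd)
    min_cM <- sample(c(0.3, 0.5, 1), 1L)
    got <- detect_ibd(panel, min_cM)
    hi <- hapsharing:::panel_hap_indiv(panel)
    cM <- panel$sites$cM
    exp_rows <- list()
    H <- ncol(panel$alleles)
    for (h1 in seq_len(H - 1L)) for (h2 in (h1 + 1L):H) {
      if (hi[h1] == hi[h2]) next
      runs <- r_ident_runs(panel$alleles[, h1], panel$alleles[, h2])
      for (k in seq_len(nrow(runs))) {
        if (cM[runs[k, 2L]] - cM[runs[k, 1L]] >= min_cM)
          exp_rows[[length(exp_rows) + 1L]] <- c(h1, h2, runs[k, ])
      }
    }
    oracle <- do.call(rbind, exp_rows)
    if (is.null(oracle)) {
      expect_equal(nrow(got), 0L)
      next
    }
    got_key <- with(got, paste(match(id_a, panel$indiv) * 2L - 2L + hap_a,
                               match(id_b, panel$indiv) * 2L - 2L + hap_b,
                               start_site, end_site))
    exp_key <- paste(oracle[, 1L], oracle[, 2L], oracle[, 3L], oracle[, 4L])
    expect_setequal(got_key, exp_key)
  }
})

test_that("gap merging follows the distance and discordance rule", {
  run <- seq(0, 3, 0.1)
  # 0.5 cM gap containing one discordant site: merged
  cM1 <- c(run, 3.25, run + 3.5)
  p1 <- two_run_panel(cM1, disc_idx = 32L)
  s1 <- detect_ibd(p1, 1)
  expect_equal(nrow(s1), 2L)
  m1 <- merge_ibd(s1, p1)
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$length_cM, 6.5)

  # 0.7 cM site-free gap (zero discordant sites): distance fails, unmerged
  cM2 <- c(run, run + 3.7)
  p2 <- two_run_panel(cM2, disc_idx = integer(0))
  s2 <- detect_ibd(p2, 1)
  one <- s2[1L, ]
  two <- one
  # split the single detected run into the two flanking segments by hand
  one$end_site <- 31L; one$end_cM <- 3; one$end_bp <- p2$sites$bp[31L]
  one$length_cM <- 3
  two$start_site <- 32L; two$start_cM <- 3.7; two$start_bp <- p2$sites$bp[32L]
  two$length_cM <- two$end_cM - two$start_cM
  s2b <- rbind(one, two)
  expect_equal(nrow(merge_ibd(s2b, p2)), 2L)

  # 0.5 cM gap with two discordant sites: discordance fails, unmerged
  cM3 <- c(run, 3.2, 3.3, run + 3.5)
  p3 <- two_run_panel(cM3, disc_idx = c(32L, 33L))
  s3 <- detect_ibd(p3, 1)
  expect_equal(nrow(s3), 2L)
  expect_equal(nrow(merge_ibd(s3, p3)), 2L)
  # ... but a permissive discordance bound merges it
  expect_equal(nrow(merge_ibd(s3, p3, max_discordant = 2L)), 1L)
})

test_that("merging improves recall of long truth segments under genotype error", {
  deltas <- vapply(1:10, function(sd) {
    cfg <- sim_config(1L, 50L, 15L,
                      chromosomes = data.frame(length_cM = 80, n_sites = 3200L),
                      genotype_error_rate = 0.002, seed = 500L + sd)
    sim <- simulate_panel(cfg)
    tr <- truth_ibd(sim$mosaic, min_cM = 4)
    raw <- detect_ibd(sim$panel, 1)
    merged <- merge_ibd(raw, sim$panel)
    ibd_accuracy(merged, tr, 4)$recall - ibd_accuracy(raw, tr, 4)$recall
  }, numeric(1L))
  expect_gt(mean(deltas), 0)
})

test_that("sharing summaries aggregate per-partner totals and counts", {
  segs <- data.frame(id_a = c("A", "A", "A"), id_b = c("B", "C", "C"),
                     length_cM = c(5, 3, 2))
  cl <- setNames(rep("x", 3L), c("A", "B", "C"))
  sm <- sharing_summary(segs, cl)
  expect_equal(sm$mean_total_cM, c(5, 2.5, 2.5))
  expect_equal(sm$mean_n_segments, c(1.5, 0.5, 1))

  # cluster of three with no segments: zeros
  sm0 <- sharing_summary(segs[0L, ], cl)
  expect_equal(sm0$mean_total_cM, c(0, 0, 0))

  # singleton cluster: undefined summary
  cl2 <- setNames(c("x", "x", "y"), c("A", "B", "C"))
  sm2 <- sharing_summary(segs, cl2)
  expect_true(is.na(sm2$mean_total_cM[sm2$id == "C"]))
  # cross-cluster segments are excluded from within-cluster sharing
  expect_equal(sm2$mean_total_cM[sm2$id == "A"], 5)
})

test_that("rank test gives exact small-sample p and reasonable power", {
  rt <- rank_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rt$U, 0)
  expect_equal(rt$p, 0.1)
  expect_error(rank_test(numeric(0), 1:3), "non-empty")
  # identical multisets: U = m * n / 2
  rt2 <- rank_test(c(1, 2, 5, 9), c(1, 2, 5, 9))
  expect_equal(rt2$U, 8)
  # power under a 1 SD shift at n = 50
  set.seed(77)
  hits <- mean(replicate(100L, {
    rank_test(rnorm(50, 1), rnorm(50))$p < 0.05
  }))
  expect_gte(hits, 0.9)
})
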