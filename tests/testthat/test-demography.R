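test_that("coalescence pmf matches hand values and normalizes", {
  expect_equal(coalescence_pmf(0.5, G = 3L)$p, c(1, 0, 0))
  expect_equal(coalescence_pmf(1, G = 2L)$p, c(0.5, 0.25))
  set.seed(2)
  for (i in 1:5) {
    ne <- runif(20, 5, 5000)
    pm <- coalescence_pmf(ne)
    expect_equal(sum(pm$p) + pm$residual, 1, tolerance = 1e-12)
    expect_true(all(pm$p >= 0))
  }
  expect_error(coalescence_pmf(c(100, -3)), "positive")
})

test_that("expected spectrum matches closed-form values and scaling laws", {
  # forced coalescence at g = 1, L = 1 Morgan, u = 0.04
  sp <- expected_spectrum(0.5, L = 1, G = 1L, bins_cM = 4)
  expect_equal(sp$tail(0.04), 2 * exp(-0.08), tolerance = 1e-12)
  # tails strictly decreasing in u; doubling L doubles every expectation
  sp2 <- expected_spectrum(300, L = 2, G = 50L)
  u <- seq(0.04, 0.4, 0.04)
  expect_true(all(diff(sp2$tail(u)) < 0))
  sp4 <- expected_spectrum(300, L = 4, G = 50L)
  expect_equal(sp4$tail(u), 2 * sp2$tail(u), tolerance = 1e-12)
  expect_error(sp2$tail(-1), "non-negative")
})

theory_spectrum <- function(ne, n_pairs, edges = c(seq(4, 20, 2), 25, 30, 40, 60)) {
  th <- expected_spectrum(ne, L = 2, G = 50L, bins_cM = edges)
  structure(list(edges_cM = th$edges_cM, counts = th$expected * n_pairs,
                 n_pairs = n_pairs, segments = NULL, individuals = NULL,
                 chrom_lengths_cM = NULL, L_morgans = 2),
            class = "segment_spectrum")
}

test_that("Ne fitting is self-consistent on noise-free spectra and scale invariant", {
  spec <- theory_spectrum(500, 79600)
  fit <- fit_ne(spec, G = 50L, n_bootstrap = 0L)
  expect_true(all(abs(fit$trajectory$Ne[5:30] / 500 - 1) < 0.1))

  spec10 <- spec
  spec10$counts <- spec$counts * 10
  spec10$n_pairs <- spec$n_pairs * 10
  fit10 <- fit_ne(spec10, G = 50L, n_bootstrap = 0L)
  expect_equal(fit10$trajectory$Ne, fit$trajectory$Ne)

  empty <- spec
  empty$counts <- spec$counts * 0
  expect_error(fit_ne(empty, n_bootstrap = 0L), "no segments")
})

test_that("truth IBD length spectra match the finite-chromosome expectation", {
  # constant N = 200 for 50 generations, 20 chromosomes x 100 cM; the
  # goodness-of-fit uses disjoint individual pairs so per-bin counts are
  # nearly independent Poisson draws
  cfg <- sim_config(1L, 200L, 50L,
                    chromosomes = data.frame(length_cM = rep(100, 20L),
                                             n_sites = rep(10L, 20L)),
                    seed = 42L)
  mos <- transmit_haplotypes(simulate_pedigree(cfg), cfg)
  set.seed(9)
  ord <- sample.int(200L)
  prs <- cbind(ord[1:50], ord[51:100])  # 50 disjoint diploid pairs
  hap_pairs <- do.call(rbind, lapply(seq_len(nrow(prs)), function(k) {
    i <- prs[k, 1L]; j <- prs[k, 2L]
    expand.grid(a = c(2L * i - 1L, 2L * i), b = c(2L * j - 1L, 2L * j))
  }))
  tr <- truth_ibd(mos, min_cM = 2, pairs = as.matrix(hap_pairs))
  len <- tr$end_cM - tr$start_cM
  edges <- c(2, 3, 4, 5, 6, 8, 10, 15, 20, 30)
  obs <- as.numeric(table(cut(len, c(edges, Inf), right = FALSE)))
  th <- expected_spectrum(200, bins_cM = edges, G = 50L,
                          chrom_lengths = rep(1, 20L))
  e <- th$expected * nrow(hap_pairs)
  chi2 <- sum((obs - e)^2 / e)
  p <- pchisq(chi2, df = length(obs), lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("a forward-simulated bottleneck is localized and sized by the fit", {
  G <- 30L
  sizes <- matrix(2000L, 1L, G + 1L)
  sizes[1L, G + 1L - (10:20)] <- 200L  # Ne = 200 for generations 10..20 ago
  hits <- vapply(1:10, function(sd) {
    cfg <- sim_config(1L, sizes, G,
                      chromosomes = data.frame(length_cM = c(75, 75), n_sites = c(10L, 10L)),
                      seed = 600L + sd)
    mos <- transmit_haplotypes(simulate_pedigree(cfg), cfg)
    set.seed(sd)
    mos <- subset_individuals(mos, sort(sample.int(2000L, 120L)))
    tr <- truth_ibd(mos, min_cM = 4)
    tr <- tr[as.character(tr$id_a) != as.character(tr$id_b), ]
    tr$length_cM <- tr$end_cM - tr$start_cM
    sp <- segment_spectrum(tr, mos$indiv, chrom_lengths_cM = c(75, 75))
    fit <- fit_ne(sp, G = G, n_bootstrap = 0L)
    ne <- fit$trajectory$Ne
    dip <- which.min(ne)
    depth_ok <- min(ne) > 100 && min(ne) < 400
    loc_ok <- dip >= 5L && dip <= 25L
    depth_ok && loc_ok
  }, logical(1L))
  expect_gte(sum(hits), 6L)  # majority of seeds
})

test_that("bootstrap bands widen as the sample shrinks", {
  cfg <- sim_config(1L, 400L, 40L,
                    chromosomes = data.frame(length_cM = c(100, 100), n_sites = c(10L, 10L)),
                    seed = 77L)
  mos <- transmit_haplotypes(simulate_pedigree(cfg), cfg)
  widths <- vapply(c(200L, 100L, 50L), function(n) {
    set.seed(n)
    sub <- subset_individuals(mos, sort(sample.int(400L, n)))
    tr <- truth_ibd(sub, min_cM = 4)
    tr <- tr[as.character(tr$id_a) != as.character(tr$id_b), ]
    tr$length_cM <- tr$end_cM - tr$start_cM
    sp <- segment_spectrum(tr, sub$indiv, chrom_lengths_cM = c(100, 100))
    fit <- fit_ne(sp, G = 40L, n_bootstrap = 15L, seed = 3L)
    mean(log(fit$trajectory$hi95[5:30]) - log(fit$trajectory$lo95[5:30]))
  }, numeric(1L))
  expect_true(widths[1L] < widths[2L] && widths[2L] < widths[3L])
})
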