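test_that("pedigree construction respects generations, subpops and seeds", {
  cfg <- sim_config(2L, 20L, 0L, seed = 1L)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 40L)
  expect_true(all(ped$gen == 0L))
  expect_true(all(is.na(ped$mother)))

  cfg <- sim_config(2L, 50L, 10L, seed = 1L)  # identity migration default
  ped <- simulate_pedigree(cfg)
  kids <- ped[ped$gen > 0L, ]
  expect_true(all(ped$subpop[kids$mother] == kids$subpop))
  expect_true(all(ped$subpop[kids$father] == kids$subpop))
  expect_true(all(ped$gen[kids$mother] == kids$gen - 1L))
  expect_identical(ped, simulate_pedigree(cfg))  # determinism under seed

  expect_error(sim_config(1L, 1L, 5L), "insufficient parents")
})

test_that("crossover counts follow the Haldane Poisson rate", {
  nrep <- 10000L
  cfg <- sim_config(1L, matrix(c(2L, nrep), 1L),
                    n_generations = 1L,
                    chromosomes = data.frame(length_cM = 100, n_sites = 10L),
                    seed = 5L)
  mos <- transmit_haplotypes(simulate_pedigree(cfg), cfg)
  # maternal gamete of each child: number of mosaic switches = crossovers
  ncx <- vapply(seq_len(nrep), function(i) length(mos$haps[[1L]][[2L * i - 1L]]$fid) - 1L,
                integer(1L))
  se <- sqrt(1 / nrep)
  expect_lt(abs(mean(ncx) - 1), 3 * se)
})

test_that("zero-length chromosomes and founder mosaics are degenerate single intervals", {
  cfg <- sim_config(1L, 4L, 2L,
                    chromosomes = data.frame(length_cM = c(0, 50), n_sites = c(1L, 500L)),
                    seed = 2L)
  mos <- transmit_haplotypes(simulate_pedigree(cfg), cfg)
  expect_true(all(lengths(lapply(mos$haps[[1L]], `[[`, "fid")) == 1L))

  cfg0 <- sim_config(1L, 4L, 0L,
                     chromosomes = data.frame(length_cM = 50, n_sites = 10L), seed = 3L)
  mos0 <- transmit_haplotypes(simulate_pedigree(cfg0), cfg0)
  expect_true(all(lengths(lapply(mos0$haps[[1L]], `[[`, "fid")) == 1L))
  expect_equal(length(unique(vapply(mos0$haps[[1L]], `[[`, integer(1L), "fid"))), 8L)
})

make_mosaic <- function(haps, L = 100) {
  structure(list(haps = list(haps), chrom_len_cM = L,
                 indiv = seq_len(length(haps) %/% 2L),
                 subpop = rep(1L, length(haps) %/% 2L),
                 n_founder_haps = 10L, config = NULL),
            class = "ancestry_mosaic")
}

test_that("truth_ibd intersects and merges founder intervals", {
  # brute-force interval case: A=[(f1,0,30),(f2,30,100)], B=[(f1,0,50),(f3,50,100)]
  hA <- list(ends = c(30, 100), fid = c(1L, 2L))
  hB <- list(ends = c(50, 100), fid = c(1L, 3L))
  mos <- make_mosaic(list(hA, hB))
  tr <- truth_ibd(mos, min_cM = 1, pairs = cbind(1L, 2L))
  expect_equal(nrow(tr), 1L)
  expect_equal(c(tr$start_cM, tr$end_cM), c(0, 30))

  # identical unrecombined copies share the whole chromosome
  same <- make_mosaic(list(list(ends = 100, fid = 7L), list(ends = 100, fid = 7L)))
  tr2 <- truth_ibd(same, min_cM = 1, pairs = cbind(1L, 2L))
  expect_equal(c(tr2$start_cM, tr2$end_cM), c(0, 100))

  # disjoint founder sets share nothing
  disj <- make_mosaic(list(list(ends = 100, fid = 1L), list(ends = 100, fid = 2L)))
  expect_equal(nrow(truth_ibd(disj, min_cM = 1, pairs = cbind(1L, 2L))), 0L)

  expect_error(truth_ibd(mos, min_cM = -1), "min_cM")
})

test_that("truth segments are symmetric, ordered and tile-consistent", {
  sim <- small_sim(seed = 9L, n = 15L, G = 6L)
  tr <- truth_ibd(sim$mosaic, min_cM = 1)
  expect_true(all(tr$end_cM > tr$start_cM))
  ia <- match(as.character(tr$id_a), as.character(sim$mosaic$indiv))
  ib <- match(as.character(tr$id_b), as.character(sim$mosaic$indiv))
  expect_true(all(ia <= ib))
  # non-overlap after maximal merging, per pair/haplotype/chromosome
  key <- paste(tr$id_a, tr$hap_a, tr$id_b, tr$hap_b, tr$chrom)
  for (k in split(seq_len(nrow(tr)), key)) {
    if (length(k) < 2L) next
    o <- tr[k, ][order(tr$start_cM[k]), ]
    expect_true(all(o$start_cM[-1L] > o$end_cM[-nrow(o)]))
  }
  # mosaics tile [0, L] exactly
  for (c in seq_along(sim$mosaic$haps)) {
    L <- sim$mosaic$chrom_len_cM[c]
    for (h in sim$mosaic$haps[[c]]) {
      expect_equal(h$ends[length(h$ends)], L)
      expect_true(all(diff(h$ends) > 0))
    }
  }
})

test_that("genotyped alleles agree inside truth-IBD segments and flip under full error", {
  sim <- small_sim(seed = 4L, n = 20L, G = 6L)
  panel <- sim$panel
  tr <- truth_ibd(sim$mosaic, min_cM = 2)
  expect_gt(nrow(tr), 0L)
  ids <- panel$indiv
  for (r in sample.int(nrow(tr), min(nrow(tr), 200L))) {
    ca <- 2L * match(as.character(tr$id_a[r]), ids) - 2L + tr$hap_a[r]
    cb <- 2L * match(as.character(tr$id_b[r]), ids) - 2L + tr$hap_b[r]
    rows <- which(panel$sites$chrom == tr$chrom[r] &
                    panel$sites$cM >= tr$start_cM[r] & panel$sites$cM <= tr$end_cM[r])
    expect_identical(panel$alleles[rows, ca], panel$alleles[rows, cb])
  }
  # full genotype error is a bitwise complement
  cfg1 <- sim_config(1L, 20L, 6L, chromosomes = data.frame(length_cM = 80, n_sites = 1600L),
                     genotype_error_rate = 1, seed = 4L)
  flipped <- genotype_panel(sim$mosaic, cfg1)
  expect_identical(flipped$alleles, 1L - panel$alleles)
})

test_that("raising the cousin-mating rate raises mean truth autozygosity", {
  # population large enough that background autozygosity noise does not
  # swamp the +rate/16 consanguinity increment; mean over a fixed seed set
  chroms <- data.frame(length_cM = c(100, 100, 100), n_sites = rep(10L, 3L))
  az <- sapply(c(0, 0.1, 0.3), function(rate) {
    mean(sapply(1:8, function(sd) {
      cfg <- sim_config(1L, 300L, 12L, cousin_mating_rate = rate,
                        chromosomes = chroms, seed = sd)
      mean(truth_autozygosity(transmit_haplotypes(simulate_pedigree(cfg), cfg)))
    }))
  })
  expect_true(az[1L] < az[2L] && az[2L] < az[3L])
})
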