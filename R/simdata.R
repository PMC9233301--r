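#' Simulation configuration
#'
#' Parameters of the forward-in-time pedigree and recombination simulator.
#' The simulator produces phased multi-subpopulation panels with known
#' subpopulation labels, ground-truth IBD segments, configurable
#' per-generation population sizes, migration, consanguinity and
#' genotyping/phase error, so every downstream stage of the pipeline has a
#' truth set.
#'
#' @param n_subpops number of subpopulations.
#' @param sizes diploid sizes: a scalar (all subpops, all generations), a
#'   vector of length `n_subpops`, or a `n_subpops x (n_generations + 1)`
#'   matrix (columns = generations 0..G) for time-varying sizes such as
#'   bottlenecks. All sizes must be >= 2.
#' @param n_generations number of generations G simulated forward from the
#'   unrelated founder generation 0.
#' @param migration per-generation mate-choice matrix: row s gives the
#'   probability that a couple with mother in subpop s has its father drawn
#'   from each subpop. Either one `n_subpops x n_subpops` matrix (constant
#'   over time) or a list of G such matrices. Rows must sum to 1.
#' @param cousin_mating_rate probability in `[0, 1]` that a couple is formed
#'   between the mother and one of her first cousins (individuals sharing at
#'   least one grandparent but no parent). Falls back to random mate choice
#'   when no cousin is available; fallbacks are counted, not an error.
#' @param chromosomes data.frame with columns `length_cM` and `n_sites`.
#' @param maf_law function of `n` drawing founder allele frequencies;
#'   default uniform on `[0.02, 0.5]`.
#' @param genotype_error_rate per-site, per-haplotype allele flip probability.
#' @param phase_switch_rate per-site probability of swapping an individual's
#'   two haplotypes from that site onward (within a chromosome).
#' @param bp_per_cM fixed physical-to-genetic scale; default 1 Mb per cM.
#' @param seed integer seed; each simulator stage consumes a seed derived
#'   from it (see [derive_seed()]).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subpops = 1L,
                       sizes = 50L,
                       n_generations = 10L,
                       migration = NULL,
                       cousin_mating_rate = 0,
                       chromosomes = data.frame(length_cM = 100, n_sites = 2000L),
                       maf_law = function(n) runif(n, 0.02, 0.5),
                       genotype_error_rate = 0,
                       phase_switch_rate = 0,
                       bp_per_cM = 1e6,
                       seed = 1L) {
  K <- as.integer(n_subpops)
  G <- as.integer(n_generations)
  if (K < 1L) stopf("n_subpops must be >= 1")
  if (G < 0L) stopf("n_generations must be >= 0")
  if (is.matrix(sizes)) {
    if (nrow(sizes) != K || ncol(sizes) != G + 1L)
      stopf("sizes matrix must be n_subpops x (n_generations + 1)")
  } else {
    sizes <- matrix(rep(as.integer(sizes), length.out = K), K, G + 1L)
  }
  storage.mode(sizes) <- "integer"
  if (any(sizes < 2L)) stopf("insufficient parents: all subpop sizes must be >= 2")
  if (is.null(migration)) migration <- diag(K)
  mig_list <- if (is.list(migration)) migration else rep(list(migration), max(G, 1L))
  for (m in mig_list) {
    if (!is.matrix(m) || nrow(m) != K || ncol(m) != K)
      stopf("migration must be a %d x %d matrix (or a list of them)", K, K)
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8))
      stopf("migration rows must be non-negative and sum to 1")
  }
  for (r in c(cousin_mating_rate, genotype_error_rate, phase_switch_rate))
    if (r < 0 || r > 1) stopf("rates must lie in [0, 1]")
  stopifnot(is.data.frame(chromosomes),
            all(c("length_cM", "n_sites") %in% names(chromosomes)),
            all(chromosomes$length_cM >= 0), all(chromosomes$n_sites >= 1))
  structure(list(
    n_subpops = K, sizes = sizes, n_generations = G,
    migration = if (G > 0L) mig_list[seq_len(G)] else list(),
    cousin_mating_rate = cousin_mating_rate,
    chromosomes = chromosomes, maf_law = maf_law,
    genotype_error_rate = genotype_error_rate,
    phase_switch_rate = phase_switch_rate,
    bp_per_cM = bp_per_cM, seed = as.integer(seed)
  ), class = "sim_config")
}

# first cousins of every individual in `ids`: children of a full sibling of
# one of the individual's parents (shares a grandparental couple but no
# parent; not self). Returns a list parallel to ids.
first_cousins <- function(ids, mother, father) {
  par1 <- mother[ids]; par2 <- father[ids]
  if (all(is.na(par1))) return(rep(list(integer(0)), length(ids)))
  # grandparental couples, keyed by "mother:father" of each parent
  cpl <- function(p) ifelse(is.na(p) | is.na(mother[p]), NA,
                            paste(mother[p], father[p]))
  gc1 <- cpl(par1); gc2 <- cpl(par2)
  long_ind <- rep(seq_along(ids), 2L)
  long_gc <- c(gc1, gc2)
  ok <- !is.na(long_gc)
  gc2gc <- split(long_ind[ok], long_gc[ok])
  p2c <- split(rep(seq_along(ids), 2L), c(par1, par2))
  lapply(seq_along(ids), function(i) {
    g <- unique(c(gc1[i], gc2[i]))
    g <- g[!is.na(g)]
    if (!length(g)) return(integer(0))
    cand <- unique(unlist(gc2gc[g], use.names = FALSE))
    sibs <- unique(unlist(p2c[as.character(c(par1[i], par2[i]))], use.names = FALSE))
    ids[setdiff(cand, c(i, sibs))]
  })
}

#' Simulate a pedigree forward in time
#'
#' Each generation, every individual of a subpopulation may act as the mother
#' of one monogamous couple; the couple's father is drawn from the subpop
#' given by the migration row (sampling fathers without replacement within a
#' subpopulation, excluding the mother and her siblings), or, with
#' probability `cousin_mating_rate`, from the mother's first cousins.
#' Children are assigned to couples uniformly at random, producing full-sib
#' families. Reproducible under `config$seed`.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `id`, `gen`, `subpop`, `mother`, `father`
#'   (NA parents for founders), class `pedigree`. The number of times cousin
#'   mating fell back to random mating is in `attr(, "n_cousin_fallback")`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  K <- config$n_subpops; G <- config$n_generations
  sizes <- config$sizes
  total <- sum(sizes)
  id <- seq_len(total)
  gen <- integer(total); subpop <- integer(total)
  sex <- integer(total)  # 1 = female, 2 = male; balanced within cohort
  mother <- rep(NA_integer_, total); father <- rep(NA_integer_, total)
  n_fallback <- 0L
  with_seed(derive_seed(config$seed, 0L), {
    assign_sexes <- function(n) sample(rep_len(c(1L, 2L), n))
    nxt <- 1L
    prev_ids <- vector("list", K)
    for (s in seq_len(K)) {
      n <- sizes[s, 1L]
      rows <- nxt:(nxt + n - 1L)
      gen[rows] <- 0L; subpop[rows] <- s
      sex[rows] <- assign_sexes(n)
      prev_ids[[s]] <- rows
      nxt <- nxt + n
    }
    for (g in seq_len(G)) {
      prev_all <- unlist(prev_ids)
      cousins <- NULL
      if (config$cousin_mating_rate > 0 && g >= 3L) {
        cl <- first_cousins(prev_all, mother, father)
        cousins <- setNames(cl, prev_all)
      }
      mig <- config$migration[[g]]
      new_ids <- vector("list", K)
      for (s in seq_len(K)) {
        n <- sizes[s, g + 1L]
        moms <- prev_ids[[s]][sex[prev_ids[[s]]] == 1L]
        if (length(moms) < 1L) stopf("insufficient parents in subpop %d, generation %d", s, g)
        nm <- length(moms)
        f_sub <- sample.int(K, nm, replace = TRUE, prob = mig[s, ])
        want_cousin <- runif(nm) < config$cousin_mating_rate
        dads <- integer(nm)
        if (config$cousin_mating_rate == 0) {
          # vectorized monogamous assignment: a uniform draw without
          # replacement is a random permutation of each source pool
          for (sp in unique(f_sub)) {
            males <- prev_ids[[sp]][sex[prev_ids[[sp]]] == 2L]
            if (!length(males)) stopf("insufficient parents in subpop %d, generation %d", sp, g)
            take <- which(f_sub == sp)
            picked <- if (length(take) <= length(males))
              males[sample.int(length(males), length(take))]
            else males[c(sample.int(length(males), length(males)),
                         sample.int(length(males), length(take) - length(males),
                                    replace = TRUE))]
            dads[take] <- picked
          }
          fam <- sample.int(nm, n, replace = TRUE)
          rows <- nxt:(nxt + n - 1L)
          gen[rows] <- g; subpop[rows] <- s
          sex[rows] <- assign_sexes(n)
          mother[rows] <- moms[fam]; father[rows] <- dads[fam]
          new_ids[[s]] <- rows
          nxt <- nxt + n
          next
        }
        used <- integer(0)
        for (m in seq_len(nm)) {
          mom <- moms[m]
          dad <- NA_integer_
          if (want_cousin[m] && !is.null(cousins)) {
            # male first cousins; cousin unions are not blocked by prior
            # couple membership (endogamous communities re-use families)
            cand <- cousins[[as.character(mom)]]
            cand <- cand[sex[cand] == 2L]
            if (length(cand)) dad <- cand[sample.int(length(cand), 1L)]
            else n_fallback <- n_fallback + 1L
          } else if (want_cousin[m]) n_fallback <- n_fallback + 1L
          if (is.na(dad)) {
            pool <- prev_ids[[f_sub[m]]]
            pool <- pool[sex[pool] == 2L]
            cand <- setdiff(pool, used)
            if (!length(cand)) cand <- pool
            if (!length(cand)) stopf("insufficient parents in subpop %d, generation %d", f_sub[m], g)
            dad <- cand[sample.int(length(cand), 1L)]
          }
          dads[m] <- dad
          used <- c(used, dad)
        }
        fam <- sample.int(nm, n, replace = TRUE)
        rows <- nxt:(nxt + n - 1L)
        gen[rows] <- g; subpop[rows] <- s
        sex[rows] <- assign_sexes(n)
        mother[rows] <- moms[fam]; father[rows] <- dads[fam]
        new_ids[[s]] <- rows
        nxt <- nxt + n
      }
      prev_ids <- new_ids
    }
  })
  ped <- data.frame(id = id, gen = gen, subpop = subpop, sex = sex,
                    mother = mother, father = father)
  attr(ped, "config") <- config
  attr(ped, "n_cousin_fallback") <- n_fallback
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# one gamete: recombinant of the parent's two haplotype mosaics under the
# Haldane model (Poisson crossovers, positions uniform in cM)
meiosis <- function(h1, h2, L) {
  ncx <- rpois(1L, L / 100)
  first <- sample.int(2L, 1L)
  if (ncx == 0L) return(if (first == 1L) h1 else h2)
  recombine(h1, h2, sort(runif(ncx, 0, L)), first, L)
}

recombine <- function(h1, h2, cuts, first, L) {
  lo <- c(0, cuts); hi <- c(cuts, L)
  ends <- numeric(0); fid <- integer(0)
  for (k in seq_along(lo)) {
    a <- lo[k]; b <- hi[k]
    if (b <= a) next
    h <- if ((k %% 2L == 1L) == (first == 1L)) h1 else h2
    i1 <- findInterval(a, h$ends) + 1L
    i2 <- findInterval(b, h$ends, left.open = TRUE) + 1L
    ends <- c(ends, if (i2 > i1) h$ends[i1:(i2 - 1L)], b)
    fid <- c(fid, h$fid[i1:i2])
  }
  n <- length(fid)
  if (n > 1L) {
    keep <- c(fid[-1L] != fid[-n], TRUE)
    ends <- ends[keep]; fid <- fid[keep]
  }
  list(ends = ends, fid = fid)
}

#' Transmit haplotypes through a pedigree
#'
#' Drops founder haplotype labels through the pedigree, one recombinant
#' gamete per parent per child, with crossover counts Poisson(length_cM/100)
#' per chromosome and crossover positions uniform in cM (Haldane model, no
#' interference). Founder haplotypes carry unique ids, so the resulting
#' ancestry mosaics define ground-truth IBD unambiguously.
#'
#' @param pedigree from [simulate_pedigree()].
#' @param config the [sim_config()]; defaults to the pedigree's.
#' @return object of class `ancestry_mosaic`: for each chromosome and each
#'   final-generation haplotype, interval right endpoints (cM) and founder
#'   haplotype ids tiling `[0, length_cM]`.
#' @export
transmit_haplotypes <- function(pedigree, config = attr(pedigree, "config")) {
  stopifnot(inherits(pedigree, "pedigree"))
  ped <- as.data.frame(pedigree)
  G <- config$n_generations
  lens <- config$chromosomes$length_cM
  C <- length(lens)
  founders <- ped$id[ped$gen == 0L]
  nf <- length(founders)
  cur <- lapply(seq_len(C), function(c) {
    unlist(lapply(seq_len(nf), function(i) {
      list(list(ends = lens[c], fid = 2L * (i - 1L) + 1L),
           list(ends = lens[c], fid = 2L * (i - 1L) + 2L))
    }), recursive = FALSE)
  })
  id2pos <- rep(NA_integer_, max(ped$id))
  id2pos[founders] <- seq_len(nf)
  final_rows <- which(ped$gen == G)
  with_seed(derive_seed(config$seed, 1L), {
    for (g in seq_len(G)) {
      rows <- which(ped$gen == g)
      mo <- id2pos[ped$mother[rows]]
      fa <- id2pos[ped$father[rows]]
      for (c in seq_len(C)) {
        L <- lens[c]
        prev <- cur[[c]]
        haps <- vector("list", 2L * length(rows))
        for (i in seq_along(rows)) {
          haps[[2L * i - 1L]] <- meiosis(prev[[2L * mo[i] - 1L]], prev[[2L * mo[i]]], L)
          haps[[2L * i]] <- meiosis(prev[[2L * fa[i] - 1L]], prev[[2L * fa[i]]], L)
        }
        cur[[c]] <- haps
      }
      id2pos <- rep(NA_integer_, max(ped$id))
      id2pos[ped$id[rows]] <- seq_along(rows)
    }
  })
  structure(list(
    haps = cur,
    chrom_len_cM = lens,
    indiv = ped$id[final_rows],
    subpop = ped$subpop[final_rows],
    n_founder_haps = 2L * nf,
    config = config
  ), class = "ancestry_mosaic")
}

#' Subset an ancestry mosaic to selected individuals
#' @param mosaic an `ancestry_mosaic`.
#' @param idx individual indices (positions, not pedigree ids) to keep.
#' @return an `ancestry_mosaic` for the selected individuals.
#' @export
subset_individuals <- function(mosaic, idx) {
  stopifnot(inherits(mosaic, "ancestry_mosaic"))
  hidx <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  mosaic$haps <- lapply(mosaic$haps, function(h) h[hidx])
  mosaic$indiv <- mosaic$indiv[idx]
  mosaic$subpop <- mosaic$subpop[idx]
  mosaic
}

#' Ground-truth IBD segments from ancestry mosaics
#'
#' For each requested haplotype pair, intervals where the founder haplotype
#' ids coincide are intersected and maximally merged; segments of genetic
#' length >= `min_cM` are reported. By default all unordered haplotype pairs
#' are scanned, including the pair formed by an individual's own two
#' haplotypes (autozygosity).
#'
#' @param mosaic an `ancestry_mosaic`.
#' @param min_cM minimum reported segment length in cM (>= 0).
#' @param pairs optional 2-column matrix of haplotype column indices
#'   (1-based, individual i's haplotypes are 2i-1 and 2i).
#' @return data.frame: `id_a`, `hap_a`, `id_b`, `hap_b`, `chrom`,
#'   `start_cM`, `end_cM`.
#' @export
truth_ibd <- function(mosaic, min_cM = 1, pairs = NULL) {
  stopifnot(inherits(mosaic, "ancestry_mosaic"))
  if (min_cM < 0) stopf("min_cM must be >= 0")
  H <- 2L * length(mosaic$indiv)
  if (is.null(pairs)) {
    pairs <- cbind(rep(seq_len(H - 1L), times = (H - 1L):1L),
                   unlist(lapply(seq_len(H - 1L), function(i) (i + 1L):H)))
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  out <- vector("list", length(mosaic$haps))
  for (c in seq_along(mosaic$haps)) {
    hl <- mosaic$haps[[c]]
    res <- cpp_truth_ibd(lapply(hl, `[[`, "ends"), lapply(hl, `[[`, "fid"),
                         pairs - 1L, min_cM)
    if (nrow(res)) {
      p1 <- pairs[res$pair, 1L]; p2 <- pairs[res$pair, 2L]
      out[[c]] <- data.frame(
        id_a = mosaic$indiv[(p1 + 1L) %/% 2L], hap_a = (p1 - 1L) %% 2L + 1L,
        id_b = mosaic$indiv[(p2 + 1L) %/% 2L], hap_b = (p2 - 1L) %% 2L + 1L,
        chrom = c, start_cM = res$start_cM, end_cM = res$end_cM
      )
    }
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(out)) {
    out <- data.frame(id_a = integer(0), hap_a = integer(0), id_b = integer(0),
                      hap_b = integer(0), chrom = integer(0),
                      start_cM = numeric(0), end_cM = numeric(0))
  }
  out
}

#' Truth-based autozygosity per individual
#'
#' Fraction of the genome where an individual's two haplotypes are IBD
#' (same founder haplotype), from the ancestry mosaics.
#' @param mosaic an `ancestry_mosaic`.
#' @param min_cM minimum counted segment length.
#' @return numeric vector, one value per individual.
#' @export
truth_autozygosity <- function(mosaic, min_cM = 0) {
  n <- length(mosaic$indiv)
  pairs <- cbind(2L * seq_len(n) - 1L, 2L * seq_len(n))
  tr <- truth_ibd(mosaic, min_cM, pairs)
  tot <- sum(mosaic$chrom_len_cM)
  v <- rep(0, n)
  if (nrow(tr)) {
    agg <- tapply(tr$end_cM - tr$start_cM, factor(tr$id_a, levels = mosaic$indiv), sum)
    v <- ifelse(is.na(agg), 0, agg) / tot
  }
  as.numeric(v)
}

#' Genotype a simulated panel
#'
#' Assigns founder haplotypes independent alleles at sites placed uniformly
#' at random along each chromosome (frequencies drawn from `maf_law`), reads
#' final-generation alleles through the ancestry mosaics, then applies
#' phase-switch errors (swapping an individual's haplotypes from a site
#' onward) and genotype errors (allele flips).
#'
#' @param mosaic an `ancestry_mosaic`.
#' @param config the [sim_config()]; defaults to the mosaic's.
#' @return a [haplotype_panel()].
#' @export
genotype_panel <- function(mosaic, config = mosaic$config) {
  stopifnot(inherits(mosaic, "ancestry_mosaic"))
  H <- 2L * length(mosaic$indiv)
  nf <- mosaic$n_founder_haps
  chrs <- config$chromosomes
  with_seed(derive_seed(config$seed, 2L), {
    blocks <- vector("list", nrow(chrs))
    sites <- vector("list", nrow(chrs))
    for (c in seq_len(nrow(chrs))) {
      S <- chrs$n_sites[c]
      nbp <- max(round(chrs$length_cM[c] * config$bp_per_cM) - 1L, S)
      bp <- sort(sample.int(nbp, S))
      cM <- bp / config$bp_per_cM
      p <- config$maf_law(S)
      founder_alleles <- matrix(rbinom(S * nf, 1L, p), S, nf)
      A <- matrix(0L, S, H)
      hl <- mosaic$haps[[c]]
      for (h in seq_len(H)) {
        idx <- findInterval(cM, hl[[h]]$ends) + 1L
        idx[idx > length(hl[[h]]$fid)] <- length(hl[[h]]$fid)
        A[, h] <- founder_alleles[cbind(seq_len(S), hl[[h]]$fid[idx])]
      }
      if (config$phase_switch_rate > 0) {
        for (i in seq_len(H %/% 2L)) {
          sw <- cumsum(rbinom(S, 1L, config$phase_switch_rate)) %% 2L == 1L
          if (any(sw)) {
            tmp <- A[sw, 2L * i - 1L]
            A[sw, 2L * i - 1L] <- A[sw, 2L * i]
            A[sw, 2L * i] <- tmp
          }
        }
      }
      if (config$genotype_error_rate > 0) {
        flip <- matrix(rbinom(S * H, 1L, config$genotype_error_rate), S, H)
        A <- (A + flip) %% 2L
      }
      blocks[[c]] <- A
      sites[[c]] <- data.frame(chrom = c, bp = bp, cM = cM)
    }
    haplotype_panel(do.call(rbind, blocks), do.call(rbind, sites),
                    indiv = as.character(mosaic$indiv),
                    labels = mosaic$subpop)
  })
}

#' Run the full simulator
#'
#' Convenience wrapper: pedigree, haplotype transmission and genotyping in
#' one call.
#' @param config a [sim_config()].
#' @return list with `panel` ([haplotype_panel()]), `mosaic`
#'   (`ancestry_mosaic`), `pedigree`, and `labels` (subpopulation per
#'   individual, named by individual id).
#' @export
simulate_panel <- function(config) {
  ped <- simulate_pedigree(config)
  mos <- transmit_haplotypes(ped, config)
  panel <- genotype_panel(mos, config)
  list(panel = panel, mosaic = mos, pedigree = ped,
       labels = setNames(mos$subpop, panel$indiv))
}
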