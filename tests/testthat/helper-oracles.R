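# Independent brute-force oracles and small fixtures used across the suite.

# mirror of the painting tie-break hash (all terms < 2^53, exact in doubles);
# t, s, d are 0-based as in the compiled code
r_tie_hash <- function(seed, t, s, d) {
  ((s + 1) * 1009 + (d + 1) * 9176 + (t + 1) * 12345 + (seed %% 100003) * 31) %% 100003
}

# longest identical interval (in sites) covering site s between two allele
# vectors, by direct left/right scan
r_cover_len <- function(x, y, s) {
  if (x[s] != y[s]) return(0L)
  a <- s
  while (a > 1L && x[a - 1L] == y[a - 1L]) a <- a - 1L
  b <- s
  S <- length(x)
  while (b < S && x[b + 1L] == y[b + 1L]) b <- b + 1L
  b - a + 1L
}

# site-by-site greedy painting oracle for one chromosome: longest covering
# match per site, seeded-hash tie-break, chunk accumulation at the donor
# individual level. Returns counts and lengths matrices.
r_paint_oracle <- function(alleles, hap_indiv, cM, seed) {
  S <- nrow(alleles); H <- ncol(alleles)
  N <- length(unique(hap_indiv))
  counts <- matrix(0, N, N)
  lengths <- matrix(0, N, N)
  w <- if (S == 1L) 0 else {
    mid <- (cM[-1] + cM[-S]) / 2
    c(mid[1] - cM[1], diff(mid), cM[S] - mid[S - 1])
  }
  for (t in seq_len(H)) {
    elig <- which(hap_indiv != hap_indiv[t])
    chosen <- integer(S)
    for (s in seq_len(S)) {
      lens <- vapply(elig, function(d) r_cover_len(alleles[, t], alleles[, d], s),
                     integer(1L))
      best <- max(lens)
      cand <- elig[lens == best]
      hs <- vapply(cand, function(d) r_tie_hash(seed, t - 1L, s - 1L, d - 1L),
                   numeric(1L))
      chosen[s] <- cand[which.max(hs)]  # max hash; first (lowest index) on hash tie
    }
    r <- rle(chosen)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      d_ind <- hap_indiv[r$values[k]] + 1L
      t_ind <- hap_indiv[t] + 1L
      counts[t_ind, d_ind] <- counts[t_ind, d_ind] + 1
      lengths[t_ind, d_ind] <- lengths[t_ind, d_ind] + sum(w[starts[k]:ends[k]])
    }
  }
  list(counts = counts, lengths = lengths)
}

# all maximal identical runs between two allele vectors, as a matrix of
# (start, end_inclusive) site indices
r_ident_runs <- function(x, y) {
  eq <- x == y
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

# random panel fixture: n_ind individuals, S sites on one chromosome with
# some shared haplotype structure so that matches exist
random_panel <- function(n_ind, S, seed, n_founder = 4L, chroms = 1L) {
  set.seed(seed)
  H <- 2L * n_ind
  blocks <- lapply(seq_len(chroms), function(ch) {
    founder <- matrix(rbinom(S * n_founder, 1L, runif(S, 0.1, 0.9)), S, n_founder)
    A <- matrix(0L, S, H)
    for (h in seq_len(H)) {
      # mosaic of founder rows: switch founder at random breakpoints
      nb <- rpois(1L, 3L)
      bks <- sort(sample.int(S - 1L, min(nb, S - 1L)))
      src <- sample.int(n_founder, length(bks) + 1L, replace = TRUE)
      lo <- c(1L, bks + 1L)
      hi <- c(bks, S)
      for (k in seq_along(lo)) A[lo[k]:hi[k], h] <- founder[lo[k]:hi[k], src[k]]
    }
    flip <- matrix(rbinom(S * H, 1L, 0.02), S, H)
    (A + flip) %% 2L
  })
  sites <- do.call(rbind, lapply(seq_len(chroms), function(ch) {
    bp <- sort(sample.int(S * 20000L, S))
    data.frame(chrom = ch, bp = bp, cM = bp / 1e6)
  }))
  haplotype_panel(do.call(rbind, blocks), sites, indiv = paste0("i", seq_len(n_ind)))
}

# panel whose individual-1/individual-2 first haplotypes are identical except
# at the given site indices; used to build controlled run/gap layouts
two_run_panel <- function(cM, disc_idx, seed = 404L) {
  set.seed(seed)
  S <- length(cM)
  x <- rbinom(S, 1L, 0.5)
  y <- x
  y[disc_idx] <- 1L - x[disc_idx]
  # filler haplotypes that match nowhere for more than a couple of sites
  f1 <- (x + rep_len(c(1L, 1L, 0L), S)) %% 2L
  f2 <- (x + rep_len(c(0L, 1L, 1L), S)) %% 2L
  alleles <- cbind(x, f1, y, f2)
  haplotype_panel(alleles,
                  data.frame(chrom = 1L, bp = round(cM * 1e6) + 1L, cM = cM),
                  indiv = c("A", "B"))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

small_sim <- function(seed = 1L, n = 30L, G = 8L,
                      chroms = data.frame(length_cM = 80, n_sites = 1600L),
                      ...) {
  simulate_panel(sim_config(1L, n, G, chromosomes = chroms, seed = seed, ...))
}
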