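# chunklength matrix with two 2-member clusters and exactly known
# cluster-level donations
block_chunklengths <- function() {
  ids <- c("a1", "a2", "b1", "b2")
  M <- matrix(0, 4, 4, dimnames = list(ids, ids))
  M["a1", c("a2", "b1", "b2")] <- c(8, 1, 1)   # a1 receives 8 from A, 2 from B
  M["a2", c("a1", "b1", "b2")] <- c(8, 1, 1)
  M["b1", c("b2", "a1", "a2")] <- c(6, 2, 2)   # b receives 6 from B, 4 from A
  M["b2", c("b1", "a1", "a2")] <- c(6, 2, 2)
  M
}

test_that("copying vectors aggregate and normalize donor clusters", {
  M <- block_chunklengths()
  cl <- setNames(c("A", "A", "B", "B"), rownames(M))
  cv <- copying_vectors(M, cl)
  expect_equal(cv["A", ], c(A = 0.8, B = 0.2))
  expect_equal(cv["B", ], c(A = 0.4, B = 0.6))

  one <- copying_vectors(M, setNames(rep("all", 4L), rownames(M)))
  expect_equal(unname(one[1L, ]), 1)

  # permuting individuals within clusters changes nothing
  perm <- c("a2", "a1", "b2", "b1")
  expect_equal(copying_vectors(M[perm, perm], cl), cv)

  expect_error(copying_vectors(M, setNames(c("A", "A", "B", NA), rownames(M))),
               "assigned")
})

test_that("nnls profiles recover exact and identity systems", {
  # three clusters; target C's donation vector equals source B's row of Y
  ids <- c("a1", "a2", "b1", "b2", "c1", "c2")
  M <- matrix(0, 6, 6, dimnames = list(ids, ids))
  # cluster-level receipts: A gets (10 from A, 1 from B); B gets (3, 5);
  # C copies exactly like B
  M["a1", "a2"] <- M["a2", "a1"] <- 10
  M[c("a1", "a2"), c("b1", "b2")] <- 0.5
  M["b1", "b2"] <- M["b2", "b1"] <- 5
  M[c("b1", "b2"), c("a1", "a2")] <- 1.5
  M[c("c1", "c2"), c("a1", "a2")] <- 1.5
  M[c("c1", "c2"), c("b1", "b2")] <- 2.5
  M[c("a1", "a2"), c("c1", "c2")] <- 0.2   # so every source system is full rank
  M[c("b1", "b2"), c("c1", "c2")] <- 0.3
  cl <- setNames(c("A", "A", "B", "B", "C", "C"), ids)
  pr <- nnls_profile(M, cl, "C")
  expect_equal(pr$beta, c(A = 0, B = 1), tolerance = 1e-9)

  # identity-like Y: beta proportional to the target's donation vector
  M2 <- matrix(0, 6, 6, dimnames = list(ids, ids))
  M2[c("a1", "a2"), c("a1", "a2")] <- 4; M2[c("b1", "b2"), c("b1", "b2")] <- 4
  diag(M2) <- 0
  M2[c("c1", "c2"), c("a1", "a2")] <- 1.5   # C receives 3 from A, 1 from B
  M2[c("c1", "c2"), c("b1", "b2")] <- 0.5
  pr2 <- nnls_profile(M2, cl, "C")
  expect_equal(pr2$beta, c(A = 0.75, B = 0.25), tolerance = 1e-9)

  expect_equal(sum(nnls_profiles(M, cl)["A", ]), 1)
  expect_error(nnls_profile(M, setNames(rep("X", 6L), ids), "X"), ">= 2 clusters")
  expect_error(nnls_profile(matrix(0, 6, 6, dimnames = list(ids, ids)), cl, "C"),
               "degenerate")
})

test_that("tvd matches hand values and is a metric on the simplex", {
  expect_equal(tvd(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5)), 0.5)
  expect_equal(tvd(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(tvd(c(1, 0), c(0, 1)), 1)
  expect_error(tvd(c(1, 0), c(1, 0, 0)), "length")
  set.seed(3)
  for (i in 1:25) {
    a <- runif(4); a <- a / sum(a)
    b <- runif(4); b <- b / sum(b)
    c_ <- runif(4); c_ <- c_ / sum(c_)
    expect_equal(tvd(a, b), tvd(b, a))
    expect_lte(tvd(a, c_), tvd(a, b) + tvd(b, c_) + 1e-12)
    expect_true(tvd(a, b) >= 0 && tvd(a, b) <= 1)
  }
  cv <- copying_vectors(block_chunklengths(),
                        setNames(c("A", "A", "B", "B"), rownames(block_chunklengths())))
  tm <- tvd_matrix(cv)
  expect_equal(tm["A", "B"], tvd(cv["A", ], cv["B", ]))
  expect_equal(diag(tm), c(A = 0, B = 0))
})

test_that("Hudson Fst matches hand values and estimator properties", {
  expect_equal(hudson_fst(data.frame(p1 = 0.3, n1 = 100, p2 = 0.5, n2 = 200)),
               0.0732, tolerance = 1e-3)
  expect_equal(hudson_fst(data.frame(p1 = 1, n1 = 50, p2 = 0, n2 = 50)), 1)
  expect_lt(abs(hudson_fst(data.frame(p1 = 0.3, n1 = 2000, p2 = 0.3, n2 = 2000))),
            0.005)
  # allele-label swap per site leaves the estimate unchanged
  set.seed(8)
  tab <- data.frame(p1 = runif(40, 0.05, 0.95), n1 = 120,
                    p2 = runif(40, 0.05, 0.95), n2 = 80)
  expect_equal(hudson_fst(tab),
               hudson_fst(transform(tab, p1 = 1 - p1, p2 = 1 - p2)))
  # one site equals the single-site form
  one <- tab[1L, ]
  num <- (one$p1 - one$p2)^2 - one$p1 * (1 - one$p1) / (one$n1 - 1) -
    one$p2 * (1 - one$p2) / (one$n2 - 1)
  den <- one$p1 * (1 - one$p2) + one$p2 * (1 - one$p1)
  expect_equal(hudson_fst(one), num / den)
  expect_error(hudson_fst(data.frame(p1 = 0.5, n1 = 1, p2 = 0.5, n2 = 10)),
               "allele copies")
})

test_that("panel-level Fst separates drifted groups and monomorphic sites are skipped", {
  set.seed(5)
  S <- 400L
  p <- runif(S, 0.2, 0.8)
  p1 <- pmin(pmax(p + rnorm(S, 0, 0.08), 0.01), 0.99)
  p2 <- pmin(pmax(p - rnorm(S, 0, 0.08), 0.01), 0.99)
  a <- cbind(matrix(rbinom(S * 20L, 1L, p1), S),
             matrix(rbinom(S * 20L, 1L, p2), S))
  panel <- haplotype_panel(a, data.frame(chrom = 1L, bp = seq_len(S), cM = seq_len(S) / 50),
                           indiv = paste0("i", 1:20))
  f <- hudson_fst(panel, 1:10, 11:20)
  expect_gt(f, 0.01)
  fm <- fst_matrix(panel, setNames(rep(c("g1", "g2"), each = 10L), panel$indiv))
  expect_equal(fm["g1", "g2"], f)
  expect_equal(diag(fm), c(g1 = 0, g2 = 0))
})
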