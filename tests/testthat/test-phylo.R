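test_that("p-distance applies pairwise deletion", {
  aln <- Biostrings::AAStringSet(c(a = "AAAA", b = "AAAT", c = "A-AA",
                                   d = "AAAA"))
  expect_equal(pDistance(aln, "a", "a"), 0)
  expect_equal(pDistance(aln, "a", "b"), 0.25)
  expect_equal(pDistance(aln, "c", "d"), 0)  # 3 compared, 0 differ
  expect_equal(pDistance(aln, "a", "b"), pDistance(aln, "b", "a"))
  gappy <- Biostrings::AAStringSet(c(x = "--AA", y = "AA--"))
  expect_error(pDistance(gappy, "x", "y"), "comparable")
})

test_that("PAM-001 inverts the Dayhoff expected-difference curve", {
  expect_equal(pamFromP(0), 0)
  # strictly increasing in p
  grid <- c(0.01, 0.05, 0.1, 0.2, 0.4, 0.6, 0.8)
  D <- vapply(grid, pamFromP, numeric(1))
  expect_true(all(diff(D) > 0))
  # re-evaluating the expected difference at the returned distance
  # reproduces p to 1e-9
  for (p in grid)
    expect_lt(abs(pamExpectedDiff(pamFromP(p) * 100) - p), 1e-9)
  # saturation beyond the attainable asymptote errors
  expect_error(pamFromP(0.999), "saturat")
})

test_that("PAM matrix powers agree with the eigen evaluation", {
  M <- pam1Matrix()
  expect_equal(unname(rowSums(M)), rep(1, 20), tolerance = 1e-12)
  pam <- PoGOfam:::.pam_setup()
  # independent oracle: repeated matrix multiplication
  Mk <- diag(20)
  for (k in 1:50) {
    Mk <- Mk %*% M
    if (k %in% c(1, 5, 20, 50)) {
      p_direct <- 1 - sum(pam$bf * diag(Mk))
      expect_equal(pamExpectedDiff(k), p_direct, tolerance = 1e-9)
    }
  }
  expect_equal(pamExpectedDiff(1), 0.01, tolerance = 1e-9)
})

test_that("neighbor joining recovers small closed-form cases", {
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- neighborJoining(d2)
  expect_equal(ape::cophenetic.phylo(t2)["A", "B"], 0.3)
  d3 <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- neighborJoining(d3)
  pend <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(pend[c("A", "B", "C")], c(A = 0.05, B = 0.15, C = 0.25))
  expect_error(neighborJoining(matrix(c(0, 1, 2, 0), 2, 2)),
               "symmetric")
})

test_that("neighbor joining is exact on additive matrices", {
  true <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  dm <- ape::cophenetic.phylo(true)
  tr <- neighborJoining(dm)
  expect_equal(max(abs(ape::cophenetic.phylo(tr)[rownames(dm),
                                                 colnames(dm)] - dm)), 0)
  # random trees, cross-checked against ape::nj topologies
  set.seed(13)
  for (k in 1:20) {
    n <- sample(4:12, 1)
    rt <- ape::rtree(n, br = function(x) runif(x, 0.05, 1))
    dm <- ape::cophenetic.phylo(rt)
    mine <- neighborJoining(dm)
    expect_lt(max(abs(ape::cophenetic.phylo(mine)[rownames(dm),
                                                  colnames(dm)] - dm)),
              1e-9)
    ref <- ape::nj(dm)
    expect_equal(
      as.numeric(ape::dist.topo(ape::unroot(mine), ape::unroot(ref))), 0)
  }
})

test_that("bootstrap supports are deterministic and bounded", {
  sim <- simulateFamily(simConfig(seed = 55, seq_length = 80))
  aln <- progressiveMsa(simProteins(sim))
  t1 <- bootstrapSupport(aln, n_replicates = 50, seed = 9)
  t2 <- bootstrapSupport(aln, n_replicates = 50, seed = 9)
  expect_identical(writeNewick(t1), writeNewick(t2))
  supp <- suppressWarnings(as.numeric(t1$node.label))
  supp <- supp[!is.na(supp)]
  expect_true(all(supp >= 0 & supp <= 100))
  # different seed is allowed to differ; same alignment, same topology
  t3 <- bootstrapSupport(aln, n_replicates = 50, seed = 10)
  expect_equal(
    as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t3))), 0)
})

test_that("alignments without signal report support 0", {
  s <- rand_aa(40)
  aln <- Biostrings::AAStringSet(setNames(rep(s, 5), paste0("S", 1:5, "_g")))
  tr <- bootstrapSupport(aln, n_replicates = 20, seed = 3)
  supp <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(supp[!is.na(supp)] == 0))
})

test_that("outgroup rooting places and validates the root", {
  tr <- readNewick("((A_1:1,B_1:1)80:1,(C_1:1,Og_1:1)70:1);")
  rooted <- rootWithOutgroup(tr, "Og_1")
  expect_true(ape::is.rooted(rooted))
  kids <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1L, 2]
  expect_true(match("Og_1", rooted$tip.label) %in% kids)
  # two-leaf outgroup clade roots on its stem
  tr2 <- readNewick("((A_1:1,B_1:1)90:1,(Og_1:1,Og_2:1)95:1);")
  rooted2 <- rootWithOutgroup(tr2, c("Og_1", "Og_2"))
  expect_true(ape::is.monophyletic(rooted2, c("Og_1", "Og_2")))
  # scattered outgroup is rejected with the conflicting leaves named
  tr3 <- readNewick("((A_1:1,Og_1:1)90:1,(B_1:1,Og_2:1)95:1,C_1:1);")
  expect_error(rootWithOutgroup(tr3, c("Og_1", "Og_2")),
               "not monophyletic")
})

test_that("newick round trips preserve topology, lengths and supports", {
  s <- "((A:1,B:2)90:1,C:3);"
  tr <- readNewick(s)
  expect_equal(writeNewick(tr), s)
  s2 <- "((A:0.5,B:0.25):1,C:3);"
  expect_equal(writeNewick(readNewick(s2)), s2)
  # random 50-leaf tree round trips through a file
  set.seed(17)
  big <- ape::rtree(50, br = function(x) runif(x, 1e-4, 2))
  tf <- tempfile(fileext = ".nwk")
  writeNewick(big, tf)
  back <- readNewick(tf)
  expect_equal(
    as.numeric(ape::dist.topo(ape::unroot(big), ape::unroot(back))), 0)
  expect_equal(sort(back$edge.length), sort(big$edge.length),
               tolerance = 1e-10)
  expect_error(readNewick("((A:1,B:2;"), "parse error")
})
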