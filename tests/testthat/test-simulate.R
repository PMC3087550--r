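test_that("the simulator is a pure function of (config, seed)", {
  cfg <- simConfig(seed = 9, seq_length = 60)
  s1 <- simulateFamily(cfg)
  s2 <- simulateFamily(cfg)
  expect_identical(writeNewick(simGeneTree(s1)),
                   writeNewick(simGeneTree(s2)))
  expect_identical(as.character(simCds(s1)), as.character(simCds(s2)))
  expect_identical(as.character(simEsts(s1)), as.character(simEsts(s2)))
  expect_identical(simOrthogroups(s1), simOrthogroups(s2))
})

test_that("without duplication or loss the gene tree mirrors the species tree", {
  cfg <- simConfig(seed = 4, dup_rate = 0, loss_rate = 0,
                   seq_length = 30)
  sim <- simulateGeneTree(cfg)
  expect_equal(nrow(simGenes(sim)), 10L)  # one gene per species
  expect_length(simOrthogroups(sim), 1L)
  gt <- simGeneTree(sim)
  # same unrooted topology as the species tree after renaming tips
  sp <- cfg$species_tree
  gt$tip.label <- sub("_g1$", "", gt$tip.label)
  expect_equal(
    as.numeric(ape::dist.topo(ape::unroot(gt), ape::unroot(sp))), 0)
})

test_that("pure-birth gene counts match the analytic expectation", {
  # two species, path length 1 from root to each tip
  tr <- "(A:1,B:1)N1;"
  lam <- 0.4
  counts <- vapply(1:200, function(k) {
    cfg <- simConfig(species_tree = tr, dup_rate = lam, loss_rate = 0,
                     outgroup_species = character(0),
                     reference_node = "N1", seed = 5000 + k)
    sim <- simulateGeneTree(cfg)
    sum(simGenes(sim)$species == "A")
  }, numeric(1))
  expect_true(all(counts >= 1))  # no loss: at least the root copy
  expected <- exp(lam * 1)
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("sequence divergence increases with path length", {
  sim <- simulateFamily(simConfig(seed = 61, dup_rate = 0))
  prot <- simProteins(sim)
  gt <- simGeneTree(sim)
  pl <- ape::cophenetic.phylo(gt)
  aln <- progressiveMsa(prot)
  ids <- names(prot)
  obs <- c(); tru <- c()
  set.seed(61)
  for (k in 1:50) {
    ij <- sample(ids, 2)
    obs <- c(obs, pDistance(aln, ij[1], ij[2]))
    tru <- c(tru, pl[ij[1], ij[2]])
  }
  expect_gt(stats::cor(obs, tru, method = "spearman"), 0)
})

test_that("orthogroup truth matches an independent traversal oracle", {
  for (seed in c(71, 72, 73, 74)) {
    cfg <- simConfig(seed = seed, dup_rate = 0.5, seq_length = 30)
    sim <- simulateGeneTree(cfg)
    if (nrow(simGenes(sim)) == 0 || nrow(simGenes(sim)) > 30) next
    got <- trueOrthogroups(sim, "N1")
    want <- oracle_orthogroups(sim, "N1")
    expect_true(partitions_equal(got, want), info = paste("seed", seed))
    # truth depends only on the gene tree, not on sequence parameters
    expect_identical(simOrthogroups(evolveSequences(sim)),
                     simOrthogroups(sim))
  }
  # one duplication ancestral to the cut yields two groups
  cfg2 <- simConfig(seed = 1, dup_rate = 0, root_copies = 2)
  sim2 <- simulateGeneTree(cfg2)
  expect_length(trueOrthogroups(sim2, "NROOT"), 2L)
  expect_error(trueOrthogroups(sim2, "Nowhere"), "not on the species")
})

test_that("error-free full-length fragments translate back to the protein", {
  cfg <- simConfig(seed = 81, seq_length = 40, est_fraction = 1,
                   est_len = 4000, est_error = 0)
  sim <- simulateFamily(cfg)
  ests <- simEsts(sim)
  cds_len <- setNames(Biostrings::nchar(simCds(sim)),
                      names(simCds(sim)))
  full <- which(Biostrings::nchar(ests) ==
                  cds_len[S4Vectors::mcols(ests)$source_gene])
  expect_gt(length(full), 0)
  for (i in full[1:min(3, length(full))]) {
    gene <- S4Vectors::mcols(ests)$source_gene[i]
    prot <- as.character(simProteins(sim)[[gene]])
    frames <- sixFrameTranslate(ests[[i]])
    expect_true(prot %in% frames)
  }
})

test_that("a 40%-length fragment survives the coverage filter", {
  cfg <- simConfig(seed = 91, seq_length = 100)
  sim <- simulateFamily(cfg)
  gene <- simGenes(sim)$id[1]
  cds <- as.character(simCds(sim)[[gene]])
  frag <- Biostrings::DNAStringSet(setNames(substr(cds, 1, 120),
                                            "Xx_frag"))  # 40 of 100 codons
  q <- Biostrings::AAStringSet(setNames(
    as.character(simProteins(sim)[[gene]]), "q"))
  h <- searchTranslated(q, frag)
  cov <- coverageFilter(h, c(q = 100L), 0.40)
  expect_equal(cov$kept, "Xx_frag")
  expect_equal(unname(cov$coverage), 0.40)
})
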