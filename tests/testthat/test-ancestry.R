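test_that("the XTH worked example reproduces the published counts", {
  reg <- xthSpeciesRegistry()
  pg <- xthPogoFixture()
  lad <- xthLineageLadder()
  expect_equal(pogosContaining(pg, reg, lad$streptophyte_algae), 2L)
  expect_equal(pogosContaining(pg, reg, lad$early_tracheophytes), 7L)
  expect_equal(pogosContaining(pg, reg, lad$angiosperms), 18L)
  # four ancestral group-I genes in the last common embryophyte ancestor
  hg <- attr(pg, "homolog_group")
  orig <- pogoOrigin(pg)
  expect_equal(sum(orig == "Embryophyta" & hg[names(orig)] == "I"), 4L)
  # moss sits in six PoGOs; the shared count excludes the moss-only one
  prof <- founderProfile(pg, reg, lad)
  bry <- prof[prof$node == "Bryophyta", ]
  expect_equal(bry$founder_count, 6L)
  expect_equal(bry$shared_count, 5L)
  # twelve PoGOs shared between eudicots and monocots
  eud <- speciesInLineage(reg, "Eudicots")
  mon <- speciesInLineage(reg, "Monocots")
  shared <- vapply(pogoSpecies(pg), function(s)
    any(s %in% eud) && any(s %in% mon), logical(1))
  expect_equal(sum(shared), 12L)
  # the paralog group never enters founder counts
  expect_length(paralogGroups(pg), 1L)
  expect_equal(pogosContaining(pg, reg, "Viridiplantae"), 21L)
})

test_that("Dollo gain/loss handles the worked loss cases", {
  reg <- xthSpeciesRegistry()
  # moss + lycophyte + all four eudicot genomes, absent in both monocot
  # genomes: one loss on the monocot stem
  gl <- dolloGainLoss(c("Pp", "Sm", "At", "Gm", "Pt", "Vv"), reg)
  expect_equal(gl$gain, "Embryophyta")
  expect_equal(gl$losses, "Monocots")
  # absent from rice only (sorghum present): terminal loss
  gl2 <- dolloGainLoss(c("Pp", "Sm", "At", "Gm", "Pt", "Vv", "Sb"), reg)
  expect_equal(gl2$losses, "Os")
  # present in every complete genome below the gain: no losses
  gl3 <- dolloGainLoss(c("Pp", "Sm", "At", "Gm", "Pt", "Vv", "Os", "Sb"),
                       reg)
  expect_equal(gl3$gain, "Embryophyta")
  expect_equal(gl3$n_losses, 0L)
  # all seed plants absent: one loss on their stem; EST-only gymnosperms
  # below it are uninformative and covered by the same loss
  gl4 <- dolloGainLoss(c("Pp", "Sm", "Tr"), reg)
  expect_equal(gl4$gain, "Embryophyta")
  expect_equal(gl4$losses, "Euphyllophyta")
  # single-species group: gain at the species, nothing to lose
  expect_equal(dolloGainLoss("Pp", reg)$n_losses, 0L)
})

test_that("Dollo loss sets are minimal (exhaustive enumeration)", {
  reg <- xthSpeciesRegistry()
  set.seed(23)
  sp <- speciesCodes(reg)
  for (k in 1:25) {
    members <- sample(sp, sample(2:8, 1))
    gl <- dolloGainLoss(members, reg)
    expect_equal(gl$n_losses, oracle_dollo_min_losses(reg, members),
                 info = paste(members, collapse = ","))
  }
  # the same holds on a smaller registry
  reg2 <- two_ref_registry()
  for (k in 1:15) {
    members <- sample(speciesCodes(reg2), sample(2:5, 1))
    gl <- dolloGainLoss(members, reg2)
    expect_equal(gl$n_losses, oracle_dollo_min_losses(reg2, members),
                 info = paste(members, collapse = ","))
  }
})

test_that("founder counting is plain set arithmetic on a toy set", {
  reg <- two_ref_registry()
  pg <- pogoSetFromMembership(
    list(A = c("At", "Os", "Pp"), B = c("At", "Vv"), C = c("Pp", "Tr")),
    reg)
  expect_equal(pogosContaining(pg, reg, "Bryophyta"), 2L)
  expect_equal(pogosContaining(pg, reg, "Angiosperms"), 2L)
  expect_equal(pogosContaining(pg, reg, "Eudicots"), 2L)
  expect_equal(pogosContaining(pg, reg, "Chlorophyta"), 0L)
  prof <- founderProfile(pg, reg, list("Bryophyta", "Eudicots"))
  # at Eudicots only A ({At,Os,Pp}) straddles the boundary; B is wholly
  # inside and C wholly outside
  expect_equal(prof$shared_count, c(1L, 1L))
  # a single PoGO spanning everything counts once everywhere
  pg1 <- pogoSetFromMembership(list(A = speciesCodes(reg)), reg)
  for (n in c("Bryophyta", "Angiosperms", "Chlorophyta"))
    expect_equal(pogosContaining(pg1, reg, n), 1L)
})

test_that("shared founder counts grow monotonically on loss-free sims", {
  # with no losses, a group's members are all species below its gain, so
  # along a nested root-to-tip ladder the shared count never decreases
  for (seed in c(41, 42, 43, 44, 45)) {
    sim <- simulateGeneTree(simConfig(seed = seed, dup_rate = 0.3))
    og <- simOrthogroups(sim)
    if (length(og) == 0) next
    reg <- simRegistry(sim)
    pg <- pogoSetFromMembership(
      lapply(og, function(g) unique(sub("_.*$", "", g))), reg)
    ladder <- list("N1", "N3", "N7", "H")  # nested path to leaf H
    prof <- founderProfile(pg, reg, ladder)
    expect_true(all(diff(prof$shared_count) >= 0),
                info = paste("seed", seed))
  }
})

test_that("ancestry reports serialize to TSV", {
  reg <- xthSpeciesRegistry()
  pg <- xthPogoFixture()
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  out <- writeAncestryReports(pg, reg, xthLineageLadder(),
                              founders_path = f1, events_path = f2)
  expect_true(file.exists(f1) && file.exists(f2))
  back <- read.table(f1, sep = "\t", header = TRUE)
  expect_equal(back$founder_count, out$founders$founder_count)
  ev <- read.table(f2, sep = "\t", header = TRUE)
  expect_equal(nrow(ev), 21L)
})
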