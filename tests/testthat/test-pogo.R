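test_that("the duplicated reference pair splits into two groups", {
  reg <- two_ref_registry()
  tr <- readNewick(
    "((At_1:.1,Os_1:.1)90:.1,(At_2:.1,Os_2:.1)85:.1)99;")
  pg <- callPogos(tr, reg)
  expect_length(pogoGroups(pg), 2L)
  expect_setequal(vapply(pogoGroups(pg), paste, character(1),
                         collapse = "+"),
                  c("At_1+Os_1", "At_2+Os_2"))
  expect_equal(unname(pogoSupport(pg)), c(90L, 85L))
  expect_equal(unname(pogoOrigin(pg)), rep("Angiosperms", 2))
})

test_that("support must strictly exceed the threshold", {
  reg <- two_ref_registry()
  tr <- readNewick(
    "((At_1:.1,Os_1:.1)50:.1,(At_2:.1,Os_2:.1)85:.1)40;")
  pg <- callPogos(tr, reg)
  expect_length(pogoGroups(pg), 1L)
  expect_setequal(pogoGroups(pg)[[1]], c("At_2", "Os_2"))
  # the rejected clade's leaves stay unassigned (not same-species)
  expect_setequal(unassignedLeaves(pg), c("At_1", "Os_1"))
})

test_that("lineage-restricted clades need two species of one lineage", {
  reg <- two_ref_registry()
  # two moss species at support 80, no reference species; the weakly
  # supported root cannot swallow them
  tr <- readNewick("((Pp_1:.1,Tr_1:.1)80:.1,(At_1:.1,Os_1:.1)90:.1)40;")
  pg <- callPogos(tr, reg)
  ids <- vapply(pogoGroups(pg), paste, character(1), collapse = "+")
  expect_true("Pp_1+Tr_1" %in% ids)
  moss <- which(ids == "Pp_1+Tr_1")
  expect_equal(pg@lineageRestrictedTo[moss], "Bryophyta")
  # a single-species clade is never a PoGO: it becomes a paralog group
  tr2 <- readNewick(paste0(
    "((Pp_1:.1,(Pp_2:.1,(Pp_3:.1,(Pp_4:.1,Pp_5:.1)88:.1)92:.1)91:.1)90:.1,",
    "(At_1:.1,Os_1:.1)99:.1)97;"))
  pg2 <- callPogos(tr2, reg)
  expect_length(pogoGroups(pg2), 1L)
  expect_length(paralogGroups(pg2), 1L)
  expect_setequal(paralogGroups(pg2)[[1]], paste0("Pp_", 1:5))
})

test_that("species-consistency rejects supported conflicts only", {
  reg <- two_ref_registry()
  # pruned subtree congruent with the species tree -> consistent
  good <- readNewick(
    "(((At_1:.1,Vv_1:.1)90:.1,Os_1:.1)88:.1,(Pp_1:.1,Sm_1:.1)80:.1)95;")
  expect_true(checkSpeciesConsistency(good, registry = reg))
  # well-supported edge grouping a eudicot with a chlorophyte against
  # other eudicots and monocots -> conflict
  bad <- readNewick(
    "((Vv_1:.1,Cr_1:.1)90:.1,(At_1:.1,Os_1:.1)88:.1)95;")
  expect_false(checkSpeciesConsistency(bad, registry = reg))
  # the same conflict at support 40 is tolerated
  ok <- readNewick(
    "((Vv_1:.1,Cr_1:.1)40:.1,(At_1:.1,Os_1:.1)45:.1)95;")
  expect_true(checkSpeciesConsistency(ok, registry = reg))
  # copy-number sanity: more than max_copies leaves of one species fail
  many <- readNewick(
    "((At_1:.1,At_2:.1)90:.1,(At_3:.1,At_4:.1)90:.1)95;")
  expect_false(checkSpeciesConsistency(many, registry = reg,
                                       max_copies = 3))
  expect_true(checkSpeciesConsistency(many, registry = reg,
                                      max_copies = 4))
})

test_that("within-group tandem paralogs are tolerated", {
  reg <- two_ref_registry()
  tr <- readNewick(
    "(((At_1:.1,At_2:.1)95:.1,Vv_1:.1)90:.1,Os_1:.1)99;")
  pg <- callPogos(tr, reg)
  expect_length(pogoGroups(pg), 1L)
  expect_setequal(pogoGroups(pg)[[1]], c("At_1", "At_2", "Vv_1", "Os_1"))
})

test_that("origins are the lineage-tree MRCA of member species", {
  reg <- xthSpeciesRegistry()
  expect_equal(inferOrigin(c("At", "Os"), reg), "Angiosperms")
  expect_equal(inferOrigin(c("At", "Pin"), reg), "Spermatophyta")
  expect_equal(inferOrigin(c("Cv", "At", "Pt"), reg), "Streptophyta")
  expect_equal(inferOrigin(c("Cr", "At"), reg), "Viridiplantae")
})

test_that("groups are disjoint clades and calling is deterministic", {
  for (seed in c(301, 302, 303)) {
    sim <- simulateFamily(simConfig(seed = seed, seq_length = 120))
    prot <- simProteins(sim)
    og <- names(prot)[sub("_.*$", "", names(prot)) %in% c("OG1", "OG2")]
    aln <- progressiveMsa(prot)
    tr <- bootstrapSupport(aln, n_replicates = 50, seed = seed)
    rooted <- rootWithOutgroup(tr, og)
    reg <- simRegistry(sim)
    pg <- callPogos(rooted, reg, reference_species = c("A", "E"),
                    outgroup_ids = og)
    members <- unlist(pogoGroups(pg))
    expect_equal(anyDuplicated(members), 0L)
    # every group is a clade of the tree
    for (g in pogoGroups(pg)) {
      mrca <- if (length(g) > 1) ape::getMRCA(rooted, g) else NA
      if (!is.na(mrca)) {
        below <- rooted$tip.label[PoGOfam:::.tips_under(rooted, mrca)]
        expect_setequal(below, g)
      }
    }
    # identical inputs give identical groupings
    pg2 <- callPogos(rooted, reg, reference_species = c("A", "E"),
                     outgroup_ids = og)
    expect_identical(pogoGroups(pg), pogoGroups(pg2))
    # raising min_support never increases the number of PoGOs
    pg80 <- callPogos(rooted, reg, reference_species = c("A", "E"),
                      outgroup_ids = og, min_support = 80)
    expect_lte(length(pogoGroups(pg80)), length(pogoGroups(pg)))
  }
})

test_that("unrooted trees are rejected", {
  reg <- two_ref_registry()
  tr <- ape::read.tree(text = "(At_1:1,Os_1:1,Pp_1:1);")
  expect_error(callPogos(tr, reg), "rooted")
})
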