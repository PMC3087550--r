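test_that("a query finds itself with full-span identity", {
  set.seed(1)
  q <- Biostrings::AAStringSet(setNames(rand_aa(60), "q1"))
  subs <- Biostrings::AAStringSet(setNames(
    c(as.character(q[[1]]), rand_aa(50)), c("Sp_self", "Sp_other")))
  h <- searchProtein(q, subs)
  expect_equal(nrow(h), 1L)
  expect_equal(h$subject_id, "Sp_self")
  expect_equal(h$identities, 60L)
  expect_equal(c(h$qstart, h$qend), c(0L, 60L))
  expect_lte(h$evalue, 1e-4)
})

test_that("search scores equal the exhaustive Smith-Waterman oracle", {
  set.seed(11)
  for (k in 1:60) {
    la <- sample(5:30, 1); lb <- sample(5:(60 - la), 1)
    a <- rand_aa(la); b <- rand_aa(lb)
    o <- oracle_sw(a, b)
    if (o > 0)
      expect_equal(localAlign(a, b)$score, o, info = paste(a, b))
  }
})

test_that("unrelated random 50-mers never pass the e-value cutoff", {
  set.seed(5)
  q_hits <- 0L
  for (k in 1:100) {
    q <- Biostrings::AAStringSet(setNames(rand_aa(50), "q"))
    s <- Biostrings::AAStringSet(setNames(rand_aa(50), "Sp_s"))
    q_hits <- q_hits + nrow(searchProtein(q, s))
  }
  expect_equal(q_hits, 0L)
})

test_that("e-values decrease in score and hits shrink with the cutoff", {
  cfg <- scoringConfig()
  e <- karlinEvalue(c(30, 40, 50), 100, 1000, cfg)
  expect_true(all(diff(e) < 0))
  # monotonicity: lowering evalue_max never adds hits
  set.seed(2)
  q <- Biostrings::AAStringSet(setNames(rand_aa(80), "q"))
  subs <- Biostrings::AAStringSet(setNames(
    vapply(1:6, function(i) {
      s <- strsplit(as.character(q[[1]]), "")[[1]]
      flip <- sample(80, i * 10)
      s[flip] <- vapply(flip, function(.) rand_aa(1), character(1))
      paste(s, collapse = "")
    }, character(1)), paste0("Sp_", 1:6)))
  loose <- searchProtein(q, subs, scoringConfig(evalue_max = 1e-2))
  strict <- searchProtein(q, subs, scoringConfig(evalue_max = 1e-8))
  expect_true(all(strict$subject_id %in% loose$subject_id))
})

test_that("translated search maps frames to nucleotide coordinates", {
  set.seed(3)
  q <- Biostrings::AAStringSet(setNames(rand_aa(80), "q1"))
  # EST: exact codon back-translation of query residues 11..60 (50 aa)
  res <- strsplit(substr(as.character(q[[1]]), 11, 60), "")[[1]]
  gc <- Biostrings::GENETIC_CODE
  bt <- vapply(res, function(a) names(gc)[gc == a][1], character(1))
  est <- Biostrings::DNAStringSet(setNames(paste(bt, collapse = ""),
                                           "Sp_e1"))
  h <- searchTranslated(q, est)
  expect_equal(nrow(h), 1L)
  expect_equal(h$frame, 1L)
  expect_equal(h$identities, 50L)
  expect_equal(c(h$sstart, h$send), c(0L, 150L))
  # reverse complement: same identities, frame -1, same forward span
  rc <- Biostrings::DNAStringSet(setNames(
    oracle_revcomp(as.character(est[[1]])), "Sp_e1"))
  hr <- searchTranslated(q, rc)
  expect_equal(hr$frame, -1L)
  expect_equal(hr$identities, 50L)
  expect_equal(c(hr$sstart, hr$send), c(0L, 150L))
  # a random EST yields nothing
  set.seed(4)
  hrand <- searchTranslated(
    q, Biostrings::DNAStringSet(setNames(rand_nt(150), "Sp_r")))
  expect_equal(nrow(hrand), 0L)
})

test_that("hitsToFasta deduplicates and reports dangling subjects", {
  subs <- Biostrings::AAStringSet(c(Sp_a = "MKV", Sp_b = "WYH",
                                    Sp_c = "MKW"))
  h <- data.frame(subject_id = c("Sp_a", "Sp_b", "Sp_a"))
  expect_equal(names(hitsToFasta(h, subs)), c("Sp_a", "Sp_b"))
  expect_length(hitsToFasta(data.frame(subject_id = character(0)), subs),
                0L)
  expect_setequal(
    names(hitsToFasta(data.frame(subject_id = names(subs)), subs)),
    names(subs))
  expect_error(hitsToFasta(data.frame(subject_id = "Sp_zzz"), subs),
               "Sp_zzz")
})

test_that("aligned-block extraction merges overlaps per frame", {
  set.seed(6)
  q <- Biostrings::AAStringSet(setNames(rand_aa(120), "q1"))
  gc <- Biostrings::GENETIC_CODE
  bt <- function(aa) paste(vapply(strsplit(aa, "")[[1]], function(a)
    names(gc)[gc == a][1], character(1)), collapse = "")
  est <- Biostrings::DNAStringSet(setNames(
    bt(substr(as.character(q[[1]]), 1, 100)), "Sp_e"))
  h_all <- searchTranslated(q, est)
  one <- extractAlignedBlocks(h_all, est)
  expect_equal(Biostrings::nchar(one)[[1]], 100L)
  expect_equal(S4Vectors::mcols(one)$source, "translated_est_block")

  # two disjoint same-frame blocks of 30 and 20 residues -> 50 residues
  mk_hsp <- function(p0, p1) data.frame(
    query_id = "q1", subject_id = "Sp_e", frame = 1L,
    qstart = p0, qend = p1, sstart = 3L * p0, send = 3L * p1,
    identities = p1 - p0, score = 100, evalue = 1e-30,
    aligned_query = strrep("A", p1 - p0),
    aligned_subject = strrep("A", p1 - p0))
  two <- extractAlignedBlocks(rbind(mk_hsp(0L, 30L), mk_hsp(50L, 70L)),
                              est)
  expect_equal(Biostrings::nchar(two)[[1]], 50L)
  # 5-residue overlap emitted once: 30 + 20 - 5 = 45
  ovl <- extractAlignedBlocks(rbind(mk_hsp(0L, 30L), mk_hsp(25L, 45L)),
                              est)
  expect_equal(Biostrings::nchar(ovl)[[1]], 45L)
  # subsequence property: emitted residues occur in order in the frame
  tr <- sixFrameTranslate(est[[1]])[["+1"]]
  expect_equal(as.character(ovl[[1]]), substr(tr, 1, 45))
  expect_error(extractAlignedBlocks(mk_hsp(0L, 0L)[0, ], est), "no HSPs")
})

test_that("coverage filter applies the 40% boundary inclusively", {
  mk <- function(subject, q0, q1) data.frame(
    query_id = "q", subject_id = subject, frame = 1L,
    qstart = q0, qend = q1, sstart = 0L, send = 3L * (q1 - q0),
    identities = q1 - q0, score = 50, evalue = 1e-10,
    aligned_query = "", aligned_subject = "")
  qlen <- c(q = 100L)
  # one HSP spanning 39 of 100 positions -> excluded (strictly < 40%)
  r39 <- coverageFilter(mk("s", 0L, 39L), qlen)
  expect_equal(r39$discarded, "s")
  # union of [0,25) and [20,45) -> 45 positions -> kept
  r45 <- coverageFilter(rbind(mk("s", 0L, 25L), mk("s", 20L, 45L)), qlen)
  expect_equal(r45$kept, "s")
  expect_equal(unname(r45$coverage), 0.45)
  # full-length hit kept
  expect_equal(coverageFilter(mk("s", 0L, 100L), qlen)$kept, "s")
  # constructed set at coverages .35/.39/.40/.50 keeps exactly two
  hs <- rbind(mk("s35", 0L, 35L), mk("s39", 0L, 39L),
              mk("s40", 0L, 40L), mk("s50", 0L, 50L))
  r <- coverageFilter(hs, qlen, 0.40)
  expect_setequal(r$kept, c("s40", "s50"))
  # raising min_fraction never adds kept subjects
  r2 <- coverageFilter(hs, qlen, 0.45)
  expect_true(all(r2$kept %in% r$kept))
  # coverage is the max over queries when a subject hits several
  h2 <- rbind(mk("s", 0L, 10L),
              within(mk("s", 0L, 60L), query_id <- "q2"))
  expect_equal(coverageFilter(h2, c(q = 100L, q2 = 100L))$kept, "s")
})

test_that("redundancy collapse clusters within species only", {
  set.seed(8)
  base <- rand_aa(100)
  near <- base
  substr(near, 50, 50) <- if (substr(base, 50, 50) == "A") "W" else "A"
  recs <- Biostrings::AAStringSet(c(
    Aa_1 = base, Aa_2 = base,          # identical same-species pair
    Bb_1 = base,                       # identical, other species
    Aa_3 = near))                      # 99% identical to base
  out <- collapseRedundant(recs, identity_threshold = 0.99)
  expect_true("Bb_1" %in% names(out))  # cross-species never merges
  # identical pair and the single-mismatch record (identity 0.99) all
  # merge into one cluster represented by the smallest id
  expect_equal(sum(startsWith(names(out), "Aa_")), 1L)
  expect_true("Aa_1" %in% names(out))
  # a more diverged same-species pair stays apart at threshold 0.99
  far <- base
  for (i in seq(10, 55, 10)) {
    old <- substr(far, i, i)
    substr(far, i, i) <- if (old == "L") "D" else "L"
  }
  recs2 <- Biostrings::AAStringSet(c(Aa_1 = base, Aa_2 = far))
  expect_length(collapseRedundant(recs2, 0.99), 2L)
  # ties by length resolved to lexicographically smallest id
  recs3 <- Biostrings::AAStringSet(c(Aa_z = base, Aa_b = base))
  expect_equal(names(collapseRedundant(recs3, 0.99)), "Aa_b")
})

test_that("BLAST tabular files round trip bit-compatibly", {
  tf <- tempfile(fileext = ".tsv")
  lines <- c(
    "q1\ts1\t98.50\t200\t3\t0\t1\t200\t10\t209\t1e-50\t380",
    "q1\ts2\t45.00\t120\t60\t2\t5\t124\t360\t1\t2e-08\t95.3")
  writeLines(lines, tf)
  tb <- readBlastTab(tf)
  expect_equal(tb$qstart, c(0L, 4L))
  expect_equal(tb$qend, c(200L, 124L))
  expect_equal(tb$frame, c(0L, -1L))
  expect_equal(tb$sstart, c(9L, 0L))
  tf2 <- tempfile(fileext = ".tsv")
  writeBlastTab(tb, tf2)
  expect_equal(readBlastTab(tf2), tb)
})
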