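# Independent oracles used across the suite: a hand-coded codon table,
# brute-force dynamic-programming aligners, exhaustive loss-set
# enumeration, and small fixture builders.  These never share code with
# the implementation paths they check.

# ---- codon table (hand-coded standard code) -------------------------------
.ORACLE_CODONS <- local({
  tab <- c(
    TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
    ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
    TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
    ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
    TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
    AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
    TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
    AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")
  stopifnot(length(tab) == 64)
  tab
})

oracle_revcomp <- function(nt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(nt, "")[[1]]]), collapse = "")
}

# brute-force translation of one frame by codon lookup
oracle_translate <- function(nt, frame) {
  if (frame < 0) nt <- oracle_revcomp(nt)
  k <- abs(frame)
  ch <- strsplit(nt, "")[[1]]
  ch <- ch[k:length(ch)]
  n_codon <- length(ch) %/% 3
  if (n_codon == 0) return("")
  out <- vapply(seq_len(n_codon), function(i) {
    cod <- paste(ch[(3 * i - 2):(3 * i)], collapse = "")
    if (grepl("N", cod)) "X" else .ORACLE_CODONS[[cod]]
  }, character(1))
  paste(out, collapse = "")
}

# ---- alignment oracles ----------------------------------------------------
.b62 <- local({
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# exhaustive local affine DP (gap run of L costs open + (L-1)*ext)
oracle_sw <- function(a, b, open = 11, ext = 1, SUB = .b62) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  best <- 0
  for (i in 1:n) for (j in 1:m) {
    s <- SUB[ca[i], cb[j]]
    M[i + 1, j + 1] <- s + max(0, M[i, j], X[i, j], Y[i, j])
    X[i + 1, j + 1] <- max(M[i, j + 1] - open, X[i, j + 1] - ext,
                           Y[i, j + 1] - open)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open, Y[i + 1, j] - ext,
                           X[i + 1, j] - open)
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

# exhaustive global affine DP score
oracle_global <- function(a, b, open = 11, ext = 1, SUB = .b62) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  if (n == 0 && m == 0) return(0)
  gapc <- function(L) if (L == 0) 0 else open + (L - 1) * ext
  if (n == 0) return(-gapc(m))
  if (m == 0) return(-gapc(n))
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 1:n) X[i + 1, 1] <- -gapc(i)
  for (j in 1:m) Y[1, j + 1] <- -gapc(j)
  for (i in 1:n) for (j in 1:m) {
    s <- SUB[ca[i], cb[j]]
    M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
    X[i + 1, j + 1] <- max(M[i, j + 1] - open, X[i, j + 1] - ext,
                           Y[i, j + 1] - open)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open, Y[i + 1, j] - ext,
                           X[i + 1, j] - open)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

rand_aa <- function(n) {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  paste(sample(aa, n, replace = TRUE), collapse = "")
}
rand_nt <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# ---- Dollo oracle ---------------------------------------------------------
# exhaustive minimal loss-set size over all branch subsets
oracle_dollo_min_losses <- function(registry, members) {
  gain <- lineageMRCA(registry, members)
  if (gain %in% speciesCodes(registry)) return(0L)
  complete <- genomeComplete(registry)
  below <- speciesInLineage(registry, gain)
  absent <- setdiff(intersect(below, complete), members)
  if (length(absent) == 0L) return(0L)
  # candidate branches: all nodes strictly below the gain that cover no
  # member; precompute each branch's informative (complete-genome) cover
  nodes <- unique(unlist(lapply(registry@paths, function(p) {
    i <- match(gain, p)
    if (is.na(i) || i == length(p)) NULL else p[(i + 1):length(p)]
  })))
  covers <- lapply(nodes, function(b) {
    spp <- speciesInLineage(registry, b)
    if (any(spp %in% members)) NULL else intersect(spp, complete)
  })
  keep <- !vapply(covers, is.null, logical(1)) & lengths(covers) > 0
  covers <- unique(covers[keep])
  for (k in 0:length(covers)) {
    combos <- utils::combn(length(covers), k, simplify = FALSE)
    for (cc in combos) {
      lost <- unique(unlist(covers[cc]))
      if (setequal(lost, absent)) return(k)
    }
  }
  stop("no valid loss set found")
}

# ---- misc fixtures --------------------------------------------------------
two_ref_registry <- function() {
  SpeciesRegistry(data.frame(
    species_code = c("At", "Os", "Pp", "Tr", "Sm", "Cr", "Vv"),
    full_name = c("arabidopsis", "rice", "moss1", "moss2", "spikemoss",
                  "chlamy", "grape"),
    lineage_path = c(
      "Viridiplantae;Streptophyta;Embryophyta;Tracheophyta;Angiosperms;Eudicots",
      "Viridiplantae;Streptophyta;Embryophyta;Tracheophyta;Angiosperms;Monocots",
      "Viridiplantae;Streptophyta;Embryophyta;Bryophyta",
      "Viridiplantae;Streptophyta;Embryophyta;Bryophyta",
      "Viridiplantae;Streptophyta;Embryophyta;Tracheophyta;Lycophyta",
      "Viridiplantae;Chlorophyta",
      "Viridiplantae;Streptophyta;Embryophyta;Tracheophyta;Angiosperms;Eudicots"),
    genome_complete = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)))
}

# orthogroup truth recomputed by an independent traversal that records,
# for every extant gene, its ancestor lineage at the reference cut
oracle_orthogroups <- function(sim, reference_node) {
  sp <- sim@speciesTree
  nt <- ape::Ntip(sp)
  v <- if (reference_node %in% sp$tip.label)
    match(reference_node, sp$tip.label)
  else nt + match(reference_node, sp$node.label)
  acc <- new.env(parent = emptyenv())
  walk <- function(node, anchor) {
    at_ref <- (node$type %in% c("spec", "leaf")) && node$snode == v
    if (at_ref && is.na(anchor)) anchor <- node$id
    if (node$type == "leaf") {
      if (!is.na(anchor)) {
        key <- as.character(anchor)
        assign(key, c(get0(key, envir = acc, ifnotfound = character(0)),
                      node$gene_id), envir = acc)
      }
      return(invisible(NULL))
    }
    for (k in node$kids) walk(k, anchor)
  }
  for (r in sim@roots) walk(r, NA_integer_)
  out <- as.list(acc)
  unname(lapply(out, sort))
}

# shared comparison: recovered PoGO partition equals truth
partitions_equal <- function(a, b) {
  setequal(lapply(a, sort), lapply(b, sort))
}

# one end-to-end recovery run; returns TRUE on exact partition match
run_recovery_family <- function(seed, n_boot = 100) {
  cfg <- simConfig(seed = seed)
  sim <- simulateFamily(cfg)
  prot <- simProteins(sim)
  og <- names(prot)[sub("_.*$", "", names(prot)) %in% c("OG1", "OG2")]
  aln <- progressiveMsa(prot)
  tr <- bootstrapSupport(aln, n_replicates = n_boot, seed = seed,
                         model = "pdist")
  rooted <- rootWithOutgroup(tr, og)
  pg <- callPogos(rooted, simRegistry(sim),
                  reference_species = c("A", "E"), outgroup_ids = og)
  partitions_equal(simOrthogroups(sim), pogoGroups(pg))
}
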