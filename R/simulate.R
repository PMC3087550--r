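# Gene-family simulator: duplication/loss birth-death process inside a
# species tree, codon-level sequence evolution, and fragmentary EST
# emission, with ground-truth orthogroup labels for end-to-end validation.
#
# Duplications and losses occur as Poisson processes along gene lineages
# (rates per branch-length unit of the species tree); every speciation
# copies each surviving lineage into both daughter species.  Sequences
# evolve at codon level - substitutions that would create an internal
# stop codon are redrawn - so that EST fragments and six-frame
# translation are exercised honestly.  Truth labels (the orthogroup
# partition relative to a reference ancestor) are derived from the gene
# tree only and are never visible to the pipeline under test.

.DEFAULT_SPECIES_TREE <- paste0(
  "((((A:0.2,B:0.2)N4:0.06,(C:0.2,D:0.2)N5:0.06)N2:0.06,",
  "((E:0.2,F:0.2)N6:0.06,(G:0.2,H:0.2)N7:0.06)N3:0.06)N1:0.08,",
  "(OG1:0.19,OG2:0.19)NOG:0.21)NROOT;")

.ensure_node_labels <- function(tree) {
  if (is.null(tree$node.label) || !all(nzchar(tree$node.label)))
    tree$node.label <- paste0("N", seq_len(tree$Nnode))
  tree
}

#' Simulation configuration
#'
#' Defaults describe the validation study conditions: an eight-species
#' ingroup plus a two-species outgroup on an ultrametric tree of depth
#' 0.4 time units, duplication rate 0.1 per unit, no loss, 400 codons and
#' a nucleotide substitution rate of 0.3 per site per unit (enough
#' divergence that true clades are well supported without saturating the
#' deepest pairs).
#'
#' @param species_tree Newick string or `phylo`; rooted, with branch
#'   lengths in time units.  Internal nodes are auto-labelled `N1...` if
#'   unnamed.
#' @param dup_rate,loss_rate Duplication / loss rates per unit.
#' @param root_copies Gene lineages entering at the species-tree root.
#' @param seq_length Ancestral sequence length in codons (>= 10).
#' @param subst_rate Nucleotide substitutions per site per unit.
#' @param indel_rate Whole-codon indel events per codon site per unit
#'   (default 0).
#' @param est_fraction Fraction of genes also emitted as EST fragments.
#' @param est_len Mean fragment length in codons (geometric tail).
#' @param est_error Per-base error rate of emitted fragments.
#' @param outgroup_species Tip labels forming the outgroup.
#' @param reference_node Species-tree node at which orthogroup truth is
#'   cut; default the MRCA of the non-outgroup species.
#' @param seed Integer seed; all simulator output is a pure function of
#'   (config, seed).
#' @return List of class `SimConfig`.
#' @export
simConfig <- function(species_tree = .DEFAULT_SPECIES_TREE,
                      dup_rate = 0.1, loss_rate = 0, root_copies = 1L,
                      seq_length = 400L, subst_rate = 0.3,
                      indel_rate = 0, est_fraction = 0.25,
                      est_len = 150, est_error = 0.005,
                      outgroup_species = c("OG1", "OG2"),
                      reference_node = NULL, seed = 1L) {
  if (is.character(species_tree))
    species_tree <- ape::read.tree(text = species_tree)
  stopifnot(inherits(species_tree, "phylo"),
            !is.null(species_tree$edge.length),
            dup_rate >= 0, loss_rate >= 0, root_copies >= 1,
            seq_length >= 10, subst_rate >= 0, indel_rate >= 0,
            est_fraction >= 0, est_fraction <= 1, est_len >= 1,
            est_error >= 0, est_error < 1)
  species_tree <- .ensure_node_labels(species_tree)
  structure(list(
    species_tree = species_tree, dup_rate = dup_rate,
    loss_rate = loss_rate, root_copies = as.integer(root_copies),
    seq_length = as.integer(seq_length), subst_rate = subst_rate,
    indel_rate = indel_rate, est_fraction = est_fraction,
    est_len = est_len, est_error = est_error,
    outgroup_species = outgroup_species,
    reference_node = reference_node, seed = as.integer(seed)
  ), class = "SimConfig")
}

#' GeneFamilySim: a simulated gene family with evolutionary truth
#'
#' @slot roots List of recursive gene-tree nodes (one per root lineage).
#' @slot speciesTree The species `phylo` (labelled internal nodes).
#' @slot genes data.frame of extant genes (`id`, `species`).
#' @slot phylo Collapsed gene tree as `phylo` (`NULL` if < 2 genes),
#'   branch lengths in time units, node labels `D`/`S` for
#'   duplication/speciation.
#' @slot orthogroups Named list: true orthogroup partition at the
#'   reference node.
#' @slot referenceNode Species-tree node of the truth cut.
#' @slot cds,proteins,ests Sequence sets (filled by [evolveSequences()] /
#'   [emitEstSet()]; `NULL` before).
#' @slot cfg The `SimConfig`.
#' @export
setClass("GeneFamilySim", representation(
  roots = "list", speciesTree = "ANY", genes = "data.frame",
  phylo = "ANY", orthogroups = "list", referenceNode = "character",
  cds = "ANY", proteins = "ANY", ests = "ANY", cfg = "list"))

setMethod("show", "GeneFamilySim", function(object) {
  cat("GeneFamilySim:", nrow(object@genes), "extant genes in",
      length(unique(object@genes$species)), "species;",
      length(object@orthogroups), "orthogroup(s) at",
      object@referenceNode, "\n")
})

#' GeneFamilySim accessors
#' @param x A [GeneFamilySim-class].
#' @rdname sim-accessors
#' @export
simGenes <- function(x) x@genes
#' @rdname sim-accessors
#' @export
simGeneTree <- function(x) x@phylo
#' @rdname sim-accessors
#' @export
simOrthogroups <- function(x) x@orthogroups
#' @rdname sim-accessors
#' @export
simProteins <- function(x) x@proteins
#' @rdname sim-accessors
#' @export
simCds <- function(x) x@cds
#' @rdname sim-accessors
#' @export
simEsts <- function(x) x@ests
#' @rdname sim-accessors
#' @export
simRegistry <- function(x) registryFromSpeciesTree(x@speciesTree)

# ---- gene tree ------------------------------------------------------------

#' Simulate a gene tree by birth-death within the species tree
#'
#' @param cfg A [simConfig()].
#' @return A [GeneFamilySim-class] skeleton (no sequences yet).  A family
#'   in which every lineage went extinct has zero genes and is flagged by
#'   `attr(, "empty")`.
#' @export
simulateGeneTree <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  sp <- cfg$species_tree
  nt <- ape::Ntip(sp)
  kids <- split(sp$edge[, 2], sp$edge[, 1])
  elen <- setNames(sp$edge.length, sp$edge[, 2])
  lam <- cfg$dup_rate; mu <- cfg$loss_rate
  node_id <- 0L
  new_node <- function(type, snode, blen, kids = list(),
                       species = NA_character_) {
    node_id <<- node_id + 1L
    list(id = node_id, type = type, snode = snode, blen = blen,
         kids = kids, species = species, gene_id = NA_character_)
  }
  lineage <- function(target, remaining, acc) {
    rate <- lam + mu
    repeat {
      dt <- if (rate > 0) rexp(1, rate) else Inf
      if (dt >= remaining) {
        # reach the end of the branch
        if (target <= nt)
          return(new_node("leaf", target, acc + remaining,
                          species = sp$tip.label[target]))
        return(speciate(target, acc + remaining))
      }
      acc <- acc + dt
      remaining <- remaining - dt
      if (runif(1) < lam / rate) {
        k1 <- lineage(target, remaining, 0)
        k2 <- lineage(target, remaining, 0)
        surv <- Filter(Negate(is.null), list(k1, k2))
        if (length(surv) == 0L) return(NULL)
        return(new_node("dup", target, acc, kids = surv))
      }
      return(NULL)  # loss
    }
  }
  speciate <- function(v, blen) {
    ks <- lapply(kids[[as.character(v)]], function(ch)
      lineage(ch, elen[[as.character(ch)]], 0))
    ks <- Filter(Negate(is.null), ks)
    if (length(ks) == 0L) return(NULL)
    new_node("spec", v, blen, kids = ks)
  }
  roots <- with_seed(cfg$seed, {
    r <- lapply(seq_len(cfg$root_copies), function(k) speciate(nt + 1L, 0))
    Filter(Negate(is.null), r)
  })
  # assign gene ids in traversal order, per-species counters
  counter <- new.env(parent = emptyenv())
  genes <- list()
  label <- function(node) {
    if (node$type == "leaf") {
      spc <- node$species
      k <- (get0(spc, envir = counter, ifnotfound = 0L)) + 1L
      assign(spc, k, envir = counter)
      node$gene_id <- paste0(spc, "_g", k)
      genes[[length(genes) + 1L]] <<- data.frame(
        id = node$gene_id, species = spc, stringsAsFactors = FALSE)
    } else {
      node$kids <- lapply(node$kids, label)
    }
    node
  }
  roots <- lapply(roots, label)
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(id = character(0), species = character(0))
  obj <- new("GeneFamilySim",
             roots = roots, speciesTree = sp, genes = genes,
             phylo = .gene_phylo(roots, sp), orthogroups = list(),
             referenceNode = NA_character_, cds = NULL, proteins = NULL,
             ests = NULL, cfg = unclass(cfg))
  ref <- cfg$reference_node
  if (is.null(ref)) {
    ingroup <- setdiff(sp$tip.label, cfg$outgroup_species)
    v <- if (length(ingroup) > 1L) ape::getMRCA(sp, ingroup) else nt + 1L
    ref <- sp$node.label[v - nt]
  }
  obj@referenceNode <- ref
  obj@orthogroups <- trueOrthogroups(obj, ref)
  attr(obj, "empty") <- nrow(genes) == 0L
  obj
}

# collapse unary chains and serialize the surviving topology as phylo
.gene_phylo <- function(roots, sp) {
  leaves <- 0L
  rec <- function(node, acc) {
    blen <- acc + node$blen
    if (node$type == "leaf") {
      leaves <<- leaves + 1L
      return(sprintf("%s:%.10g", node$gene_id, blen))
    }
    if (length(node$kids) == 1L) return(rec(node$kids[[1]], blen))
    lab <- if (node$type == "dup") "D" else "S"
    sprintf("(%s)%s:%.10g",
            paste(vapply(node$kids, rec, character(1), acc = 0),
                  collapse = ","), lab, blen)
  }
  if (length(roots) == 0L) return(NULL)
  frags <- vapply(roots, rec, character(1), acc = 0)
  if (leaves < 2L) return(NULL)
  txt <- if (length(frags) == 1L) paste0(sub(":[0-9.eE+-]+$", "", frags), ";")
         else paste0("(", paste(frags, collapse = ","), ")R;")
  ape::read.tree(text = txt)
}

#' True orthogroup partition at a reference ancestor
#'
#' Cuts the gene tree at the given species-tree node: every gene lineage
#' present in the ancestral species at that speciation defines one
#' orthogroup consisting of its extant descendants.
#'
#' @param sim A [GeneFamilySim-class].
#' @param reference_node Species-tree internal node label (or tip label).
#' @return Named list of gene-id vectors (`OG1`, `OG2`, ... in traversal
#'   order); genes not descending from the cut (e.g. outgroup genes) are
#'   not part of any group.
#' @export
trueOrthogroups <- function(sim, reference_node = NULL) {
  sp <- sim@speciesTree
  nt <- ape::Ntip(sp)
  if (is.null(reference_node)) reference_node <- sim@referenceNode
  v <- if (reference_node %in% sp$tip.label)
    match(reference_node, sp$tip.label)
  else nt + match(reference_node, sp$node.label)
  if (is.na(v))
    stop("reference node '", reference_node,
         "' not on the species tree", call. = FALSE)
  groups <- list()
  extant <- function(node) {
    if (node$type == "leaf") return(node$gene_id)
    unlist(lapply(node$kids, extant))
  }
  walk <- function(node) {
    if ((node$type == "spec" && node$snode == v) ||
        (node$type == "leaf" && node$snode == v)) {
      g <- extant(node)
      if (length(g)) groups[[length(groups) + 1L]] <<- g
      return(invisible(NULL))
    }
    if (node$type != "leaf") for (k in node$kids) walk(k)
    invisible(NULL)
  }
  for (r in sim@roots) walk(r)
  if (length(groups)) names(groups) <- paste0("OG", seq_along(groups))
  groups
}

# ---- sequences ------------------------------------------------------------

.sense_codons <- function() {
  if (is.null(.pogo_cache$SENSE)) {
    nts <- c("A", "C", "G", "T")
    all64 <- as.vector(outer(outer(nts, nts, paste0), nts, paste0))
    gc <- Biostrings::GENETIC_CODE
    .pogo_cache$SENSE <- all64[gc[all64] != "*"]
  }
  .pogo_cache$SENSE
}

.is_stop_codon <- function(codon) {
  Biostrings::GENETIC_CODE[[codon]] == "*"
}

# mutate a codon character vector along a branch of length blen
.mutate_seq <- function(codons, blen, subst_rate, indel_rate) {
  nts <- c("A", "C", "G", "T")
  L <- length(codons)
  if (L == 0L) return(codons)
  nsub <- rpois(1, subst_rate * blen * 3 * L)
  if (nsub > 0) {
    flat <- strsplit(paste(codons, collapse = ""), "")[[1]]
    for (k in seq_len(nsub)) {
      for (try in 1:10) {
        pos <- sample.int(length(flat), 1)
        old <- flat[pos]
        newb <- sample(setdiff(nts, old), 1)
        ci <- (pos - 1L) %/% 3L
        cod <- paste(flat[(3 * ci + 1):(3 * ci + 3)], collapse = "")
        newcod <- cod
        substr(newcod, ((pos - 1L) %% 3L) + 1L,
               ((pos - 1L) %% 3L) + 1L) <- newb
        if (!.is_stop_codon(newcod)) { flat[pos] <- newb; break }
      }
    }
    codons <- vapply(seq_len(L), function(i)
      paste(flat[(3 * i - 2):(3 * i)], collapse = ""), character(1))
  }
  if (indel_rate > 0) {
    nind <- rpois(1, indel_rate * blen * length(codons))
    for (k in seq_len(nind)) {
      if (length(codons) <= 10L) break
      if (runif(1) < 0.5) {
        codons <- codons[-sample.int(length(codons), 1)]
      } else {
        at <- sample.int(length(codons) + 1L, 1)
        codons <- append(codons, sample(.sense_codons(), 1), after = at - 1L)
      }
    }
  }
  codons
}

#' Evolve coding sequences over a simulated gene tree
#'
#' One ancestral codon sequence is drawn uniformly over sense codons;
#' nucleotide substitutions accumulate as a Poisson process along each
#' branch (silent and amino-acid-changing alike; substitutions creating
#' an internal stop are redrawn), plus optional whole-codon indels.
#' Proteins are the translations of the coding sequences.
#'
#' @param sim A [GeneFamilySim-class] from [simulateGeneTree()].
#' @return The object with `cds` and `proteins` filled.
#' @export
evolveSequences <- function(sim) {
  cfg <- sim@cfg
  with_seed(cfg$seed + 1000000L, {
    root_codons <- sample(.sense_codons(), cfg$seq_length, replace = TRUE)
    cds <- list()
    evolve <- function(node, codons) {
      codons <- .mutate_seq(codons, node$blen, cfg$subst_rate,
                            cfg$indel_rate)
      if (node$type == "leaf") {
        cds[[node$gene_id]] <<- paste(codons, collapse = "")
      } else for (k in node$kids) evolve(k, codons)
      invisible(NULL)
    }
    for (r in sim@roots) evolve(r, root_codons)
    if (length(cds)) {
      dna <- Biostrings::DNAStringSet(unlist(cds))
      sim@cds <- dna[sim@genes$id]
      prot <- Biostrings::translate(sim@cds, no.init.codon = TRUE)
      names(prot) <- names(sim@cds)
      sim@proteins <- prot
      S4Vectors::mcols(sim@proteins) <- S4Vectors::DataFrame(
        species = sim@genes$species[match(names(prot), sim@genes$id)],
        description = "", source = "genome")
    } else {
      sim@cds <- Biostrings::DNAStringSet()
      sim@proteins <- Biostrings::AAStringSet()
    }
  })
  sim
}

#' Emit fragmentary ESTs for a seeded subset of genes
#'
#' Each selected gene contributes one fragment: a contiguous codon window
#' with geometric-tailed length (mean `est_len` codons), random strand,
#' and per-base errors at rate `est_error`.  The source gene of each
#' fragment is recorded in `mcols()` for truth tracking only.
#'
#' @param sim A [GeneFamilySim-class] with sequences evolved.
#' @return The object with `ests` filled (`DNAStringSet`).
#' @export
emitEstSet <- function(sim) {
  cfg <- sim@cfg
  if (is.null(sim@cds)) stop("evolve sequences first", call. = FALSE)
  nts <- c("A", "C", "G", "T")
  # ESTs emulate the focal (ingroup) transcript databases; the outgroup
  # stands for reference sequences added separately, so it emits none
  ingroup <- !(sim@genes$species[match(names(sim@cds), sim@genes$id)]
               %in% cfg$outgroup_species)
  with_seed(cfg$seed + 2000000L, {
    frags <- character(0); src <- character(0); strand <- character(0)
    for (i in seq_along(sim@cds)) {
      if (!ingroup[i]) next
      if (runif(1) >= cfg$est_fraction) next
      gene <- names(sim@cds)[i]
      L <- Biostrings::nchar(sim@cds)[i] %/% 3L
      len <- min(L, 1L + rgeom(1, 1 / cfg$est_len))
      start <- sample.int(L - len + 1L, 1) - 1L
      nt <- substr(as.character(sim@cds[[i]]), 3 * start + 1L,
                   3 * (start + len))
      minus <- runif(1) < 0.5
      if (minus)
        nt <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(nt)))
      ch <- strsplit(nt, "")[[1]]
      err <- which(runif(length(ch)) < cfg$est_error)
      for (e in err) ch[e] <- sample(setdiff(nts, ch[e]), 1)
      frags <- c(frags, paste(ch, collapse = ""))
      src <- c(src, gene)
      strand <- c(strand, if (minus) "-" else "+")
    }
    ests <- Biostrings::DNAStringSet(frags)
    if (length(ests)) {
      sp <- sub("_.*$", "", src)
      names(ests) <- paste0(sp, "_est", seq_along(ests))
      S4Vectors::mcols(ests) <- S4Vectors::DataFrame(
        species = sp, description = "", source = "est",
        source_gene = src, strand = strand)
    }
    sim@ests <- ests
  })
  sim
}

#' Simulate a complete gene family
#'
#' Convenience wrapper: [simulateGeneTree()], [evolveSequences()] and
#' [emitEstSet()] in sequence.  Empty families (all lineages extinct) are
#' redrawn with consecutive seeds up to `max_redraw` times.
#'
#' @param cfg A [simConfig()].
#' @param max_redraw Redraw budget for empty families (default 10).
#' @return A [GeneFamilySim-class].
#' @export
simulateFamily <- function(cfg, max_redraw = 10L) {
  for (k in 0:max_redraw) {
    cfg_k <- cfg
    cfg_k$seed <- cfg$seed + k * 10000L
    class(cfg_k) <- "SimConfig"
    sim <- simulateGeneTree(cfg_k)
    if (!isTRUE(attr(sim, "empty"))) {
      sim <- evolveSequences(sim)
      sim <- emitEstSet(sim)
      return(sim)
    }
  }
  stop("all redraws produced empty families", call. = FALSE)
}

#' Write simulator outputs to a directory
#'
#' Emits one proteome FASTA per species, one EST FASTA, a species
#' manifest TSV (registry columns plus `fasta_path`), the event-labelled
#' truth gene tree (newick), the truth orthogroup partition (TSV) and a
#' config echo (YAML).  Truth files are separate from pipeline inputs so
#' recovery benchmarking stays honest.
#'
#' @param sim A [GeneFamilySim-class] with sequences.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimOutputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reg <- simRegistry(sim)
  tb <- registryTable(reg)
  tb$genome_complete <- ifelse(tb$genome_complete, "yes", "no")
  tb$fasta_path <- file.path(dir, paste0(tb$species_code, ".faa"))
  for (i in seq_len(nrow(tb))) {
    sel <- sim@proteins[sim@genes$species[
      match(names(sim@proteins), sim@genes$id)] == tb$species_code[i]]
    writeFasta(sel, tb$fasta_path[i])
  }
  utils::write.table(tb, file.path(dir, "species_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim@ests) && length(sim@ests))
    writeFasta(sim@ests, file.path(dir, "ests.fna"))
  if (!is.null(sim@phylo))
    writeNewick(sim@phylo, file.path(dir, "truth_gene_tree.nwk"))
  og <- sim@orthogroups
  if (length(og)) {
    df <- data.frame(orthogroup = rep(names(og), lengths(og)),
                     gene_id = unlist(og))
    utils::write.table(df, file.path(dir, "truth_orthogroups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- sim@cfg
  cfg$species_tree <- ape::write.tree(cfg$species_tree)
  yaml::write_yaml(cfg, file.path(dir, "config_echo.yaml"))
  invisible(dir)
}
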