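# Species registry with lineage annotation.
#
# The registry maps short species codes to full names, to a root-to-tip
# path of named lineage nodes (the reference phylogeny of plant lineages
# used by the ortholog-group criteria), and to a genome-completeness flag.
# Species with a complete predicted proteome may assert gene *absence*;
# EST-only species are evidence of presence but never of absence.
#
# The lineage paths jointly define a rooted lineage tree (polytomies
# allowed).  Every tree operation the package needs - MRCA, subtree
# species, children, ancestry - is derived from the paths.

#' @slot table data.frame with columns `species_code`, `full_name`,
#'   `lineage_path` (semicolon-delimited root-to-tip), `genome_complete`.
#' @slot paths named list: species code -> character vector of lineage
#'   nodes root-to-tip, terminated by the species code itself.
#' @rdname SpeciesRegistry
#' @export
setClass("SpeciesRegistry",
  representation(table = "data.frame", paths = "list"))

setValidity("SpeciesRegistry", function(object) {
  tb <- object@table
  need <- c("species_code", "full_name", "lineage_path", "genome_complete")
  if (!all(need %in% names(tb)))
    return(paste("missing column(s):",
                 paste(setdiff(need, names(tb)), collapse = ",")))
  if (anyDuplicated(tb$species_code))
    return("duplicate species codes")
  # paths must be prefix-consistent: each node has a single parent
  parent <- character(0)
  for (p in object@paths) {
    for (i in seq_along(p)) {
      par <- if (i == 1L) NA_character_ else p[i - 1L]
      if (p[i] %in% names(parent)) {
        if (!identical(parent[[p[i]]], par))
          return(paste0("lineage node '", p[i],
                        "' has conflicting parents"))
      } else parent[[p[i]]] <- par
    }
  }
  roots <- unique(vapply(object@paths, `[`, character(1), 1L))
  if (length(roots) != 1L) return("lineage paths have multiple roots")
  TRUE
})

#' Construct a species registry
#'
#' @param table data.frame with columns `species_code`, `full_name`,
#'   `lineage_path` (semicolon-delimited, root to tip, excluding the
#'   species itself) and `genome_complete` (logical).
#' @return A [SpeciesRegistry-class] object.
#' @examples
#' reg <- SpeciesRegistry(data.frame(
#'   species_code = c("At", "Os"),
#'   full_name = c("Arabidopsis thaliana", "Oryza sativa"),
#'   lineage_path = c("Viridiplantae;Angiosperms;Eudicots",
#'                    "Viridiplantae;Angiosperms;Monocots"),
#'   genome_complete = c(TRUE, TRUE)))
#' lineageMRCA(reg, c("At", "Os"))
#' @export
SpeciesRegistry <- function(table) {
  table$species_code <- as.character(table$species_code)
  table$lineage_path <- as.character(table$lineage_path)
  table$genome_complete <- as.logical(table$genome_complete)
  paths <- lapply(seq_len(nrow(table)), function(i)
    c(strsplit(table$lineage_path[i], ";", fixed = TRUE)[[1]],
      table$species_code[i]))
  names(paths) <- table$species_code
  new("SpeciesRegistry", table = table, paths = paths)
}

#' Read a species registry from a tab-separated manifest
#'
#' The manifest has columns `species_code`, `full_name`, `lineage_path`
#' (semicolon-delimited root-to-tip), `genome_complete` (`yes`/`no` or
#' logical) and optionally `fasta_path`.
#'
#' @param path Path to the TSV manifest.
#' @return A [SpeciesRegistry-class]; any `fasta_path` column is kept in
#'   `registryTable()`.
#' @export
readSpeciesRegistry <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (is.character(tb$genome_complete))
    tb$genome_complete <- tolower(tb$genome_complete) %in%
      c("yes", "true", "1")
  SpeciesRegistry(tb)
}

setMethod("show", "SpeciesRegistry", function(object) {
  tb <- object@table
  cat("SpeciesRegistry with", nrow(tb), "species (",
      sum(tb$genome_complete), "complete genomes )\n")
  cat("  codes:", paste(tb$species_code, collapse = " "), "\n")
  cat("  root lineage:", object@paths[[1]][1], "\n")
})

#' Registry accessors
#'
#' `speciesCodes()` returns all species codes; `genomeComplete()` the
#' codes of species with complete genomes (which may assert absence);
#' `registryTable()` the underlying data.frame; `lineageNodes()` all named
#' internal lineage nodes; `lineageRoot()` the root node name.
#'
#' @param registry A [SpeciesRegistry-class].
#' @return Character vectors (or a data.frame for `registryTable`).
#' @rdname registry-accessors
#' @export
speciesCodes <- function(registry) registry@table$species_code

#' @rdname registry-accessors
#' @export
genomeComplete <- function(registry)
  registry@table$species_code[registry@table$genome_complete]

#' @rdname registry-accessors
#' @export
registryTable <- function(registry) registry@table

#' @rdname registry-accessors
#' @export
lineageNodes <- function(registry)
  unique(unlist(lapply(registry@paths, function(p) p[-length(p)])))

#' @rdname registry-accessors
#' @export
lineageRoot <- function(registry) registry@paths[[1]][1]

.check_node <- function(registry, nodes) {
  known <- c(lineageNodes(registry), speciesCodes(registry))
  bad <- setdiff(nodes, known)
  if (length(bad))
    stop("unknown lineage node(s): ", paste(bad, collapse = ","),
         call. = FALSE)
  invisible(TRUE)
}

#' Species contained in the subtree of one or more lineage nodes
#'
#' @param registry A [SpeciesRegistry-class].
#' @param nodes Lineage node name(s) or species code(s); for a grade
#'   (e.g. the streptophyte algae), pass the set of nodes and the union of
#'   their subtrees is used.
#' @return Character vector of species codes.
#' @export
speciesInLineage <- function(registry, nodes) {
  .check_node(registry, nodes)
  keep <- vapply(registry@paths, function(p) any(nodes %in% p), logical(1))
  names(registry@paths)[keep]
}

#' Most recent common ancestor of a species set on the lineage tree
#'
#' @param registry A [SpeciesRegistry-class].
#' @param species Character vector of species codes (non-empty).
#' @return The name of the deepest lineage node whose subtree contains all
#'   the given species (the species code itself for a single species).
#' @export
lineageMRCA <- function(registry, species) {
  stopifnot(length(species) >= 1L)
  .check_node(registry, species)
  paths <- registry@paths[species]
  ref <- paths[[1]]
  k <- length(ref)
  for (p in paths[-1]) {
    m <- min(k, length(p))
    same <- which(ref[seq_len(m)] != p[seq_len(m)])
    k <- if (length(same)) same[1] - 1L else m
    if (k == 0L) stop("species share no lineage root", call. = FALSE)
  }
  ref[k]
}

#' Children of a lineage node
#'
#' @param registry A [SpeciesRegistry-class].
#' @param node A lineage node name.
#' @return Character vector of child node names (lineage nodes and/or
#'   species codes); empty for a species leaf.
#' @export
lineageChildren <- function(registry, node) {
  .check_node(registry, node)
  kids <- unlist(lapply(registry@paths, function(p) {
    i <- match(node, p)
    if (!is.na(i) && i < length(p)) p[i + 1L] else NULL
  }))
  unique(kids)
}

#' Is node `a` an ancestor of (or equal to) node `b`?
#' @noRd
.lineage_is_ancestor <- function(registry, a, b) {
  any(vapply(registry@paths, function(p) {
    ia <- match(a, p); ib <- match(b, p)
    !is.na(ia) && !is.na(ib) && ia <= ib
  }, logical(1)))
}

#' Build a registry from a species tree
#'
#' Convenience for simulated datasets: internal nodes of the (rooted)
#' species tree become lineage nodes named by their node labels (labels
#' `N1`, `N2`, ... are assigned where missing) and every leaf becomes a
#' species with the root-to-tip path of internal node names.
#'
#' @param tree A rooted `phylo` object.
#' @param genome_complete Logical vector (recycled) flagging which species
#'   carry complete genomes; default all `TRUE`.
#' @return A [SpeciesRegistry-class].
#' @export
registryFromSpeciesTree <- function(tree, genome_complete = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab) || !all(nzchar(lab)))
    lab <- paste0("N", seq_len(nn))
  paths <- character(nt)
  parent <- integer(nt + nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  for (i in seq_len(nt)) {
    p <- character(0)
    v <- i
    while (v != 0L) {
      if (v > nt) p <- c(lab[v - nt], p)
      v <- if (parent[v] > 0) parent[v] else 0L
    }
    paths[i] <- paste(p, collapse = ";")
  }
  SpeciesRegistry(data.frame(
    species_code = tree$tip.label,
    full_name = tree$tip.label,
    lineage_path = paths,
    genome_complete = rep_len(genome_complete, nt),
    stringsAsFactors = FALSE
  ))
}
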