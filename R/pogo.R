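# Delineation of Possible Groups of Orthologs (PoGOs) on a rooted,
# support-annotated gene tree.
#
# A clade is accepted as a PoGO when
#   (1) it is supported: bootstrap support strictly greater than
#       `min_support` (missing supports count as 0);
#   (2) it contains at least one gene from a reference species, or all of
#       its members fall within one proper lineage-tree node's subtree
#       and represent at least two distinct species (a lineage-restricted
#       group); and
#   (3) its internal structure is consistent with the known species
#       phylogeny (see checkSpeciesConsistency).
# Accepted clades are maximal: the shallowest passing node on each
# root-to-leaf path wins and its descendants are never separately
# accepted.  Leaves left outside every PoGO that form supported
# single-species clades become paralog groups; the rest stay unassigned.

#' PoGOSet: the result of ortholog-group delineation
#'
#' @slot groups Named list (`A`, `B`, ...) of member leaf-id vectors.
#' @slot support Integer vector of clade supports (NA for fixture sets
#'   built without a tree).
#' @slot origin Character vector: inferred lineage node of origin.
#' @slot lineageRestrictedTo Character vector: the restricting lineage
#'   node for groups accepted without a reference species, else `NA`.
#' @slot speciesSets Named list of member species-code vectors.
#' @slot paralogGroups List of member vectors of same-species groups.
#' @slot unassigned Character vector of leaf ids in no group.
#' @slot tree The rooted gene tree the groups were called on (or `NULL`).
#' @slot params List of calling parameters.
#' @export
setClass("PoGOSet", representation(
  groups = "list", support = "integer", origin = "character",
  lineageRestrictedTo = "character", speciesSets = "list",
  paralogGroups = "list", unassigned = "character",
  tree = "ANY", params = "list"))

setValidity("PoGOSet", function(object) {
  g <- object@groups
  if (length(g)) {
    all_members <- unlist(g)
    if (anyDuplicated(all_members))
      return("PoGOs are not pairwise disjoint")
    if (length(object@support) != length(g) ||
        length(object@origin) != length(g) ||
        length(object@speciesSets) != length(g))
      return("per-group vectors have inconsistent lengths")
  }
  TRUE
})

setMethod("show", "PoGOSet", function(object) {
  cat("PoGOSet:", length(object@groups), "PoGOs,",
      length(object@paralogGroups), "paralog group(s),",
      length(object@unassigned), "unassigned leaf/leaves\n")
  if (length(object@groups)) {
    df <- data.frame(
      pogo = names(object@groups),
      support = object@support,
      origin = object@origin,
      n_members = lengths(object@groups),
      n_species = lengths(object@speciesSets))
    print(df, row.names = FALSE)
  }
})

#' PoGOSet accessors
#'
#' @param x A [PoGOSet-class].
#' @return `pogoGroups()`: named list of member-id vectors;
#'   `pogoSupport()`: integer supports; `pogoOrigin()`: lineage node of
#'   origin per group; `pogoSpecies()`: named list of species sets;
#'   `paralogGroups()`: list of same-species groups;
#'   `unassignedLeaves()`: character vector.
#' @rdname pogo-accessors
#' @export
pogoGroups <- function(x) x@groups
#' @rdname pogo-accessors
#' @export
pogoSupport <- function(x) setNames(x@support, names(x@groups))
#' @rdname pogo-accessors
#' @export
pogoOrigin <- function(x) setNames(x@origin, names(x@groups))
#' @rdname pogo-accessors
#' @export
pogoSpecies <- function(x) x@speciesSets
#' @rdname pogo-accessors
#' @export
paralogGroups <- function(x) x@paralogGroups
#' @rdname pogo-accessors
#' @export
unassignedLeaves <- function(x) x@unassigned

.group_letters <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  c(LETTERS, paste0(rep(LETTERS, each = 26), LETTERS))[seq_len(n)]
}

#' Build a PoGOSet from explicit species-level memberships
#'
#' Used for encoded published group tables and for simulator truth:
#' members may be species codes (one pseudo-member per species) or
#' namespaced gene ids.
#'
#' @param groups Named list of member vectors (PoGOs).
#' @param registry A [SpeciesRegistry-class].
#' @param paralog_groups Optional list of paralog-group member vectors.
#' @param support Optional integer supports (default `NA`).
#' @param species_map Optional named vector mapping member id to species
#'   code; by default the prefix before the first underscore (or the id
#'   itself if it is a known species code).
#' @return A [PoGOSet-class].
#' @export
pogoSetFromMembership <- function(groups, registry,
                                  paralog_groups = list(),
                                  support = NA_integer_,
                                  species_map = NULL) {
  to_species <- function(ids) {
    if (!is.null(species_map)) return(unique(unname(species_map[ids])))
    sp <- ifelse(ids %in% speciesCodes(registry), ids,
                 sub("_.*$", "", ids))
    unique(sp)
  }
  spsets <- lapply(groups, to_species)
  # species-level membership tables reuse species codes across groups;
  # namespace the pseudo-members per group to keep ids disjoint
  if (anyDuplicated(unlist(groups)))
    groups <- lapply(seq_along(groups), function(k)
      paste0(names(groups)[k], ":", groups[[k]])) |>
      stats::setNames(names(groups))
  origin <- vapply(spsets, function(s) lineageMRCA(registry, s),
                   character(1))
  new("PoGOSet",
      groups = groups,
      support = rep_len(as.integer(support), length(groups)),
      origin = unname(origin),
      lineageRestrictedTo = rep(NA_character_, length(groups)),
      speciesSets = spsets,
      paralogGroups = paralog_groups,
      unassigned = character(0),
      tree = NULL, params = list())
}

# ---- species-tree compatibility -------------------------------------------

# Can the species set C form a clade in (a resolution of) the lineage
# tree restricted to the species set S?  Polytomy-aware: every child
# subtree of MRCA(C) must be fully inside or fully outside C.
.potential_clade <- function(registry, C, S) {
  if (length(C) <= 1L) return(TRUE)
  v <- lineageMRCA(registry, C)
  for (ch in lineageChildren(registry, v)) {
    spc <- intersect(speciesInLineage(registry, ch), S)
    if (length(spc) == 0L) next
    inside <- spc %in% C
    if (any(inside) && !all(inside)) return(FALSE)
  }
  TRUE
}

#' Is a species bipartition compatible with the lineage tree?
#'
#' `A | B` is compatible iff, on the lineage tree restricted to
#' `A` and `B`'s species, either side can form a clade once polytomies
#' are resolved.
#'
#' @param registry A [SpeciesRegistry-class].
#' @param A,B Disjoint species-code sets.
#' @return Logical.
#' @export
splitCompatible <- function(registry, A, B) {
  S <- union(A, B)
  .potential_clade(registry, A, S) || .potential_clade(registry, B, S)
}

# supports as numbers; missing/empty labels -> 0
.node_support <- function(tree) {
  lab <- tree$node.label
  if (is.null(lab)) return(rep(0, tree$Nnode))
  s <- suppressWarnings(as.numeric(lab))
  s[is.na(s)] <- 0
  s
}

#' Check a clade's consistency with the species phylogeny
#'
#' Operationalizes the by-eye judgement that a candidate ortholog group
#' must not contradict the known phylogeny of the species:
#' \enumerate{
#'   \item copy-number sanity: no species contributes more than
#'     `max_copies` leaves to the clade (within-group tandem paralogy is
#'     common, a species represented many times indicates a super-group);
#'   \item supported-edge test: every internal edge of the clade with
#'     support strictly above `conflict_support` splits the clade's
#'     species into two sets; if the two sides share two or more species
#'     the edge implies a duplication ancestral to several species and
#'     the clade spans more than one ortholog group; if the sides are
#'     disjoint the implied species bipartition must be compatible with
#'     the lineage tree (hard polytomies resolve freely).  A single
#'     shared species (a tandem paralog pair straddling the edge) is
#'     tolerated, as are conflicts on weakly supported edges.
#' }
#'
#' @param tree Rooted `phylo` gene (sub)tree.
#' @param node Internal node number of the clade to test (default: root).
#' @param registry A [SpeciesRegistry-class].
#' @param conflict_support Edges at or below this support are ignored
#'   (default 50).
#' @param max_copies Maximum leaves per species within one group
#'   (default 3).
#' @param species_map Optional named vector leaf id -> species code.
#' @return Logical.
#' @export
checkSpeciesConsistency <- function(tree, node = NULL, registry,
                                    conflict_support = 50,
                                    max_copies = 3L,
                                    species_map = NULL) {
  nt <- ape::Ntip(tree)
  if (is.null(node)) node <- nt + 1L
  tips <- .tips_under(tree, node)
  sm <- .leaf_species(tree, registry, species_map,
                      check_tips = tree$tip.label[tips])
  spp <- sm[tree$tip.label[tips]]
  if (any(table(spp) > max_copies)) return(FALSE)
  if (node <= nt) return(TRUE)
  supp <- .node_support(tree)
  desc_int <- setdiff(.nodes_under(tree, node), c(tips, node))
  clade_leaves <- tree$tip.label[tips]
  for (v in desc_int) {
    if (supp[v - nt] <= conflict_support) next
    inside <- tree$tip.label[.tips_under(tree, v)]
    Sx <- unique(sm[inside])
    Sy <- unique(sm[setdiff(clade_leaves, inside)])
    ov <- intersect(Sx, Sy)
    if (length(ov) >= 2L) return(FALSE)
    A <- setdiff(Sx, Sy); B <- setdiff(Sy, Sx)
    if (length(A) && length(B) && !splitCompatible(registry, A, B))
      return(FALSE)
  }
  TRUE
}

# all node numbers (tips + internals) in the subtree of `node`
.nodes_under <- function(tree, node) {
  nt <- ape::Ntip(tree)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    out <- c(out, v)
    if (v > nt) stack <- c(stack, kids[[as.character(v)]])
  }
  out
}

.leaf_species <- function(tree, registry, species_map = NULL,
                          check_tips = tree$tip.label) {
  if (!is.null(species_map)) {
    sm <- species_map[tree$tip.label]
    names(sm) <- tree$tip.label
  } else {
    sm <- sub("_.*$", "", tree$tip.label)
    names(sm) <- tree$tip.label
  }
  bad <- setdiff(unique(unname(sm[check_tips])), speciesCodes(registry))
  if (length(bad))
    stop("species missing from registry: ", paste(bad, collapse = ","),
         call. = FALSE)
  sm
}

#' Infer a group's lineage of origin
#'
#' The most recent common ancestor, on the lineage tree, of all member
#' species.
#'
#' @param species Character vector of member species codes (or a
#'   [PoGOSet-class], in which case all groups are processed).
#' @param registry A [SpeciesRegistry-class].
#' @return Lineage node name(s).
#' @export
inferOrigin <- function(species, registry) {
  if (is(species, "PoGOSet"))
    return(vapply(species@speciesSets, function(s)
      lineageMRCA(registry, s), character(1)))
  lineageMRCA(registry, species)
}

#' Call possible groups of orthologs on a rooted gene tree
#'
#' Pre-order scan applying the three acceptance criteria (support,
#' reference-species or lineage-restricted membership, species-phylogeny
#' consistency); accepted clades are maximal.  Outgroup leaves are
#' excluded from grouping.  Remaining leaves that form supported
#' single-species clades become paralog groups; the rest are unassigned.
#'
#' @param tree Rooted `phylo` with supports in `node.label`.
#' @param registry A [SpeciesRegistry-class] covering every leaf species.
#' @param reference_species Species whose presence anchors a PoGO
#'   (default `c("At", "Os")`).
#' @param min_support Support must be strictly greater (default 50).
#' @param conflict_support Consistency-test threshold (default 50).
#' @param max_copies Copy-number sanity bound (default 3).
#' @param outgroup_ids Leaf ids excluded from grouping.
#' @param species_map Optional named vector leaf id -> species code
#'   (default: prefix before the first underscore).
#' @return A [PoGOSet-class].
#' @examples
#' reg <- SpeciesRegistry(data.frame(
#'   species_code = c("At", "Os"),
#'   full_name = c("Arabidopsis", "rice"),
#'   lineage_path = c("Viridiplantae;Angiosperms;Eudicots",
#'                    "Viridiplantae;Angiosperms;Monocots"),
#'   genome_complete = TRUE))
#' tr <- readNewick("((At_1:0.1,Os_1:0.1)90:0.1,(At_2:0.1,Os_2:0.1)85:0.1)99;")
#' callPogos(tr, reg)
#' @export
callPogos <- function(tree, registry, reference_species = c("At", "Os"),
                      min_support = 50, conflict_support = 50,
                      max_copies = 3L, outgroup_ids = character(0),
                      species_map = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree))
    stop("gene tree must be rooted (use rootWithOutgroup)", call. = FALSE)
  nt <- ape::Ntip(tree)
  og <- intersect(outgroup_ids, tree$tip.label)
  sm <- .leaf_species(tree, registry, species_map,
                      check_tips = setdiff(tree$tip.label, og))
  supp <- .node_support(tree)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  root_lineage <- lineageRoot(registry)

  passes <- function(v) {
    tips <- tree$tip.label[.tips_under(tree, v)]
    spp <- unique(unname(sm[tips]))
    if (supp[v - nt] <= min_support) return(NULL)
    restricted <- NA_character_
    if (!any(spp %in% reference_species)) {
      mrca <- lineageMRCA(registry, spp)
      if (length(spp) < 2L || mrca == root_lineage) return(NULL)
      restricted <- mrca
    }
    if (!checkSpeciesConsistency(tree, v, registry,
                                 conflict_support = conflict_support,
                                 max_copies = max_copies,
                                 species_map = sm)) return(NULL)
    list(members = tips, species = spp, support = supp[v - nt],
         restricted = restricted)
  }

  groups <- list(); gsupport <- integer(0); grestrict <- character(0)
  scan <- function(v) {
    if (v <= nt) return(invisible(NULL))
    tips <- tree$tip.label[.tips_under(tree, v)]
    if (any(tips %in% og)) {
      for (ch in kids[[as.character(v)]]) scan(ch)
      return(invisible(NULL))
    }
    hit <- passes(v)
    if (!is.null(hit)) {
      groups[[length(groups) + 1L]] <<- hit$members
      gsupport <<- c(gsupport, as.integer(hit$support))
      grestrict <<- c(grestrict, hit$restricted)
    } else {
      for (ch in kids[[as.character(v)]]) scan(ch)
    }
    invisible(NULL)
  }
  scan(nt + 1L)

  assigned <- unlist(groups)
  # paralog groups: maximal supported single-species clades among the rest
  paralogs <- list()
  pscan <- function(v) {
    if (v <= nt) return(invisible(NULL))
    tips <- tree$tip.label[.tips_under(tree, v)]
    free <- setdiff(tips, c(assigned, og))
    if (!setequal(tips, free)) {
      for (ch in kids[[as.character(v)]]) pscan(ch)
      return(invisible(NULL))
    }
    spp <- unique(unname(sm[tips]))
    if (length(spp) == 1L && supp[v - nt] > min_support) {
      paralogs[[length(paralogs) + 1L]] <<- tips
    } else {
      for (ch in kids[[as.character(v)]]) pscan(ch)
    }
    invisible(NULL)
  }
  pscan(nt + 1L)

  unassigned <- setdiff(tree$tip.label, c(assigned, unlist(paralogs), og))
  ids <- .group_letters(length(groups))
  names(groups) <- ids
  spsets <- lapply(groups, function(m) unique(unname(sm[m])))
  origin <- vapply(spsets, function(s) lineageMRCA(registry, s),
                   character(1))
  new("PoGOSet",
      groups = groups, support = gsupport, origin = unname(origin),
      lineageRestrictedTo = grestrict, speciesSets = spsets,
      paralogGroups = paralogs, unassigned = unassigned,
      tree = tree,
      params = list(reference_species = reference_species,
                    min_support = min_support,
                    conflict_support = conflict_support,
                    max_copies = max_copies,
                    outgroup_ids = outgroup_ids))
}

#' Write a PoGO report as TSV
#'
#' Columns: `pogo_id`, `support`, `origin`, `n_members`, `species`
#' (comma-separated), `members` (comma-separated).
#'
#' @param pogos A [PoGOSet-class].
#' @param path Output path.
#' @return The report data.frame, invisibly.
#' @export
writePogoReport <- function(pogos, path) {
  df <- data.frame(
    pogo_id = names(pogos@groups),
    support = pogos@support,
    origin = pogos@origin,
    n_members = lengths(pogos@groups),
    species = vapply(pogos@speciesSets, paste, character(1),
                     collapse = ","),
    members = vapply(pogos@groups, paste, character(1), collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}
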