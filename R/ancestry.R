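# From a PoGO set to evolutionary statements: founder-gene counts along
# the lineage ladder and Dollo-parsimony gain/loss events.
#
# A PoGO shared between lineages stands for one founder gene in their
# common ancestor.  Two counting modes are reported side by side, because
# published founder arithmetic mixes them:
#   founder_count(node): PoGOs with at least one member species inside
#     the node's subtree (containment);
#   shared_count(node): PoGOs with member species both inside and outside
#     the node's subtree.
# Gene absence is assertable only for species with complete genomes;
# EST-only species are uninformative for loss inference.

#' Number of PoGOs represented within a lineage
#'
#' Counts PoGOs having at least one member species inside the subtree of
#' the given lineage node; for a grade, pass several nodes and the union
#' of their subtrees is used.  Paralog groups are never counted.
#'
#' @param pogos A [PoGOSet-class].
#' @param registry A [SpeciesRegistry-class].
#' @param nodes Lineage node name(s) (or species codes).
#' @return Integer count.
#' @export
pogosContaining <- function(pogos, registry, nodes) {
  inside <- speciesInLineage(registry, nodes)
  sum(vapply(pogos@speciesSets, function(s) any(s %in% inside),
             logical(1)))
}

#' Dollo gain and minimal loss set for one ortholog group
#'
#' The gain is placed at the MRCA (on the lineage tree) of the member
#' species; losses are the minimal set of branches below the gain whose
#' removal explains every absence.  A species counts as absent only if
#' its genome is complete and it is not a member; EST-only species are
#' uninformative.  The minimal loss set is the antichain of maximal
#' branches whose subtrees contain no member but at least one
#' complete-genome species.
#'
#' @param species Member species codes of the group (or a
#'   [PoGOSet-class] plus `pogo_id`).
#' @param registry A [SpeciesRegistry-class].
#' @param pogo_id When `species` is a `PoGOSet`, the group to analyse.
#' @return List with `gain` (lineage node), `losses` (character vector of
#'   branch names, each branch named by its child node) and `n_losses`.
#' @examples
#' # a group present in moss, lycophyte and eudicots but lost in monocots
#' # yields one loss on the monocot stem
#' @export
dolloGainLoss <- function(species, registry, pogo_id = NULL) {
  if (is(species, "PoGOSet")) {
    stopifnot(!is.null(pogo_id))
    species <- species@speciesSets[[pogo_id]]
  }
  stopifnot(length(species) >= 1L)
  gain <- lineageMRCA(registry, species)
  complete <- genomeComplete(registry)
  losses <- character(0)
  recurse <- function(node) {
    spp <- speciesInLineage(registry, node)
    if (any(spp %in% species)) {
      for (ch in lineageChildren(registry, node)) recurse(ch)
    } else if (any(spp %in% complete)) {
      losses[[length(losses) + 1L]] <<- node
    } # else: EST-only subtree, uninformative
    invisible(NULL)
  }
  if (gain %in% speciesCodes(registry)) {
    return(list(gain = gain, losses = character(0), n_losses = 0L))
  }
  for (ch in lineageChildren(registry, gain)) recurse(ch)
  # round-trip invariant: replaying gain + losses must reproduce the
  # observed presence/absence over complete genomes
  below <- speciesInLineage(registry, gain)
  lost <- unique(unlist(lapply(losses, function(b)
    speciesInLineage(registry, b))))
  replay <- setdiff(intersect(below, complete), lost)
  observed <- intersect(species, complete)
  if (!setequal(replay, observed))
    stop("internal error: Dollo replay does not reproduce observations",
         call. = FALSE)
  list(gain = gain, losses = unlist(losses), n_losses = length(losses))
}

#' Founder-gene profile along a lineage ladder
#'
#' For each focal lineage node (ordered root to tip), reports the
#' containment count (`founder_count`), the shared count
#' (`shared_count`) and the ids of the counted PoGOs.
#'
#' @param pogos A [PoGOSet-class].
#' @param registry A [SpeciesRegistry-class].
#' @param focal_nodes Character vector of lineage nodes (a node may be a
#'   list entry of several nodes to express a grade).
#' @return data.frame with one row per focal node.
#' @export
founderProfile <- function(pogos, registry, focal_nodes) {
  if (!is.list(focal_nodes)) focal_nodes <- as.list(focal_nodes)
  labels <- vapply(focal_nodes, paste, character(1), collapse = "+")
  rows <- lapply(seq_along(focal_nodes), function(k) {
    inside <- speciesInLineage(registry, focal_nodes[[k]])
    has_in <- vapply(pogos@speciesSets, function(s) any(s %in% inside),
                     logical(1))
    has_out <- vapply(pogos@speciesSets, function(s)
      any(!(s %in% inside)), logical(1))
    data.frame(
      node = labels[k],
      founder_count = sum(has_in),
      shared_count = sum(has_in & has_out),
      pogo_ids = paste(names(pogos@groups)[has_in], collapse = ","),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write founder and event reports as TSV
#'
#' @param pogos A [PoGOSet-class].
#' @param registry A [SpeciesRegistry-class].
#' @param focal_nodes Ladder of lineage nodes for [founderProfile()].
#' @param founders_path,events_path Output paths (either may be `NULL`).
#' @return List with the two data.frames, invisibly.
#' @export
writeAncestryReports <- function(pogos, registry, focal_nodes,
                                 founders_path = NULL,
                                 events_path = NULL) {
  prof <- founderProfile(pogos, registry, focal_nodes)
  ev <- do.call(rbind, lapply(names(pogos@groups), function(id) {
    gl <- dolloGainLoss(pogos, registry, pogo_id = id)
    data.frame(pogo_id = id, gain_node = gl$gain,
               loss_branches = paste(gl$losses, collapse = ","),
               n_losses = gl$n_losses, stringsAsFactors = FALSE)
  }))
  if (!is.null(founders_path))
    utils::write.table(prof, founders_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(ev) && !is.null(events_path))
    utils::write.table(ev, events_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(list(founders = prof, events = ev))
}
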