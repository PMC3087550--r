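# Shipped worked example: the green-plant XTH family.
#
# The package ships, as plain TSV, the species registry and the published
# species-level memberships of the 21 XTH possible groups of orthologs
# (plus the bryophyte paralog group K).  They serve as the worked example
# for the ancestry module: founder counts along the lineage ladder
# (streptophyte algae, early tracheophytes, angiosperms), the number of
# ancestral embryophyte genes in homolog group I, and monocot-specific
# loss inference are all recomputed from these tables.

#' Species registry of the XTH worked example
#'
#' Eighteen green-plant species: twelve with complete genomes and six
#' EST-only species (which can attest presence but never absence), with
#' their lineage paths on the reference plant phylogeny.  The two
#' streptophyte algae classes (Charophyceae, Zygnemophyceae) are modelled
#' as a grade directly under Streptophyta.
#'
#' @return A [SpeciesRegistry-class].
#' @examples
#' reg <- xthSpeciesRegistry()
#' speciesInLineage(reg, "Bryophyta")
#' @export
xthSpeciesRegistry <- function() {
  readSpeciesRegistry(system.file("extdata", "xth_species_registry.tsv",
                                  package = "PoGOfam", mustWork = TRUE))
}

#' XTH ortholog groups of the worked example
#'
#' Species-level memberships of the 21 XTH PoGOs (U, V, A-J, L-T) and the
#' bryophyte paralog group K.  Group V is homolog group II; all others
#' form homolog group I.
#'
#' @return A [PoGOSet-class]; the homolog group of each PoGO is kept in
#'   the attribute `homolog_group`.
#' @examples
#' pogos <- xthPogoFixture()
#' reg <- xthSpeciesRegistry()
#' pogosContaining(pogos, reg, c("Charophyceae", "Zygnemophyceae"))  # 2
#' @export
xthPogoFixture <- function() {
  tb <- utils::read.table(
    system.file("extdata", "xth_pogos.tsv", package = "PoGOfam",
                mustWork = TRUE),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  reg <- xthSpeciesRegistry()
  members <- strsplit(tb$species, ",", fixed = TRUE)
  is_par <- tolower(tb$is_paralog_group) %in% c("yes", "true", "1")
  groups <- members[!is_par]
  names(groups) <- tb$pogo_id[!is_par]
  out <- pogoSetFromMembership(groups, reg,
                               paralog_groups = members[is_par])
  attr(out, "homolog_group") <- setNames(tb$homolog_group[!is_par],
                                         tb$pogo_id[!is_par])
  out
}

#' The lineage ladder of the XTH worked example
#'
#' The ordered series of focal lineages used for founder counting:
#' streptophyte algae (a grade of two nodes), Bryophyta (early
#' embryophytes), Lycophyta (early tracheophytes) and Angiosperms.
#'
#' @return Named list of lineage node sets.
#' @export
xthLineageLadder <- function() {
  list(
    streptophyte_algae = c("Charophyceae", "Zygnemophyceae"),
    early_embryophytes = "Bryophyta",
    early_tracheophytes = "Lycophyta",
    angiosperms = "Angiosperms"
  )
}
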