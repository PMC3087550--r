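# Bootstrap support, outgroup rooting and newick I/O.
#
# Supports are attached to the bipartitions of the full-data tree (not a
# consensus): each internal edge is scored by the percentage of replicate
# trees containing the same bipartition, rounded to the nearest integer.

# non-trivial bipartitions of an unrooted tree as canonical keys
# (the side not containing the lexicographically smallest taxon, sorted)
.tree_splits <- function(tree) {
  nt <- ape::Ntip(tree)
  ref <- sort(tree$tip.label)[1]
  pp <- ape::prop.part(tree)
  keys <- character(0)
  nodes <- integer(0)
  for (k in seq_along(pp)) {
    side <- tree$tip.label[pp[[k]]]
    other <- setdiff(tree$tip.label, side)
    if (length(side) < 2L || length(other) < 2L) next
    use <- if (ref %in% side) other else side
    keys <- c(keys, paste(sort(use), collapse = "\r"))
    nodes <- c(nodes, nt + k)
  }
  list(keys = keys, nodes = nodes)
}

#' Neighbor-joining tree with nonparametric bootstrap supports
#'
#' Alignment columns are resampled with replacement per replicate using a
#' seeded generator; the tree built from the full data is annotated, on
#' each internal edge, with the percentage of replicate trees containing
#' the same bipartition (rounded to the nearest integer).  The same seed
#' always yields the identical annotated tree.  A replicate in which a
#' distance saturates is re-drawn (the count of re-draws is attached as
#' attribute `bootstrap_redraws`).  Internal edges of length zero carry no
#' distance signal and are reported with support 0.
#'
#' @param aln Aligned `AAStringSet` with at least 4 rows.
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the resampling generator.
#' @param model Distance model, `"pdist"` or `"pam001"`.
#' @param builder Tree building function taking a distance matrix
#'   (default [neighborJoining()]).
#' @return The full-data `phylo` tree with integer supports in
#'   `node.label` (root label empty).
#' @export
bootstrapSupport <- function(aln, n_replicates = 1000L, seed = 1L,
                             model = c("pdist", "pam001"),
                             builder = neighborJoining) {
  model <- match.arg(model)
  rows <- .aln_rows(aln)
  if (length(rows) < 4L)
    stop("bootstrap needs an alignment of at least 4 rows", call. = FALSE)
  L <- unique(nchar(rows))
  stopifnot(length(L) == 1L)
  full <- builder(distanceMatrix(Biostrings::AAStringSet(rows), model))
  sp <- .tree_splits(full)
  counts <- setNames(numeric(length(sp$keys)), sp$keys)
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  rownames(mat) <- names(rows)
  redraws <- 0L
  with_seed(seed, {
    done <- 0L
    while (done < n_replicates) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_aln <- Biostrings::AAStringSet(
        apply(mat[, cols, drop = FALSE], 1, paste, collapse = ""))
      names(rep_aln) <- rownames(mat)
      tr <- tryCatch(builder(distanceMatrix(rep_aln, model)),
                     error = function(e) NULL)
      if (is.null(tr)) {
        redraws <- redraws + 1L
        if (redraws > 100L + 10L * n_replicates)
          stop("bootstrap: too many saturated replicates", call. = FALSE)
        next
      }
      ks <- .tree_splits(tr)$keys
      hit <- intersect(ks, sp$keys)
      counts[hit] <- counts[hit] + 1
      done <- done + 1L
    }
  })
  supp <- round(100 * counts / n_replicates)
  nt <- ape::Ntip(full)
  lab <- rep("", full$Nnode)
  lab[sp$nodes - nt] <- as.character(as.integer(supp))
  # zero-length internal edges: no signal, report 0
  for (k in seq_along(sp$nodes)) {
    e <- which(full$edge[, 2] == sp$nodes[k])
    if (length(e) == 1L && full$edge.length[e] < 1e-12)
      lab[sp$nodes[k] - nt] <- "0"
  }
  full$node.label <- lab
  attr(full, "bootstrap_redraws") <- redraws
  full
}

#' Root a gene tree on its outgroup
#'
#' Places the root on the edge separating a monophyletic outgroup from
#' the ingroup; support labels follow their edges.  A non-monophyletic
#' outgroup is an error naming the conflicting (intruding) leaves.
#'
#' @param tree An unrooted (or arbitrarily rooted) `phylo`.
#' @param outgroup_ids Leaf labels of the outgroup (non-empty, proper
#'   subset of the leaves).
#' @return A rooted `phylo` with the outgroup as one child of the root.
#' @export
rootWithOutgroup <- function(tree, outgroup_ids) {
  stopifnot(inherits(tree, "phylo"), length(outgroup_ids) >= 1L)
  missing <- setdiff(outgroup_ids, tree$tip.label)
  if (length(missing))
    stop("outgroup leaves absent from tree: ",
         paste(missing, collapse = ","), call. = FALSE)
  ingroup <- setdiff(tree$tip.label, outgroup_ids)
  if (length(ingroup) == 0L)
    stop("outgroup covers the whole tree", call. = FALSE)
  if (length(outgroup_ids) > 1L) {
    # check monophyly by rooting at an ingroup leaf
    tmp <- ape::root(tree, outgroup = ingroup[1], resolve.root = TRUE)
    mrca <- ape::getMRCA(tmp, outgroup_ids)
    desc <- tmp$tip.label[.tips_under(tmp, mrca)]
    intruders <- setdiff(desc, outgroup_ids)
    if (length(intruders))
      stop("outgroup is not monophyletic; conflicting leaves: ",
           paste(sort(intruders), collapse = ","), call. = FALSE)
  }
  rooted <- ape::root(tree, outgroup = outgroup_ids,
                      resolve.root = TRUE, edgelabel = TRUE)
  rooted
}

# tip indices under a node (the node itself if a tip)
.tips_under <- function(tree, node) {
  nt <- ape::Ntip(tree)
  if (node <= nt) return(node)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= nt) out <- c(out, v)
    else stack <- c(stack, kids[[as.character(v)]])
  }
  out
}

#' Read a newick tree
#'
#' Internal node labels are interpreted as integer bootstrap supports
#' where numeric.  Unbalanced parentheses raise a parse error reporting
#' the offending character position.
#'
#' @param path Path to a newick file, or a literal newick string
#'   (detected by a terminating `;`).
#' @return A `phylo` object.
#' @export
readNewick <- function(path) {
  text <- if (grepl(";", path, fixed = TRUE)) path
          else paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("newick parse error: unbalanced ')' at position ", i,
           call. = FALSE)
  }
  if (depth != 0L)
    stop("newick parse error: ", depth, " unclosed '(' at end of input",
         call. = FALSE)
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("newick parse error", call. = FALSE)
  tr
}

# recursive canonical serializer: children ordered by smallest
# descendant leaf label
.newick_string <- function(tree, canonical = TRUE, digits = 12) {
  nt <- ape::Ntip(tree)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  elen <- tree$edge.length
  eidx <- seq_len(nrow(tree$edge))
  edge_of <- integer(nt + tree$Nnode)
  edge_of[tree$edge[, 2]] <- eidx
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  minlab <- function(v) {
    tl <- tree$tip.label[.tips_under(tree, v)]
    sort(tl)[1]
  }
  rec <- function(v) {
    if (v <= nt) s <- tree$tip.label[v]
    else {
      ch <- kids[[as.character(v)]]
      if (canonical) ch <- ch[order(vapply(ch, minlab, character(1)))]
      lab <- if (!is.null(tree$node.label)) tree$node.label[v - nt] else ""
      if (is.na(lab)) lab <- ""
      s <- paste0("(", paste(vapply(ch, rec, character(1)),
                             collapse = ","), ")", lab)
    }
    e <- edge_of[v]
    if (e > 0L && !is.null(elen)) s <- paste0(s, ":", fmt(elen[e]))
    s
  }
  paste0(rec(nt + 1L), ";")
}

#' Write a newick tree
#'
#' Supports are stored as internal-node labels and branch lengths after
#' colons; children are emitted in canonical order (by smallest
#' descendant leaf label) so that equal trees serialize identically.
#' Round trips preserve topology, branch lengths (to `1e-10`) and
#' supports.
#'
#' @param tree A `phylo` object.
#' @param path Output path; if `NULL` the newick string is returned.
#' @param canonical Order children canonically (default `TRUE`).
#' @return The newick string, invisibly when written to a file.
#' @export
writeNewick <- function(tree, path = NULL, canonical = TRUE) {
  s <- .newick_string(tree, canonical = canonical)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
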