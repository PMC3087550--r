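# Multiple protein alignment: optimal pairwise global alignment and a
# progressive aligner (neighbor-joining guide tree on pairwise
# p-distances, profiles merged leaf to root).  The progressive aligner is
# deterministic and self-contained; externally produced alignments can be
# supplied as aligned FASTA to bypass it.

.PROFILE_ALPHABET <- c(.AA_VALID, "-")

# 23x23 score matrix over the profile alphabet; gap scores 0 against
# everything (gap placement is charged through the affine penalties)
.profile_score_matrix <- function(cfg) {
  key <- "PROFILE_SC"
  if (!is.null(.pogo_cache[[key]])) return(.pogo_cache[[key]])
  SUB <- cfg$substitution_matrix
  al <- .PROFILE_ALPHABET
  SC <- matrix(0, length(al), length(al), dimnames = list(al, al))
  aa <- intersect(al, rownames(SUB))
  SC[aa, aa] <- SUB[aa, aa]
  SC["-", ] <- 0; SC[, "-"] <- 0
  .pogo_cache[[key]] <- SC
  SC
}

# alignment (named character vector of equal-length gapped strings)
# -> character matrix rows x cols
.aln_matrix <- function(rows) {
  stopifnot(length(unique(nchar(rows))) == 1L)
  mat <- do.call(rbind, strsplit(rows, ""))
  rownames(mat) <- names(rows)
  mat
}

.aln_profile <- function(mat) {
  al <- .PROFILE_ALPHABET
  P <- vapply(al, function(l) colSums(mat == l), numeric(ncol(mat)))
  if (ncol(mat) == 1L) P <- matrix(P, nrow = 1L, dimnames = list(NULL, al))
  P / nrow(mat)
}

.gap_run_cost <- function(L, cfg) {
  if (L == 0) 0 else cfg$gap_open + (L - 1) * cfg$gap_extend
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch with affine gaps (a run of length L costs
#' `gap_open + (L - 1) * gap_extend`) under the configured substitution
#' matrix.  Tie-breaking is deterministic: match/mismatch is preferred
#' over a gap, and a gap in `a` over a gap in `b`.
#'
#' @param a,b Protein sequences (character, `AAString`, or single-record
#'   `AAStringSet`); either may be empty.
#' @param cfg A [scoringConfig()].
#' @return List with `a`, `b` (gapped strings) and `score`.
#' @examples
#' globalAlignPair("MKV", "MV")$score
#' @export
globalAlignPair <- function(a, b, cfg = scoringConfig()) {
  as_chr <- function(x) {
    if (is.character(x)) x else as.character(if (is(x, "AAStringSet")) x[[1]] else x)
  }
  a <- as_chr(a); b <- as_chr(b)
  n <- nchar(a); m <- nchar(b)
  if (n == 0L && m == 0L) return(list(a = "", b = "", score = 0))
  if (n == 0L)
    return(list(a = strrep("-", m), b = b, score = -.gap_run_cost(m, cfg)))
  if (m == 0L)
    return(list(a = a, b = strrep("-", n), score = -.gap_run_cost(n, cfg)))
  SUB <- cfg$substitution_matrix
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  bad <- setdiff(unique(c(ca, cb)), rownames(SUB))
  if (length(bad))
    stop("residue(s) not in substitution matrix: ",
         paste(bad, collapse = ","), call. = FALSE)
  sim <- SUB[ca, cb, drop = FALSE]
  res <- .gotoh_align(matrix(as.numeric(sim), n, m),
                      cfg$gap_open, cfg$gap_extend)
  ga <- ifelse(res$a_idx > 0, ca[pmax(res$a_idx, 1L)], "-")
  gb <- ifelse(res$b_idx > 0, cb[pmax(res$b_idx, 1L)], "-")
  list(a = paste(ga, collapse = ""), b = paste(gb, collapse = ""),
       score = res$score)
}

# merge two alignments (named character vectors) with profile Gotoh
.merge_alignments <- function(ra, rb, cfg) {
  SC <- .profile_score_matrix(cfg)
  ma <- .aln_matrix(ra); mb <- .aln_matrix(rb)
  Pa <- .aln_profile(ma); Pb <- .aln_profile(mb)
  sim <- Pa %*% SC %*% t(Pb)
  res <- .gotoh_align(sim, cfg$gap_open, cfg$gap_extend)
  k <- length(res$a_idx)
  outA <- matrix("-", nrow(ma), k)
  outB <- matrix("-", nrow(mb), k)
  selA <- res$a_idx > 0; selB <- res$b_idx > 0
  outA[, selA] <- ma[, res$a_idx[selA], drop = FALSE]
  outB[, selB] <- mb[, res$b_idx[selB], drop = FALSE]
  rows <- c(apply(outA, 1, paste, collapse = ""),
            apply(outB, 1, paste, collapse = ""))
  names(rows) <- c(rownames(ma), rownames(mb))
  rows
}

#' Progressive multiple alignment of a protein family
#'
#' Pairwise global alignments give p-distances, a neighbor-joining guide
#' tree is built on them, and profiles are merged leaf to root with the
#' same affine scoring.  De-gapping any output row reproduces the input
#' sequence; row order follows the input.
#'
#' @param records Named `AAStringSet` of at least two protein records.
#' @param cfg A [scoringConfig()].
#' @return An aligned `AAStringSet` (equal widths, `-` gap character).
#' @export
progressiveMsa <- function(records, cfg = scoringConfig()) {
  stopifnot(is(records, "AAStringSet"))
  if (length(records) < 2L)
    stop("progressive alignment needs at least 2 records", call. = FALSE)
  if (is.null(names(records)) || anyDuplicated(names(records)))
    stop("records must have unique names", call. = FALSE)
  seqs <- as.character(records)
  n <- length(seqs)
  if (n == 2L) {
    pr <- globalAlignPair(seqs[1], seqs[2], cfg)
    out <- Biostrings::AAStringSet(c(pr$a, pr$b))
    names(out) <- names(seqs)
    return(out)
  }
  # guide distances from pairwise alignments
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pr <- globalAlignPair(seqs[i], seqs[j], cfg)
    p <- tryCatch(.pdist_strings(pr$a, pr$b), error = function(e) 1)
    D[i, j] <- D[j, i] <- p
  }
  guide <- neighborJoining(D)
  # postorder profile merge over the guide tree
  nt <- ape::Ntip(guide)
  kids <- split(guide$edge[, 2], guide$edge[, 1])
  build <- function(v) {
    if (v <= nt) {
      r <- seqs[guide$tip.label[v]]
      return(r)
    }
    parts <- lapply(kids[[as.character(v)]], build)
    Reduce(function(x, y) .merge_alignments(x, y, cfg), parts)
  }
  rows <- build(nt + 1L)
  rows <- rows[names(seqs)]
  out <- Biostrings::AAStringSet(rows)
  names(out) <- names(seqs)
  out
}

#' Drop sparsely occupied alignment columns
#'
#' Optional column-occupancy trim: removes columns in which fewer than
#' `min_occupancy` of the rows carry a residue.  No trimming is applied
#' anywhere by default.
#'
#' @param aln Aligned `AAStringSet`.
#' @param min_occupancy Minimum fraction of non-gap rows per column.
#' @return Trimmed aligned `AAStringSet`.
#' @export
trimAlignment <- function(aln, min_occupancy = 0.5) {
  mat <- .aln_matrix(setNames(as.character(aln), names(aln)))
  occ <- colMeans(mat != "-")
  keep <- occ >= min_occupancy
  out <- Biostrings::AAStringSet(apply(mat[, keep, drop = FALSE], 1,
                                       paste, collapse = ""))
  names(out) <- names(aln)
  out
}

#' Read / write aligned FASTA (gap character `-`)
#'
#' @param path File path.
#' @return `readAlignedFasta` returns an aligned `AAStringSet` (all rows
#'   equal width, validated).
#' @export
readAlignedFasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  if (length(unique(Biostrings::nchar(x))) > 1L)
    stop("rows of an aligned FASTA must have equal length", call. = FALSE)
  x
}

#' @rdname readAlignedFasta
#' @param aln Aligned `AAStringSet`.
#' @export
writeAlignedFasta <- function(aln, path) {
  Biostrings::writeXStringSet(aln, filepath = path, width = 60L)
  invisible(path)
}
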