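# Post-search harvesting: exporting hit subjects, extracting aligned
# translated-EST blocks, query-coverage filtering and redundancy collapse.

#' Collect the full subject records for a set of hits
#'
#' The classic "hits to FASTA" step: every subject that appears in the HSP
#' table is returned once, in the order of the subject set.
#'
#' @param hsps HSP data.frame (see [searchProtein()]).
#' @param subjects Named `AAStringSet`/`DNAStringSet` resolving every
#'   `subject_id`.
#' @return The deduplicated subject records, input order preserved.
#' @export
hitsToFasta <- function(hsps, subjects) {
  ids <- unique(hsps$subject_id)
  missing <- setdiff(ids, names(subjects))
  if (length(missing))
    stop("subject id(s) not resolvable: ",
         paste(missing, collapse = ","), call. = FALSE)
  subjects[names(subjects) %in% ids]
}

# union of 0-based half-open intervals -> total covered length
.interval_union_len <- function(starts, ends) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0L; cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] > cur_e) {
      tot <- tot + (cur_e - cur_s); cur_s <- starts[i]; cur_e <- ends[i]
    } else cur_e <- max(cur_e, ends[i])
  }
  tot + (cur_e - cur_s)
}

# union of 0-based half-open intervals -> merged interval matrix
.interval_union <- function(starts, ends) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  out_s <- starts[1]; out_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    k <- length(out_s)
    if (starts[i] > out_e[k]) {
      out_s <- c(out_s, starts[i]); out_e <- c(out_e, ends[i])
    } else out_e[k] <- max(out_e[k], ends[i])
  }
  cbind(start = out_s, end = out_e)
}

#' Concatenate the aligned translated blocks of one EST subject
#'
#' Takes all HSPs of a single EST subject (frames may differ) and returns
#' one protein record whose residues are the subject-side aligned blocks,
#' gaps removed, concatenated in ascending subject (nucleotide)
#' coordinate.  Overlapping blocks on the same frame are merged so that no
#' residue is emitted twice; blocks on conflicting frames are emitted in
#' coordinate order without merging.
#'
#' @param hsps HSP data.frame, all rows sharing one `subject_id` and with
#'   non-zero `frame` (translated-EST hits).
#' @param est The corresponding nucleotide record (`DNAString` or
#'   single-record `DNAStringSet`).
#' @return A single-record `AAStringSet` named `<subject_id>_blocks`, with
#'   `mcols()$source == "translated_est_block"`.
#' @export
extractAlignedBlocks <- function(hsps, est) {
  if (nrow(hsps) == 0L) stop("no HSPs supplied", call. = FALSE)
  if (length(unique(hsps$subject_id)) != 1L)
    stop("all HSPs must share one subject_id", call. = FALSE)
  if (is(est, "DNAStringSet")) est <- est[[1]]
  nt_len <- length(est)
  tr <- sixFrameTranslate(est)
  frame_key <- c("+1", "+2", "+3", "-1", "-2", "-3")
  names(frame_key) <- c("1", "2", "3", "-1", "-2", "-3")
  # recover frame-local protein spans from the stored nucleotide spans
  pspan <- lapply(seq_len(nrow(hsps)), function(r) {
    f <- hsps$frame[r]; k <- abs(f)
    if (f > 0) {
      p0 <- (hsps$sstart[r] - (k - 1L)) %/% 3L
      p1 <- (hsps$send[r] - (k - 1L)) %/% 3L
    } else {
      p0 <- (nt_len - hsps$send[r] - (k - 1L)) %/% 3L
      p1 <- (nt_len - hsps$sstart[r] - (k - 1L)) %/% 3L
    }
    list(frame = f, p0 = p0, p1 = p1,
         nt0 = hsps$sstart[r])
  })
  # merge same-frame overlaps on protein coordinates
  frames <- vapply(pspan, function(x) x$frame, integer(1))
  blocks <- list()
  for (f in unique(frames)) {
    sel <- pspan[frames == f]
    u <- .interval_union(vapply(sel, function(x) x$p0, integer(1)),
                         vapply(sel, function(x) x$p1, integer(1)))
    for (i in seq_len(nrow(u))) {
      nt <- .frame_to_nt(f, u[i, 1], u[i, 2], nt_len)
      blocks[[length(blocks) + 1L]] <- list(
        frame = f, p0 = u[i, 1], p1 = u[i, 2], nt0 = nt[1])
    }
  }
  blocks <- blocks[order(vapply(blocks, function(x) x$nt0, integer(1)),
                         vapply(blocks, function(x) x$frame, integer(1)))]
  res <- vapply(blocks, function(b) {
    substr(tr[[frame_key[as.character(b$frame)]]], b$p0 + 1L, b$p1)
  }, character(1))
  out <- Biostrings::AAStringSet(paste(res, collapse = ""))
  names(out) <- paste0(unique(hsps$subject_id), "_blocks")
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    species = NA_character_, description = "aligned translated blocks",
    source = "translated_est_block")
  out
}

#' Filter hit subjects by query coverage
#'
#' A subject's coverage of a query is the length of the union of its HSPs'
#' query spans divided by the query length; when a subject hits several
#' queries its coverage is the maximum over queries.  Subjects strictly
#' below `min_fraction` are discarded (a subject at exactly the threshold
#' is kept).
#'
#' @param hsps HSP data.frame (possibly several queries).
#' @param query_lengths Named integer vector of query lengths (residues).
#' @param min_fraction Minimum retained coverage fraction (default 0.40).
#' @return List with `kept` and `discarded` subject id vectors and the
#'   named `coverage` vector.
#' @export
coverageFilter <- function(hsps, query_lengths, min_fraction = 0.40) {
  stopifnot(all(query_lengths > 0), min_fraction >= 0)
  if (nrow(hsps) == 0L)
    return(list(kept = character(0), discarded = character(0),
                coverage = numeric(0)))
  missing <- setdiff(unique(hsps$query_id), names(query_lengths))
  if (length(missing))
    stop("query length(s) missing for: ",
         paste(missing, collapse = ","), call. = FALSE)
  cov <- tapply(seq_len(nrow(hsps)), hsps$subject_id, function(idx) {
    per_query <- tapply(idx, hsps$query_id[idx], function(j) {
      .interval_union_len(hsps$qstart[j], hsps$qend[j]) /
        query_lengths[[hsps$query_id[j][1]]]
    })
    max(per_query)
  })
  cov <- setNames(as.numeric(cov), names(cov))
  list(kept = names(cov)[cov >= min_fraction],
       discarded = names(cov)[cov < min_fraction],
       coverage = cov)
}

#' Collapse redundant sequences and splice isoforms within species
#'
#' Within each species, records whose global-alignment identity (matches
#' divided by the shorter sequence's length) reaches the threshold are
#' clustered by single linkage; the longest member of each cluster (ties:
#' lexicographically smallest id) represents it.  Records from different
#' species never merge.  This is an automated stand-in for the manual
#' redundancy/isoform curation a human would apply.
#'
#' @param records Named `AAStringSet` with `mcols()$species` (falls back
#'   to the id prefix before the first underscore).
#' @param identity_threshold Minimum identity to merge (default 0.99).
#' @param cfg A [scoringConfig()] for the global alignments.
#' @return The surviving records, input order preserved.
#' @export
collapseRedundant <- function(records, identity_threshold = 0.99,
                              cfg = scoringConfig()) {
  stopifnot(is(records, "AAStringSet"))
  if (length(records) <= 1L) return(records)
  sp <- S4Vectors::mcols(records)$species
  if (is.null(sp))
    sp <- sub("_.*$", "", names(records))
  keep <- rep(TRUE, length(records))
  for (s in unique(sp)) {
    idx <- which(sp == s)
    if (length(idx) < 2L) next
    # single-linkage clusters at >= threshold identity
    parent <- seq_along(idx)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (a in seq_along(idx)[-length(idx)]) for (b in (a + 1):length(idx)) {
      ga <- records[[idx[a]]]; gb <- records[[idx[b]]]
      pa <- Biostrings::pairwiseAlignment(
        ga, gb, type = "global",
        substitutionMatrix = cfg$substitution_matrix,
        gapOpening = cfg$gap_open - cfg$gap_extend,
        gapExtension = cfg$gap_extend)
      ident <- Biostrings::nmatch(pa) / min(length(ga), length(gb))
      if (ident >= identity_threshold) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
    roots <- vapply(seq_along(idx), find, integer(1))
    for (r in unique(roots)) {
      members <- idx[roots == r]
      if (length(members) < 2L) next
      w <- Biostrings::nchar(records)[members]
      best <- members[order(-w, names(records)[members])][1]
      keep[setdiff(members, best)] <- FALSE
    }
  }
  records[keep]
}

#' Read / write BLAST 12-column tabular hit files
#'
#' `readBlastTab()` ingests standard `outfmt 6` (columns `qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue
#' bitscore`; 1-based inclusive coordinates) as a drop-in alternative to
#' the internal search; coordinates are converted to the package's 0-based
#' half-open convention and a subject start greater than its end is
#' interpreted as a minus-strand (translated) hit.  `writeBlastTab()` is
#' the exact inverse for tables that came from `readBlastTab()`.
#'
#' @param path File path.
#' @return For `readBlastTab`, an HSP-style data.frame with the extra
#'   columns `pident`, `length`, `mismatch`, `gapopen`, `bitscore`;
#'   `aligned_query`/`aligned_subject` are `NA` (tabular files do not
#'   carry alignments) and `score` holds the bit score.
#' @export
readBlastTab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, col.names = cols)
  minus <- tb$sstart > tb$send
  s0 <- ifelse(minus, tb$send, tb$sstart) - 1L
  s1 <- ifelse(minus, tb$sstart, tb$send)
  data.frame(
    query_id = tb$qseqid, subject_id = tb$sseqid,
    frame = ifelse(minus, -1L, 0L),
    qstart = tb$qstart - 1L, qend = tb$qend,
    sstart = s0, send = s1,
    identities = as.integer(round(tb$pident * tb$length / 100)),
    score = tb$bitscore, evalue = tb$evalue,
    aligned_query = NA_character_, aligned_subject = NA_character_,
    pident = tb$pident, length = tb$length, mismatch = tb$mismatch,
    gapopen = tb$gapopen, bitscore = tb$bitscore,
    stringsAsFactors = FALSE
  )
}

#' @rdname readBlastTab
#' @param hsps Table produced by [readBlastTab()].
#' @export
writeBlastTab <- function(hsps, path) {
  minus <- hsps$frame < 0
  out <- data.frame(
    qseqid = hsps$query_id, sseqid = hsps$subject_id,
    pident = hsps$pident, length = hsps$length,
    mismatch = hsps$mismatch, gapopen = hsps$gapopen,
    qstart = hsps$qstart + 1L, qend = hsps$qend,
    sstart = ifelse(minus, hsps$send, hsps$sstart + 1L),
    send = ifelse(minus, hsps$sstart + 1L, hsps$send),
    evalue = hsps$evalue, bitscore = hsps$bitscore
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
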