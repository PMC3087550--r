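# Homology search: protein queries against proteomes and against
# six-frame-translated ESTs.
#
# The engine scores each query/subject pair by exhaustive Smith-Waterman
# dynamic programming (Biostrings), so the best local alignment per
# subject is exact; significance is assessed with Karlin-Altschul
# e-values and hits above the cutoff are discarded.  Hit tables ("HSPs")
# are plain data.frames with 0-based half-open coordinates; conversion to
# the 1-based inclusive convention happens only at the BLAST-tabular
# boundary (see readBlastTab/writeBlastTab).

.hsp_cols <- c("query_id", "subject_id", "frame", "qstart", "qend",
               "sstart", "send", "identities", "score", "evalue",
               "aligned_query", "aligned_subject")

.empty_hsps <- function() {
  df <- data.frame(query_id = character(0), subject_id = character(0),
                   frame = integer(0), qstart = integer(0),
                   qend = integer(0), sstart = integer(0),
                   send = integer(0), identities = integer(0),
                   score = numeric(0), evalue = numeric(0),
                   aligned_query = character(0),
                   aligned_subject = character(0),
                   stringsAsFactors = FALSE)
  df
}

#' Validate an HSP table's structural invariants
#'
#' Checks that aligned strings have equal length, that their ungapped
#' lengths match the span lengths, that identity counts are attainable and
#' that e-values are positive.  Used defensively by downstream consumers.
#'
#' @param hsps An HSP data.frame.
#' @return `hsps`, invisibly; stops with a message on violation.
#' @export
validateHsps <- function(hsps) {
  stopifnot(all(.hsp_cols %in% names(hsps)))
  if (nrow(hsps) == 0) return(invisible(hsps))
  ql <- hsps$qend - hsps$qstart
  sl <- hsps$send - hsps$sstart
  gq <- nchar(gsub("-", "", hsps$aligned_query, fixed = TRUE))
  if (!all(nchar(hsps$aligned_query) == nchar(hsps$aligned_subject)))
    stop("aligned strings differ in length")
  if (!all(gq == ql))
    stop("ungapped aligned_query length != query span")
  if (!all(hsps$identities <= pmin(ql, abs(sl))))
    stop("identities exceed span length")
  if (!all(hsps$evalue > 0)) stop("non-positive evalue")
  invisible(hsps)
}

.as_single_query <- function(query) {
  if (is(query, "AAString")) {
    query <- Biostrings::AAStringSet(query)
    names(query) <- "query"
  }
  stopifnot(is(query, "AAStringSet"))
  if (length(query) != 1L || Biostrings::nchar(query)[1] == 0L)
    stop("query must be a single non-empty protein record", call. = FALSE)
  if (is.null(names(query))) names(query) <- "query"
  query
}

#' Best local alignment of two protein sequences
#'
#' Exhaustive Smith-Waterman with affine gaps under the configured
#' substitution matrix; a gap run of length L costs
#' `gap_open + (L - 1) * gap_extend`.
#'
#' @param a,b Protein sequences (character, `AAString`, or single-record
#'   `AAStringSet`).
#' @param cfg A [scoringConfig()].
#' @return List with elements `score`, `aligned_a`, `aligned_b`,
#'   `a_span` and `b_span` (0-based half-open integer pairs) and
#'   `identities`.
#' @export
localAlign <- function(a, b, cfg = scoringConfig()) {
  a <- if (is.character(a)) Biostrings::AAString(a) else a
  b <- if (is.character(b)) Biostrings::AAString(b) else b
  if (is(a, "AAStringSet")) a <- a[[1]]
  if (is(b, "AAStringSet")) b <- b[[1]]
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "local",
    substitutionMatrix = cfg$substitution_matrix,
    gapOpening = cfg$gap_open - cfg$gap_extend,
    gapExtension = cfg$gap_extend
  )
  pr <- Biostrings::pattern(pa)
  sr <- Biostrings::subject(pa)
  list(
    score = Biostrings::score(pa),
    aligned_a = as.character(Biostrings::alignedPattern(pa)),
    aligned_b = as.character(Biostrings::alignedSubject(pa)),
    a_span = c(Biostrings::start(pr) - 1L, Biostrings::end(pr)),
    b_span = c(Biostrings::start(sr) - 1L, Biostrings::end(sr)),
    identities = Biostrings::nmatch(pa)
  )
}

#' Search a protein query against a set of protein subjects
#'
#' For each subject the best-scoring local alignment is computed; the hit
#' is reported iff its Karlin-Altschul e-value (with `m` the query length
#' and `n` the summed subject lengths) is at or below `cfg$evalue_max`.
#' Results are sorted by ascending e-value, ties broken by subject id.
#'
#' @param query A single protein record (`AAString` or named
#'   single-record `AAStringSet`).
#' @param subjects An `AAStringSet` of protein subjects (may be empty).
#' @param cfg A [scoringConfig()].
#' @return HSP data.frame (0-based half-open coordinates, `frame = 0`).
#' @export
searchProtein <- function(query, subjects, cfg = scoringConfig()) {
  query <- .as_single_query(query)
  stopifnot(is(subjects, "AAStringSet"))
  if (length(subjects) == 0L) return(.empty_hsps())
  if (is.null(names(subjects)))
    stop("subjects must be named", call. = FALSE)
  S4Vectors::mcols(subjects) <- NULL
  m <- Biostrings::nchar(query)[1]
  n <- sum(Biostrings::nchar(subjects))
  pa <- Biostrings::pairwiseAlignment(
    pattern = subjects, subject = query[[1]], type = "local",
    substitutionMatrix = cfg$substitution_matrix,
    gapOpening = cfg$gap_open - cfg$gap_extend,
    gapExtension = cfg$gap_extend
  )
  sc <- Biostrings::score(pa)
  ev <- karlinEvalue(sc, m, n, cfg)
  keep <- which(ev <= cfg$evalue_max)
  if (length(keep) == 0L) return(.empty_hsps())
  pr <- Biostrings::pattern(pa)   # ranges on the subjects
  qr <- Biostrings::subject(pa)   # ranges on the query
  df <- data.frame(
    query_id = names(query),
    subject_id = names(subjects)[keep],
    frame = 0L,
    qstart = Biostrings::start(qr)[keep] - 1L,
    qend = Biostrings::end(qr)[keep],
    sstart = Biostrings::start(pr)[keep] - 1L,
    send = Biostrings::end(pr)[keep],
    identities = Biostrings::nmatch(pa)[keep],
    score = sc[keep],
    evalue = ev[keep],
    aligned_query = as.character(Biostrings::alignedSubject(pa))[keep],
    aligned_subject = as.character(Biostrings::alignedPattern(pa))[keep],
    stringsAsFactors = FALSE
  )
  df <- df[order(df$evalue, df$subject_id), , drop = FALSE]
  rownames(df) <- NULL
  validateHsps(df)
  df
}

# frame-local protein span -> forward-strand nucleotide span
# (0-based half-open on both sides)
.frame_to_nt <- function(frame, p0, p1, nt_len) {
  k <- abs(frame)
  lo <- (k - 1L) + 3L * p0
  hi <- (k - 1L) + 3L * p1
  if (frame > 0) c(lo, hi) else c(nt_len - hi, nt_len - lo)
}

#' Search a protein query against six-frame-translated ESTs
#'
#' Runs the protein search against all six translation frames of every
#' EST.  `frame` records the frame of each hit; `sstart`/`send` are
#' reported in nucleotide coordinates of the input EST (forward strand,
#' 0-based half-open), derived from the frame-local protein coordinates.
#' The search space `n` is the summed length of all translated frames.
#'
#' @param query A single protein record.
#' @param ests A `DNAStringSet` of EST records (may be empty).
#' @param cfg A [scoringConfig()].
#' @return HSP data.frame; `aligned_subject` holds the translated EST side.
#' @export
searchTranslated <- function(query, ests, cfg = scoringConfig()) {
  query <- .as_single_query(query)
  stopifnot(is(ests, "DNAStringSet"))
  if (length(ests) == 0L) return(.empty_hsps())
  if (is.null(names(ests))) stop("ests must be named", call. = FALSE)
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  prot <- character(0); est_of <- character(0); frame_of <- character(0)
  for (i in seq_along(ests)) {
    tr <- sixFrameTranslate(ests[[i]])
    ok <- nchar(tr) > 0
    prot <- c(prot, unname(tr[ok]))
    est_of <- c(est_of, rep(names(ests)[i], sum(ok)))
    frame_of <- c(frame_of, frames[ok])
  }
  if (length(prot) == 0L) return(.empty_hsps())
  subj <- Biostrings::AAStringSet(prot)
  names(subj) <- paste0(est_of, "|", frame_of)
  hits <- searchProtein(query, subj, cfg)
  if (nrow(hits) == 0L) return(hits)
  idx <- match(hits$subject_id, names(subj))
  hits$frame <- as.integer(frame_of[idx])
  nt_len <- Biostrings::nchar(ests)[match(est_of[idx], names(ests))]
  span <- t(vapply(seq_len(nrow(hits)), function(r)
    .frame_to_nt(hits$frame[r], hits$sstart[r], hits$send[r], nt_len[r]),
    integer(2)))
  hits$sstart <- span[, 1]
  hits$send <- span[, 2]
  hits$subject_id <- est_of[idx]
  hits <- hits[order(hits$evalue, hits$subject_id, hits$frame), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}
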