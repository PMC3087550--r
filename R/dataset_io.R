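# Reading and writing sequence sets, with species namespacing and
# six-frame translation for EST mining.
#
# Sequence sets are Biostrings AAStringSet / DNAStringSet objects whose
# names are record ids and whose mcols() carry species, source and the
# original FASTA description.  Ids are namespaced with the species code
# ("At_XTH22") on ingestion so that downstream ortholog-group criteria,
# which key on species, never have to re-parse headers.

.AA_VALID <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
               "P","S","T","W","Y","V","X","*")
.NT_VALID <- c("A","C","G","T","N")

.check_residues <- function(x, valid, what) {
  chars <- strsplit(as.character(x), "")
  for (i in seq_along(chars)) {
    bad <- setdiff(unique(chars[[i]]), valid)
    if (length(bad))
      stop("illegal residue(s) ", paste(bad, collapse = ","),
           " in record '", names(x)[i], "' (", what, ")", call. = FALSE)
  }
  invisible(TRUE)
}

.empty_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) return(TRUE)
  lines <- readLines(path, warn = FALSE)
  !any(startsWith(trimws(lines), ">"))
}

.ingest_names <- function(x, species, prefix) {
  if (length(x) == 0) return(x)
  hdr <- names(x)
  if (any(is.na(hdr) | hdr == ""))
    stop("malformed FASTA header: empty id in entry ",
         which(is.na(hdr) | hdr == "")[1], call. = FALSE)
  id <- vapply(strsplit(hdr, "[ \t]+"), `[`, character(1), 1L)
  desc <- sub("^[^ \t]+[ \t]*", "", hdr)
  if (prefix) id <- paste0(species, "_", id)
  if (anyDuplicated(id))
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ","), call. = FALSE)
  names(x) <- id
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(
    species = rep(species, length(x)),
    description = desc
  )
  x
}

#' Read a protein FASTA file into a namespaced sequence set
#'
#' One record is produced per FASTA entry, in file order; arbitrary line
#' wrapping is accepted.  The species code is prepended to every record id
#' (`"At_" + local id`) so ids stay unique when datasets are pooled across
#' species.  Residues are validated against the 20 amino acids plus `X`
#' (ambiguity) and `*` (stop).
#'
#' @param path Path to a FASTA file.  An empty file yields an empty set.
#' @param species Short species code (e.g. `"At"`, `"Os"`).
#' @param source Provenance tag stored in `mcols()`: `"genome"`, `"est"` or
#'   `"translated_est_block"`.
#' @param prefix_species Prepend `species` to record ids (default `TRUE`).
#' @return An [Biostrings::AAStringSet] with `mcols()` columns `species`,
#'   `description` and `source`.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">q1 a kinase", "MKVLLAG"), tf)
#' readProteinFasta(tf, species = "At")
#' @export
readProteinFasta <- function(path, species, source = "genome",
                             prefix_species = TRUE) {
  stopifnot(is.character(species), length(species) == 1L, nzchar(species))
  if (.empty_fasta(path)) {
    out <- Biostrings::AAStringSet()
    return(out)
  }
  x <- Biostrings::readBStringSet(path)  # raw read so validation sees
  seqs <- toupper(as.character(x))       # every original character
  names(seqs) <- names(x)
  x <- Biostrings::BStringSet(seqs)
  x <- .ingest_names(x, species, prefix_species)
  .check_residues(x, .AA_VALID, "protein")
  y <- Biostrings::AAStringSet(as.character(x))
  names(y) <- names(x)
  S4Vectors::mcols(y) <- S4Vectors::mcols(x)
  S4Vectors::mcols(y)$source <- rep(source, length(y))
  y
}

#' Read a nucleotide FASTA file (EST set) into a namespaced sequence set
#'
#' As [readProteinFasta()] but for nucleotide records; only `A,C,G,T,N`
#' are accepted (`U` is converted to `T` on ingestion).
#'
#' @inheritParams readProteinFasta
#' @return A [Biostrings::DNAStringSet] with `mcols()` columns `species`,
#'   `description` and `source`.
#' @export
readNucleotideFasta <- function(path, species, source = "est",
                                prefix_species = TRUE) {
  stopifnot(is.character(species), length(species) == 1L, nzchar(species))
  if (.empty_fasta(path)) return(Biostrings::DNAStringSet())
  x <- Biostrings::readBStringSet(path)
  seqs <- gsub("U", "T", toupper(as.character(x)))
  names(seqs) <- names(x)
  x <- Biostrings::BStringSet(seqs)
  x <- .ingest_names(x, species, prefix_species)
  .check_residues(x, .NT_VALID, "nucleotide")
  y <- Biostrings::DNAStringSet(as.character(x))
  names(y) <- names(x)
  S4Vectors::mcols(y) <- S4Vectors::mcols(x)
  S4Vectors::mcols(y)$source <- rep(source, length(y))
  y
}

#' Write a sequence set to FASTA
#'
#' Emits 60-column wrapped FASTA.  Reading the file back with
#' [readProteinFasta()] / [readNucleotideFasta()] (with
#' `prefix_species = FALSE`) reproduces ids and residues exactly.
#'
#' @param records An `AAStringSet` or `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(records, path) {
  Biostrings::writeXStringSet(records, filepath = path, width = 60L)
  invisible(path)
}

# standard-code translation of one reading frame; trailing partial codon
# dropped; any codon containing an ambiguity translates to X
.translate_frame <- function(dna, offset) {
  L <- Biostrings::nchar(dna)
  n_codon <- (L - offset) %/% 3L
  if (n_codon <= 0L) return("")
  sub <- Biostrings::subseq(dna, start = offset + 1L, width = 3L * n_codon)
  as.character(Biostrings::translate(sub, if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

#' Six-frame translation of a nucleotide sequence
#'
#' Frame `+k` translates codons starting at offset `k - 1` of the forward
#' strand; `-k` does the same on the reverse complement.  The trailing
#' partial codon is dropped, stop codons are rendered `*`, and codons
#' containing `N` translate to `X` (standard genetic code).
#'
#' @param x A `DNAString`, single-record `DNAStringSet`, or a nucleotide
#'   character string.
#' @return Named character vector of six protein strings, names
#'   `"+1","+2","+3","-1","-2","-3"`.
#' @examples
#' sixFrameTranslate("ATGAAATGA")[["+1"]]  # "MK*"
#' @export
sixFrameTranslate <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAString(x)
  if (is(x, "DNAStringSet")) {
    stopifnot(length(x) == 1L)
    x <- x[[1L]]
  }
  rc <- Biostrings::reverseComplement(x)
  out <- c(
    "+1" = .translate_frame(x, 0L), "+2" = .translate_frame(x, 1L),
    "+3" = .translate_frame(x, 2L),
    "-1" = .translate_frame(rc, 0L), "-2" = .translate_frame(rc, 1L),
    "-3" = .translate_frame(rc, 2L)
  )
  out
}
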