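# Scoring configuration for local and global protein alignment.
#
# Defaults mirror the common blastp setup: BLOSUM62 with affine gaps
# 11/1 and published Karlin-Altschul parameters for that combination
# (lambda = 0.267, K = 0.041, gapped).  A gap run of length L costs
# gap_open + (L - 1) * gap_extend, i.e. the first gapped residue pays the
# opening penalty.  E-values computed from these constants are used as a
# significance cutoff, not as a reproduction of NCBI's composition-adjusted
# statistics.

#' Default BLOSUM62 substitution matrix (integer, 25 letters incl. X and *)
#' @noRd
.blosum62 <- function() {
  if (is.null(.pogo_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pogo_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pogo_cache$BLOSUM62
}

#' Build a scoring configuration
#'
#' @param substitution_matrix Square integer matrix with amino-acid
#'   dimnames (default BLOSUM62, including `X` and `*`).
#' @param gap_open Positive penalty for the first residue of a gap run
#'   (default 11).
#' @param gap_extend Positive penalty for each further gapped residue
#'   (default 1).  Must satisfy `gap_open >= gap_extend >= 1`.
#' @param karlin_lambda,karlin_K Karlin-Altschul parameters used to turn a
#'   raw local score into an e-value `K * m * n * exp(-lambda * score)`;
#'   defaults are the published gapped BLOSUM62-11/1 values.
#' @param evalue_max E-value cutoff for reporting hits (default `1e-4`).
#' @param seed_word_length Word length a seeded search heuristic would use;
#'   retained for interface completeness (the internal engine scores by
#'   exhaustive dynamic programming, so no hit below the cutoff is missed).
#' @return A list of class `ScoringConfig`.
#' @examples
#' cfg <- scoringConfig()
#' cfg$evalue_max
#' @export
scoringConfig <- function(substitution_matrix = NULL,
                          gap_open = 11L, gap_extend = 1L,
                          karlin_lambda = 0.267, karlin_K = 0.041,
                          evalue_max = 1e-4, seed_word_length = 3L) {
  if (is.null(substitution_matrix)) substitution_matrix <- .blosum62()
  stopifnot(
    is.matrix(substitution_matrix),
    nrow(substitution_matrix) == ncol(substitution_matrix),
    gap_open >= gap_extend, gap_extend >= 1,
    karlin_lambda > 0, karlin_K > 0, evalue_max > 0
  )
  structure(list(
    substitution_matrix = substitution_matrix,
    gap_open = as.numeric(gap_open),
    gap_extend = as.numeric(gap_extend),
    karlin_lambda = karlin_lambda,
    karlin_K = karlin_K,
    evalue_max = evalue_max,
    seed_word_length = as.integer(seed_word_length)
  ), class = "ScoringConfig")
}

#' Karlin-Altschul e-value for a raw local alignment score
#'
#' `E = K * m * n * exp(-lambda * score)`, with `m` the query length and
#' `n` the summed subject length (the search space actually scanned).
#' Strictly decreasing in `score`.
#'
#' @param score Raw alignment score (matrix units).
#' @param m Query length (residues).
#' @param n Summed subject length (residues).
#' @param cfg A [scoringConfig()].
#' @return Numeric e-value (> 0).
#' @export
karlinEvalue <- function(score, m, n, cfg = scoringConfig()) {
  stopifnot(m > 0, n > 0)
  cfg$karlin_K * m * n * exp(-cfg$karlin_lambda * score)
}
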