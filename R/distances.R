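# Evolutionary distances between aligned protein sequences: the
# uncorrected p-distance and the PAM-001 (Dayhoff) correction obtained by
# numerically inverting the expected proportion of differences under
# powers of the Dayhoff PAM1 transition matrix.
#
# Gap handling is pairwise deletion: a column contributes to a pair only
# if both rows carry an unambiguous residue (gaps, X and * are skipped),
# which wastes as few EST-fragment columns as possible.

.pdist_strings <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  skip <- c("-", "X", "*")
  ok <- !(ca %in% skip) & !(cb %in% skip)
  ncomp <- sum(ok)
  if (ncomp == 0L)
    stop("no comparable columns (saturated pair)", call. = FALSE)
  sum(ca[ok] != cb[ok]) / ncomp
}

.aln_rows <- function(aln) {
  if (is(aln, "AAStringSet")) setNames(as.character(aln), names(aln))
  else aln
}

#' p-distance between two rows of an alignment
#'
#' Proportion of differing residues among compared positions, with
#' pairwise deletion: columns where either row has a gap (or `X`/`*`) are
#' skipped.
#'
#' @param aln Aligned `AAStringSet` (or named character vector of gapped
#'   strings).
#' @param i,j Row indices or names.
#' @return p-distance in `[0, 1]`; errors if no column is comparable.
#' @examples
#' aln <- Biostrings::AAStringSet(c(a = "AAAA", b = "AAAT"))
#' pDistance(aln, "a", "b")  # 0.25
#' @export
pDistance <- function(aln, i, j) {
  rows <- .aln_rows(aln)
  .pdist_strings(rows[[i]], rows[[j]])
}

# ---- Dayhoff PAM machinery ------------------------------------------------
# PAM1 is derived from the Dayhoff rate matrix (exchangeabilities and
# stationary composition as shipped with phangorn): the rate matrix is
# scaled so one unit corresponds to an expected 1% of sites substituted,
# and M^D for real D is evaluated through the (symmetrizable) eigenbasis.

.pam_setup <- function() {
  if (!is.null(.pogo_cache$PAM)) return(.pogo_cache$PAM)
  day <- utils::getFromNamespace(".Dayhoff", "phangorn")
  bf <- day$bf
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  S <- matrix(0, 20, 20, dimnames = list(aa, aa))
  S[lower.tri(S)] <- day$Q
  S <- S + t(S)
  R <- S * rep(bf, each = 20)       # R[i,j] = S[i,j] * pi_j
  diag(R) <- -rowSums(R)
  mu <- -sum(bf * diag(R))
  R <- R / mu                       # unit expected substitution rate
  # symmetrize: B = D^{1/2} R D^{-1/2}
  sq <- sqrt(bf)
  B <- diag(sq) %*% R %*% diag(1 / sq)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  # [exp(t*R)]_aa = sum_k V[a,k]^2 * exp(t * lambda_k)
  V <- eig$vectors
  W <- V * V
  ck <- as.numeric(bf %*% W)        # sum_a pi_a [e^{tR}]_aa coefficients
  pdiff <- function(t) 1 - sum(ck * exp(eig$values * t))
  # calibrate one PAM unit: exactly 1% observed differences
  lo <- 0; hi <- 0.02
  while (pdiff(hi) < 0.01) hi <- hi * 2
  for (k in 1:80) {
    mid <- (lo + hi) / 2
    if (pdiff(mid) < 0.01) lo <- mid else hi <- mid
  }
  t1 <- (lo + hi) / 2
  pam <- list(bf = bf, theta = eig$values * t1, ck = ck, aa = aa,
              R = R * t1, pmax_inf = 1 - sum(bf^2))
  .pogo_cache$PAM <- pam
  pam
}

#' Expected proportion of differing sites after D PAM units
#'
#' `1 - sum_a pi_a [M^D]_aa`, with `M` the Dayhoff PAM1 transition matrix
#' and `pi` its stationary composition; `M^D` for real `D` is evaluated in
#' the eigenbasis.  Strictly increasing in `D`.
#'
#' @param D Evolutionary distance in PAM units (`>= 0`).
#' @return Expected proportion of observed differences.
#' @export
pamExpectedDiff <- function(D) {
  pam <- .pam_setup()
  vapply(D, function(d) 1 - sum(pam$ck * exp(pam$theta * d)), numeric(1))
}

#' Dayhoff PAM1 transition matrix
#'
#' The 20x20 one-PAM transition probability matrix (rows sum to one;
#' expected fraction of sites substituted = 1%) underlying the PAM-001
#' distance.
#'
#' @return Numeric 20x20 matrix with amino-acid dimnames.
#' @export
pam1Matrix <- function() {
  pam <- .pam_setup()
  sq <- sqrt(pam$bf)
  eig <- eigen((diag(sq) %*% pam$R %*% diag(1 / sq) +
                t(diag(sq) %*% pam$R %*% diag(1 / sq))) / 2,
               symmetric = TRUE)
  M <- diag(1 / sq) %*% eig$vectors %*% diag(exp(eig$values)) %*%
    t(eig$vectors) %*% diag(sq)
  dimnames(M) <- list(pam$aa, pam$aa)
  M
}

.PAM_CAP <- 1000

#' PAM-001 corrected distance between two rows of an alignment
#'
#' Let `p` be the pairwise-deletion p-distance.  The PAM distance `D`
#' solves `pamExpectedDiff(D) = p` by monotone bisection to
#' `|delta p| <= 1e-9`; the result is returned in substitutions per site
#' (`D / 100`).  `D` is capped at 1000 PAM units; a `p` beyond the
#' attainable asymptote raises a saturation error.
#'
#' @inheritParams pDistance
#' @return Distance in substitutions per site (`>= 0`).
#' @export
pam001Distance <- function(aln, i, j) {
  p <- pDistance(aln, i, j)
  pamFromP(p)
}

#' @rdname pam001Distance
#' @param p Observed proportion of differences.
#' @export
pamFromP <- function(p) {
  stopifnot(p >= 0, p <= 1)
  if (p == 0) return(0)
  pmax_cap <- pamExpectedDiff(.PAM_CAP)
  if (p > pmax_cap)
    stop("p-distance ", signif(p, 4),
         " beyond the attainable PAM asymptote (saturated pair)",
         call. = FALSE)
  lo <- 0; hi <- .PAM_CAP
  repeat {
    mid <- (lo + hi) / 2
    pm <- pamExpectedDiff(mid)
    if (abs(pm - p) <= 1e-9 || (hi - lo) < 1e-12) break
    if (pm < p) lo <- mid else hi <- mid
  }
  mid / 100
}

#' Pairwise distance matrix of an alignment
#'
#' @param aln Aligned `AAStringSet`.
#' @param model `"pdist"` (default) or `"pam001"`.
#' @return Symmetric labeled matrix with zero diagonal and attribute
#'   `model`; a saturated pair raises an error.
#' @export
distanceMatrix <- function(aln, model = c("pdist", "pam001")) {
  model <- match.arg(model)
  rows <- .aln_rows(aln)
  n <- length(rows)
  ids <- names(rows)
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  skip <- mat == "-" | mat == "X" | mat == "*"
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !skip[i, ] & !skip[j, ]
    ncomp <- sum(ok)
    if (ncomp == 0L)
      stop("no comparable columns between '", ids[i], "' and '", ids[j],
           "' (saturated pair)", call. = FALSE)
    p <- sum(mat[i, ok] != mat[j, ok]) / ncomp
    D[i, j] <- D[j, i] <- if (model == "pdist") p else pamFromP(p)
  }
  attr(D, "model") <- model
  D
}
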