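# Neighbor joining (Saitou & Nei agglomeration) with deterministic
# tie-breaking and non-negative branch lengths.
#
# The classic Q-criterion is minimized at every step; ties (within
# 1e-12 relative tolerance) are broken by the lexicographic order of the
# joined clusters' labels, a cluster being labelled by its smallest
# member taxon.  Negative branch lengths are clamped to zero with the
# deficit moved to the sister edge, so path lengths within a cherry are
# preserved.  On an additive matrix the generating topology and all
# branch lengths are recovered exactly.

.fmt_len <- function(x) sprintf("%.12g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' @param dm Symmetric numeric matrix with zero diagonal and taxon
#'   dimnames (at least two taxa).  Asymmetry beyond `1e-8` is an error.
#' @return An unrooted `phylo` object (a trifurcating root for more than
#'   three taxa; for two taxa the single edge is split evenly across the
#'   two pendant branches).
#' @examples
#' d <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' neighborJoining(d)$edge.length  # 0.05 0.15 0.25
#' @export
neighborJoining <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  n0 <- nrow(dm)
  if (n0 < 2L) stop("need at least two taxa", call. = FALSE)
  if (is.null(rownames(dm)))
    dimnames(dm) <- list(paste0("t", seq_len(n0)), paste0("t", seq_len(n0)))
  if (max(abs(dm - t(dm))) > 1e-8)
    stop("distance matrix is not symmetric", call. = FALSE)
  labels <- rownames(dm)
  if (any(grepl("[(),:;[:space:]]", labels)))
    stop("taxon labels must not contain newick metacharacters",
         call. = FALSE)
  if (n0 == 2L) {
    h <- dm[1, 2] / 2
    return(ape::read.tree(text = sprintf(
      "(%s:%s,%s:%s);", labels[1], .fmt_len(h), labels[2], .fmt_len(h))))
  }
  # working state: newick fragments per active cluster + sort key
  frag <- labels
  key <- labels
  D <- dm
  clamp2 <- function(vi, vj, dij) {
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    c(max(vi, 0), max(vj, 0))
  }
  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-12 * max(1, abs(qmin))
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # lexicographic tie-break on sorted label pairs
    pk <- apply(cand, 1, function(ij) {
      p <- sort(c(key[ij[1]], key[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(pk)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    v <- clamp2(vi, vj, D[i, j])
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], .fmt_len(v[1]),
                        frag[j], .fmt_len(v[2]))
    new_key <- min(key[i], key[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    key <- c(key[keep], new_key)
    rownames(D2) <- colnames(D2) <- seq_len(nrow(D2))
    D <- D2
  }
  # final three clusters joined at an unresolved root
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  v1 <- (d12 + d13 - d23) / 2
  v2 <- (d12 + d23 - d13) / 2
  v3 <- (d13 + d23 - d12) / 2
  v1 <- max(v1, 0); v2 <- max(v2, 0); v3 <- max(v3, 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], .fmt_len(v1), frag[2], .fmt_len(v2),
                 frag[3], .fmt_len(v3))
  ape::read.tree(text = txt)
}
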