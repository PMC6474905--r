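#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step join the pair minimizing the
#' Q-criterion `(m - 2) d_ij - R_i - R_j`; ties are broken by the lowest
#' taxon-index pair. Branch lengths come from the standard two-point
#' formulas; negative lengths are clamped to zero with the deficit moved to
#' the sibling edge (logged via `message()`). The result is unrooted (the
#' last three clusters meet at a trifurcation).
#'
#' @param D symmetric numeric distance matrix with taxon names as dimnames.
#' @return an [ape::phylo] tree with branch lengths.
#' @export
neighbor_joining <- function(D) {
  fail_if(!is.matrix(D) || nrow(D) != ncol(D), "D must be a square matrix")
  fail_if(nrow(D) < 3L, "need >= 3 taxa")
  fail_if(any(is.na(D)) || any(!is.finite(D)),
          "distance matrix contains NaN/Inf; re-estimate the inestimable pairs first")
  labels <- rownames(D) %||% paste0("t", seq_len(nrow(D)))
  clamped <- 0L
  clamp2 <- function(vi, vj) {
    if (vi < 0) { vj <- vj + vi; vi <- 0; clamped <<- clamped + 1L }
    if (vj < 0) { vi <- vi + vj; vj <- 0; clamped <<- clamped + 1L }
    c(max(vi, 0), max(vj, 0))
  }
  nodes <- as.list(labels)          # newick fragment per active cluster
  active <- seq_along(labels)
  while (length(active) > 3L) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    R <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(R, R, `+`)
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    pick <- idx[order(idx[, 1], idx[, 2])[1], ]
    ii <- pick[1]; jj <- pick[2]
    i <- active[ii]; j <- active[jj]
    dij <- Dm[ii, jj]
    vi <- 0.5 * dij + (R[ii] - R[jj]) / (2 * (m - 2))
    vj <- dij - vi
    v <- clamp2(vi, vj)
    nodes[[i]] <- sprintf("(%s:%.10g,%s:%.10g)", nodes[[i]], v[1],
                          nodes[[j]], v[2])
    newd <- 0.5 * (D[i, active] + D[j, active] - dij)
    D[i, active] <- newd; D[active, i] <- newd
    D[i, i] <- 0
    active <- setdiff(active, j)
  }
  a <- active[1]; b <- active[2]; c3 <- active[3]
  va <- max(0, (D[a, b] + D[a, c3] - D[b, c3]) / 2)
  vb <- max(0, (D[a, b] + D[b, c3] - D[a, c3]) / 2)
  vc <- max(0, (D[a, c3] + D[b, c3] - D[a, b]) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nodes[[a]], va, nodes[[b]], vb, nodes[[c3]], vc)
  if (clamped > 0L) {
    message(sprintf("neighbor_joining: clamped %d negative branch length(s) to 0",
                    clamped))
  }
  ape::read.tree(text = nwk)
}
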