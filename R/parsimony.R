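#' Fitch parsimony score of a tree on an alignment
#'
#' Sum over alignment columns of the Fitch small-parsimony change counts.
#' Gaps and `N` are treated as missing (full state set, never forcing a
#' change); IUPAC ambiguity codes contribute their state subsets.
#' Multifurcations (e.g. the unrooted trifurcated root) are combined
#' child-by-child in edge order.
#'
#' @param tree an [ape::phylo]; tip labels must match the alignment taxa.
#' @param alignment an `its_alignment`.
#' @param weights optional per-column integer weights (default 1).
#' @return integer parsimony score.
#' @export
fitch_score <- function(tree, alignment, weights = NULL) {
  mat <- alignment$mat
  fail_if(!all(tree$tip.label %in% rownames(mat)),
          "tree tips not all present in alignment")
  fail_if(!all(rownames(mat) %in% tree$tip.label),
          "alignment taxa not all present in tree")
  L <- ncol(mat)
  if (is.null(weights)) weights <- rep(1L, L)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  masks <- matrix(0L, ntip + nnode, L)
  for (i in seq_len(ntip)) {
    ch <- mat[tree$tip.label[i], ]
    m <- unname(IUPAC_MASK[ch])
    m[is.na(m) | ch == "-"] <- 15L
    masks[i, ] <- m
  }
  seen <- logical(ntip + nnode)
  score <- 0
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    cm <- masks[ch, ]
    if (!seen[p]) {
      masks[p, ] <- cm
      seen[p] <- TRUE
    } else {
      inter <- bitwAnd(masks[p, ], cm)
      empty <- inter == 0L
      score <- score + sum(weights[empty])
      masks[p, ] <- ifelse(empty, bitwOr(masks[p, ], cm), inter)
    }
  }
  as.integer(score)
}

#' Maximum-parsimony tree search by NNI hill climbing
#'
#' Starts from the neighbor-joining tree (or a supplied start topology) and
#' repeatedly scans all nearest-neighbor-interchange rearrangements in a
#' deterministic order, accepting the first neighbor attaining the best
#' strictly-improving score, until no rearrangement improves the Fitch
#' score. Branch lengths are not estimated (topology only).
#'
#' @param alignment an `its_alignment` of >= 4 taxa.
#' @param start optional starting [ape::phylo]; default: NJ on the K2P
#'   distance matrix (pairwise deletion).
#' @return an [ape::phylo] topology with attribute `score` (Fitch score).
#' @export
mp_search <- function(alignment, start = NULL) {
  fail_if(length(alignment$taxa) < 4L, "need >= 4 taxa")
  if (is.null(start)) {
    ## NJ start on K2P distances; p-distances when K2P saturates (the start
    ## tree only seeds the hill climb, so any finite distances will do)
    D <- suppressWarnings(k2p_distance_matrix(alignment, "pairwise"))
    if (any(is.nan(D))) D <- p_distance_matrix(alignment)
    start <- neighbor_joining(D)
  }
  cur <- ape::unroot(start)
  cur$edge.length <- NULL
  cur_score <- fitch_score(cur, alignment)
  repeat {
    neighbors <- phangorn::nni(cur)
    scores <- vapply(neighbors, fitch_score, integer(1), alignment = alignment)
    best <- min(scores)
    if (best >= cur_score) break
    cur <- neighbors[[which(scores == best)[1L]]]
    cur_score <- best
  }
  attr(cur, "score") <- cur_score
  cur
}
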