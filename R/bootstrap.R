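#' Nontrivial bipartitions of a tree
#'
#' Each internal edge of an unrooted tree splits the taxa in two; a split is
#' canonicalized as the sorted member list of the side containing the
#' alphabetically first taxon, collapsed to a single key string. Trivial
#' splits (single taxon or its complement) are excluded.
#'
#' @param tree an [ape::phylo].
#' @return character vector of canonical split keys.
#' @export
tree_bipartitions <- function(tree) {
  labels <- tree$tip.label
  n <- length(labels)
  anchor <- sort(labels)[1L]
  parts <- ape::prop.part(tree)
  keys <- vapply(seq_along(parts), function(k) {
    side <- labels[parts[[k]]]
    if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
    if (!anchor %in% side) side <- setdiff(labels, side)
    paste(sort(side), collapse = ";")
  }, character(1))
  unique(keys[!is.na(keys)])
}

split_key <- function(taxa, all_labels) {
  anchor <- sort(all_labels)[1L]
  if (!anchor %in% taxa) taxa <- setdiff(all_labels, taxa)
  paste(sort(taxa), collapse = ";")
}

#' Nonparametric bootstrap support for a tree
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate with the chosen builder, and reports for each nontrivial
#' bipartition of the point-estimate tree the percentage of successful
#' replicates containing it. Supports are attached as integer internal-node
#' labels.
#'
#' @param alignment an `its_alignment`.
#' @param builder `"nj"` (neighbor-joining on K2P distances) or `"mp"`
#'   (Fitch/NNI parsimony search).
#' @param B number of replicates (>= 1).
#' @param seed integer seed; resampling is reproducible given the seed.
#' @param deletion deletion policy for the K2P matrices.
#' @param point optional precomputed point-estimate tree.
#' @return the point tree with `node.label` support percentages and
#'   attributes `supports` (data.frame: split, support) and
#'   `replicates_used`.
#' @export
bootstrap_tree <- function(alignment, builder = c("nj", "mp"), B = 1000L,
                           seed = 1L, deletion = c("pairwise", "complete"),
                           point = NULL) {
  builder <- match.arg(builder)
  deletion <- match.arg(deletion)
  fail_if(B < 1L, "B must be >= 1")
  build <- function(aln) {
    if (builder == "nj") {
      neighbor_joining(k2p_distance_matrix(aln, deletion))
    } else {
      mp_search(aln)
    }
  }
  if (is.null(point)) point <- build(alignment)
  keys <- tree_bipartitions(point)
  counts <- setNames(numeric(length(keys)), keys)
  L <- ncol(alignment$mat)
  set.seed(seed)
  used <- 0L
  failed <- 0L
  for (b in seq_len(B)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- its_alignment(alignment$mat[, cols, drop = FALSE])
    tr <- tryCatch(suppressWarnings(suppressMessages(build(rep_aln))),
                   error = function(e) NULL)
    if (is.null(tr)) { failed <- failed + 1L; next }
    used <- used + 1L
    rk <- tree_bipartitions(tr)
    hit <- keys %in% rk
    counts[hit] <- counts[hit] + 1
  }
  if (failed > 0L) {
    warning(sprintf("%d of %d bootstrap replicates failed and were skipped",
                    failed, B), call. = FALSE)
  }
  fail_if(used == 0L, "all bootstrap replicates failed")
  supports <- round(100 * counts / used)
  point <- annotate_supports(point, supports)
  attr(point, "supports") <- data.frame(split = names(supports),
                                        support = unname(supports))
  attr(point, "replicates_used") <- used
  point
}

## Write support values onto internal-node labels of the point tree.
annotate_supports <- function(tree, supports) {
  labels <- tree$tip.label
  n <- length(labels)
  parts <- ape::prop.part(tree)
  node.label <- character(tree$Nnode)
  for (k in seq_along(parts)) {
    side <- labels[parts[[k]]]
    if (length(side) < 2L || length(side) > n - 2L) { node.label[k] <- ""; next }
    key <- split_key(side, labels)
    node.label[k] <- if (key %in% names(supports))
      as.character(supports[[key]]) else ""
  }
  tree$node.label <- node.label
  tree
}

#' Root a tree on its out-group
#'
#' Places the root on the out-group's pendant edge.
#'
#' @param tree an [ape::phylo].
#' @param outgroup tip label.
#' @return rooted [ape::phylo].
#' @export
root_on_outgroup <- function(tree, outgroup) {
  fail_if(!outgroup %in% tree$tip.label, "out-group '%s' not in tree", outgroup)
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Newick I/O
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()]; supports are
#' written as internal-node labels and branch lengths after colons.
#'
#' @param tree an [ape::phylo].
#' @param path file path, or `NULL` to return the Newick string.
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @param x file path or Newick string (detected by the trailing `;`).
#' @export
read_newick <- function(x) {
  if (length(x) == 1L && !grepl(";", x) && file.exists(x)) {
    return(ape::read.tree(x))
  }
  ape::read.tree(text = x)
}

#' Test whether two taxa are sisters (form a cherry) in a tree
#'
#' @param tree an [ape::phylo].
#' @param a,b tip labels.
#' @return logical.
#' @export
are_sisters <- function(tree, a, b) {
  key <- split_key(c(a, b), tree$tip.label)
  key %in% tree_bipartitions(tree)
}
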