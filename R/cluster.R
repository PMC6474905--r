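#' Block (Manhattan) distance between feature vectors
#'
#' Sum of absolute coordinate differences, optionally after per-feature
#' min-max scaling (supply the dataset-wide `mins`/`ranges`).
#'
#' @param u,v equal-length numeric vectors.
#' @param scaling optional `list(mins =, ranges =)` from
#'   [minmax_scaling()]; default no scaling.
#' @return non-negative real.
#' @export
block_distance <- function(u, v, scaling = NULL) {
  fail_if(length(u) != length(v), "vectors differ in length (%d vs %d)",
          length(u), length(v))
  if (!is.null(scaling)) {
    u <- (u - scaling$mins) / scaling$ranges
    v <- (v - scaling$mins) / scaling$ranges
  }
  sum(abs(u - v))
}

#' Per-feature min-max scaling parameters for a feature matrix
#'
#' Constant features get range 1 so they contribute zero after scaling.
#'
#' @param X numeric matrix (observations x features).
#' @return `list(mins, ranges)`.
#' @export
minmax_scaling <- function(X) {
  mins <- apply(X, 2, min)
  ranges <- apply(X, 2, max) - mins
  ranges[ranges == 0] <- 1
  list(mins = mins, ranges = ranges)
}

#' Agglomerative clustering with Block distance and between-groups linkage
#'
#' Average linkage ("between-groups linkage"): the distance between two
#' clusters is the mean of all cross-pair Block distances. Ties are broken
#' deterministically by the smallest original leaf index among the
#' candidate pair. Merge heights are non-decreasing.
#'
#' @param X numeric matrix (>= 2 rows; rownames are leaf labels).
#' @param scaling `"none"` (default: raw degrees/bp/counts) or `"minmax"`.
#' @return object of class `bg_dendrogram`: list with `merge` (hclust-style
#'   matrix), `height`, `labels`, `members` (leaf index sets per step),
#'   `linkage`, `distance`.
#' @export
between_groups_cluster <- function(X, scaling = c("none", "minmax")) {
  scaling <- match.arg(scaling)
  fail_if(!is.matrix(X) || nrow(X) < 2L, "need a matrix of >= 2 feature vectors")
  n <- nrow(X)
  labels <- rownames(X) %||% paste0("v", seq_len(n))
  sc <- if (scaling == "minmax") minmax_scaling(X) else NULL
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- block_distance(X[i, ], X[j, ], sc)
  }
  active <- seq_len(n)
  id <- -seq_len(n)                    # hclust convention: negative = leaf
  members <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  step_members <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    m <- length(active)
    best <- Inf; pick <- NULL
    for (ai in 1:(m - 1)) for (aj in (ai + 1):m) {
      i <- active[ai]; j <- active[aj]
      d <- D[i, j]
      if (d < best - 1e-12) {
        best <- d; pick <- c(i, j)
      } else if (abs(d - best) <= 1e-12) {
        key_new <- sort(c(min(members[[i]]), min(members[[j]])))
        key_old <- sort(c(min(members[[pick[1]]]), min(members[[pick[2]]])))
        if (key_new[1] < key_old[1] ||
            (key_new[1] == key_old[1] && key_new[2] < key_old[2])) {
          pick <- c(i, j)
        }
      }
    }
    i <- pick[1]; j <- pick[2]
    height[s] <- D[i, j]
    merge[s, ] <- c(id[i], id[j])
    others <- setdiff(active, c(i, j))
    for (k in others) {
      D[i, k] <- D[k, i] <- (sizes[i] * D[i, k] + sizes[j] * D[j, k]) /
        (sizes[i] + sizes[j])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    step_members[[s]] <- sort(members[[i]])
    sizes[i] <- sizes[i] + sizes[j]
    id[i] <- s
    active <- setdiff(active, j)
  }
  structure(list(merge = merge, height = height, labels = labels,
                 members = step_members, linkage = "average",
                 distance = "manhattan", scaling = scaling),
            class = "bg_dendrogram")
}

#' @export
print.bg_dendrogram <- function(x, ...) {
  cat(sprintf("<bg_dendrogram> %d leaves, %s linkage, %s distance (scaling: %s)\n",
              length(x$labels), x$linkage, x$distance, x$scaling))
  invisible(x)
}

#' @export
as.hclust.bg_dendrogram <- function(x, ...) {
  ## leaf order by recursive left-to-right traversal
  ord <- integer(0)
  walk <- function(node) {
    if (node < 0L) ord <<- c(ord, -node)
    else { walk(x$merge[node, 1]); walk(x$merge[node, 2]) }
  }
  walk(nrow(x$merge))
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = x$labels, method = x$linkage,
                 dist.method = x$distance, call = match.call()),
            class = "hclust")
}

#' Serialize a dendrogram as ultrametric Newick
#'
#' A node merged at height `h` places its two children at depth `h / 2`
#' (so two leaves merged at height `h` become `(A:h/2,B:h/2);`).
#'
#' @param dendro a `bg_dendrogram`.
#' @param path optional file; when `NULL` the Newick string is returned.
#' @return Newick string (invisibly, the path when writing to file).
#' @export
dendrogram_to_newick <- function(dendro, path = NULL) {
  fmt <- function(node) {
    if (node < 0L) return(list(label = dendro$labels[-node], h = 0))
    a <- fmt(dendro$merge[node, 1])
    b <- fmt(dendro$merge[node, 2])
    h <- dendro$height[node]
    list(label = sprintf("(%s:%.10g,%s:%.10g)", a$label, (h - a$h) / 2,
                         b$label, (h - b$h) / 2),
         h = h)
  }
  nwk <- paste0(fmt(nrow(dendro$merge))$label, ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(path)
}

#' Write the merge history as a tab-separated table
#'
#' @param dendro a `bg_dendrogram`.
#' @param path output file.
#' @export
write_merge_table <- function(dendro, path) {
  tab <- data.frame(step = seq_along(dendro$height),
                    height = dendro$height,
                    members = vapply(dendro$members, function(m) {
                      paste(dendro$labels[m], collapse = ",")
                    }, character(1)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
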