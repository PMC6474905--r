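## Independent brute-force oracles used across tests. These enumerate the
## solution space directly and never share code with the implementation.

## All global alignments of a vs b, affine gap cost open + (L-1) * ext.
brute_align_score <- function(a, b, match, mismatch, gap_open, gap_extend) {
  if (length(a) == 1L) a <- strsplit(a, "")[[1]]
  if (length(b) == 1L) b <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == b[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= length(a)) {
      best <- max(best, (if (last == "X") gap_extend else gap_open) +
                    rec(i + 1L, j, "X"))
    }
    if (j <= length(b)) {
      best <- max(best, (if (last == "Y") gap_extend else gap_open) +
                    rec(i, j + 1L, "Y"))
    }
    best
  }
  rec(1L, 1L, "M")
}

## Maximum number of nested base pairs (min hairpin loop 3) by recursion.
brute_max_pairs <- function(seq) {
  if (length(seq) == 1L) seq <- strsplit(seq, "")[[1]]
  seq[seq == "T"] <- "U"
  can <- function(x, y) paste0(x, y) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  rec <- function(i, j) {
    if (j - i < 4L) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + 4L):j) {
      if (can(seq[i], seq[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) +
                      (if (k < j) rec(k + 1L, j) else 0L))
      }
    }
    best
  }
  rec(1L, length(seq))
}

## Minimum Fitch score over all unrooted topologies on the alignment's taxa.
brute_min_parsimony <- function(alignment) {
  taxa <- alignment$taxa
  topos <- phangorn::allTrees(length(taxa), rooted = FALSE, tip.label = taxa)
  scores <- vapply(topos, fitch_score, integer(1), alignment = alignment)
  list(score = min(scores), trees = topos[scores == min(scores)])
}

## A simple four-hairpin ITS2-like dot-bracket structure built by hand.
toy_four_helix <- function(stems = c(4L, 4L, 4L, 4L),
                           spacers = c(0L, 0L, 0L, 0L)) {
  arm <- function(z) paste0(strrep("(", z), "AAA", strrep(")", z))
  body <- paste0(arm(stems[1]), strrep("A", spacers[1]),
                 arm(stems[2]), strrep("A", spacers[2]),
                 arm(stems[3]), strrep("A", spacers[3]),
                 arm(stems[4]), strrep("A", spacers[4]))
  chars <- strsplit(body, "")[[1]]
  seq <- ifelse(chars == "(", "G", ifelse(chars == ")", "C", "A"))
  db <- ifelse(chars %in% c("(", ")"), chars, ".")
  secondary_structure(paste(seq, collapse = ""), paste(db, collapse = ""))
}
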