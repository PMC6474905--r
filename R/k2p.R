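#' Transition/transversion site patterns between two aligned rows
#'
#' Sites where either row carries a gap or an ambiguity code are skipped
#' (pairwise deletion). `P` is the proportion of compared sites differing by
#' a transition (A<->G, C<->T), `Q` the proportion differing by a
#' transversion.
#'
#' @param rowA,rowB equal-length gapped character vectors (or strings).
#' @return list with `n` (compared sites), `P`, `Q`.
#' @export
site_patterns <- function(rowA, rowB) {
  if (length(rowA) == 1L) rowA <- strsplit(rowA, "")[[1]]
  if (length(rowB) == 1L) rowB <- strsplit(rowB, "")[[1]]
  fail_if(length(rowA) != length(rowB), "rows differ in length")
  ok <- rowA %in% BASES & rowB %in% BASES
  n <- sum(ok)
  fail_if(n == 0L, "no comparable sites")
  a <- rowA[ok]; b <- rowB[ok]
  diff <- a != b
  purine <- c("A", "G")
  ts <- diff & ((a %in% purine) == (b %in% purine))
  list(n = n, P = sum(ts) / n, Q = sum(diff & !ts) / n)
}

#' Kimura 2-parameter distance
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`, defined while
#' `1 - 2P - Q > 0` and `1 - 2Q > 0`.
#'
#' @param P,Q observed transition and transversion proportions.
#' @return the distance `d`.
#' @export
k2p <- function(P, Q) {
  fail_if(P < 0 || Q < 0 || P + Q > 1, "invalid proportions")
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  fail_if(w1 <= 0 || w2 <= 0, "K2P undefined (saturation)")
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise K2P distance matrix from an alignment
#'
#' @param alignment an `its_alignment`.
#' @param deletion `"pairwise"` (default): sites with a gap/ambiguity in the
#'   compared pair are skipped per pair; `"complete"`: columns with a gap or
#'   ambiguity in *any* row are removed once for all pairs.
#' @return symmetric numeric matrix (taxa x taxa); saturated or incomparable
#'   pairs become `NaN` with a warning.
#' @export
k2p_distance_matrix <- function(alignment, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  mat <- alignment$mat
  fail_if(nrow(mat) < 2L, "need >= 2 rows")
  if (deletion == "complete") {
    keep <- apply(mat, 2, function(col) all(col %in% BASES))
    fail_if(!any(keep), "no complete columns")
    mat <- mat[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  bad <- character(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- tryCatch({
      sp <- site_patterns(mat[i, ], mat[j, ])
      k2p(sp$P, sp$Q)
    }, error = function(e) {
      bad <<- c(bad, sprintf("%s-%s (%s)", rownames(mat)[i], rownames(mat)[j],
                             conditionMessage(e)))
      NaN
    })
    D[i, j] <- D[j, i] <- d
  }
  if (length(bad)) {
    warning("inestimable pairs set to NaN: ", paste(bad, collapse = "; "),
            call. = FALSE)
  }
  D
}

## Observed-proportion (p) distances with pairwise deletion; always finite.
p_distance_matrix <- function(alignment) {
  mat <- alignment$mat
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- mat[i, ] %in% BASES & mat[j, ] %in% BASES
    D[i, j] <- D[j, i] <- if (any(ok)) mean(mat[i, ok] != mat[j, ok]) else 0
  }
  D
}

#' Parse a printed lower-triangular distance matrix
#'
#' Accepts the text layout of a printed pairwise-distance table: one row per
#' taxon, `row k` carrying `k - 1` entries; a leading integer index and/or a
#' non-numeric name token may precede the numbers. Comment lines start with
#' `#`.
#'
#' @param x a file path or a character vector of lines.
#' @return symmetric numeric matrix with taxon names (or `t<No>` labels)
#'   as dimnames.
#' @export
parse_printed_matrix <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else x
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fail_if(length(lines) == 0L, "empty matrix input")
  n <- length(lines)
  names <- character(n)
  D <- matrix(0, n, n)
  for (k in seq_len(n)) {
    tok <- strsplit(lines[k], "[\\s,]+", perl = TRUE)[[1]]
    is_num <- grepl("^[0-9]*\\.[0-9]+$", tok)
    ## leading integer index and/or name token(s)
    lead <- tok[!is_num]
    vals <- as.numeric(tok[is_num])
    nm <- lead[!grepl("^[0-9]+$", lead)]
    names[k] <- if (length(nm)) nm[1] else paste0("t", k)
    fail_if(length(vals) != k - 1L,
            "row %d has %d entries, expected %d", k, length(vals), k - 1L)
    if (k > 1L) {
      D[k, 1:(k - 1L)] <- vals
      D[1:(k - 1L), k] <- vals
    }
  }
  dimnames(D) <- list(names, names)
  D
}

#' Distance matrix I/O
#'
#' Square tab-separated table (`write_distance_tsv`) and PHYLIP distance
#' format (`write_distance_phylip` / `read_distance_phylip`).
#'
#' @param D symmetric numeric matrix with dimnames.
#' @param path file path.
#' @param digits decimals for the TSV presentation (full precision if `NA`).
#' @export
write_distance_tsv <- function(D, path, digits = NA) {
  out <- if (is.na(digits)) D else round_half_up(D, digits)
  utils::write.table(format(out, trim = TRUE), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
write_distance_phylip <- function(D, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    writeLines(paste(formatC(rownames(D)[i], width = -10),
                     paste(sprintf("%.6f", D[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1]))
  rows <- lapply(lines[1 + seq_len(n)], function(l) strsplit(trimws(l), "\\s+")[[1]])
  D <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  dimnames(D) <- list(vapply(rows, `[`, character(1), 1),
                      vapply(rows, `[`, character(1), 1))
  D
}
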