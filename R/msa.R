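#' Alignment container
#'
#' Rows are equal-length gapped sequences over the IUPAC alphabet plus `-`;
#' de-gapping row *i* reproduces input sequence *i*.
#'
#' @param mat character matrix (taxa x columns) of single characters.
#' @param taxa taxon ids (defaults to rownames).
#' @return object of class `its_alignment`.
#' @export
its_alignment <- function(mat, taxa = rownames(mat)) {
  fail_if(is.null(taxa) || any(!nzchar(taxa)), "alignment taxa must be named")
  fail_if(anyDuplicated(taxa) > 0L, "duplicate taxa in alignment")
  rownames(mat) <- taxa
  structure(list(taxa = taxa, mat = mat), class = "its_alignment")
}

#' @export
print.its_alignment <- function(x, ...) {
  cat(sprintf("<its_alignment> %d taxa x %d columns\n",
              length(x$taxa), ncol(x$mat)))
  invisible(x)
}

#' @export
dim.its_alignment <- function(x) dim(x$mat)

degap_row <- function(aln, i) {
  r <- aln$mat[i, ]
  r[r != "-"]
}

as_base_vector <- function(x, id = "<sequence>") {
  if (inherits(x, "its_record")) return(x$seq)
  check_nucleotides(x, id = id)
}

#' Global pairwise alignment with affine gap costs
#'
#' Needleman-Wunsch over match/mismatch scoring; a gap of length L costs
#' `gap_open + (L - 1) * gap_extend`. Traceback ties prefer diagonal, then
#' up, then left, so the result is deterministic.
#'
#' @param a,b sequences ([its_record()], string, or base vector).
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return `its_alignment` of 2 rows with attribute `score`.
#' @export
pairwise_align <- function(a, b, match = 1, mismatch = -1,
                           gap_open = -4, gap_extend = -1) {
  ida <- if (inherits(a, "its_record")) a$id else "seq1"
  idb <- if (inherits(b, "its_record")) b$id else "seq2"
  av <- as_base_vector(a, ida); bv <- as_base_vector(b, idb)
  fail_if(length(av) == 0L || length(bv) == 0L, "empty sequence")
  S <- seq_score_matrix(av, bv, match, mismatch)
  tb <- nw_traceback(nw_core(S, gap_open, gap_extend, "global"))
  rowa <- ifelse(tb$rows > 0L, av[pmax(tb$rows, 1L)], "-")
  rowb <- ifelse(tb$cols > 0L, bv[pmax(tb$cols, 1L)], "-")
  mat <- rbind(rowa, rowb)
  rownames(mat) <- c(ida, idb)
  out <- its_alignment(mat)
  attr(out, "score") <- tb$score
  out
}

## Column-frequency profile over states A,C,G,T,- ; ambiguity codes carry
## zero weight (neutral in profile scoring).
profile_freq <- function(mat) {
  states <- c(BASES, "-")
  F <- vapply(seq_len(ncol(mat)), function(j) {
    tabulate(match(mat[, j], states), nbins = 5L)
  }, numeric(5))
  F / nrow(mat)
}

profile_score_matrix <- function(match, mismatch, gap_extend) {
  S <- matrix(mismatch, 5, 5, dimnames = list(c(BASES, "-"), c(BASES, "-")))
  diag(S) <- match
  S["-", ] <- gap_extend; S[, "-"] <- gap_extend; S["-", "-"] <- 0
  S
}

merge_profiles <- function(A, B, match, mismatch, gap_open, gap_extend) {
  S5 <- profile_score_matrix(match, mismatch, gap_extend)
  D <- t(profile_freq(A)) %*% S5 %*% profile_freq(B)
  tb <- nw_traceback(nw_core(D, gap_open, gap_extend, "global"))
  n <- length(tb$rows)
  out <- matrix("-", nrow(A) + nrow(B), n)
  ia <- tb$rows > 0L; ib <- tb$cols > 0L
  out[seq_len(nrow(A)), ia] <- A[, tb$rows[ia], drop = FALSE]
  out[nrow(A) + seq_len(nrow(B)), ib] <- B[, tb$cols[ib], drop = FALSE]
  rownames(out) <- c(rownames(A), rownames(B))
  out
}

#' Progressive multiple sequence alignment
#'
#' ClustalW-style progressive alignment: all pairwise alignments give K2P
#' guide distances, a neighbor-joining guide tree fixes the merge order, and
#' profiles are merged by profile-profile dynamic programming with affine
#' gaps. Deterministic given input order.
#'
#' @param records list of >= 2 [its_record()]s (or named sequences).
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return `its_alignment`; original records kept in attribute `records`.
#' @export
progressive_msa <- function(records, match = 1, mismatch = -1,
                            gap_open = -4, gap_extend = -1) {
  fail_if(length(records) < 2L, "progressive_msa needs >= 2 records")
  n <- length(records)
  seqs <- lapply(seq_len(n), function(i) as_base_vector(records[[i]], paste0("record ", i)))
  ids <- vapply(seq_len(n), function(i) {
    if (inherits(records[[i]], "its_record")) records[[i]]$id
    else names(records)[i] %||% paste0("seq", i)
  }, character(1))
  fail_if(anyDuplicated(ids) > 0L, "duplicate ids: %s", ids[duplicated(ids)][1])
  if (n == 2L) {
    aln <- pairwise_align(records[[1]], records[[2]], match, mismatch,
                          gap_open, gap_extend)
    rownames(aln$mat) <- ids
    aln$taxa <- ids
    attr(aln, "records") <- records
    return(aln)
  }
  ## guide distances: K2P on pairwise alignments (p-distance fallback at
  ## saturation so the guide tree always exists)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pa <- pairwise_align(seqs[[i]], seqs[[j]], match, mismatch,
                         gap_open, gap_extend)
    sp <- site_patterns(pa$mat[1, ], pa$mat[2, ])
    d <- tryCatch(k2p(sp$P, sp$Q), error = function(e) 3 * (sp$P + sp$Q))
    D[i, j] <- D[j, i] <- d
  }
  merges <- nj_merge_order(D)
  profiles <- lapply(seq_len(n), function(i) {
    m <- matrix(seqs[[i]], 1); rownames(m) <- ids[i]; m
  })
  for (mg in merges) {
    a <- mg[1]; b <- mg[2]
    profiles[[a]] <- merge_profiles(profiles[[a]], profiles[[b]],
                                    match, mismatch, gap_open, gap_extend)
    profiles[b] <- list(NULL)
  }
  live <- which(!vapply(profiles, is.null, logical(1)))
  acc <- profiles[[live[1]]]
  for (k in live[-1]) {
    acc <- merge_profiles(acc, profiles[[k]], match, mismatch,
                          gap_open, gap_extend)
  }
  acc <- acc[match(ids, rownames(acc)), , drop = FALSE]  # input order
  out <- its_alignment(acc)
  attr(out, "records") <- records
  out
}

## NJ agglomeration order on a distance matrix: list of index pairs
## (surviving cluster slot, absorbed slot), the same join sequence the
## neighbor-joining tree construction performs.
nj_merge_order <- function(D) {
  n <- nrow(D)
  active <- seq_len(n)
  merges <- list()
  while (length(active) > 2L) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    R <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(R, R, `+`)
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    pick <- idx[order(idx[, 1], idx[, 2])[1], ]
    i <- active[pick[1]]; j <- active[pick[2]]
    merges[[length(merges) + 1L]] <- c(i, j)
    newd <- 0.5 * (D[i, active] + D[j, active] - D[i, j])
    D[i, active] <- newd; D[active, i] <- newd
    D[i, i] <- 0
    active <- setdiff(active, j)
  }
  merges
}

#' Count variable (polymorphic) alignment columns
#'
#' A column is variable iff it contains at least two distinct states among
#' `A, C, G, T` and (by default) the gap `-`; ambiguity codes are ignored.
#' With `mode = "substitutions_only"` gaps are ignored too, so only
#' substitution polymorphism counts.
#'
#' @param alignment an `its_alignment`.
#' @param columns integer vector of column indices (default: all columns).
#' @param mode `"gap_as_state"` (default) or `"substitutions_only"`.
#' @param region optional label carried into the result.
#' @return list: `region`, `n_variable_sites`, `alignment_length`, `percent`
#'   (one decimal, half-up).
#' @export
count_variable_sites <- function(alignment, columns = NULL,
                                 mode = c("gap_as_state", "substitutions_only"),
                                 region = NA_character_) {
  mode <- match.arg(mode)
  mat <- alignment$mat
  fail_if(nrow(mat) == 0L || ncol(mat) == 0L, "empty alignment")
  if (is.null(columns)) columns <- seq_len(ncol(mat))
  fail_if(length(columns) == 0L, "empty column range")
  states <- if (mode == "gap_as_state") c(BASES, "-") else BASES
  nv <- sum(vapply(columns, function(j) {
    s <- mat[, j]
    length(unique(s[s %in% states])) >= 2L
  }, logical(1)))
  list(region = region, n_variable_sites = nv,
       alignment_length = length(columns),
       percent = round_half_up(100 * nv / length(columns), 1))
}

#' Project a partitioned reference row's regions onto alignment columns
#'
#' The designated reference record's ITS1/5.8S/ITS2 partition is projected
#' through its gaps: each region's columns run from the column of its first
#' residue up to the column before the next region's first residue; leading
#' and trailing gap-only columns fall to ITS1 and ITS2 respectively.
#'
#' @param alignment an `its_alignment` whose `records` attribute (or the
#'   `ref_record` argument) provides the partitioned reference.
#' @param ref_id id of the reference row.
#' @param ref_record optionally, the partitioned [its_record()] itself.
#' @return named list of integer column vectors: ITS, ITS1, `5.8S`, ITS2.
#' @export
msa_region_columns <- function(alignment, ref_id, ref_record = NULL) {
  if (is.null(ref_record)) {
    recs <- attr(alignment, "records")
    fail_if(is.null(recs), "alignment carries no records; pass ref_record")
    ids <- vapply(recs, function(r) r$id, character(1))
    fail_if(!ref_id %in% ids, "reference id '%s' not in alignment", ref_id)
    ref_record <- recs[[match(ref_id, ids)]]
  }
  fail_if(is.null(ref_record$regions), "reference record is not partitioned")
  row <- alignment$mat[ref_id, ]
  cols_of_res <- which(row != "-")
  fail_if(length(cols_of_res) != length(ref_record$seq),
          "reference row does not de-gap to the reference sequence")
  rp <- ref_record$regions
  start_58s <- cols_of_res[rp$r58s[1] + 1L]
  start_its2 <- cols_of_res[rp$its2[1] + 1L]
  nc <- ncol(alignment$mat)
  list(ITS = seq_len(nc),
       ITS1 = seq_len(start_58s - 1L),
       `5.8S` = start_58s:(start_its2 - 1L),
       ITS2 = start_its2:nc)
}

#' Alignment I/O: aligned FASTA and relaxed PHYLIP
#'
#' @param alignment an `its_alignment`.
#' @param path file path.
#' @return `read_alignment_fasta`/`read_alignment_phylip` return an
#'   `its_alignment`; writers return `path` invisibly.
#' @export
write_alignment_fasta <- function(alignment, path) {
  seqinr::write.fasta(lapply(seq_along(alignment$taxa),
                             function(i) alignment$mat[i, ]),
                      names = alignment$taxa, file.out = path, nbchar = 70)
  invisible(path)
}

#' @rdname write_alignment_fasta
#' @export
read_alignment_fasta <- function(path) {
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                           whole.header = TRUE)
  fail_if(length(fa) == 0L, "empty FASTA: %s", path)
  rows <- lapply(fa, function(s) strsplit(toupper(as.character(s)), "")[[1]])
  lens <- vapply(rows, length, integer(1))
  fail_if(length(unique(lens)) != 1L, "rows are not equal length")
  mat <- do.call(rbind, rows)
  rownames(mat) <- unname(vapply(names(fa),
                                 function(h) parse_fasta_header(h)$id,
                                 character(1)))
  its_alignment(mat)
}

#' @rdname write_alignment_fasta
#' @export
write_alignment_phylip <- function(alignment, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d", length(alignment$taxa), ncol(alignment$mat)), con)
  for (i in seq_along(alignment$taxa)) {
    writeLines(paste(alignment$taxa[i],
                     paste(alignment$mat[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' @rdname write_alignment_fasta
#' @export
read_alignment_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  mat <- do.call(rbind, lapply(rows, function(r) strsplit(toupper(r[2]), "")[[1]]))
  rownames(mat) <- vapply(rows, `[`, character(1), 1)
  fail_if(nrow(mat) != hdr[1] || ncol(mat) != hdr[2],
          "PHYLIP header does not match data")
  its_alignment(mat)
}
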