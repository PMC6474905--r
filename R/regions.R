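#' Region partition of an ITS amplicon
#'
#' Intervals are 0-based half-open on the (trimmed) sequence and must tile it
#' contiguously in the order ITS1, 5.8S, ITS2.
#'
#' @param its1,r58s,its2 integer length-2 vectors `c(start, end)`.
#' @return an object of class `region_partition`.
#' @export
region_partition <- function(its1, r58s, its2) {
  iv <- list(its1 = as.integer(its1), r58s = as.integer(r58s),
             its2 = as.integer(its2))
  for (nm in names(iv)) {
    fail_if(length(iv[[nm]]) != 2L || iv[[nm]][2] <= iv[[nm]][1],
            "region %s must be a non-empty interval", nm)
  }
  fail_if(iv$its1[2] != iv$r58s[1] || iv$r58s[2] != iv$its2[1],
          "regions must be contiguous and ordered ITS1 < 5.8S < ITS2")
  structure(iv, class = "region_partition")
}

#' Partition an ITS amplicon into ITS1 / 5.8S / ITS2
#'
#' Locates the conserved 5.8S gene by best semi-global alignment of a 5.8S
#' reference against the record; ITS1 is everything 5' of the anchor and
#' ITS2 everything 3' of it. If a primer pair is supplied, flanking
#' 18S/26S tails beyond the primer match positions are trimmed first (the
#' trimmed record is returned in the result).
#'
#' @param record an [its_record()].
#' @param ref58s 5.8S reference: nucleotide string, character vector, or a
#'   FASTA path; defaults to the bundled reference ([ref_5p8s_path()]).
#' @param primers optional `list(fwd =, rev =)` primer sequences (the reverse
#'   primer given 5'->3' on the opposite strand, as ordered).
#' @param min_identity minimum identity of the 5.8S anchor alignment
#'   (matches / reference length), default 0.8.
#' @param match,mismatch,gap_open,gap_extend anchor alignment scoring.
#' @return the record with `$regions` set (and `$seq` trimmed if primers
#'   were given).
#' @export
partition_regions <- function(record, ref58s = NULL, primers = NULL,
                              min_identity = 0.8,
                              match = 1, mismatch = -1,
                              gap_open = -4, gap_extend = -1) {
  fail_if(!inherits(record, "its_record"), "record must be an its_record")
  ref <- load_ref58s(ref58s)
  fail_if(length(ref) < 140L || length(ref) > 190L,
          "5.8S reference length %d outside [140, 190]", length(ref))
  if (!is.null(primers)) {
    record <- trim_primer_tails(record, primers, match, mismatch,
                                gap_open, gap_extend)
  }
  seq <- record$seq
  S <- seq_score_matrix(ref, seq, match, mismatch)
  dp <- nw_core(S, gap_open, gap_extend, "anchor")
  tb <- nw_traceback(dp)
  matched <- tb$cols > 0L & tb$rows > 0L
  fail_if(!any(matched), "5.8S anchor not found (no aligned columns)")
  identity <- sum(ref[tb$rows[matched]] == seq[tb$cols[matched]]) / length(ref)
  fail_if(identity < min_identity,
          "5.8S anchor not found (best identity %.2f < %.2f)",
          identity, min_identity)
  a_start <- min(tb$cols[matched]) - 1L  # 0-based
  a_end <- max(tb$cols[matched])         # half-open
  fail_if(a_start == 0L, "ITS1 has length 0 (5.8S anchor at sequence start)")
  fail_if(a_end == length(seq), "ITS2 has length 0 (5.8S anchor at sequence end)")
  record$regions <- region_partition(c(0L, a_start), c(a_start, a_end),
                                     c(a_end, length(seq)))
  record
}

load_ref58s <- function(ref58s) {
  if (is.null(ref58s)) ref58s <- ref_5p8s_path()
  if (length(ref58s) == 1L && file.exists(ref58s)) {
    return(read_its_fasta(ref58s)[[1]]$seq)
  }
  check_nucleotides(ref58s, id = "5.8S reference")
}

## Trim bases outside the primer-annealing footprint: everything 5' of the
## forward primer's match start and 3' of the reverse primer's match end.
trim_primer_tails <- function(record, primers, match, mismatch,
                              gap_open, gap_extend) {
  fail_if(!all(c("fwd", "rev") %in% names(primers)),
          "primers must be list(fwd =, rev =)")
  seq <- record$seq
  fwd <- check_nucleotides(primers$fwd, id = "fwd primer")
  rev <- revcomp(check_nucleotides(primers$rev, id = "rev primer"))
  loc_f <- anchor_span(fwd, seq, match, mismatch, gap_open, gap_extend)
  loc_r <- anchor_span(rev, seq, match, mismatch, gap_open, gap_extend)
  fail_if(loc_r[2] <= loc_f[1], "primer matches out of order")
  record$seq <- seq[(loc_f[2] + 1L):loc_r[1]]  # interior of the amplicon
  record
}

anchor_span <- function(probe, seq, match, mismatch, gap_open, gap_extend) {
  S <- seq_score_matrix(probe, seq, match, mismatch)
  tb <- nw_traceback(nw_core(S, gap_open, gap_extend, "anchor"))
  matched <- tb$cols > 0L & tb$rows > 0L
  fail_if(!any(matched), "primer not found")
  c(min(tb$cols[matched]) - 1L, max(tb$cols[matched]))  # 0-based half-open
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
                W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
                N = "N")

revcomp <- function(seq) unname(COMPLEMENT[rev(seq)])

#' Per-region length and GC statistics
#'
#' GC is computed over unambiguous bases only (ambiguity codes excluded from
#' numerator and denominator) as `100 * (G + C) / (A + C + G + T)`, rounded
#' half-up to one decimal; `ITS` is the concatenation of the three regions.
#'
#' @param record a partitioned [its_record()] (see [partition_regions()]).
#' @param ambiguity_fractional if `TRUE`, IUPAC ambiguity codes contribute
#'   fractionally (e.g. S counts as 1 GC, R as 0.5) instead of being excluded.
#' @return list with `lengths` and `gc`, each named over
#'   `c("ITS", "ITS1", "5.8S", "ITS2")`.
#' @export
region_stats <- function(record, ambiguity_fractional = FALSE) {
  fail_if(is.null(record$regions), "record '%s' has no region partition", record$id)
  rp <- record$regions
  pieces <- list(ITS1 = record$seq[(rp$its1[1] + 1L):rp$its1[2]],
                 `5.8S` = record$seq[(rp$r58s[1] + 1L):rp$r58s[2]],
                 ITS2 = record$seq[(rp$its2[1] + 1L):rp$its2[2]])
  pieces <- c(list(ITS = unlist(pieces, use.names = FALSE)), pieces)
  lengths <- vapply(pieces, length, integer(1))
  gc <- vapply(names(pieces), function(nm) {
    x <- pieces[[nm]]
    if (ambiguity_fractional) {
      gc_w <- c(A = 0, C = 1, G = 1, T = 0, R = 0.5, Y = 0.5, S = 1, W = 0,
                K = 0.5, M = 0.5, B = 2 / 3, D = 1 / 3, H = 1 / 3, V = 2 / 3,
                N = 0.5)
      num <- sum(gc_w[x]); den <- length(x)
    } else {
      num <- sum(x %in% c("G", "C")); den <- sum(x %in% BASES)
    }
    fail_if(den == 0, "region %s of '%s' contains only ambiguity codes",
            nm, record$id)
    unname(round_half_up(100 * num / den, 1))
  }, numeric(1))
  list(lengths = lengths, gc = gc)
}

#' Summarize region statistics by section
#'
#' Length ranges (min/max) and mean GC per region within each section.
#' Means are computed on unrounded GC values and rounded half-up to one
#' decimal, mirroring the way per-section averages are reported.
#'
#' @param records list of partitioned [its_record()]s.
#' @param ambiguity_fractional passed to [region_stats()].
#' @return data.frame with one row per (section, region): n, min/max length,
#'   mean GC.
#' @export
summarize_sections <- function(records, ambiguity_fractional = FALSE) {
  fail_if(length(records) == 0L, "no records")
  stats <- lapply(records, region_stats, ambiguity_fractional = ambiguity_fractional)
  sections <- vapply(records, function(r) r$section, character(1))
  regions <- c("ITS", "ITS1", "5.8S", "ITS2")
  rows <- list()
  for (sec in unique(sections)) {
    idx <- which(sections == sec)
    fail_if(length(idx) == 0L, "empty group %s", sec)
    for (rg in regions) {
      lens <- vapply(idx, function(i) stats[[i]]$lengths[[rg]], numeric(1))
      ## mean on exact (unrounded) GC values
      gcs <- vapply(idx, function(i) {
        exact_gc(records[[i]], rg, ambiguity_fractional)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        section = sec, region = rg, n = length(idx),
        len_min = min(lens), len_max = max(lens),
        gc_mean = round_half_up(mean(gcs), 1))
    }
  }
  do.call(rbind, rows)
}

exact_gc <- function(record, region, ambiguity_fractional = FALSE) {
  rp <- record$regions
  x <- switch(region,
              ITS1 = record$seq[(rp$its1[1] + 1L):rp$its1[2]],
              `5.8S` = record$seq[(rp$r58s[1] + 1L):rp$r58s[2]],
              ITS2 = record$seq[(rp$its2[1] + 1L):rp$its2[2]],
              ITS = record$seq[(rp$its1[1] + 1L):rp$its2[2]])
  num <- sum(x %in% c("G", "C")); den <- sum(x %in% BASES)
  100 * num / den
}

#' Tabulate per-record region statistics
#'
#' One row per record in the column order of the study's presentation:
#' lengths of ITS, 5.8S, ITS1, ITS2, then GC of the same regions.
#'
#' @param records list of partitioned [its_record()]s.
#' @return data.frame.
#' @export
region_stats_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    st <- region_stats(r)
    data.frame(id = r$id, species = r$species, section = r$section,
               len_its = st$lengths[["ITS"]], len_58s = st$lengths[["5.8S"]],
               len_its1 = st$lengths[["ITS1"]], len_its2 = st$lengths[["ITS2"]],
               gc_its = st$gc[["ITS"]], gc_58s = st$gc[["5.8S"]],
               gc_its1 = st$gc[["ITS1"]], gc_its2 = st$gc[["ITS2"]])
  }))
}
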