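#' dendrobarcode: ITS-barcode authentication of Dendrobium species
#'
#' Region partitioning, per-region statistics, progressive alignment,
#' Kimura 2-parameter distances, NJ/MP phylogenies with bootstrap support,
#' ITS2 secondary-structure features and their hierarchical clustering,
#' plus a synthetic-data generator so the whole workflow runs offline.
#'
#' @keywords internal
"_PACKAGE"

## IUPAC nucleotide codes (DNA). Bitmask encoding: A=1, C=2, G=4, T=8.
IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

BASES <- c("A", "C", "G", "T")

#' Round half away from zero ("half-up"), as tables in the field print values
#'
#' `base::round()` rounds half to even; printed tables in this domain use
#' conventional half-up rounding (0.05 -> 0.1 at one decimal).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Validate a nucleotide string; returns uppercase character vector of bases.
## `rna` allows U (converted to T internally when dna_mode = TRUE keeps U out).
check_nucleotides <- function(seq, id = "<sequence>", rna = FALSE) {
  if (length(seq) == 1L) seq <- strsplit(seq, "")[[1]]
  seq <- toupper(seq)
  allowed <- names(IUPAC_MASK)
  if (rna) allowed <- c(allowed, "U")
  bad <- which(!seq %in% allowed)
  if (length(bad) > 0L) {
    stop(sprintf("non-IUPAC character '%s' at position %d in %s",
                 seq[bad[1L]], bad[1L], id), call. = FALSE)
  }
  seq
}

## Collapse a character vector to a string.
seq_string <- function(x) paste(x, collapse = "")

## stopifnot with a formatted message
fail_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
}
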