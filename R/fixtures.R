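#' Packaged study tables
#'
#' `dendrobium_table2()` returns the printed per-species region lengths and
#' GC contents for the 13 study accessions; `dendrobium_table3()` returns
#' the printed 14-taxon K2P distance matrix (13 Dendrobium species plus the
#' out-group *Pholidota yunnanensis*) parsed from its lower-triangular text
#' fixture.
#'
#' @return `dendrobium_table2()`: a data.frame; `dendrobium_table3()`: a
#'   symmetric numeric matrix with taxon names as dimnames.
#' @export
dendrobium_table2 <- function() {
  path <- system.file("extdata", "table2_region_stats.tsv",
                      package = "dendrobarcode", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname dendrobium_table2
#' @export
dendrobium_table3 <- function() {
  path <- system.file("extdata", "table3_k2p_matrix.txt",
                      package = "dendrobarcode", mustWork = TRUE)
  parse_printed_matrix(path)
}

#' Path to the bundled (synthetic) 5.8S anchor reference
#'
#' A 163-nt synthetic 5.8S stand-in at the conserved gene's typical length
#' and GC content, used as the default anchor for [partition_regions()].
#' For real rDNA data, replace it with a true 5.8S reference sequence.
#'
#' @return file path of a single-record FASTA.
#' @export
ref_5p8s_path <- function() {
  system.file("extdata", "ref_5p8s_synthetic.fasta",
              package = "dendrobarcode", mustWork = TRUE)
}
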