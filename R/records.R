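#' ITS sequence records
#'
#' An `its_record` holds one taxon's identifier, species and section labels,
#' and its nucleotide sequence (uppercase, IUPAC alphabet), with an optional
#' region partition attached by [partition_regions()].
#'
#' @param id unique identifier (accession or label).
#' @param seq nucleotide string or character vector of bases.
#' @param species free-text species name.
#' @param section one of `"Formosae"`, `"Chrysotoxae"`, `"outgroup"`,
#'   `"unknown"`.
#' @param rna accept `U` (RNA input); stored as-is.
#' @return an object of class `its_record`.
#' @export
its_record <- function(id, seq, species = NA_character_,
                       section = c("unknown", "Formosae", "Chrysotoxae", "outgroup"),
                       rna = FALSE) {
  section <- match.arg(section)
  fail_if(is.null(id) || !nzchar(id), "record id must be non-empty")
  seq <- check_nucleotides(seq, id = id, rna = rna)
  fail_if(length(seq) == 0L, "sequence for '%s' is empty", id)
  structure(list(id = id, species = species, section = section,
                 seq = seq, regions = NULL),
            class = "its_record")
}

#' @export
print.its_record <- function(x, ...) {
  cat(sprintf("<its_record> %s (%s, %s), %d nt%s\n", x$id,
              ifelse(is.na(x$species), "?", x$species), x$section,
              length(x$seq),
              if (!is.null(x$regions)) ", partitioned" else ""))
  invisible(x)
}

SECTION_LEVELS <- c("Formosae", "Chrysotoxae", "outgroup", "unknown")

parse_fasta_header <- function(header) {
  header <- sub("^>", "", header)
  parts <- strsplit(header, "|", fixed = TRUE)[[1]]
  id <- trimws(parts[1])
  species <- if (length(parts) >= 2) trimws(parts[2]) else NA_character_
  section <- if (length(parts) >= 3) trimws(parts[3]) else "unknown"
  if (!section %in% SECTION_LEVELS) section <- "unknown"
  list(id = id, species = species, section = section)
}

#' Read ITS records from a FASTA file
#'
#' Headers of the form `id|species|section` are parsed into the record's
#' fields; a bare header becomes the id with section `"unknown"`.
#'
#' @param path FASTA file (wrapped or unwrapped, multi-record).
#' @param rna accept `U` residues.
#' @return list of [its_record()] objects in file order.
#' @export
read_its_fasta <- function(path, rna = FALSE) {
  fail_if(!file.exists(path), "file not found: %s", path)
  fail_if(!any(startsWith(readLines(path, warn = FALSE), ">")),
          "empty or invalid FASTA file: %s", path)
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                           whole.header = TRUE)
  ids <- character(0)
  out <- vector("list", length(fa))
  for (k in seq_along(fa)) {
    h <- parse_fasta_header(attr(fa[[k]], "Annot") %||% names(fa)[k])
    fail_if(h$id %in% ids, "duplicate id in FASTA: %s", h$id)
    ids <- c(ids, h$id)
    out[[k]] <- its_record(h$id, as.character(fa[[k]]), species = h$species,
                           section = h$section, rna = rna)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write ITS records to FASTA
#'
#' @param records list of [its_record()].
#' @param path output file.
#' @param width line wrap width.
#' @export
write_its_fasta <- function(records, path, width = 70) {
  headers <- vapply(records, function(r) {
    if (!is.na(r$species) || r$section != "unknown") {
      paste(r$id, ifelse(is.na(r$species), "", r$species), r$section, sep = "|")
    } else r$id
  }, character(1))
  seqinr::write.fasta(lapply(records, function(r) r$seq), names = headers,
                      file.out = path, nbchar = width)
  invisible(path)
}

#' Read ITS records from a GenBank flat file
#'
#' Minimal reader for LOCUS/DEFINITION/FEATURES/ORIGIN blocks. When the
#' feature table annotates ITS1, 5.8S and ITS2 (misc_RNA/rRNA features whose
#' notes or products name the regions), the annotation is attached as the
#' record's region partition; otherwise the record is returned unpartitioned
#' and [partition_regions()] can anchor the 5.8S by alignment.
#'
#' @param path GenBank flat file, possibly multi-record.
#' @return list of [its_record()] objects.
#' @export
read_genbank <- function(path) {
  fail_if(!file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  fail_if(length(lines) == 0L, "empty GenBank file: %s", path)
  starts <- grep("^LOCUS", lines)
  fail_if(length(starts) == 0L, "no LOCUS line found in %s", path)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    block <- lines[starts[k]:ends[k]]
    parse_genbank_block(block)
  })
}

parse_genbank_block <- function(block) {
  acc_line <- grep("^ACCESSION", block, value = TRUE)
  id <- if (length(acc_line)) strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]][1]
        else strsplit(trimws(sub("^LOCUS", "", block[1])), "\\s+")[[1]][1]
  def_line <- grep("^DEFINITION", block, value = TRUE)
  species <- NA_character_
  org_line <- grep("^\\s+ORGANISM", block, value = TRUE)
  if (length(org_line)) species <- trimws(sub("^\\s+ORGANISM", "", org_line[1]))
  ori <- grep("^ORIGIN", block)
  fail_if(length(ori) == 0L, "no ORIGIN block for %s", id)
  seq_lines <- block[(ori[1] + 1L):length(block)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- gsub("[^A-Za-z]", "", paste(seq_lines, collapse = ""))
  rec <- its_record(id, seq, species = species)
  part <- genbank_region_features(block, length(rec$seq))
  if (!is.null(part)) rec$regions <- part
  rec
}

## Extract ITS1/5.8S/ITS2 intervals from a GenBank feature table, if all
## three are annotated contiguously. Returns NULL when unavailable.
genbank_region_features <- function(block, seq_len) {
  feat_rx <- "^\\s{5}(misc_RNA|rRNA)\\s+(<?)(\\d+)\\.\\.(>?)(\\d+)"
  hits <- grep(feat_rx, block)
  if (!length(hits)) return(NULL)
  found <- list()
  for (h in hits) {
    m <- regmatches(block[h], regexec(feat_rx, block[h]))[[1]]
    from <- as.integer(m[4]); to <- as.integer(m[6])
    desc <- tolower(paste(block[seq(h + 1L, min(h + 4L, length(block)))], collapse = " "))
    lbl <- if (grepl("spacer 1|its1|its 1", desc)) "its1"
           else if (grepl("5\\.8", desc)) "r58s"
           else if (grepl("spacer 2|its2|its 2", desc)) "its2"
           else NA_character_
    if (!is.na(lbl)) found[[lbl]] <- c(from - 1L, to)  # to 0-based half-open
  }
  if (!all(c("its1", "r58s", "its2") %in% names(found))) return(NULL)
  region_partition(found$its1, found$r58s, found$its2)
}

#' Fetch the study accessions from GenBank (network helper)
#'
#' Downloads nucleotide records from NCBI efetch and writes them to
#' `dest`. This helper needs network access and is never invoked by the
#' package's tests or analysis drivers; it exists so the accession-based
#' reproduction can be run once on a connected machine, after which the whole
#' pipeline is offline.
#'
#' @param accessions character vector of GenBank accessions; defaults to the
#'   13 study records.
#' @param dest output file path.
#' @param rettype `"fasta"` or `"gb"`.
#' @return `dest`, invisibly.
#' @export
fetch_genbank_its <- function(accessions = dendrobium_accessions()$accession,
                              dest = "dendrobium_its.gb", rettype = "gb") {
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi?",
                "db=nuccore&id=", paste(accessions, collapse = ","),
                "&rettype=", rettype, "&retmode=text")
  utils::download.file(url, dest, quiet = TRUE)
  invisible(dest)
}

#' The 13 study accessions and their species/section labels
#'
#' @return data.frame with columns `no`, `species`, `section`, `accession`.
#' @export
dendrobium_accessions <- function() {
  tab <- dendrobium_table2()
  tab[, c("no", "species", "section", "accession")]
}
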