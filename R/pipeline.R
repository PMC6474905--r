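#' Run the full ITS authentication workflow
#'
#' Orchestrates the end-to-end analysis: read sequences, partition regions,
#' tabulate per-region statistics, align, count variable sites, estimate the
#' K2P distance matrix, build NJ and MP trees with bootstrap support rooted
#' on the out-group, extract ITS2 structure features (from supplied
#' structure files, or the fallback folder applied to each record's ITS2
#' region), and cluster the feature vectors. All artifacts are written under
#' `out_dir`; reruns with the same inputs, config and seed are
#' byte-identical.
#'
#' @param input FASTA path or a list of [its_record()]s.
#' @param outgroup out-group tip label (required; checked before any
#'   computation).
#' @param out_dir output directory (created if missing).
#' @param structures optional named list of `secondary_structure`s or a
#'   directory of Vienna/CT files named `<id>.*`.
#' @param ref58s 5.8S anchor reference (default: bundled).
#' @param bootstrap bootstrap replicates `B` for both tree builders.
#' @param seed integer seed for all stochastic stages.
#' @param deletion K2P deletion policy, `"pairwise"` or `"complete"`.
#' @param scaling feature scaling for clustering, `"none"` or `"minmax"`.
#' @param verbose emit progress via `message()`.
#' @return (invisibly) a list with every intermediate result: records,
#'   stats, alignment, variation, distance matrix, trees, features,
#'   dendrogram, and the paths written.
#' @export
run_pipeline <- function(input, outgroup, out_dir = "its_pipeline_out",
                         structures = NULL, ref58s = NULL,
                         bootstrap = 1000L, seed = 1L,
                         deletion = c("pairwise", "complete"),
                         scaling = c("none", "minmax"),
                         verbose = TRUE) {
  deletion <- match.arg(deletion)
  scaling <- match.arg(scaling)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  records <- stage("input", {
    if (is.character(input)) read_its_fasta(input) else input
  })
  ids <- vapply(records, function(r) r$id, character(1))
  fail_if(!outgroup %in% ids, "out-group label '%s' not among records", outgroup)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  say("partitioning %d records", length(records))
  records <- stage("partition", lapply(records, function(r) {
    if (is.null(r$regions)) partition_regions(r, ref58s) else r
  }))
  stats <- stage("stats", region_stats_table(records))
  paths$stats <- file.path(out_dir, "region_stats.tsv")
  utils::write.table(stats, paths$stats, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  section_summary <- stage("stats", summarize_sections(records))
  paths$section_summary <- file.path(out_dir, "section_summary.tsv")
  utils::write.table(section_summary, paths$section_summary, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  say("aligning")
  aln <- stage("align", progressive_msa(records))
  paths$alignment <- file.path(out_dir, "alignment.fasta")
  write_alignment_fasta(aln, paths$alignment)

  variation <- stage("variation", {
    cols <- msa_region_columns(aln, records[[1]]$id)
    do.call(rbind, lapply(names(cols), function(rg) {
      v <- count_variable_sites(aln, cols[[rg]], region = rg)
      data.frame(region = rg, n_variable = v$n_variable_sites,
                 length = v$alignment_length, percent = v$percent)
    }))
  })
  paths$variation <- file.path(out_dir, "variable_sites.tsv")
  utils::write.table(variation, paths$variation, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  say("estimating K2P distances (%s deletion)", deletion)
  D <- stage("dist", k2p_distance_matrix(aln, deletion))
  paths$distances <- file.path(out_dir, "k2p_matrix.tsv")
  write_distance_tsv(D, paths$distances, digits = 3)
  paths$distances_phylip <- file.path(out_dir, "k2p_matrix.phy")
  write_distance_phylip(D, paths$distances_phylip)

  say("building NJ and MP trees, bootstrap B = %d", bootstrap)
  nj_tree <- stage("tree", bootstrap_tree(aln, "nj", B = bootstrap,
                                          seed = seed, deletion = deletion))
  mp_tree <- stage("tree", bootstrap_tree(aln, "mp", B = bootstrap,
                                          seed = seed + 1L,
                                          deletion = deletion))
  nj_rooted <- stage("tree", root_on_outgroup(nj_tree, outgroup))
  mp_rooted <- stage("tree", root_on_outgroup(mp_tree, outgroup))
  paths$nj <- file.path(out_dir, "nj_tree.nwk")
  paths$mp <- file.path(out_dir, "mp_tree.nwk")
  write_newick(nj_rooted, paths$nj)
  write_newick(mp_rooted, paths$mp)

  say("extracting ITS2 structure features")
  structs <- stage("struct", resolve_structures(structures, records))
  features <- stage("struct", feature_table(structs))
  paths$features <- file.path(out_dir, "its2_features.tsv")
  utils::write.table(data.frame(id = rownames(features), features),
                     paths$features, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  say("clustering feature vectors (%s scaling)", scaling)
  dendro <- stage("cluster", between_groups_cluster(features, scaling))
  paths$dendrogram <- file.path(out_dir, "structure_dendrogram.nwk")
  dendrogram_to_newick(dendro, paths$dendrogram)
  paths$merges <- file.path(out_dir, "structure_merges.tsv")
  write_merge_table(dendro, paths$merges)

  paths$log <- file.path(out_dir, "run_info.txt")
  writeLines(c(
    sprintf("dendrobarcode %s",
            as.character(utils::packageVersion("dendrobarcode"))),
    sprintf("records: %d", length(records)),
    sprintf("outgroup: %s", outgroup),
    sprintf("bootstrap: %d", bootstrap),
    sprintf("seed: %d", seed),
    sprintf("deletion: %s", deletion),
    sprintf("scaling: %s", scaling)), paths$log)

  invisible(list(records = records, stats = stats,
                 section_summary = section_summary, alignment = aln,
                 variation = variation, distances = D,
                 nj = nj_rooted, mp = mp_rooted, features = features,
                 dendrogram = dendro, paths = paths))
}

## Structures argument: NULL -> fold each record's ITS2 with the fallback
## folder; a directory -> parse <id>.* files; else a named list passed on.
resolve_structures <- function(structures, records) {
  ids <- vapply(records, function(r) r$id, character(1))
  if (is.null(structures)) {
    out <- lapply(records, function(r) {
      fail_if(is.null(r$regions), "record '%s' not partitioned", r$id)
      rp <- r$regions
      fold_fallback(r$seq[(rp$its2[1] + 1L):rp$its2[2]])
    })
    names(out) <- ids
    return(out)
  }
  if (is.character(structures) && length(structures) == 1L &&
      dir.exists(structures)) {
    files <- list.files(structures, full.names = TRUE)
    stems <- sub("\\.[^.]*$", "", basename(files))
    out <- lapply(ids, function(id) {
      hit <- which(stems == id)
      fail_if(length(hit) == 0L, "no structure file for '%s'", id)
      parse_structure(files[hit[1]])
    })
    names(out) <- ids
    return(out)
  }
  fail_if(is.null(names(structures)) || !all(ids %in% names(structures)),
          "structures must be named for every record")
  structures[ids]
}

#' Reproduce the study tables from the downloaded accessions
#'
#' Runs the accession-based reproduction: reads the 13 GenBank records
#' (fetched once with [fetch_genbank_its()]), partitions them, and returns
#' the per-region statistics, the progressive alignment, per-section
#' variable-site counts, the K2P matrix under both deletion policies, and
#' the NJ bootstrap tree, ready to compare against the packaged printed
#' tables.
#'
#' @param path GenBank flat file (or FASTA with `id|species|section`
#'   headers) containing the 13 study records.
#' @param ref58s 5.8S anchor; defaults to the 5.8S feature annotation when
#'   the GenBank records carry one, else the bundled reference.
#' @param bootstrap NJ bootstrap replicates.
#' @param seed integer seed.
#' @return list: `records`, `stats`, `alignment`, `variation` (per section
#'   and region), `k2p_pairwise`, `k2p_complete`, `nj` (support-annotated).
#' @export
reproduce_from_accessions <- function(path, ref58s = NULL,
                                      bootstrap = 1000L, seed = 1L) {
  fail_if(!file.exists(path),
          paste0("'%s' not found; run fetch_genbank_its() once on a ",
                 "connected machine to create it"), path)
  is_gb <- any(grepl("^LOCUS", readLines(path, n = 50L, warn = FALSE)))
  records <- if (is_gb) read_genbank(path) else read_its_fasta(path)
  meta <- dendrobium_accessions()
  idx <- match(vapply(records, function(r) r$id, character(1)), meta$accession)
  for (k in seq_along(records)) {
    if (!is.na(idx[k])) {
      records[[k]]$species <- meta$species[idx[k]]
      records[[k]]$section <- meta$section[idx[k]]
    }
  }
  ## anchor with an annotated 5.8S if any record carries one
  if (is.null(ref58s)) {
    ann <- Filter(function(r) !is.null(r$regions), records)
    if (length(ann)) {
      rp <- ann[[1]]$regions
      ref58s <- ann[[1]]$seq[(rp$r58s[1] + 1L):rp$r58s[2]]
    }
  }
  records <- lapply(records, function(r) {
    if (is.null(r$regions)) partition_regions(r, ref58s) else r
  })
  stats <- region_stats_table(records)
  aln <- progressive_msa(records)
  sections <- vapply(records, function(r) r$section, character(1))
  variation <- do.call(rbind, lapply(unique(sections), function(sec) {
    sub <- records[sections == sec]
    saln <- progressive_msa(sub)
    cols <- msa_region_columns(saln, sub[[1]]$id)
    do.call(rbind, lapply(names(cols), function(rg) {
      v <- count_variable_sites(saln, cols[[rg]], region = rg)
      data.frame(section = sec, region = rg,
                 n_variable = v$n_variable_sites,
                 length = v$alignment_length, percent = v$percent)
    }))
  }))
  list(records = records, stats = stats, alignment = aln,
       variation = variation,
       k2p_pairwise = k2p_distance_matrix(aln, "pairwise"),
       k2p_complete = k2p_distance_matrix(aln, "complete"),
       nj = bootstrap_tree(aln, "nj", B = bootstrap, seed = seed))
}
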