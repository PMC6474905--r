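#!/usr/bin/env Rscript
## Step 3 — region partitioning and per-region statistics.
##
## Reads the synthetic amplicons from step 2, locates the 5.8S gene in each
## by semi-global alignment against the run's 5.8S reference, and tabulates
## lengths and GC contents per region and per section, mirroring the layout
## of the study's sequence-characteristics table.

suppressPackageStartupMessages(library(dendrobarcode))

records <- read_its_fasta("results/02_synthetic_its.fasta")
ref58s <- readLines("results/02_ref58s.txt")[1]
records <- lapply(records, partition_regions, ref58s = ref58s)

stats <- region_stats_table(records)
utils::write.table(stats, "results/03_region_stats.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
summary <- summarize_sections(records)
utils::write.table(summary, "results/03_section_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("per-record region stats (first rows):\n")
print(utils::head(stats, 4), row.names = FALSE)
cat("\nper-section summary:\n")
print(summary, row.names = FALSE)
cat(sprintf("\n5.8S length range: %d-%d (conserved by construction)\n",
            min(stats$len_58s), max(stats$len_58s)))
cat("wrote results/03_region_stats.tsv and results/03_section_summary.tsv\n")
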