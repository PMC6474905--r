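#!/usr/bin/env Rscript
## Step 1 — desk-scale reproduction from the printed distance matrix.
##
## The packaged fixture carries the published 14-taxon K2P matrix (13
## Dendrobium species, two sections, plus the out-group Pholidota
## yunnanensis). This script re-reads it, reports the distance ranges the
## text quotes, rebuilds the NJ tree and roots it on the out-group.

suppressPackageStartupMessages(library(dendrobarcode))
dir.create("results", showWarnings = FALSE)

D <- dendrobium_table3()
lt <- D[lower.tri(D)]
F7 <- D[1:7, 1:7]; C6 <- D[8:13, 8:13]

cat(sprintf("14-taxon K2P range: %.3f - %.3f\n", min(lt), max(lt)))
cat(sprintf("within Formosae (1-7): %.3f - %.3f\n",
            min(F7[lower.tri(F7)]), max(F7[lower.tri(F7)])))
cat(sprintf("within Chrysotoxae (8-13): %.3f - %.3f\n",
            min(C6[lower.tri(C6)]), max(C6[lower.tri(C6)])))
cat(sprintf("out-group distances: %.3f - %.3f\n",
            min(D[14, 1:13]), max(D[14, 1:13])))

tr <- neighbor_joining(D)
taxa <- rownames(D)
cat("NJ sister checks:",
    sprintf("williamsonii+cariniferum=%s,", are_sisters(tr, taxa[5], taxa[6])),
    sprintf("jenkinsii+lindleyi=%s,", are_sisters(tr, taxa[8], taxa[12])),
    sprintf("thyrsiflorum+densiflorum=%s\n", are_sisters(tr, taxa[10], taxa[11])))

rooted <- root_on_outgroup(tr, "Pholidota_yunnanensis")
write_newick(rooted, "results/01_nj_printed_matrix.nwk")
write_distance_tsv(D, "results/01_printed_k2p.tsv", digits = 3)
cat("wrote results/01_nj_printed_matrix.nwk and results/01_printed_k2p.tsv\n")
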