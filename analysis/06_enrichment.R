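#!/usr/bin/env Rscript
## Stage 6 — gene-set over-representation of the DE mRNAs.
##
## Local hypergeometric test of the DE mRNA list against the dataset's
## gene-set collection; the background universe is every mRNA symbol on
## the array. BH adjustment across tested sets.

library(lncnet)

ann <- read_annotation("results/data/annotation.tsv")
de <- utils::read.table("results/de.tsv", sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
sets <- read_gmt("results/data/sets.gmt")

de_mrna <- de$gene_symbol[de$biotype == "mRNA" & de$status != "ns"]
universe <- ann$gene_symbol[ann$biotype == "mRNA"]
enr <- ora(de_mrna, sets, universe)
utils::write.table(enr, "results/enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("Tested %d sets against %d DE mRNAs (universe %d)\n",
            nrow(enr), length(unique(de_mrna)), length(unique(universe))))
cat("Top sets:\n")
print(utils::head(enr[, c("set_name", "k_overlap", "K_set", "gene_ratio",
                          "p_value", "adj_p")], 3), row.names = FALSE)
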