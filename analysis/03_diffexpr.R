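#!/usr/bin/env Rscript
## Stage 3 — two-group differential expression.
##
## Pooled Student's t per probe on log2 intensities; a probe is called
## up/down when |log2FC| > 1 (fold change > 2, strictly) and p < 0.05.
## lncRNA and mRNA volcano classifications are reported separately.

library(lncnet)

norm <- read_expression("results/norm_log2.tsv", "results/data/groups.tsv",
                        scale_tag = "log2")
ann <- read_annotation("results/data/annotation.tsv")

de <- differential_expression(norm, ann, case_label = "tibetan",
                              control_label = "han")
write_tsv <- function(df, p) utils::write.table(df, p, sep = "\t",
                                                quote = FALSE,
                                                row.names = FALSE)
write_tsv(de, "results/de.tsv")
write_tsv(volcano_table(de), "results/volcano.tsv")

counts <- table(factor(de$status, c("up", "down", "ns")), de$biotype)
cat("Differential expression calls (|log2FC| > 1 & p < 0.05):\n")
print(counts)
cat(sprintf("Total DE: %d lncRNAs, %d mRNAs\n",
            sum(counts[c("up", "down"), "lncRNA"]),
            sum(counts[c("up", "down"), "mRNA"])))
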