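#!/usr/bin/env Rscript
## Stage 2 — quantile normalization, then log2.
##
## Every sample's raw intensity distribution is forced onto the common
## rank-mean reference, after which signals are log2 transformed. The
## order (normalize, then log) matters and is fixed.

library(lncnet)

raw <- read_expression("results/data/matrix.tsv", "results/data/groups.tsv")
qn <- quantile_normalize(raw)
norm <- log2_transform(qn$matrix)
write_expression(norm, "results/norm_log2.tsv")

cat(sprintf("Normalized %d probes x %d samples -> results/norm_log2.tsv\n",
            qn$report$n_probes, qn$report$n_samples))
cat(sprintf("Reference distribution spans %.2f .. %.2f (raw scale)\n",
            min(qn$report$reference_distribution),
            max(qn$report$reference_distribution)))
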