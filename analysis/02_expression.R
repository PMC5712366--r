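#!/usr/bin/env Rscript
# Normalise counts to RPM, call expressed genes (RPM >= 1 in all three
# replicates at one or more time points), and write the replicate-mean
# series for the expressed set under results/expression/.
suppressMessages(library(dielnet))

dir.create("results/expression", recursive = TRUE, showWarnings = FALSE)
counts <- read_counts_tsv("results/data/counts.tsv",
                          "results/data/metadata.tsv")
tensor <- compute_rpm(counts)
expressed <- filter_expressed(tensor, min_rpm = 1)
writeLines(expressed, "results/expression/expressed_genes.txt")

mean_series <- replicate_mean(subset_genes(tensor, expressed))
write_series_tsv(mean_series, "results/expression/rpm_mean_series.tsv")

cat(sprintf("%d of %d genes called expressed (RPM >= 1 in all replicates at >= 1 time)\n",
            length(expressed), nrow(counts$counts)))
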