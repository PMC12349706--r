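#!/usr/bin/env Rscript
# Chiasma counts from metaphase I shapes, bivalent counts in zmm
# backgrounds, and foci-count summaries, on the synthetic reconstructions
# of the published cytology tables.

suppressPackageStartupMessages(library(tetraco))
dir.create("results", showWarnings = FALSE)

ext <- function(f) system.file("extdata", f, package = "tetraco")

## chiasmata per cell from ring/rod configurations
ch <- read_bivalent_table(ext("synthetic_chiasmata.csv"))
ch$chiasmata <- vapply(seq_len(nrow(ch)), function(i) chiasma_count(ch[i, ]),
                       numeric(1))
chm <- aggregate(chiasmata ~ genotype, ch, function(x) c(mean = mean(x), n = length(x)))
cat("Chiasmata per cell (ring = 2, rod = 1):\n"); print(chm)
tt <- ttest_unpaired(ch$chiasmata[ch$genotype == "WT"],
                     ch$chiasmata[ch$genotype == "srs2-1"])
cat(sprintf("WT vs srs2-1: t = %.3f, p = %.3f (%s)\n",
            tt$statistic, tt$p_value, tt$method))

## bivalents per cell in zmm backgrounds
bv <- read_bivalent_table(ext("synthetic_bivalents.csv"))
mb <- mean_bivalents(bv)
cat("\nBivalents per cell:\n"); print(mb$summary, digits = 3)
cat("\nDistribution (% cells by bivalent count):\n")
print(round(mb$distribution, 1))
mw <- mann_whitney(bv$rod[bv$genotype == "zip4"],
                   bv$rod[bv$genotype == "zip4 srs2-1"])
cat(sprintf("zip4 vs zip4 srs2-1: U = %.0f, p = %.4f\n",
            mw$statistic, mw$p_value))
kd <- kruskal_dunn(split(bv$rod, bv$genotype))
cat(sprintf("Across genotypes: H = %.2f, p = %.2g; pairwise (Dunn):\n",
            kd$statistic, kd$p_value))
print(kd$pairwise, digits = 3)
utils::write.csv(mb$summary, "results/bivalent_summary.csv", row.names = FALSE)

## foci counts
fc <- read_foci_table(ext("synthetic_foci.csv"))
fm <- aggregate(count ~ kind + genotype, fc, mean)
cat("\nMean foci per cell:\n"); print(fm, digits = 3)
for (k in unique(fc$kind)) {
  sub <- fc[fc$kind == k, ]
  mwf <- mann_whitney(sub$count[sub$genotype == "WT"],
                      sub$count[sub$genotype == "srs2-1"])
  cat(sprintf("%s WT vs srs2-1: U = %.0f, p = %.4f\n", k, mwf$statistic,
              mwf$p_value))
}
cat("\nBinned (simulated RAD51-style) foci:\n")
rad <- data.frame(genotype = "sim", treatment = "MMC",
                  count = simulate_foci(400, "zero_inflated_poisson",
                                        list(pi = 0.55, lambda = 12), seed = 4))
print(bin_foci(rad), digits = 3)
utils::write.csv(fm, "results/foci_summary.csv", row.names = FALSE)
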