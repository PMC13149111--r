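#!/usr/bin/env Rscript
# 4x4 dinucleotide composition of non-canonical splice sites, with and
# without the canonical GT (donor) / AG (acceptor) classes, plus
# power-law (gamma = 0.5) color values for heatmap rendering.

suppressMessages(library(ncsplice))

sj <- read_sj_table("scratch/sim/sim_SJ.tab")
genome <- read_genome("scratch/sim/sim_genome.fa")
catalog <- build_catalog(sj, genome)
nc <- catalog[catalog$category == "non_canonical", ]

dir.create("results", showWarnings = FALSE)
mats <- list(
  "04_dinuc_donor" = dinuc_counts(nc$donor_dinuc, "donor"),
  "04_dinuc_acceptor" = dinuc_counts(nc$acceptor_dinuc, "acceptor"),
  "04_dinuc_donor_noGT" = dinuc_counts(nc$donor_dinuc, "donor", "GT"),
  "04_dinuc_acceptor_noAG" = dinuc_counts(nc$acceptor_dinuc, "acceptor",
                                          "AG"))
for (nm in names(mats)) {
  write_tsv(dinuc_table(mats[[nm]], gamma = 0.5),
            file.path("results", paste0(nm, ".tsv")))
}

cat("Non-canonical donor dinucleotide counts:\n")
print(mats[["04_dinuc_donor"]]$counts)
cat("\nAcceptor counts after removing canonical AG:\n")
print(mats[["04_dinuc_acceptor_noAG"]]$counts)

# optional heatmap rendering (binary output, kept out of results/)
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("scratch/figures", recursive = TRUE, showWarnings = FALSE)
  long <- do.call(rbind, lapply(names(mats), function(nm) {
    cbind(panel = nm, dinuc_table(mats[[nm]]))
  }))
  p <- ggplot(long, aes(second, first, fill = color_value)) +
    geom_tile() +
    geom_text(aes(label = ifelse(is.na(frequency), "",
                                 sprintf("%.3f", frequency))), size = 2.6) +
    facet_wrap(~panel) +
    scale_fill_gradient(low = "white", high = "firebrick") +
    labs(x = "second base", y = "first base",
         fill = "power-law\ncolor value")
  ggsave("scratch/figures/dinuc_heatmaps.pdf", p, width = 8, height = 7)
  cat("\nHeatmaps -> scratch/figures/dinuc_heatmaps.pdf\n")
}
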