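#!/usr/bin/env Rscript
# Intron-length contrasts between canonical, non-canonical, U2/U12-like
# and non-U2/U12-like junctions: Mann-Whitney U tests, log10 ECDFs and
# 1.5 x IQR boxplot summaries.

suppressMessages(library(ncsplice))

sj <- read_sj_table("scratch/sim/sim_SJ.tab")
genome <- read_genome("scratch/sim/sim_genome.fa")
catalog <- build_catalog(sj, genome)
catalog <- classify_junctions(catalog, genome, seed = 42L)$catalog

groups <- group_lengths(catalog)
tests <- length_contrasts(groups)

dir.create("results", showWarnings = FALSE)
dir.create("scratch/tables", recursive = TRUE, showWarnings = FALSE)
write_tsv(tests, "results/05_length_tests.tsv")
ecdfs <- do.call(rbind, lapply(names(groups), function(g) {
  cbind(group = g, ecdf_points(groups[[g]]))
}))
write_tsv(ecdfs, "scratch/tables/05_ecdf_points.tsv")  # per-value, bulky
boxes <- do.call(rbind, lapply(names(groups), function(g) {
  b <- boxplot_summary(groups[[g]])
  data.frame(group = g, n = b$n, q1 = b$q1, median = b$median, q3 = b$q3,
             whisker_low = b$whisker_low, whisker_high = b$whisker_high,
             n_outliers = length(b$outliers))
}))
write_tsv(boxes, "results/05_boxplot_summary.tsv")

cat("Length contrasts (medians in bp):\n")
print(tests[, c("group_a", "group_b", "n_a", "n_b", "median_a",
                "median_b", "median_difference", "p_two_sided")],
      row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("scratch/figures", recursive = TRUE, showWarnings = FALSE)
  p1 <- ggplot(ecdfs, aes(value, cum_prop, color = group)) +
    geom_step() +
    labs(x = "log10 intron length (bp)", y = "cumulative proportion")
  df <- do.call(rbind, lapply(names(groups), function(g) {
    data.frame(group = g, length = groups[[g]])
  }))
  p2 <- ggplot(df, aes(group, length)) +
    geom_boxplot(outlier.size = 0.6) +
    scale_y_log10() +
    labs(y = "intron length (bp, log scale)", x = NULL) +
    theme(axis.text.x = element_text(angle = 20, hjust = 1))
  ggsave("scratch/figures/length_ecdf.pdf", p1, width = 6, height = 4)
  ggsave("scratch/figures/length_boxplot.pdf", p2, width = 6, height = 4)
  cat("\nFigures -> scratch/figures/\n")
}
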