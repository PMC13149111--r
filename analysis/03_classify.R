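#!/usr/bin/env Rscript
# Classify non-canonical junctions as U2/U12-like vs non-U2/U12-like:
# PWMs trained on the sample's canonical junctions, threshold from the
# 95th percentile of a composition-preserving scrambled null.

suppressMessages(library(ncsplice))

sj <- read_sj_table("scratch/sim/sim_SJ.tab")
genome <- read_genome("scratch/sim/sim_genome.fa")
catalog <- build_catalog(sj, genome)

cls <- classify_junctions(catalog, genome, pseudocount = 1,
                          n_scrambles = 10000L, percentile = 95,
                          seed = 42L)
catalog <- cls$catalog

dir.create("results", showWarnings = FALSE)
dir.create("scratch/tables", recursive = TRUE, showWarnings = FALSE)
write_tsv(catalog[catalog$category != "canonical",
                  c("junction_id", "donor_score", "acceptor_score",
                    "total_score", "classification",
                    "not_classified_reason")],
          "scratch/tables/03_classification.tsv")
write_tsv(pwm_table(cls$donor_pwm), "results/03_pwm_donor.tsv")
write_tsv(pwm_table(cls$acceptor_pwm), "results/03_pwm_acceptor.tsv")

cat("Scrambled-null threshold (95th percentile):",
    round(cls$threshold, 3), "bits\n")
print(table(catalog$classification))

# agreement with the planted ground truth
truth <- utils::read.delim("scratch/sim/sim_truth.tsv")
tc <- truth_compare(catalog, truth)
cat("\nMotif agreement with planted truth:", tc$motif_agreement, "\n")
print(tc$classification_confusion)
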