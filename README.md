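# ncsplice

Cataloging and classification of non-canonical splice junctions from
spliced-aligner output.

## The problem

Splice-aware RNA-seq aligners emit a junction table alongside the
alignments. The overwhelming majority of those junctions are canonical
GT–AG introns; a small remainder deviates at the donor end, the
acceptor end, or both. Part of that remainder (GC–AG and AT–AC above
all) sits in sequence context that still looks like spliceosomal
recognition signal and is plausibly spliced by the U2/U12 machinery;
the rest has no recognizable context and mixes rare mechanisms with
technical artifacts. `ncsplice` is for transcriptomics analysts who
want to take an aligner junction table, a genome FASTA and a GTF, and
separate those groups reproducibly:

1. **Catalog** — keep junctions with ≥ 2 uniquely mapped supporting
   reads, resolve strand, read the terminal dinucleotides from the
   genome in sense orientation, categorize canonical (GT–AG) vs
   non-canonical, assign containing genes, compute intron lengths.
2. **Classify** — train donor (9-nt: 3 exonic + site + 4 intronic) and
   acceptor (23-nt: 18 intronic + site + 3 exonic) position weight
   matrices on the sample's *own* canonical junctions, with Laplace
   smoothing. Score each window in bits as summed log-odds against a
   uniform background,
   `S(w) = Σ_j log2( p_j(w_j) / 0.25 )`,
   and each non-canonical junction by its donor + acceptor total.
   Junctions whose total exceeds the 95th percentile of a
   composition-preserving scrambled-window null (10,000 draws) are
   **U2/U12-like**; at or below it, **non-U2/U12-like**; junctions
   without a valid score (unresolved strand, window off the contig,
   non-ACGT bases) are **not classified** and excluded downstream.
3. **Summarize** — splice-site class tables, 4×4 dinucleotide
   matrices for non-canonical donors/acceptors (with GT- and
   AG-excluded variants and power-law γ = 0.5 heatmap scaling), and
   intron-length contrasts via two-sided Mann–Whitney U tests, log10
   ECDFs and 1.5 × IQR boxplot summaries.

A seeded synthetic-data generator (`simulate_dataset()`) produces a
toy genome, annotation, junction table and planted ground truth with
the statistical structure the analysis assumes — consensus-context
junctions with swapped terminals, random-context junctions, and
shorter non-canonical introns — so the entire pipeline is testable
offline. See `vignettes/noncanonical-splicing.Rmd` for the methods.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
synthetic dataset (tables land in `results/`, bulky intermediates in
`scratch/`):

```sh
Rscript analysis/01_simulate.R   # genome + junction table + truth
Rscript analysis/02_catalog.R    # filter, motifs, class table
Rscript analysis/03_classify.R   # PWMs, scrambled null, classification
Rscript analysis/04_motifs.R     # 4x4 dinucleotide matrices
Rscript analysis/05_lengths.R    # ECDF, boxplots, Mann-Whitney tests
Rscript analysis/06_pipeline_end_to_end.R
```

`03_classify.R` prints, for the default simulation (1000 canonical +
300 non-canonical junctions, seed 1):

```
Scrambled-null threshold (95th percentile): -12.783 bits

non_u2u12_like not_applicable not_classified     u2u12_like
           134            901              6            135

Motif agreement with planted truth: 1
           classification
planted     non_u2u12_like not_applicable not_classified u2u12_like
  canonical              0            901              0          0
  nc_random            134              0              3          3
  nc_u2like              0              0              3        132
```

Every planted consensus-context junction that could be scored was
called U2/U12-like and only 3/137 random-context junctions crossed the
null threshold; the 6 not-classified junctions are the simulated
N-containing windows. `05_lengths.R` then recovers the planted length
structure (canonical median 2015 bp vs non-canonical 795 bp):

```
    group_a           group_b n_a n_b median_a median_b median_difference  p_two_sided
  canonical non_canonical_all 901 275     2015    795.0            1220.0 4.137337e-71
  canonical        u2u12_like 901 135     2015    808.0            1207.0 1.260300e-41
  canonical    non_u2u12_like 901 134     2015    811.5            1203.5 6.602817e-38
 u2u12_like    non_u2u12_like 135 134      808    811.5              -3.5 7.682396e-01
```

i.e. non-canonical introns are ~1200 bp shorter at the median, in both
classified subsets, while the two non-canonical subsets (planted with
the same length law) do not differ.

The package also ships a published reference table of splice-site
class counts from a mouse neuronal RNA-seq sample
(`published_class_counts()`; 56 classes, 151,385 junctions), whose
relative frequencies — GT–AG 98.9438%, GC–AG 0.8277%, AT–AC 0.1222% —
are recomputed from the raw counts by `class_percentages()`.

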