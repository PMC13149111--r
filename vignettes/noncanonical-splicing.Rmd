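---
title: "Cataloging and classifying non-canonical splice junctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cataloging and classifying non-canonical splice junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Most introns are excised at GT–AG terminal dinucleotides by the major
spliceosome, but a small minority of junctions called from RNA-seq
deviate at one or both ends. Some of these non-canonical junctions sit
in sequence context that still resembles major/minor spliceosomal
recognition signals (GC–AG and AT–AC being the prominent classes) and
are plausibly genuine splicing events; others have no recognizable
context and are a mixed bag of rare mechanisms and technical artifacts.
`ncsplice` takes the junction table emitted by a splice-aware aligner,
a genome FASTA and a gene annotation, and produces: a categorized
junction catalog, a U2/U12-like vs non-U2/U12-like classification of
the non-canonical junctions, splice-site dinucleotide composition
matrices, and intron-length comparisons between the groups.

The package is organized as an analysis workflow: each numbered script
under `analysis/` drives one stage on a simulated dataset, and every
computation lives in package functions so the stages are individually
testable.

## Cataloging

The junction table dialect is 9 whitespace-separated columns per
junction: contig, intron start and end (1-based inclusive; start is
the first intronic base, end the last), a strand code (0 undefined,
1 plus, 2 minus), the aligner's motif code (0–6), an annotation flag,
unique-read and multi-read support, and the maximum alignment
overhang. All internal coordinates stay 1-based inclusive; intron
length is `end - start + 1`.

Junctions with fewer than 2 uniquely mapped supporting reads are
dropped (`min_unique = 2`, i.e. "more than one unique read";
multi-mapping reads never count). Strand codes 1/2 are taken at face
value; code 0 is inferred by asking whether the terminal dinucleotides
read as a known splice pattern (GT–AG, GC–AG, AT–AC) in exactly one of
the two orientations, and left unresolved otherwise.

Terminal dinucleotides are always derived from the genome sequence in
sense orientation (reverse-complemented for minus-strand junctions),
and a junction is canonical exactly when that sense pair is GT–AG.
The aligner's own motif code is only cross-checked against the
sequence-derived code, because motif codes are assigned on the genomic
forward strand: taken literally, "code ≠ 1 is non-canonical" would
misclassify every minus-strand GT–AG junction (code 2, CT–AC on the
forward strand) as non-canonical, which contradicts any sense-strand
class table in which GT–AG dominates and no CT–AC class appears. The
literal rule remains available behind `literal_motif_code_rule = TRUE`
for comparison. Junctions with unresolved strand or non-ACGT terminal
bases are `excluded` and kept out of class tables and downstream
statistics.

Gene assignment reports every annotated gene whose span fully contains
the intron, ";"-joined with an ambiguity flag — the containment rule is
deliberately lossless because a junction inside two overlapping genes
has no unique owner. Gene spans come from gene-level annotation rows
when present, otherwise from the min/max envelope of same-`gene_id`
features.

## U2/U12-like classification

For every canonical junction with resolved strand we extract two sense
windows:

* donor: 3 exonic nt + the 2-nt donor site + 4 intronic nt (9 nt);
* acceptor: 18 intronic nt (covering the polypyrimidine tract) + the
  2-nt acceptor site + 3 exonic nt (23 nt).

Windows containing anything outside A/C/G/T, or running off a contig,
are discarded from training. Each window set trains a position weight
matrix with a Laplace pseudocount:

$$p_{j}(b) = \frac{n_{j}(b) + \alpha}{N + 4\alpha}, \qquad \alpha = 1.$$

A window $w$ is scored in bits as summed log-odds against a uniform
background,

$$S(w) = \sum_{j} \log_2 \frac{p_j(w_j)}{0.25},$$

so a uniform PWM scores 0 everywhere and the self-trained
zero-pseudocount score is 2 bits per position. Donor and acceptor
scores add to a total score per junction. The terminal positions are
*not* masked when scoring non-canonical junctions: the penalty a
non-GT/non-AG terminal incurs under canonical-trained columns is part
of the score, and swapped-terminal classes such as GC–AG pass mainly
on the strength of their surrounding context.

The decision threshold comes from a scrambled control: each of 10,000
null draws samples one donor and one acceptor training window
(uniformly, with replacement), permutes the bases within each window —
a composition-preserving scramble, so the null keeps single-nucleotide
content and destroys only positional structure — and records the summed
score. The threshold is the 95th percentile of this null by linear
interpolation between order statistics. Totals strictly above the
threshold are `u2u12_like`; totals at or below it are
`non_u2u12_like`. Junctions whose score cannot be computed are
`not_classified` with a reason (`strand_unresolved`,
`extraction_failed`, `invalid_bases`) and appear in no downstream
statistic.

Three of these choices are genuinely open and are fixed here as
package defaults rather than inferred facts: the log-odds scoring form
(standard for PWMs and zero-centered under a uniform model), the
scrambling of *canonical training* windows (scrambling candidate
windows instead would tie the null to the tested set's composition),
and the 95th percentile (a conventional one-sided false-positive
budget; classification counts are monotone in this percentile, which
the tests assert). All three are exposed as arguments.

## Dinucleotide composition and length contrasts

Non-canonical donor and acceptor dinucleotides are tallied into 4×4
matrices (rows = first base, columns = second). Because many
non-canonical junctions are non-canonical at only one end, each matrix
is also produced after excluding the canonical dinucleotide for that
side (GT for donors, AG for acceptors); frequencies are renormalized
over the remaining sites, so each matrix answers "given a site in this
set, what is its composition?". For display, color values are
power-law normalized per matrix, $(f/f_{\max})^{\gamma}$ with
$\gamma = 0.5$, while numeric labels stay untransformed; the per-matrix
maximum (rather than a fixed range) is used so each panel spans the
full color scale.

Intron lengths are compared between canonical, all non-canonical,
U2/U12-like and non-U2/U12-like junctions with a two-sided
Mann–Whitney U test: exact by full enumeration when the combined
sample size is at most 20 and tie-free, otherwise the normal
approximation with tie and continuity corrections (delegated to
`stats::wilcox.test` with that switch made explicit). ECDFs are
reported over log10 lengths; boxplot summaries use linear-interpolation
quartiles and the 1.5 × IQR outlier rule with whiskers at the extreme
non-outliers. Median differences are signed in tables (canonical minus
the comparison group) and quoted as "shorter by X bp" in text. No
multiplicity correction is applied: the four contrasts are
pre-specified and reported raw.

## The synthetic dataset

`simulate_dataset()` emits a genome FASTA, a gene-per-junction GTF, a
9-column junction table and a ground-truth table, all a deterministic
function of the configuration and seed. Background sequence is i.i.d.
uniform; each planted junction writes its donor and acceptor windows
into the genome at the junction coordinates (reverse-complemented for
minus placements), so motif extraction must agree with the truth table
exactly.

The defaults define the simulated study conditions:

* 1000 canonical junctions, 150 consensus-context swapped-terminal
  (`nc_u2like`) and 150 random-context (`nc_random`) junctions —
  enough non-canonical junctions (300) for stable medians while
  keeping canonical training dominant, as in real data;
* donor consensus `CAGGTAAGT` with per-position match probability
  0.85, and an acceptor of 18 pyrimidine-rich nt (pyrimidine
  probability 0.85) + AG + a G-led exonic triplet — the textbook
  vertebrate donor/acceptor signal at a strength that leaves realistic
  per-window variability;
* swapped-terminal classes weighted GC–AG 0.6, AT–AC 0.2,
  single-sided swaps 0.2, mirroring the observed dominance of GC–AG
  among context-bearing non-canonical junctions;
* log-normal intron lengths with medians 2000 bp (canonical) and
  800 bp (non-canonical), log-sigma 0.6 — shorter non-canonical introns
  by construction, at a magnitude (1200 bp median difference) in the
  same order as reported contrasts on real neuronal data;
* 10% of rows emitted with `unique_reads ≤ 1` to exercise the support
  filter, and 2% of junctions with an `N` injected at a *non-terminal*
  window position, exercising the invalid-bases path without touching
  the planted terminals.

Junctions are placed non-overlapping with ≥ 60 bp flanks and ≥ 120 bp
gaps so window extraction never collides; dedicated edge contigs
(`n_edge > 0`) place junctions 1 bp from the contig start to force the
extraction-failure path. Contigs are auto-sized from the drawn lengths
unless a length is given, in which case an infeasible configuration
errors with the required length.

What the generator does **not** emulate: alignment artifacts, read-level
noise, splice-site usage levels, GC/repeat structure, genuinely shared
or overlapping gene models, and any U12-specific signal (the
"U2/U12-like" label here, as in the pipeline itself, rests entirely on
sample-canonical PWMs). Passing tests therefore demonstrate that the
pipeline recovers planted structure under its own assumptions, not that
the classifier is biologically validated.

## Numerical choices and degenerate inputs

* Percentiles and quartiles use linear interpolation between order
  statistics (`stats::quantile` type 7) throughout.
* Ties in classification go to `non_u2u12_like` (a total exactly at
  the threshold is not called U2/U12-like).
* `pseudocount = 0` is allowed for PWM training but scoring then
  errors on an unseen base instead of returning negative infinity.
* Empty training sets, empty test groups and zero-site dinucleotide
  matrices error, warn-and-skip, and flag as degenerate respectively.
* A single seeded generator drives each scrambled null; the seed is
  recorded in the run report and identical seeds give bit-identical
  classifications.

## Problem sizes

The test suite and the acceptance script run the generator at its
defaults (1300 junctions) for round-trip, partition and length checks,
and at 500 junctions per class for classifier recovery; PWM/score unit
tests use toy windows and contigs of a few hundred bases. These sizes
give stable medians and rates (the classifier margins are wide — the
planted consensus class scores tens of bits above the null threshold)
while keeping a full run in the low minutes on one core.

## Known limitations

* The classifier is relative to the sample's own canonical signal;
  it does not implement a separately trained minor-spliceosome (U12)
  model, maximum-entropy or higher-order splice models.
* Strand inference for code-0 junctions uses only the three known
  terminal patterns; a code-0 junction with none of them stays
  unresolved even when context would disambiguate it.
* Gene assignment is by containment in gene spans, not exon structure.
* The dinucleotide analysis is descriptive; no enrichment test is
  attached to the 4×4 matrices.
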