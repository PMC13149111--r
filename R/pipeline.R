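#' Run the full non-canonical splice-junction analysis
#'
#' Orchestrates every stage on one set of inputs: read-support filtering,
#' strand/motif resolution, canonical vs non-canonical categorization,
#' gene assignment, PWM training on the sample's canonical junctions,
#' scrambled-null thresholding, classification of the non-canonical
#' junctions, splice-site class and dinucleotide tables, and
#' intron-length statistics. All result tables are written to `outdir`
#' as TSV; the returned run report carries the stage counts and their
#' partition identities.
#'
#' @param sj_path Junction table path (9-column dialect).
#' @param genome_path Genome FASTA path.
#' @param annotation_path Optional GTF/GFF path for gene assignment
#'   (`NULL` skips it).
#' @param outdir Output directory, created if missing.
#' @param min_unique Read-support threshold (default 2).
#' @param pseudocount PWM pseudocount (default 1).
#' @param n_scrambles Scrambled-null draws (default 10000).
#' @param percentile Null percentile for the threshold (default 95).
#' @param seed Seed for the scrambled null (default 42).
#' @param gamma Power-law exponent for heatmap color values (default 0.5).
#' @param literal_motif_code_rule Categorize by aligner motif code
#'   instead of sequence-derived motifs (default `FALSE`; see
#'   [build_catalog()]).
#' @return A run-report list: `counts` (parsed, filtered, dropped,
#'   canonical, non_canonical, excluded, u2u12_like, non_u2u12_like,
#'   not_classified and per-reason breakdown), `threshold`, `percentile`,
#'   `seed`, `params`, `outdir`, plus the classified `catalog` and
#'   `length_tests` for programmatic use.
#' @export
run_pipeline <- function(sj_path, genome_path, annotation_path = NULL,
                         outdir, min_unique = 2L, pseudocount = 1,
                         n_scrambles = 10000L, percentile = 95,
                         seed = 42L, gamma = 0.5,
                         literal_motif_code_rule = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sj <- read_sj_table(sj_path)
  genome <- read_genome(genome_path)
  gene_index <- if (is.null(annotation_path)) NULL
                else build_gene_index(annotation_path)

  catalog <- build_catalog(sj, genome, gene_index, min_unique,
                           literal_motif_code_rule)
  cls <- classify_junctions(catalog, genome, pseudocount, n_scrambles,
                            percentile, seed)
  catalog <- cls$catalog

  write_tsv(catalog, file.path(outdir, "junctions.tsv"))
  write_tsv(motif_table(catalog), file.path(outdir, "motif_table.tsv"))
  write_tsv(catalog[catalog$category != "canonical",
                    c("junction_id", "donor_score", "acceptor_score",
                      "total_score", "classification",
                      "not_classified_reason")],
            file.path(outdir, "classification.tsv"))
  write_tsv(data.frame(total_score = cls$null$null_scores),
            file.path(outdir, "null_scores.tsv"))
  write_tsv(pwm_table(cls$donor_pwm), file.path(outdir, "pwm_donor.tsv"))
  write_tsv(pwm_table(cls$acceptor_pwm),
            file.path(outdir, "pwm_acceptor.tsv"))

  nc <- catalog[catalog$category == "non_canonical", , drop = FALSE]
  dinuc_files <- list(
    dinuc_donor = dinuc_counts(nc$donor_dinuc, "donor"),
    dinuc_acceptor = dinuc_counts(nc$acceptor_dinuc, "acceptor"),
    dinuc_donor_noGT = dinuc_counts(nc$donor_dinuc, "donor", "GT"),
    dinuc_acceptor_noAG = dinuc_counts(nc$acceptor_dinuc, "acceptor", "AG"))
  for (nm in names(dinuc_files)) {
    write_tsv(dinuc_table(dinuc_files[[nm]], gamma),
              file.path(outdir, paste0(nm, ".tsv")))
  }

  groups <- group_lengths(catalog)
  tests <- length_contrasts(groups)
  write_tsv(tests, file.path(outdir, "length_tests.tsv"))
  ecdfs <- do.call(rbind, lapply(names(groups), function(g) {
    if (length(groups[[g]]) == 0L) return(NULL)
    cbind(group = g, ecdf_points(groups[[g]]))
  }))
  if (!is.null(ecdfs)) {
    write_tsv(ecdfs, file.path(outdir, "ecdf_points.tsv"))
  }
  boxes <- do.call(rbind, lapply(names(groups), function(g) {
    if (length(groups[[g]]) == 0L) return(NULL)
    b <- boxplot_summary(groups[[g]])
    data.frame(group = g, n = b$n, q1 = b$q1, median = b$median,
               q3 = b$q3, whisker_low = b$whisker_low,
               whisker_high = b$whisker_high,
               n_outliers = length(b$outliers))
  }))
  if (!is.null(boxes)) {
    write_tsv(boxes, file.path(outdir, "boxplot_summary.tsv"))
  }

  reasons <- table(catalog$not_classified_reason[
    catalog$classification == "not_classified"])
  counts <- list(
    parsed = nrow(sj),
    filtered = nrow(catalog),
    dropped = nrow(sj) - nrow(catalog),
    canonical = sum(catalog$category == "canonical"),
    non_canonical = sum(catalog$category == "non_canonical"),
    excluded = sum(catalog$category == "excluded"),
    u2u12_like = sum(catalog$classification == "u2u12_like"),
    non_u2u12_like = sum(catalog$classification == "non_u2u12_like"),
    not_classified = sum(catalog$classification == "not_classified"),
    not_classified_by_reason = as.list(reasons))
  report <- list(counts = counts, threshold = cls$threshold,
                 percentile = percentile, seed = seed,
                 params = list(min_unique = min_unique,
                               pseudocount = pseudocount,
                               n_scrambles = n_scrambles, gamma = gamma,
                               literal_motif_code_rule =
                                 literal_motif_code_rule),
                 outdir = outdir, catalog = catalog,
                 length_tests = tests)
  report_df <- data.frame(key = c(names(unlist(counts[1:9])),
                                  "threshold", "percentile", "seed"),
                          value = c(unlist(counts[1:9]), cls$threshold,
                                    percentile, seed))
  write_tsv(report_df, file.path(outdir, "run_report.tsv"))
  report
}

#' Published splice-site class counts bundled with the package
#'
#' The splice-site class count table observed in an embryonic mouse
#' neuronal bulk RNA-seq sample (sorted EGFP+ cells): 56 donor+acceptor
#' 4-mer classes with absolute junction counts, dominated by GT-AG with
#' GC-AG and AT-AC as the leading non-canonical classes. Used to verify
#' that [class_percentages()] reproduces the published relative
#' frequencies.
#'
#' @return Data.frame with `class` and `count`.
#' @export
published_class_counts <- function() {
  path <- system.file("extdata", "mouse_neuron_sj_class_counts.tsv",
                      package = "ncsplice")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
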