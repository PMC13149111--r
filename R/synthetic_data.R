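#' Configuration for the synthetic splice-junction dataset
#'
#' Defines the generative model the pipeline is tested against: a small
#' multi-contig genome of i.i.d. uniform background sequence into which
#' junctions of three planted classes are written. `canonical` junctions
#' carry GT-AG terminals inside consensus-like context windows (donor
#' consensus CAGGTAAGT with per-position match probability
#' `consensus_match_prob`; acceptor = 18-nt pyrimidine tract with
#' pyrimidine probability `pyrimidine_prob`, the AG site, then a G-led
#' exonic triplet). `nc_u2like` junctions keep the same consensus context
#' but swap terminal dinucleotides (GC-AG, AT-AC, or a single-sided
#' swap, weighted by `nc_terminal_classes`). `nc_random` junctions have
#' fully uniform-random windows and uniform-random non-GT-AG terminals.
#' Intron lengths are log-normal per class (canonical median 2000 bp,
#' non-canonical 800 bp, log-scale sigma 0.6), and a configurable
#' fraction of rows gets unique-read support <= 1 to exercise the
#' read-support filter.
#'
#' @param n_contigs Number of contigs (default 3).
#' @param contig_length Common contig length in bases; `NULL` (default)
#'   sizes contigs automatically from the drawn intron lengths.
#' @param n_canonical,n_nc_u2like,n_nc_random Junctions per class
#'   (defaults 1000 / 150 / 150).
#' @param donor_consensus 9-nt donor consensus (default "CAGGTAAGT").
#' @param consensus_match_prob Per-position probability of emitting the
#'   consensus base at non-terminal consensus positions (default 0.85).
#' @param pyrimidine_prob Pyrimidine probability per polypyrimidine-tract
#'   position (default 0.85; C and T equally likely within pyrimidines).
#' @param nc_terminal_classes Named weights for the swapped-terminal
#'   classes (default `c(gc_ag = 0.6, at_ac = 0.2, single_sided = 0.2)`).
#' @param canonical_median_bp,nc_median_bp Median intron lengths of the
#'   class log-normal laws (defaults 2000 and 800 bp).
#' @param length_sdlog Log-scale sigma of the length laws (default 0.6).
#' @param low_support_frac Fraction of junctions emitted with
#'   `unique_reads <= 1` (default 0.1).
#' @param n_injection_frac Fraction of junctions with one `N` injected at
#'   a non-terminal window position, exercising the invalid-bases rule
#'   (default 0.02).
#' @param n_edge Number of extra junctions planted so close to a contig
#'   start that donor-window extraction must fail (default 0).
#' @param seed Integer seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_contigs = 3L, contig_length = NULL,
                       n_canonical = 1000L, n_nc_u2like = 150L,
                       n_nc_random = 150L,
                       donor_consensus = "CAGGTAAGT",
                       consensus_match_prob = 0.85,
                       pyrimidine_prob = 0.85,
                       nc_terminal_classes = c(gc_ag = 0.6, at_ac = 0.2,
                                               single_sided = 0.2),
                       canonical_median_bp = 2000, nc_median_bp = 800,
                       length_sdlog = 0.6, low_support_frac = 0.1,
                       n_injection_frac = 0.02, n_edge = 0L, seed = 1L) {
  stopifnot(n_contigs >= 1L, n_canonical >= 0L, n_nc_u2like >= 0L,
            n_nc_random >= 0L, nchar(donor_consensus) == 9L,
            consensus_match_prob >= 0, consensus_match_prob <= 1,
            pyrimidine_prob >= 0, pyrimidine_prob <= 1,
            all(nc_terminal_classes >= 0), sum(nc_terminal_classes) > 0,
            canonical_median_bp > 0, nc_median_bp > 0, length_sdlog > 0,
            low_support_frac >= 0, low_support_frac <= 1,
            n_injection_frac >= 0, n_injection_frac <= 1, n_edge >= 0L)
  structure(as.list(environment()), class = "sim_config")
}

NON_GTAG_DINUCS <- function() {
  all2 <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  all2
}

draw_consensus_base <- function(consensus_base, match_prob) {
  if (stats::runif(1) < match_prob) consensus_base
  else sample(setdiff(DNA_BASES, consensus_base), 1L)
}

draw_donor_window <- function(consensus, match_prob, terminals) {
  cons <- strsplit(consensus, "")[[1L]]
  w <- vapply(seq_len(9L), function(i) {
    draw_consensus_base(cons[i], match_prob)
  }, character(1L))
  w[4:5] <- strsplit(terminals, "")[[1L]]
  paste(w, collapse = "")
}

draw_acceptor_window <- function(pyr_prob, match_prob, terminals) {
  ppt <- vapply(seq_len(18L), function(i) {
    if (stats::runif(1) < pyr_prob) sample(c("C", "T"), 1L)
    else sample(c("A", "G"), 1L)
  }, character(1L))
  exon <- c(draw_consensus_base("G", match_prob),
            sample(DNA_BASES, 2L, replace = TRUE))
  paste(c(ppt, strsplit(terminals, "")[[1L]], exon), collapse = "")
}

draw_random_window <- function(width) {
  paste(sample(DNA_BASES, width, replace = TRUE), collapse = "")
}

draw_nc_terminals <- function(weights) {
  cls <- sample(names(weights), 1L, prob = weights)
  if (cls == "gc_ag") return(list(donor = "GC", acceptor = "AG"))
  if (cls == "at_ac") return(list(donor = "AT", acceptor = "AC"))
  # single-sided swap: one end stays canonical
  if (stats::runif(1) < 0.5) {
    list(donor = sample(setdiff(NON_GTAG_DINUCS(), "GT"), 1L),
         acceptor = "AG")
  } else {
    list(donor = "GT",
         acceptor = sample(setdiff(NON_GTAG_DINUCS(), "AG"), 1L))
  }
}

draw_random_terminals <- function() {
  repeat {
    d <- sample(NON_GTAG_DINUCS(), 1L)
    a <- sample(NON_GTAG_DINUCS(), 1L)
    if (!(d == "GT" && a == "AG")) return(list(donor = d, acceptor = a))
  }
}

#' Generate the synthetic dataset
#'
#' Draws every junction's class attributes (strand, intron length,
#' donor/acceptor windows, read support), places junctions
#' non-overlapping with >= 60 bp flanks on the contigs, writes the
#' sense-orientation windows into the background genome
#' (reverse-complemented for "-" placements), and emits four files:
#' `sim_genome.fa`, `sim_annotation.gtf` (one gene span per junction),
#' `sim_SJ.tab` (9-column junction table) and `sim_truth.tsv` (planted
#' ground truth). Outputs are byte-identical for identical
#' configuration and seed.
#'
#' @param config A `sim_config`.
#' @param outdir Output directory (created if missing); `NULL` skips
#'   file output and returns in-memory objects only.
#' @return List with `genome` (`DNAStringSet`), `sj` (junction table),
#'   `truth` (ground-truth data.frame), `genes` (gene spans) and `paths`
#'   (named file paths, when written).
#' @export
simulate_dataset <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_dataset_impl(config, outdir))
}

simulate_dataset_impl <- function(config, outdir) {
  n_total <- config$n_canonical + config$n_nc_u2like + config$n_nc_random
  classes <- rep(c("canonical", "nc_u2like", "nc_random"),
                 c(config$n_canonical, config$n_nc_u2like,
                   config$n_nc_random))

  jx <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    cls <- classes[i]
    med <- if (cls == "canonical") config$canonical_median_bp
           else config$nc_median_bp
    len <- max(60L, as.integer(round(stats::rlnorm(1, log(med),
                                                   config$length_sdlog))))
    strand <- sample(c("+", "-"), 1L)
    if (cls == "canonical") {
      term <- list(donor = "GT", acceptor = "AG")
      dwin <- draw_donor_window(config$donor_consensus,
                                config$consensus_match_prob, term$donor)
      awin <- draw_acceptor_window(config$pyrimidine_prob,
                                   config$consensus_match_prob,
                                   term$acceptor)
    } else if (cls == "nc_u2like") {
      term <- draw_nc_terminals(config$nc_terminal_classes)
      dwin <- draw_donor_window(config$donor_consensus,
                                config$consensus_match_prob, term$donor)
      awin <- draw_acceptor_window(config$pyrimidine_prob,
                                   config$consensus_match_prob,
                                   term$acceptor)
    } else {
      term <- draw_random_terminals()
      dwin <- draw_random_window(9L)
      awin <- draw_random_window(23L)
      substr(dwin, 4L, 5L) <- term$donor
      substr(awin, 19L, 20L) <- term$acceptor
    }
    n_injected <- stats::runif(1) < config$n_injection_frac
    if (n_injected) {
      # inject at a non-terminal donor position: terminals stay intact
      pos <- sample(c(1:3, 6:9), 1L)
      substr(dwin, pos, pos) <- "N"
    }
    jx[[i]] <- list(class = cls, strand = strand, len = len,
                    donor = term$donor, acceptor = term$acceptor,
                    dwin = dwin, awin = awin, n_injected = n_injected)
  }

  # sequential non-overlapping placement, round-robin over contigs
  contig_names <- sprintf("simChr%02d", seq_len(config$n_contigs))
  cursor <- stats::setNames(rep(61L, config$n_contigs), contig_names)
  gap <- 120L
  for (i in seq_len(n_total)) {
    ctg <- contig_names[((i - 1L) %% config$n_contigs) + 1L]
    jx[[i]]$chrom <- ctg
    jx[[i]]$start <- cursor[[ctg]]
    jx[[i]]$end <- cursor[[ctg]] + jx[[i]]$len - 1L
    cursor[[ctg]] <- jx[[i]]$end + gap
  }
  required <- max(cursor) + 60L
  if (is.null(config$contig_length)) {
    contig_len <- as.integer(ceiling(required / 1000) * 1000)
  } else {
    contig_len <- as.integer(config$contig_length)
    if (contig_len < required) {
      stop("contig_length ", contig_len, " too short for the planted ",
           "junctions; required contig length: ", required)
    }
  }

  # edge-case junctions on a dedicated contig, too close to the start
  # for donor-window extraction
  edge <- list()
  if (config$n_edge > 0L) {
    for (k in seq_len(config$n_edge)) {
      term <- draw_random_terminals()
      edge[[k]] <- list(class = "nc_random", strand = "+", len = 80L,
                        donor = term$donor, acceptor = term$acceptor,
                        dwin = NA_character_, awin = NA_character_,
                        n_injected = FALSE,
                        chrom = sprintf("simEdge%02d", k),
                        start = 2L, end = 81L)
    }
  }

  # background genome + planted window writes
  genome_list <- lapply(contig_names, function(ctg) {
    paste(sample(DNA_BASES, contig_len, replace = TRUE), collapse = "")
  })
  names(genome_list) <- contig_names
  for (e in edge) {
    genome_list[[e$chrom]] <- paste(sample(DNA_BASES, 200L,
                                           replace = TRUE), collapse = "")
  }
  genome <- Biostrings::DNAStringSet(unlist(genome_list))

  all_jx <- c(jx, edge)
  repl <- list()
  for (j in all_jx) {
    if (is.na(j$dwin)) {
      # edge case: write only the terminal dinucleotides
      repl[[length(repl) + 1L]] <-
        list(chrom = j$chrom, start = j$start, end = j$start + 1L,
             value = j$donor)
      repl[[length(repl) + 1L]] <-
        list(chrom = j$chrom, start = j$end - 1L, end = j$end,
             value = j$acceptor)
    } else if (j$strand == "+") {
      repl[[length(repl) + 1L]] <-
        list(chrom = j$chrom, start = j$start - 3L, end = j$start + 5L,
             value = j$dwin)
      repl[[length(repl) + 1L]] <-
        list(chrom = j$chrom, start = j$end - 19L, end = j$end + 3L,
             value = j$awin)
    } else {
      repl[[length(repl) + 1L]] <-
        list(chrom = j$chrom, start = j$end - 5L, end = j$end + 3L,
             value = revcomp(j$dwin))
      repl[[length(repl) + 1L]] <-
        list(chrom = j$chrom, start = j$start - 3L, end = j$start + 19L,
             value = revcomp(j$awin))
    }
  }
  repl_chrom <- vapply(repl, `[[`, character(1L), "chrom")
  for (ctg in unique(repl_chrom)) {
    sel <- repl[repl_chrom == ctg]
    at <- IRanges::IRanges(vapply(sel, `[[`, numeric(1L), "start"),
                           vapply(sel, `[[`, numeric(1L), "end"))
    genome[[ctg]] <- Biostrings::replaceAt(
      genome[[ctg]], at, vapply(sel, `[[`, character(1L), "value"))
  }

  # junction table rows
  sj <- do.call(rbind, lapply(all_jx, function(j) {
    fwd_d <- if (j$strand == "+") j$donor else revcomp(j$acceptor)
    fwd_a <- if (j$strand == "+") j$acceptor else revcomp(j$donor)
    low <- stats::runif(1) < config$low_support_frac
    data.frame(
      chrom = j$chrom, start = j$start, end = j$end,
      strand_code = if (j$strand == "+") 1L else 2L,
      motif_code = expected_motif_code(fwd_d, fwd_a),
      annotated = j$class == "canonical",
      unique_reads = if (low) sample(0:1, 1L)
                     else 2L + stats::rpois(1, 8),
      multi_reads = stats::rpois(1, 2),
      max_overhang = sample(20:60, 1L),
      stringsAsFactors = FALSE)
  }))

  truth <- do.call(rbind, lapply(all_jx, function(j) {
    data.frame(
      junction_id = paste0(j$chrom, ":", j$start, "-", j$end, ":",
                           j$strand),
      class = j$class, donor_dinuc = j$donor, acceptor_dinuc = j$acceptor,
      intron_length = j$len, strand = j$strand, n_injected = j$n_injected,
      stringsAsFactors = FALSE)
  }))
  stopifnot(!anyDuplicated(truth$junction_id))

  genes <- do.call(rbind, lapply(seq_along(all_jx), function(i) {
    j <- all_jx[[i]]
    clen <- length(genome[[j$chrom]])
    data.frame(gene_id = sprintf("SIMG%05d", i), chrom = j$chrom,
               start = max(1L, j$start - 100L),
               end = min(clen, j$end + 100L), strand = j$strand,
               stringsAsFactors = FALSE)
  }))

  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(genome = file.path(outdir, "sim_genome.fa"),
               annotation = file.path(outdir, "sim_annotation.gtf"),
               sj = file.path(outdir, "sim_SJ.tab"),
               truth = file.path(outdir, "sim_truth.tsv"))
    Biostrings::writeXStringSet(genome, paths[["genome"]])
    gtf <- sprintf(
      '%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s";',
      genes$chrom, genes$start, genes$end, genes$strand, genes$gene_id,
      genes$gene_id)
    writeLines(gtf, paths[["annotation"]])
    write_sj_table(sj, paths[["sj"]])
    write_tsv(truth, paths[["truth"]])
  }
  list(genome = genome, sj = sj, truth = truth, genes = genes,
       paths = paths)
}

#' Compare pipeline output against planted ground truth
#'
#' Per-stage agreement between a classified catalog and the generator's
#' truth table, joined on junction key: extracted sense motifs vs planted
#' terminal pairs, catalog category vs planted class, and classification
#' vs planted context type.
#'
#' @param catalog Classified junction catalog (must carry `junction_id`,
#'   motif, category and classification columns).
#' @param truth Truth table from [simulate_dataset()].
#' @return List with `motif_agreement` (fraction of truth junctions
#'   present in the catalog whose extracted motif pair matches the
#'   planted pair), `category_confusion` and `classification_confusion`
#'   (contingency tables), and `n_compared`.
#' @export
truth_compare <- function(catalog, truth) {
  idx <- match(catalog$junction_id, truth$junction_id)
  if (anyNA(idx)) {
    stop("catalog contains junction keys absent from the truth table")
  }
  tr <- truth[idx, , drop = FALSE]
  motif_ok <- catalog$donor_dinuc == tr$donor_dinuc &
    catalog$acceptor_dinuc == tr$acceptor_dinuc
  list(
    motif_agreement = mean(motif_ok),
    category_confusion = table(planted = tr$class,
                               category = catalog$category),
    classification_confusion = table(planted = tr$class,
                                     classification =
                                       catalog$classification),
    n_compared = nrow(catalog))
}
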