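#' Filter junctions by unique-read support
#'
#' Retains junctions supported by at least `min_unique` uniquely mapped
#' reads. The default of 2 keeps junctions with more than one unique read;
#' multi-mapping reads never count toward the filter.
#'
#' @param sj Junction data.frame (see [read_sj_table()]).
#' @param min_unique Minimum unique-read count to retain (default 2).
#' @return The retained rows, original order preserved. Retained/dropped
#'   counts are reported via `message()`.
#' @export
filter_junctions <- function(sj, min_unique = 2L) {
  stopifnot(min_unique >= 0)
  keep <- sj$unique_reads >= min_unique
  message("read-support filter (unique_reads >= ", min_unique, "): retained ",
          sum(keep), ", dropped ", sum(!keep))
  sj[keep, , drop = FALSE]
}

KNOWN_SPLICE_PATTERNS <- c("GTAG", "GCAG", "ATAC")

#' Resolve the transcribed strand of a junction
#'
#' Strand codes 1 and 2 map directly to "+" and "-". For code 0 the strand
#' is inferred from the intron's terminal dinucleotides: if exactly one of
#' the two readings (genomic-forward, or reverse-complemented) matches a
#' known splice pattern (GT-AG, GC-AG or AT-AC), that orientation is
#' returned; if both or neither match, the strand is "unresolved".
#'
#' @param chrom,start,end Intron coordinates (1-based inclusive).
#' @param strand_code Aligner strand code in \{0, 1, 2\}.
#' @param genome `DNAStringSet` genome.
#' @return One of `"+"`, `"-"`, `"unresolved"`.
#' @export
resolve_strand <- function(chrom, start, end, strand_code, genome) {
  if (strand_code == 1L) return("+")
  if (strand_code == 2L) return("-")
  pats <- tryCatch({
    d_fwd <- fetch_seq(genome, chrom, start, start + 1L)
    a_fwd <- fetch_seq(genome, chrom, end - 1L, end)
    list(fwd = paste0(d_fwd, a_fwd),
         rev = paste0(revcomp(a_fwd), revcomp(d_fwd)))
  }, error = function(e) NULL)
  if (is.null(pats)) return("unresolved")
  fwd_known <- pats$fwd %in% KNOWN_SPLICE_PATTERNS
  rev_known <- pats$rev %in% KNOWN_SPLICE_PATTERNS
  if (fwd_known && !rev_known) return("+")
  if (rev_known && !fwd_known) return("-")
  "unresolved"
}

#' Extract sense-strand terminal dinucleotides
#'
#' On "+" the donor dinucleotide is the first two intronic bases and the
#' acceptor the last two; on "-" both are read from the opposite intron
#' end and reverse-complemented, so the result is always reported in the
#' orientation of the spliced transcript.
#'
#' @inheritParams resolve_strand
#' @param strand `"+"` or `"-"`.
#' @return List with `donor` and `acceptor` 2-mers, or the invalid marker
#'   `"??"` in either slot when a terminal base is outside A/C/G/T or the
#'   coordinates fall off the contig.
#' @export
extract_motif <- function(chrom, start, end, strand, genome) {
  stopifnot(strand %in% c("+", "-"))
  res <- tryCatch({
    left <- fetch_seq(genome, chrom, start, start + 1L)
    right <- fetch_seq(genome, chrom, end - 1L, end)
    if (strand == "+") list(donor = left, acceptor = right)
    else list(donor = revcomp(right), acceptor = revcomp(left))
  }, error = function(e) list(donor = "??", acceptor = "??"))
  if (!grepl("^[ACGT]{2}$", res$donor)) res$donor <- "??"
  if (!grepl("^[ACGT]{2}$", res$acceptor)) res$acceptor <- "??"
  res
}

#' Categorize a junction from its sense-strand motif
#'
#' @param donor,acceptor Sense-strand terminal dinucleotides.
#' @return `"canonical"` for GT-AG, `"excluded"` when either dinucleotide
#'   carries the invalid marker, `"non_canonical"` otherwise.
#' @export
categorize <- function(donor, acceptor) {
  ifelse(donor == "??" | acceptor == "??", "excluded",
         ifelse(donor == "GT" & acceptor == "AG", "canonical",
                "non_canonical"))
}

#' Intron length in bases
#'
#' 1-based inclusive convention: `end - start + 1`.
#'
#' @param start,end Intron bounds.
#' @return Positive integer length.
#' @export
intron_length <- function(start, end) {
  stopifnot(all(end >= start))
  end - start + 1L
}

#' Assign containing genes to junctions
#'
#' A gene is assigned when its annotated span fully contains the intron
#' interval; junctions straddling a gene boundary get no assignment from
#' that gene. All containing genes are reported, ";"-joined, with an
#' ambiguity flag when more than one contains the junction.
#'
#' @param junctions Data.frame with `chrom`, `start`, `end`.
#' @param index A `gene_index` (see [build_gene_index()]); `NULL` skips
#'   assignment.
#' @return `junctions` with `genes` (character, "" when none) and
#'   `gene_ambiguous` (logical) columns added.
#' @export
assign_genes <- function(junctions, index) {
  if (is.null(index) || nrow(junctions) == 0L) {
    junctions$genes <- rep("", nrow(junctions))
    junctions$gene_ambiguous <- rep(FALSE, nrow(junctions))
    return(junctions)
  }
  gr <- attr(index, "granges")
  q <- GenomicRanges::GRanges(junctions$chrom,
                              IRanges::IRanges(junctions$start, junctions$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, gr, type = "within"))
  by_junction <- split(index$gene_name[S4Vectors::subjectHits(hits)],
                       factor(S4Vectors::queryHits(hits),
                              levels = seq_len(nrow(junctions))))
  junctions$genes <- vapply(by_junction, paste, character(1L), collapse = ";")
  junctions$gene_ambiguous <- lengths(by_junction) > 1L
  junctions
}

# Expected aligner motif code for genomic-forward terminal dinucleotides.
expected_motif_code <- function(fwd_donor, fwd_acceptor) {
  pair <- paste0(fwd_donor, fwd_acceptor)
  codes <- c(GTAG = 1L, CTAC = 2L, GCAG = 3L, CTGC = 4L,
             ATAC = 5L, GTAT = 6L)
  out <- codes[pair]
  out[is.na(out)] <- 0L
  unname(out)
}

#' Build the junction catalog
#'
#' Runs the cataloging stage end-to-end: read-support filtering, strand
#' resolution, sense-strand motif extraction, canonical/non-canonical
#' categorization, gene assignment and intron lengths. Motifs are always
#' derived from the genome sequence; the aligner's motif code is only
#' cross-checked against the sequence-derived code (mismatches are
#' reported, never trusted).
#'
#' @param sj Junction table (see [read_sj_table()]).
#' @param genome `DNAStringSet` genome.
#' @param gene_index Optional `gene_index` for gene assignment.
#' @param min_unique Read-support threshold (default 2).
#' @param literal_motif_code_rule If `TRUE`, categorize by the aligner's
#'   motif code (canonical iff code 1) instead of the sequence-derived
#'   sense-strand motif. Intended for comparison only; the sequence rule
#'   is the default because reported motif tables are sense-strand 4-mers.
#' @return A junction catalog data.frame: the filtered records plus
#'   `strand`, `donor_dinuc`, `acceptor_dinuc`, `intron_length`,
#'   `category` (canonical / non_canonical / excluded), `genes`,
#'   `gene_ambiguous` and `junction_id`.
#' @export
build_catalog <- function(sj, genome, gene_index = NULL, min_unique = 2L,
                          literal_motif_code_rule = FALSE) {
  jx <- filter_junctions(sj, min_unique)
  n <- nrow(jx)
  jx$strand <- character(n)
  jx$donor_dinuc <- character(n)
  jx$acceptor_dinuc <- character(n)
  for (i in seq_len(n)) {
    s <- resolve_strand(jx$chrom[i], jx$start[i], jx$end[i],
                        jx$strand_code[i], genome)
    jx$strand[i] <- s
    if (s %in% c("+", "-")) {
      m <- extract_motif(jx$chrom[i], jx$start[i], jx$end[i], s, genome)
      jx$donor_dinuc[i] <- m$donor
      jx$acceptor_dinuc[i] <- m$acceptor
    } else {
      jx$donor_dinuc[i] <- "??"
      jx$acceptor_dinuc[i] <- "??"
    }
  }
  jx$intron_length <- intron_length(jx$start, jx$end)
  if (literal_motif_code_rule) {
    jx$category <- ifelse(jx$motif_code == 1L, "canonical", "non_canonical")
    jx$category[jx$donor_dinuc == "??" | jx$acceptor_dinuc == "??"] <- "excluded"
  } else {
    jx$category <- categorize(jx$donor_dinuc, jx$acceptor_dinuc)
  }
  # cross-check the aligner's motif code against the sequence-derived one
  resolved <- jx$strand %in% c("+", "-") & jx$donor_dinuc != "??" &
    jx$acceptor_dinuc != "??"
  if (any(resolved)) {
    fwd_d <- ifelse(jx$strand[resolved] == "+", jx$donor_dinuc[resolved],
                    vapply(jx$acceptor_dinuc[resolved], revcomp, character(1L)))
    fwd_a <- ifelse(jx$strand[resolved] == "+", jx$acceptor_dinuc[resolved],
                    vapply(jx$donor_dinuc[resolved], revcomp, character(1L)))
    mismatch <- expected_motif_code(fwd_d, fwd_a) != jx$motif_code[resolved]
    if (any(mismatch)) {
      message(sum(mismatch),
              " junction(s) with aligner motif code differing from the ",
              "sequence-derived code (sequence-derived motifs kept)")
    }
  }
  jx <- assign_genes(jx, gene_index)
  jx$junction_id <- junction_key(jx)
  jx
}

junction_key <- function(jx) {
  paste0(jx$chrom, ":", jx$start, "-", jx$end, ":", jx$strand)
}

#' Tabulate splice-site classes
#'
#' Counts junctions per 4-mer splice-site class (donor dinucleotide
#' followed by acceptor dinucleotide) and converts counts to percentages
#' of all validly-motifed junctions, reported to 4 decimals and sorted by
#' descending count. Junctions with category `"excluded"` are left out.
#'
#' @param catalog Junction catalog (see [build_catalog()]).
#' @return Data.frame with `class`, `count`, `percent`.
#' @export
motif_table <- function(catalog) {
  valid <- catalog[catalog$category != "excluded", , drop = FALSE]
  counts <- table(paste0(valid$donor_dinuc, valid$acceptor_dinuc))
  class_percentages(data.frame(class = names(counts),
                               count = as.integer(counts),
                               stringsAsFactors = FALSE))
}

#' Percentages for a splice-site class count table
#'
#' Shared summarizer for count tables, whether tallied from a catalog or
#' supplied externally (e.g. a published class-count table): percent =
#' count / total * 100, rounded to 4 decimals, sorted by descending count.
#'
#' @param counts Data.frame with `class` and `count` columns.
#' @return Data.frame with `class`, `count`, `percent`.
#' @export
class_percentages <- function(counts) {
  stopifnot(all(c("class", "count") %in% names(counts)))
  total <- sum(counts$count)
  out <- counts[order(-counts$count, counts$class), c("class", "count")]
  out$percent <- round(out$count / total * 100, 4L)
  rownames(out) <- NULL
  out
}
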