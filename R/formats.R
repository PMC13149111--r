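#' Read a 9-column splice-junction table
#'
#' Parses the junction-table dialect emitted by splice-aware aligners:
#' one whitespace-separated row per junction with columns contig, intron
#' start, intron end (both 1-based inclusive), strand code (0 = undefined,
#' 1 = plus, 2 = minus), motif code (0-6), annotation flag, number of
#' uniquely mapping supporting reads, number of multi-mapping reads, and
#' maximum spliced-alignment overhang.
#'
#' @param path Path to the junction table (plain text, no header).
#' @return A data.frame with one row per junction and columns `chrom`,
#'   `start`, `end`, `strand_code`, `motif_code`, `annotated` (logical),
#'   `unique_reads`, `multi_reads`, `max_overhang`, in file order.
#' @export
read_sj_table <- function(path) {
  if (!file.exists(path)) {
    stop("junction table not found: ", path)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(empty_sj_table())
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 9L)
  if (length(bad) > 0L) {
    stop("malformed junction line ", bad[1L], ": expected 9 fields, found ",
         nf[bad[1L]])
  }
  mat <- t(vapply(fields, function(f) f[1:9], character(9L)))
  num <- suppressWarnings(apply(mat[, 2:9, drop = FALSE], 2L, as.integer))
  num <- matrix(num, nrow = nrow(mat))
  bad <- which(apply(is.na(num), 1L, any))
  if (length(bad) > 0L) {
    stop("malformed junction line ", bad[1L],
         ": non-integer value in a numeric field")
  }
  sj <- data.frame(
    chrom        = mat[, 1L],
    start        = num[, 1L],
    end          = num[, 2L],
    strand_code  = num[, 3L],
    motif_code   = num[, 4L],
    annotated    = num[, 5L] != 0L,
    unique_reads = num[, 6L],
    multi_reads  = num[, 7L],
    max_overhang = num[, 8L],
    stringsAsFactors = FALSE
  )
  validate_sj_table(sj)
  sj
}

empty_sj_table <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand_code = integer(), motif_code = integer(),
             annotated = logical(), unique_reads = integer(),
             multi_reads = integer(), max_overhang = integer(),
             stringsAsFactors = FALSE)
}

validate_sj_table <- function(sj) {
  bad <- which(sj$start < 1L | sj$end < sj$start |
                 !(sj$strand_code %in% 0:2) | !(sj$motif_code %in% 0:6) |
                 sj$unique_reads < 0L | sj$multi_reads < 0L |
                 sj$max_overhang < 0L)
  if (length(bad) > 0L) {
    stop("invalid junction record at line ", bad[1L],
         ": coordinate, code or count out of range")
  }
  invisible(sj)
}

#' Write a splice-junction table
#'
#' Inverse of [read_sj_table()]: writes the 9 positional columns as a
#' tab-separated file with no header, so a written table re-reads to
#' identical records.
#'
#' @param sj Data.frame as returned by [read_sj_table()].
#' @param path Output path.
#' @export
write_sj_table <- function(sj, path) {
  out <- data.frame(sj$chrom, sj$start, sj$end, sj$strand_code,
                    sj$motif_code, as.integer(sj$annotated),
                    sj$unique_reads, sj$multi_reads, sj$max_overhang)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load a genome FASTA for random access
#'
#' @param path FASTA path (a sidecar .fai index is tolerated but not
#'   required; the whole genome is held in memory as a `DNAStringSet`).
#' @return A named `Biostrings::DNAStringSet`; names are truncated at the
#'   first whitespace of the FASTA description line.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Fetch a genomic subsequence
#'
#' Coordinates are 1-based inclusive. Bases are uppercased on fetch;
#' non-ACGT letters (e.g. N) are returned as-is so callers can apply
#' their own invalid-base rules.
#'
#' @param genome A `DNAStringSet` (see [read_genome()]).
#' @param chrom Contig name.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param orientation `"forward"` or `"reverse_complement"`.
#' @return A character scalar of length `end - start + 1`.
#' @export
fetch_seq <- function(genome, chrom, start, end,
                      orientation = c("forward", "reverse_complement")) {
  orientation <- match.arg(orientation)
  if (!chrom %in% names(genome)) {
    stop("unknown contig: ", chrom)
  }
  len <- length(genome[[chrom]])
  if (start < 1L || end > len || start > end) {
    stop("coordinates out of bounds for ", chrom, ": ", start, "-", end,
         " (contig length ", len, ")")
  }
  s <- Biostrings::subseq(genome[[chrom]], start, end)
  if (orientation == "reverse_complement") {
    s <- Biostrings::reverseComplement(s)
  }
  toupper(as.character(s))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Build a gene span index from a GTF/GFF annotation
#'
#' One span per `gene_id`: the span of an explicit gene-level feature when
#' present, otherwise the min-start/max-end envelope of that gene's
#' transcript/exon records. Genes whose records disagree on the contig are
#' skipped with a warning.
#'
#' @param path GTF/GFF2/GFF3 annotation path.
#' @return An object of class `gene_index`: a data.frame of `gene_id`,
#'   `gene_name`, `chrom`, `start`, `end`, `strand` spans with a
#'   precomputed `GRanges` attached for containment queries.
#' @export
build_gene_index <- function(path) {
  gff <- tryCatch(rtracklayer::import(path),
                  error = function(e) stop("unparseable annotation: ",
                                           conditionMessage(e)))
  meta <- S4Vectors::mcols(gff)
  if (!"gene_id" %in% names(meta)) {
    stop("annotation carries no gene_id attribute")
  }
  df <- data.frame(
    chrom  = as.character(GenomicRanges::seqnames(gff)),
    start  = GenomicRanges::start(gff),
    end    = GenomicRanges::end(gff),
    strand = as.character(GenomicRanges::strand(gff)),
    type   = as.character(meta$type),
    gene_id = as.character(meta$gene_id),
    gene_name = if ("gene_name" %in% names(meta)) {
      as.character(meta$gene_name)
    } else {
      NA_character_
    },
    stringsAsFactors = FALSE
  )
  df <- df[!is.na(df$gene_id), , drop = FALSE]
  # prefer explicit gene rows; fall back to the feature envelope per gene
  gene_rows <- df[df$type == "gene", , drop = FALSE]
  rest <- df[!df$gene_id %in% gene_rows$gene_id, , drop = FALSE]
  spans <- rbind(gene_rows, rest)
  out <- do.call(rbind, lapply(split(spans, spans$gene_id), function(g) {
    if (length(unique(g$chrom)) > 1L) {
      warning("gene ", g$gene_id[1L],
              " spans multiple contigs; skipped", call. = FALSE)
      return(NULL)
    }
    data.frame(gene_id = g$gene_id[1L],
               gene_name = if (all(is.na(g$gene_name))) g$gene_id[1L]
                           else stats::na.omit(g$gene_name)[1L],
               chrom = g$chrom[1L],
               start = min(g$start), end = max(g$end),
               strand = g$strand[1L], stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), gene_name = character(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "granges") <- GenomicRanges::GRanges(
    out$chrom, IRanges::IRanges(out$start, out$end))
  class(out) <- c("gene_index", "data.frame")
  out
}

#' Query genes fully containing an interval
#'
#' @param index A `gene_index` from [build_gene_index()].
#' @param chrom,start,end Query interval, 1-based inclusive.
#' @return Character vector of `gene_name` labels whose span fully contains
#'   `[start, end]` (empty when none do).
#' @export
query_genes <- function(index, chrom, start, end) {
  gr <- attr(index, "granges")
  if (is.null(gr) || length(gr) == 0L) return(character())
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  # seqlevels may legitimately differ between query and annotation
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, gr, type = "within"))
  index$gene_name[S4Vectors::subjectHits(hits)]
}

#' Write a result table as TSV
#'
#' UTF-8 tab-separated output with a header line; the common writer for
#' all pipeline result tables.
#'
#' @param df Data.frame to write.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
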