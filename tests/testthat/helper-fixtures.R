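# Toy-data builders and independent oracles shared across the suite.

toy_genome <- function(...) {
  Biostrings::DNAStringSet(c(...))
}

write_fasta <- function(genome, path = tempfile(fileext = ".fa")) {
  Biostrings::writeXStringSet(genome, path)
  path
}

write_sj_lines <- function(lines, path = tempfile(fileext = ".tab")) {
  writeLines(lines, path)
  path
}

write_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_line <- function(chrom, type, start, end, strand, gene_id,
                     gene_name = gene_id) {
  sprintf('%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s";',
          chrom, type, start, end, strand, gene_id, gene_name)
}

# Full-enumeration two-sided Mann-Whitney p for tie-free samples: every
# C(n+m, n) assignment of ranks to x is equally likely under the null.
mwu_enum_p <- function(x, y) {
  n <- length(x)
  m <- length(y)
  stopifnot(anyDuplicated(c(x, y)) == 0L)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  sets <- utils::combn(n + m, n)
  u_all <- apply(sets, 2L, function(idx) sum(idx) - n * (n + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Brute-force containment query over gene spans.
brute_query <- function(spans, chrom, start, end) {
  hit <- spans$chrom == chrom & spans$start <= start & spans$end >= end
  spans$gene_name[hit]
}
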