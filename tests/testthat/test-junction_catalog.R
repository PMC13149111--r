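# A 60-bp contig with an intron at [11, 40]: terminal bases are set per
# test by splicing dinucleotides into a fixed background.
intron_contig <- function(donor_fwd = "GT", acceptor_fwd = "AG") {
  set.seed(5)
  bg <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  bg[11:12] <- strsplit(donor_fwd, "")[[1]]
  bg[39:40] <- strsplit(acceptor_fwd, "")[[1]]
  toy_genome(chr = paste(bg, collapse = ""))
}

test_that("read-support filter keeps unique_reads >= 2 by default", {
  sj <- data.frame(chrom = "c", start = 1:4, end = 11:14,
                   strand_code = 1L, motif_code = 1L, annotated = FALSE,
                   unique_reads = c(1L, 2L, 0L, 7L),
                   multi_reads = c(0L, 0L, 50L, 0L), max_overhang = 20L)
  expect_message(kept <- filter_junctions(sj), "retained 2, dropped 2")
  expect_equal(kept$start, c(2L, 4L))  # order preserved; multi reads ignored
  expect_message(all_kept <- filter_junctions(sj, min_unique = 0L))
  expect_equal(nrow(all_kept), 4L)
})

test_that("strand codes 1 and 2 map directly; code 0 is inferred", {
  g <- intron_contig("GT", "AG")
  expect_equal(resolve_strand("chr", 11, 40, 1L, g), "+")
  expect_equal(resolve_strand("chr", 11, 40, 2L, g), "-")
  # forward reading GT..AG is a known pattern, reverse reading CT..AC is not
  expect_equal(resolve_strand("chr", 11, 40, 0L, g), "+")
  # genomic CT..AC only reads as a known pattern after reverse complement
  expect_equal(resolve_strand("chr", 11, 40, 0L, intron_contig("CT", "AC")),
               "-")
  # GT..AC matches no known pattern in either reading
  expect_equal(resolve_strand("chr", 11, 40, 0L, intron_contig("GT", "AC")),
               "unresolved")
  # out-of-bounds coordinates cannot be oriented
  expect_equal(resolve_strand("chr", 55, 70, 0L, g), "unresolved")
})

test_that("terminal dinucleotides are reported in sense orientation", {
  plus <- extract_motif("chr", 11, 40, "+", intron_contig("GT", "AG"))
  expect_equal(plus, list(donor = "GT", acceptor = "AG"))
  # a minus-strand GT-AG intron appears as CT..AC on the forward genome
  minus <- extract_motif("chr", 11, 40, "-", intron_contig("CT", "AC"))
  expect_equal(minus, list(donor = "GT", acceptor = "AG"))
  withN <- extract_motif("chr", 11, 40, "+", intron_contig("GN", "AG"))
  expect_equal(withN$donor, "??")
  expect_equal(withN$acceptor, "AG")
  off <- extract_motif("chr", 55, 70, "+", intron_contig())
  expect_equal(off, list(donor = "??", acceptor = "??"))
})

test_that("categorization splits GT-AG from everything else", {
  expect_equal(categorize("GT", "AG"), "canonical")
  expect_equal(categorize("GC", "AG"), "non_canonical")
  expect_equal(categorize("GT", "TG"), "non_canonical")
  expect_equal(categorize("AT", "AC"), "non_canonical")
  expect_equal(categorize("??", "AG"), "excluded")
})

test_that("intron length uses the 1-based inclusive convention", {
  expect_equal(intron_length(1001L, 1100L), 100L)
  expect_equal(intron_length(5L, 104L), 100L)
  expect_equal(intron_length(7L, 7L), 1L)  # degenerate single-base intron
})

test_that("gene assignment requires full containment and reports all hits", {
  idx <- build_gene_index(write_gtf(c(
    gtf_line("chr1", "gene", 100, 500, "+", "A"),
    gtf_line("chr1", "gene", 300, 800, "+", "B"))))
  jx <- data.frame(chrom = "chr1", start = c(150L, 450L, 350L),
                   end = c(200L, 850L, 360L))
  out <- assign_genes(jx, idx)
  expect_equal(out$genes[1], "A")
  expect_equal(out$genes[2], "")    # straddles both gene ends
  expect_setequal(strsplit(out$genes[3], ";")[[1]], c("A", "B"))
  expect_equal(out$gene_ambiguous, c(FALSE, FALSE, TRUE))
})

test_that("minus-strand extraction mirrors plus-strand extraction", {
  # reverse-complementing the contig and mirroring coordinates must give
  # identical sense motifs with the opposite strand label
  set.seed(31)
  for (k in 1:10) {
    n <- 80
    bases <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    s <- sample(10:20, 1)
    e <- s + sample(20:40, 1)
    g_fwd <- toy_genome(c = paste(bases, collapse = ""))
    g_rev <- toy_genome(c = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(paste(bases, collapse = "")))))
    m_plus <- extract_motif("c", s, e, "+", g_fwd)
    m_mirror <- extract_motif("c", n - e + 1, n - s + 1, "-", g_rev)
    expect_equal(m_mirror, m_plus)
  }
})

test_that("catalog categories partition the filtered junctions", {
  run <- small_run()
  catalog <- run$report$catalog
  counts <- run$report$counts
  expect_equal(counts$canonical + counts$non_canonical + counts$excluded,
               counts$filtered)
  expect_equal(counts$filtered + counts$dropped, counts$parsed)
})

test_that("the literal aligner-code rule is available behind its flag", {
  # a minus-strand GT-AG intron: genomic CT..AC, aligner motif code 2
  g <- intron_contig("CT", "AC")
  sj <- data.frame(chrom = "chr", start = 11L, end = 40L,
                   strand_code = 2L, motif_code = 2L, annotated = FALSE,
                   unique_reads = 5L, multi_reads = 0L, max_overhang = 20L)
  seq_rule <- suppressMessages(build_catalog(sj, g))
  expect_equal(seq_rule$category, "canonical")
  literal <- suppressMessages(
    build_catalog(sj, g, literal_motif_code_rule = TRUE))
  expect_equal(literal$category, "non_canonical")
})

test_that("splice-site class table counts, sorts and renormalizes", {
  catalog <- data.frame(
    donor_dinuc = c("GT", "GT", "GT", "GC", "??"),
    acceptor_dinuc = c("AG", "AG", "AG", "AG", "AG"),
    category = c(rep("canonical", 3), "non_canonical", "excluded"))
  tab <- motif_table(catalog)
  expect_equal(tab$class, c("GTAG", "GCAG"))
  expect_equal(tab$count, c(3L, 1L))
  expect_equal(tab$percent, c(75, 25))

  single <- motif_table(data.frame(donor_dinuc = "GT",
                                   acceptor_dinuc = "AG",
                                   category = "canonical"))
  expect_equal(single$percent, 100)
})

test_that("class percentages sum to 100 within rounding slack", {
  run <- default_run()
  tab <- motif_table(run$report$catalog)
  expect_lt(abs(sum(tab$percent) - 100), 0.01)
  expect_equal(order(tab$count, decreasing = TRUE), seq_len(nrow(tab)))
})
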