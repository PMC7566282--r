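# Readers/writers and coordinate conventions for coverage tracks, gene
# annotations, terminator predictions and site catalogs.

test_that("bedGraph intervals expand to per-base 1-based counts", {
  td <- withr::local_tempdir()
  writeLines("chr\t9\t12\t5", file.path(td, "p.bg"))
  writeLines(character(), file.path(td, "m.bg"))
  tk <- read_end_coverage(c(plus = file.path(td, "p.bg"),
                            minus = file.path(td, "m.bg")),
                          "bedgraph_pair", c(chr = 100L), "lib")
  expect_identical(tk$counts$pos, 10:12)
  expect_true(all(tk$counts$count == 5))
  expect_true(all(tk$counts$strand == "+"))
})

test_that("per-base depth lines are read as identity", {
  td <- withr::local_tempdir()
  writeLines("chr\t7\t3", file.path(td, "p.d"))
  writeLines("chr\t9\t2", file.path(td, "m.d"))
  tk <- read_end_coverage(c(plus = file.path(td, "p.d"),
                            minus = file.path(td, "m.d")),
                          "per_base_depth", c(chr = 100L), "lib")
  expect_identical(tk$counts[tk$counts$strand == "+", ]$pos, 7L)
  expect_identical(tk$counts[tk$counts$strand == "+", ]$count, 3)
  expect_identical(tk$counts[tk$counts$strand == "-", ]$pos, 9L)
})

test_that("coverage write-then-read round-trips any simulated track", {
  td <- withr::local_tempdir()
  for (s in 1:5) {
    set.seed(s)
    n <- sample(10:60, 1)
    df <- data.frame(replicon = "chr", strand = sample(c("+", "-"), n, TRUE),
                     pos = sample.int(400, n),
                     count = stats::rpois(n, 5) + 1)
    tk <- make_track(df, c(chr = 400L))
    for (dia in c("bedgraph_pair", "per_base_depth")) {
      paths <- c(plus = file.path(td, "p"), minus = file.path(td, "m"))
      write_end_coverage(tk, paths, dia)
      tk2 <- read_end_coverage(paths, dia, c(chr = 400L), "lib",
                               "c1", "rep1", "termseq")
      expect_identical(tk2$counts, tk$counts)
    }
  }
})

test_that("coverage readers reject malformed input with line numbers", {
  td <- withr::local_tempdir()
  writeLines(c("chr\t1\t2\t3", "chr\tx\t5\t1"), file.path(td, "p.bg"))
  writeLines(character(), file.path(td, "m.bg"))
  expect_error(
    read_end_coverage(c(plus = file.path(td, "p.bg"),
                        minus = file.path(td, "m.bg")),
                      "bedgraph_pair", c(chr = 100L), "lib"),
    "line 2")
  writeLines("chr\t1\t2\t-4", file.path(td, "p.bg"))
  expect_error(
    read_end_coverage(c(plus = file.path(td, "p.bg"),
                        minus = file.path(td, "m.bg")),
                      "bedgraph_pair", c(chr = 100L), "lib"),
    "negative count")
})

test_that("track construction validates counts and positions", {
  df <- data.frame(replicon = "chr", strand = "+", pos = 5L, count = -1)
  expect_error(make_track(df, c(chr = 10L)), "negative")
  df$count <- 1
  df$pos <- 11L
  expect_error(make_track(df, c(chr = 10L)), "outside replicon")
  df$pos <- 5L
  df$strand <- "."
  expect_error(make_track(df, c(chr = 10L)), "strand")
})

test_that("gene annotations carry strand-aware start codons and classes", {
  td <- withr::local_tempdir()
  writeLines(c("##gff-version 3",
               "chr\t.\tgene\t100\t400\t.\t+\t.\tID=gA;gene_biotype=protein_coding",
               "chr\t.\tgene\t500\t700\t.\t-\t.\tID=gB;gene_biotype=protein_coding",
               "chr\t.\ttRNA\t800\t875\t.\t+\t.\tID=tR1"),
             file.path(td, "g.gff3"))
  genes <- read_gene_annotations(file.path(td, "g.gff3"))
  expect_identical(genes$start_codon_pos[genes$gene_id == "gA"], 100L)
  expect_identical(genes$start_codon_pos[genes$gene_id == "gB"], 700L)
  expect_identical(genes$feature_class[genes$gene_id == "tR1"], "tRNA")
  # TSV dialect, including strand validation
  tsv <- file.path(td, "g.tsv")
  utils::write.table(
    data.frame(gene_id = "g1", replicon_id = "chr", start = 10, end = 90,
               strand = "-", feature_class = "protein_coding"),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  g2 <- read_gene_annotations(tsv, "bed_like_tsv")
  expect_identical(g2$start_codon_pos, 90L)
  utils::write.table(
    data.frame(gene_id = "g1", replicon_id = "chr", start = 10, end = 90,
               strand = "?", feature_class = "protein_coding"),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_gene_annotations(tsv, "bed_like_tsv"), "strand")
})

test_that("TransTermHP reports parse with strand-aware 12-nt tails", {
  td <- withr::local_tempdir()
  # toy genome: 60 bp, known sequence
  gseq <- paste(rep("ACGT", 15), collapse = "")
  genome <- Biostrings::DNAStringSet(structure(gseq, names = "chr"))
  lines <- c(
    "SEQUENCE chr (length 60)",
    "  TERM 1           20 - 35  + F    96  -11.5  -4.2 | bidir",
    "    AAAAAAAAAAAAAAA        GCCGC TCTT GCGGC        TTTTTTTTATCG",
    "  TERM 2           45 - 30  - F    88  -10.0  -3.1 |",
    "    AAAAAAAAAAAAAAA        GCCGC TCTT GCGGC        TTTTTTTTGGCC",
    "  TERM 3           10 - 22  + T    54   -9.0  -2.2 |",
    "    AAAAAAAAAAAAAAA        GGGG TTTT CCCC        TTTTTTTTCCAA")
  writeLines(lines, file.path(td, "t.tt"))
  pred <- read_transterm_output(file.path(td, "t.tt"), genome)
  expect_identical(nrow(pred), 3L)
  expect_identical(pred$hairpin_start[2], 30L)
  expect_identical(pred$hairpin_end[2], 45L)
  # "-"-strand tail: reverse complement of genomic hairpin_start-12 ..
  # hairpin_start-1 (here 18..29)
  expected <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substr(gseq, 18, 29))))
  expect_identical(pred$tail_seq[2], expected)
  # "+"-strand tail is the plain downstream flank
  expect_identical(pred$tail_seq[1], substr(gseq, 36, 47))
  # truncated record and missing confidence are parse errors
  writeLines(lines[1:2], file.path(td, "bad.tt"))
  expect_error(read_transterm_output(file.path(td, "bad.tt")), "truncated")
  bad <- lines
  bad[2] <- "  TERM 1           20 - 35  + F    xx  -11.5  -4.2 |"
  writeLines(bad, file.path(td, "bad2.tt"))
  expect_error(read_transterm_output(file.path(td, "bad2.tt")), "confidence")
})

test_that("site catalogs write BED6 with 0-based intervals and phred scores", {
  td <- withr::local_tempdir()
  sc <- site_calls("chr", c(100L, 200L), c("+", "-"), "tss_primary",
                   fdr = c(0.05, 1e-200))
  bed <- file.path(td, "s.bed")
  write_site_catalog(sc, bed, "bed6")
  lines <- readLines(bed)
  f <- strsplit(lines[2], "\t")[[1]]
  expect_identical(f[2:3], c("99", "100"))
  expect_identical(f[5], "13")  # -10 log10(0.05) = 13.01, rounded
  expect_identical(strsplit(lines[3], "\t")[[1]][5], "1000")  # capped
  # empty catalog -> header-only file
  write_site_catalog(sc[0, ], bed, "bed6")
  expect_identical(length(readLines(bed)), 1L)
  # TSV round trip
  tsv <- file.path(td, "s.tsv")
  write_site_catalog(sc, tsv)
  sc2 <- read_site_catalog(tsv)
  expect_equal(sc2$position, sc$position)
  expect_equal(sc2$fdr, sc$fdr)
  expect_identical(sc2$strand, sc$strand)
})
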