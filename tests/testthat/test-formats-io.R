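# FASTA / GFF3 / bedGraph / read-table I/O and the interval conventions.

test_that("FASTA reading normalises case and RNA alphabet and keeps lengths", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGTacgt", ">c2 description", "uuACGn"), f)
  g <- read_fasta(f)
  expect_equal(names(g), c("c1", "c2"))
  expect_equal(as.character(g[["c1"]]), "ACGTACGT")
  expect_equal(as.character(g[["c2"]]), "TTACGN")
  expect_equal(unname(Biostrings::width(g)), c(8L, 6L))
})

test_that("FASTA parse errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT", ">c2", "ACXT"), f)
  expect_error(read_fasta(f), "line 4")
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "AC-T"), f2)
  expect_error(read_fasta(f2), "illegal character")
})

test_that("FASTA round trip is lossless", {
  g <- Biostrings::DNAStringSet(c(a = "ACGTN", b = "TTTTACGT"))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g, f)
  g2 <- read_fasta(f)
  expect_equal(as.character(g2), as.character(g))
})

test_that("GFF3 coordinates convert between 1-based inclusive and 0-based half-open", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1"), f)
  a <- read_gff3(f)
  expect_equal(a$records$start, 100L)
  expect_equal(a$records$end, 200L)
  expect_error(
    {
      f2 <- tempfile(); writeLines("chr1\tsrc\tgene\t10\t5\t.\t+\t.\tID=g2", f2)
      read_gff3(f2)
    },
    "end < start")
})

test_that("GFF3 round trip is byte-stable for the nine mandatory columns", {
  set.seed(3)
  n <- 10
  rec <- data.frame(
    seqid = sample(c("chr1", "chr2"), n, TRUE), source = "x",
    type = sample(c("gene", "mRNA"), n, TRUE),
    start = as.integer(sample(1000, n)), end = NA_integer_,
    score = sample(c(".", "0.5", "12"), n, TRUE),
    strand = sample(c("+", "-", "."), n, TRUE), phase = ".",
    attributes = sprintf("ID=f%02d;Note=a,b", 1:n),
    stringsAsFactors = FALSE)
  rec$end <- rec$start + sample(500, n)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gff3(annotation_set(rec), f1)
  write_gff3(read_gff3(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("overlap queries agree with a linear scan", {
  set.seed(42)
  n <- 500
  rec <- data.frame(
    seqid = sample(c("c1", "c2", "c3"), n, TRUE), source = ".",
    type = "gene", start = as.integer(sample(0:99000, n)),
    end = NA_integer_, score = ".", strand = ".", phase = ".",
    attributes = sprintf("ID=%d", 1:n), stringsAsFactors = FALSE)
  rec$end <- rec$start + sample(50:2000, n, TRUE)
  a <- annotation_set(rec)
  for (q in 1:25) {
    qc <- sample(c("c1", "c2", "c3"), 1)
    qs <- sample(0:100000, 1); qe <- qs + sample(10:5000, 1)
    got <- sort(annotation_overlaps(a, qc, qs, qe))
    want <- which(rec$seqid == qc & rec$start < qe & rec$end > qs)
    expect_equal(got, want)
  }
  # point query hits the single covering record
  p <- annotation_set(data.frame(seqid = "chr1", source = ".", type = "g",
                                 start = 100L, end = 200L, score = ".",
                                 strand = ".", phase = ".",
                                 attributes = "ID=x"))
  expect_equal(annotation_overlaps(p, "chr1", 150, 151), 1L)
})

test_that("bedGraph rasterisation is a length-weighted binning", {
  f <- withr::local_tempfile()
  writeLines("c1\t0\t100\t4", f)
  tr <- read_bedgraph(f, 50, c(c1 = 100L))
  expect_equal(tr$values$c1, c(4, 4))
  # partial coverage of the second bin: length-weighted value
  writeLines("c1\t0\t75\t4", f)
  tr <- read_bedgraph(f, 50, c(c1 = 100L))
  expect_equal(tr$values$c1, c(4, 2))
  # empty file -> all-zero track
  writeLines(character(0), f)
  tr <- read_bedgraph(f, 50, c(c1 = 100L))
  expect_equal(tr$values$c1, c(0, 0))
  # overlapping input intervals are ambiguous
  writeLines(c("c1\t0\t60\t1", "c1\t50\t80\t2"), f)
  expect_error(read_bedgraph(f, 50, c(c1 = 100L)), "overlapping")
})

test_that("bedGraph write/read round trip preserves the rasterised track", {
  set.seed(9)
  for (i in 1:5) {
    v <- round(rexp(40), 3)
    v[sample(40, 10)] <- 0
    tr <- coverage_track(list(c1 = v), 25, contig_lengths = c(c1 = 1000L))
    f <- withr::local_tempfile()
    write_bedgraph(tr, f)
    tr2 <- read_bedgraph(f, 25, c(c1 = 1000L))
    expect_equal(tr2$values$c1, v)
  }
  # ragged final bin survives the round trip
  v <- c(1, 2, 3)
  tr <- coverage_track(list(c1 = v), 50, contig_lengths = c(c1 = 130L))
  f <- withr::local_tempfile()
  write_bedgraph(tr, f)
  expect_equal(read_bedgraph(f, 50, c(c1 = 130L))$values$c1, v)
})

test_that("read tables parse from TSV and SAM with the strand-aware 5' rule", {
  g <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 50), collapse = "")))
  f <- withr::local_tempfile()
  writeLines(c("contig\tstart\tend\tstrand\tcount",
               "chr1\t100\t124\t+\t3",
               "chr1\t100\t124\t-\t1"), f)
  r <- read_reads(f, g)
  expect_equal(r$length, c(24L, 24L))
  expect_equal(r$count, c(3L, 1L))
  # + strand: base at start (position 100 -> "A"); - strand: complement of
  # base at end-1 (position 123 -> "T" -> "A")
  expect_equal(r$five_prime_nt[1], "A")
  expect_equal(r$five_prime_nt[2], "A")
  # SAM: 24M at 1-based pos 101 -> interval (100, 124); flag 16 = minus
  s <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               paste("r1", 0, "chr1", 101, 60, "24M", "*", 0, 0, "*", "*",
                     sep = "\t"),
               paste("r2", 16, "chr1", 11, 60, "10M2D10M", "*", 0, 0, "*",
                     "*", sep = "\t")), s)
  rs <- read_reads(s, g)
  expect_equal(rs$start, c(100L, 10L))
  expect_equal(rs$end, c(124L, 32L))
  expect_equal(rs$strand, c("+", "-"))
  # errors
  f2 <- withr::local_tempfile()
  writeLines(c("contig\tstart\tend\tstrand\tcount", "chr1\t10\t30\t*\t1"), f2)
  expect_error(read_reads(f2), "strand")
  writeLines(c("contig\tstart\tend\tstrand\tcount", "chr1\t30\t30\t+\t1"), f2)
  expect_error(read_reads(f2), "end")
})
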