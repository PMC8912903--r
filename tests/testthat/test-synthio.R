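# The planted-element generator: determinism, divergence model, read
# statistics, coverage structure, truth round trip.

test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_config(seed = 21)
  a <- build_genome(cfg)
  b <- build_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
  expect_identical(a$features, b$features)
  ra <- simulate_reads(a, "wild_type")
  rb <- simulate_reads(b, "wild_type")
  expect_identical(ra, rb)
})

test_that("zero families yields a pure background genome with empty truth", {
  cfg <- synth_config(seed = 2, n_families = 0L,
                      contig_lengths = c(c1 = 60000L), n_decoy_genes = 4L)
  sg <- build_genome(cfg)
  expect_equal(nrow(sg$truth), 0L)
  expect_equal(unname(Biostrings::width(sg$genome)), 60000L)
  expect_equal(nrow(simulate_reads(sg, "wild_type")), 0L)
})

test_that("zero within-family divergence gives identical same-family copies", {
  cfg <- small_config(seed = 5, within_divergence = 0)
  sg <- build_genome(cfg)
  tr <- sg$truth[sg$truth$class == "full_length", ]
  fams <- split(seq_len(nrow(tr)), tr$family)
  # with one full copy per family, compare the element to a second build's
  # copy via its own LTRs: both LTRs of one copy must be exact repeats
  ft <- sg$features[sg$features$feature == "LTR", ]
  for (i in seq_len(nrow(tr))) {
    l <- ft[ft$element_id == tr$element_id[i], ]
    s1 <- as.character(Biostrings::subseq(sg$genome[[tr$contig[i]]],
                                          l$start[1] + 1, l$end[1]))
    s2 <- as.character(Biostrings::subseq(sg$genome[[tr$contig[i]]],
                                          l$start[2] + 1, l$end[2]))
    expect_identical(s1, s2)
  }
})

test_that("planted elements are disjoint and inside their contigs", {
  sg <- small_dataset()
  tr <- sg$truth
  for (cn in unique(tr$contig)) {
    d <- tr[tr$contig == cn, ]
    d <- d[order(d$start), ]
    expect_true(all(d$start >= 0))
    expect_true(all(d$end <= Biostrings::width(sg$genome)[
      match(cn, names(sg$genome))]))
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  # full-length records carry exactly two flanking LTR sub-intervals
  fl <- tr[tr$class == "full_length", ]
  for (i in seq_len(nrow(fl))) {
    l <- sg$features[sg$features$element_id == fl$element_id[i] &
                       sg$features$feature == "LTR", ]
    expect_equal(nrow(l), 2L)
    expect_equal(min(l$start), fl$start[i])
    expect_equal(max(l$end), fl$end[i])
  }
})

test_that("wild-type read statistics match the configured distributions", {
  sg <- small_dataset()
  cfg <- sg$config
  reads <- simulate_reads(sg, "wild_type")
  n_elem <- sum(sg$truth$class != "solo_LTR")
  # counts are exact
  expect_equal(sum(reads$count), n_elem * cfg$sirna_per_element)
  # realized 5'U fraction within +/- 0.05 of the target
  expect_lt(abs(mean(reads$five_prime_nt == "U") - cfg$five_prime_u), 0.05)
  # antisense fraction within +/- 0.03 of the target (binomial bound)
  tr <- sg$truth[sg$truth$class != "solo_LTR", ]
  sense <- 0
  for (i in seq_len(nrow(tr))) {
    sel <- reads$contig == tr$contig[i] & reads$start >= tr$start[i] &
      reads$end <= tr$end[i]
    sense <- sense + sum(reads$strand[sel] == tr$strand[i])
  }
  expect_lt(abs(1 - sense / sum(reads$count) - cfg$antisense_fraction), 0.03)
  # length distribution is supported on the configured lengths
  expect_true(all(reads$length %in%
                    as.integer(names(cfg$sirna_length_probs))))
})

test_that("mutant reads are sense-only degradation over the mobilizing family", {
  sg <- small_dataset()
  reads <- simulate_reads(sg, "mutant")
  tr <- sg$truth
  mob <- tr[tr$family == sg$config$mobilizing_family &
              tr$class != "solo_LTR", ]
  other <- tr[tr$family != sg$config$mobilizing_family, ]
  # all reads fall on mobilizing-family elements, on the element strand
  for (i in seq_len(nrow(mob))) {
    sel <- reads$contig == mob$contig[i] & reads$start >= mob$start[i] &
      reads$end <= mob$end[i]
    expect_true(all(reads$strand[sel] == mob$strand[i]))
  }
  for (i in seq_len(nrow(other))) {
    sel <- reads$contig == other$contig[i] & reads$start >= other$start[i] &
      reads$end <= other$end[i]
    expect_equal(sum(sel), 0L)
  }
  expect_true(all(reads$length >= 18 & reads$length <= 30))
})

test_that("mRNA coverage shows the configured fold over elements in the mutant", {
  sg <- small_dataset()
  cfg <- sg$config
  wt <- simulate_coverage(sg, "mRNA", "wild_type")
  mut <- simulate_coverage(sg, "mRNA", "mutant")
  tr <- sg$truth[sg$truth$class != "solo_LTR", ]
  rats <- vapply(seq_len(nrow(tr)), function(i) {
    b0 <- tr$start[i] %/% cfg$bin_size + 2L
    b1 <- tr$end[i] %/% cfg$bin_size - 1L
    mean(mut$values[[tr$contig[i]]][b0:b1]) /
      mean(wt$values[[tr$contig[i]]][b0:b1])
  }, 0.0)
  expect_true(all(abs(rats - cfg$mrna_fold) / cfg$mrna_fold < 0.3))
  # background bins are unchanged (ratio about 1)
  bg <- mean(mut$values$chrI[1:500]) / mean(wt$values$chrI[1:500])
  expect_lt(abs(bg - 1), 0.2)
  # sRNA track in the mutant is empty outside the mobilizing family
  smut <- simulate_coverage(sg, "sRNA", "mutant")
  other <- sg$truth[sg$truth$family != cfg$mobilizing_family, ]
  for (i in seq_len(nrow(other))) {
    b0 <- other$start[i] %/% cfg$bin_size + 1L
    b1 <- (other$end[i] - 1L) %/% cfg$bin_size + 1L
    expect_equal(sum(smut$values[[other$contig[i]]][b0:b1]), 0)
  }
})

test_that("truth GFF3 round trip preserves the in-memory truth", {
  sg <- small_dataset()
  f <- withr::local_tempfile(fileext = ".gff3")
  write_truth_gff3(sg, f)
  back <- read_truth_gff3(f)
  expect_equal(back$truth, sg$truth, ignore_attr = TRUE)
  ord <- order(back$features$element_id, back$features$start,
               back$features$feature)
  ord0 <- order(sg$features$element_id, sg$features$start,
                sg$features$feature)
  expect_equal(back$features[ord, ], sg$features[ord0, ],
               ignore_attr = TRUE)
})
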