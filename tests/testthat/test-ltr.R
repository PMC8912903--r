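# Direct-repeat (LTR) detection and element classification.

test_that("an exact planted repeat pair is recovered at its exact coordinates", {
  set.seed(12)
  ltr <- random_seq(300)
  mid <- random_seq(1500)
  seq <- paste0(random_seq(400), ltr, mid, ltr, random_seq(400))
  # anchor on the internal cassette
  pairs <- find_direct_repeats(seq, 700, 2200, flank = 700, min_len = 100)
  expect_gte(nrow(pairs), 1)
  best <- pairs[1, ]
  expect_equal(best$left_start, 400L)
  expect_equal(best$left_end, 700L)
  expect_equal(best$right_start, 2200L)
  expect_equal(best$right_end, 2500L)
  expect_equal(best$identity, 1.0)
})

test_that("a diverged repeat pair reports its true identity", {
  set.seed(13)
  ltr <- random_seq(300)
  n_mut <- 45   # 15% divergence -> 85% identity
  ltr2 <- mutate_at(ltr, sample(300, n_mut))
  seq <- paste0(random_seq(500), ltr, random_seq(1200), ltr2,
                random_seq(500))
  pairs <- find_direct_repeats(seq, 800, 2000, flank = 800, min_len = 100,
                               min_identity = 0.8)
  expect_gte(nrow(pairs), 1)
  expect_lt(abs(pairs$identity[1] - 0.85), 0.03)
  # identity is symmetric in the two repeats
  rev_pairs <- find_direct_repeats(seq, 800, 2000, flank = 800,
                                   min_len = 100, min_identity = 0.8)
  expect_equal(pairs$identity[1], rev_pairs$identity[1])
})

test_that("shuffled sequence of equal composition yields no repeat pair", {
  set.seed(14)
  base <- strsplit(random_seq(3000), "")[[1]]
  seq <- paste(sample(base), collapse = "")
  pairs <- find_direct_repeats(seq, 1400, 1600, flank = 1400,
                               min_len = 100, min_identity = 0.80)
  expect_equal(nrow(pairs), 0L)
})

test_that("the seeded finder agrees with all-substring-pair brute force on short sequences", {
  for (trial in 1:5) {
    set.seed(100 + trial)
    rep_len <- sample(60:90, 1)
    rep_seq <- random_seq(rep_len)
    rep2 <- if (trial %% 2 == 0) rep_seq else
      mutate_at(rep_seq, sample(rep_len, ceiling(rep_len * 0.05)))
    up_pad <- sample(10:40, 1); dn_pad <- sample(10:40, 1)
    up <- paste0(random_seq(up_pad), rep_seq, random_seq(20))
    dn <- paste0(random_seq(20), rep2, random_seq(dn_pad))
    seq <- paste0(up, "ACGT", dn)   # tiny anchor between the flanks
    a0 <- nchar(up); a1 <- a0 + 4L
    got <- suppressWarnings(
      find_direct_repeats(seq, a0, a1, flank = max(nchar(up), nchar(dn)),
                          k = 12, min_len = 50, min_identity = 0.8))
    want <- oracle_best_repeat(up, substr(seq, a1 + 1, nchar(seq)),
                               min_len = 50, min_identity = 0.8)
    expect_false(is.null(want))
    expect_gte(nrow(got), 1)
    best <- got[1, ]
    # same repeat locus (ungapped oracle vs gapped extension: allow the
    # trimmed terminal mismatch columns)
    expect_lt(abs(best$left_start - want$u_start), 6)
    expect_lt(abs(best$left_end - want$u_end), 6)
    expect_lt(abs(best$right_start - (a1 + want$d_start)), 6)
    expect_lt(abs(best$identity - want$identity), 0.05)
    # negative control: both methods find nothing on random flanks
    up_r <- random_seq(150); dn_r <- random_seq(150)
    seq_r <- paste0(up_r, "ACGT", dn_r)
    got_r <- suppressWarnings(
      find_direct_repeats(seq_r, 150, 154, flank = 150, k = 12,
                          min_len = 50, min_identity = 0.8))
    want_r <- oracle_best_repeat(up_r, dn_r, 50, 0.8)
    expect_equal(nrow(got_r), 0L)
    expect_null(want_r)
  }
})

test_that("classification applies the structural rules", {
  hits <- data.frame(contig = "c", start = c(1000L, 2000L, 3000L),
                     end = c(1300L, 2300L, 3300L), frame = 1L,
                     model = c("gag", "reverse_transcriptase", "integrase"),
                     score = c(50, 80, 70), stringsAsFactors = FALSE)
  pair <- data.frame(left_start = 500L, left_end = 800L,
                     right_start = 3500L, right_end = 3800L,
                     identity = 0.95, length = 300L, score = 280,
                     span = 3300L)
  reg <- list(contig = "c", start = 400L, end = 3900L)
  full <- classify_element(reg, hits, pair)
  expect_equal(full$class, "full_length")
  expect_equal(full$start, 500L)
  expect_equal(full$end, 3800L)
  # single domain, no pair -> partial over the domain envelope
  part <- classify_element(reg, hits[hits$model == "reverse_transcriptase", ],
                           NULL)
  expect_equal(part$class, "partial")
  expect_equal(c(part$start, part$end), c(2000L, 2300L))
  # RT + integrase but no pair -> still partial
  expect_equal(classify_element(reg, hits, NULL)$class, "partial")
  # lone LTR with the nearest domain 5 kb away -> solo
  far_hits <- data.frame(contig = "c", start = 9000L, end = 9300L,
                         frame = 1L, model = "gag", score = 50,
                         stringsAsFactors = FALSE)
  solo <- classify_element(list(contig = "c", start = 400L, end = 700L),
                           far_hits, NULL, is_ltr_match = TRUE)
  expect_equal(solo$class, "solo_LTR")
  # a domain within the exclusion distance blocks the solo call
  near_hits <- data.frame(contig = "c", start = 1200L, end = 1500L,
                          frame = 1L, model = "gag", score = 50,
                          stringsAsFactors = FALSE)
  expect_null(classify_element(list(contig = "c", start = 400L, end = 700L),
                               near_hits, NULL, is_ltr_match = TRUE))
  # no evidence at all -> no call
  expect_null(classify_element(reg, hits[0, ], NULL))
})

test_that("TG...CA termini are flagged but never required", {
  g <- Biostrings::DNAStringSet(c(c = paste0(
    strrep("A", 100), "TG", random_seq(296, seed = 5), "CA",
    strrep("A", 100))))
  hits <- data.frame(contig = "c", start = 150L, end = 300L, frame = 1L,
                     model = "reverse_transcriptase", score = 60,
                     stringsAsFactors = FALSE)
  hits <- rbind(hits, within(hits, model <- "integrase"))
  pair <- data.frame(left_start = 100L, left_end = 160L,
                     right_start = 340L, right_end = 400L,
                     identity = 0.9, length = 60L, score = 50, span = 300L)
  cl <- classify_element(list(contig = "c", start = 90L, end = 410L),
                         hits, pair, genome = g)
  expect_true(cl$tg_ca)
  expect_equal(cl$class, "full_length")
})
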