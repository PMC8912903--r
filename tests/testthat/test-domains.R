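# Six-frame translation, PSSM construction and calibration, domain scans.

test_that("six-frame translation follows the standard code and frames", {
  tr <- six_frame_translate("ATGGCC")
  expect_equal(tr[["+1"]]$aa, "MA")
  # reverse frames equal the forward frames of the reverse complement
  fwd_of_rc <- six_frame_translate("CAT")
  rev <- six_frame_translate("ATG")
  expect_equal(rev[["-1"]]$aa, fwd_of_rc[["+1"]]$aa)
  # frame +2 residue 0 on a 7-mer covers nucleotides (1, 4)
  expect_equal(frame_residue_interval(2L, 0L, 7L), c(1L, 4L))
  # minus-frame map is the mirrored interval
  expect_equal(frame_residue_interval(-1L, 0L, 9L), c(6L, 9L))
  # all-N input yields empty translations
  trN <- six_frame_translate("NNNNNN")
  expect_true(all(vapply(trN, function(f) f$aa == "", TRUE)))
  expect_error(six_frame_translate("AT"), "shorter")
})

test_that("PSSM columns follow the smoothed log-odds formula", {
  aln <- c("WA", "WA", "WC", "WD")
  m <- build_model(aln, pseudocount = 0.5)
  expect_equal(unname(m$matrix["W", 1]), log2((4.5 / 14) / 0.05))
  # uniform column: score equal for present residues, lower for absent
  aln20 <- vapply(AA20 <- rownames(m$matrix), function(a) paste0(a, "A"), "")
  m20 <- build_model(unname(aln20), pseudocount = 0.5)
  expect_equal(length(unique(round(m20$matrix[, 1], 12))), 1L)
  expect_lt(m$matrix["Y", 1], min(m$matrix[c("A", "C", "D"), 2]))
  expect_error(build_model(c("WA", "WAA")), "ragged")
})

test_that("threshold calibration is deterministic, monotone in alpha, and edge-correct", {
  m <- build_model(c("WWAC", "WWAD", "WYAC"), name = "toy")
  t1 <- calibrate_threshold(m, 500, alpha = 1e-2, seed = 4)$threshold
  t2 <- calibrate_threshold(m, 500, alpha = 1e-2, seed = 4)$threshold
  expect_identical(t1, t2)
  tm <- calibrate_threshold(m, 500, alpha = 1, seed = 4)
  # alpha = 1 gives the minimum null score
  expect_lte(tm$threshold, t1)
  t_strict <- calibrate_threshold(m, 500, alpha = 1e-3, seed = 4)$threshold
  expect_gte(t_strict, t1)
})

test_that("a model's consensus outscores any single-residue mutant", {
  set.seed(8)
  cons <- paste(sample(rownames(build_model(c("AA", "CC"))$matrix), 30,
                       TRUE), collapse = "")
  vars <- vapply(1:4, function(i) {
    ch <- strsplit(cons, "")[[1]]
    p <- sample(30, 2)
    ch[p] <- sample(setdiff(LETTERS[LETTERS %in% rownames(
      build_model(c("AA", "CC"))$matrix)], ch[p]), 2)
    paste(ch, collapse = "")
  }, "")
  m <- build_model(c(cons, vars))
  score_of <- function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(m$matrix[cbind(match(ch, rownames(m$matrix)), seq_along(ch))])
  }
  s0 <- score_of(cons)
  aas <- rownames(m$matrix)
  for (i in c(1, 10, 30)) for (a in aas[c(3, 11, 17)]) {
    ch <- strsplit(cons, "")[[1]]
    if (ch[i] == a) next
    ch[i] <- a
    expect_lte(score_of(paste(ch, collapse = "")), s0)
  }
})

test_that("planted cassette domains are all detected in the encoding frame", {
  sg <- small_dataset()
  models <- load_domain_models()
  tr <- sg$truth[sg$truth$class == "full_length", ][1, ]
  hits <- scan_domains(list(contig = tr$contig, start = tr$start,
                            end = tr$end), sg$genome, models)
  doms <- sg$features[sg$features$element_id == tr$element_id &
                        sg$features$feature != "LTR", ]
  for (i in seq_len(nrow(doms))) {
    hd <- hits[hits$model == doms$feature[i], ]
    expect_true(any(hd$start < doms$end[i] & hd$end > doms$start[i]),
                info = doms$feature[i])
  }
  # best hits recover the planted coordinates exactly
  for (i in seq_len(nrow(doms))) {
    hd <- hits[hits$model == doms$feature[i], ]
    best <- hd[which.max(hd$score), ]
    expect_equal(best$start, doms$start[i])
    expect_equal(best$end, doms$end[i])
  }
})

test_that("false-positive rate on random sequence respects the calibrated null", {
  models <- load_domain_models()
  g <- Biostrings::DNAStringSet(c(bg = random_seq(10000, seed = 33)))
  hits <- scan_domains(list(contig = "bg", start = 0L, end = 10000L),
                       g, models)
  # expected false windows ~ alpha * windows per model (about 8 before the
  # same-model overlap reduction); allow 3x the bound after reduction
  n_windows <- sum(vapply(models, function(m) {
    6 * (floor(10000 / 3) - m$length + 1)
  }, 0.0))
  expect_lte(nrow(hits), 3 * 1e-3 * n_windows)
})

test_that("the vectorised scan equals naive all-window rescoring", {
  sg <- small_dataset()
  models <- load_domain_models()
  tr <- sg$truth[sg$truth$class == "full_length", ][1, ]
  start <- tr$start + 500L; end <- start + 2000L
  seq <- as.character(Biostrings::subseq(sg$genome[[tr$contig]], start + 1L,
                                         end))
  for (mn in c("reverse_transcriptase", "gag")) {
    model <- models[[mn]]
    got <- scan_domains(list(contig = tr$contig, start = start, end = end),
                        sg$genome, models[mn])
    want <- oracle_scan(seq, model)
    if (nrow(want) == 0L) { expect_equal(nrow(got), 0L); next }
    # the oracle keeps overlapping windows; reduce it the same way and
    # compare coordinates and scores
    want <- want[order(-want$score), ]
    kept <- want[0, ]
    for (r in seq_len(nrow(want))) {
      if (!any(kept$start < want$end[r] & want$start[r] < kept$end)) {
        kept <- rbind(kept, want[r, ])
      }
    }
    kept <- kept[order(kept$start), ]
    expect_equal(got$start - start, kept$start)
    expect_equal(got$end - start, kept$end)
    expect_equal(got$score, kept$score, tolerance = 1e-10)
  }
})

test_that("hits map inside the scanned region and uncalibrated models error", {
  sg <- small_dataset()
  models <- load_domain_models()
  tr <- sg$truth[sg$truth$class == "full_length", ][1, ]
  hits <- scan_domains(list(contig = tr$contig, start = tr$start,
                            end = tr$end), sg$genome, models)
  expect_true(all(hits$start >= tr$start & hits$end <= tr$end))
  expect_true(all(hits$end - hits$start == 3 * vapply(
    models[hits$model], function(m) m$length, 0L)))
  m <- build_model(c("WWA", "WWC"), name = "raw")
  expect_error(scan_domains(list(contig = tr$contig, start = tr$start,
                                 end = tr$end), sg$genome, list(raw = m)),
               "uncalibrated")
})
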