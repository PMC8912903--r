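# Differential-coverage candidate calling.

mk_track <- function(..., bin = 50, norm = "RPKM", lens = NULL) {
  vals <- list(...)
  coverage_track(vals, bin, normalization = norm, contig_lengths = lens)
}

test_that("ratio_track computes the pseudocounted per-bin ratio", {
  mut <- mk_track(c1 = c(7, 3, 0))
  wt <- mk_track(c1 = c(3, 3, 0))
  r <- ratio_track(mut, wt, pseudocount = 1)
  expect_equal(r$values$c1, c(2, 1, 1))
  expect_error(ratio_track(mut, mk_track(c1 = c(1, 2))), "bin counts")
  expect_error(ratio_track(mut, coverage_track(list(c1 = c(1, 2, 3)), 25)),
               "bin sizes")
})

test_that("identical conditions produce no candidates", {
  sw <- mk_track(c1 = rep(10, 200))
  mm <- mk_track(c1 = rep(5, 200))
  ann <- annotation_set(data.frame(seqid = character(), source = character(),
                                   type = character(), start = integer(),
                                   end = integer(), score = character(),
                                   strand = character(), phase = character(),
                                   attributes = character()))
  out <- call_candidates(sw, sw, mm, mm, ann)
  expect_equal(nrow(out), 0L)
})

test_that("signal regions are called, annotated regions are excluded", {
  nb <- 400
  sw <- rep(0, nb); sm <- rep(0, nb); mw <- rep(5, nb); mm <- rep(5, nb)
  # element across bins 101..200 (5000 bp at bin 50): sRNA lost, mRNA gained
  sw[101:200] <- 100; mm[101:200] <- 40
  ann0 <- annotation_set(data.frame(seqid = character(), source = character(),
                                    type = character(), start = integer(),
                                    end = integer(), score = character(),
                                    strand = character(), phase = character(),
                                    attributes = character()))
  out <- call_candidates(mk_track(c1 = sw), mk_track(c1 = sm),
                         mk_track(c1 = mw), mk_track(c1 = mm), ann0)
  expect_equal(nrow(out), 1L)
  expect_equal(out$class, "lost")
  expect_true(out$long_enough)
  expect_lt(abs(out$start - 100 * 50), 150)
  expect_lt(abs(out$end - 200 * 50), 150)
  # covering annotation removes the region
  ann1 <- annotation_set(data.frame(seqid = "c1", source = ".", type = "gene",
                                    start = 4000L, end = 11000L, score = ".",
                                    strand = "+", phase = ".",
                                    attributes = "ID=g"))
  out1 <- call_candidates(mk_track(c1 = sw), mk_track(c1 = sm),
                          mk_track(c1 = mw), mk_track(c1 = mm), ann1)
  expect_equal(nrow(out1), 0L)
})

test_that("a mutant-gained sRNA population is called as changed", {
  nb <- 400
  sw <- rep(0, nb); sm <- rep(0, nb); mw <- rep(5, nb); mm <- rep(5, nb)
  sw[101:200] <- 50; sm[101:200] <- 260; mm[101:200] <- 40
  ann0 <- annotation_set(data.frame(seqid = character(), source = character(),
                                    type = character(), start = integer(),
                                    end = integer(), score = character(),
                                    strand = character(), phase = character(),
                                    attributes = character()))
  out <- call_candidates(mk_track(c1 = sw), mk_track(c1 = sm),
                         mk_track(c1 = mw), mk_track(c1 = mm), ann0)
  expect_equal(out$class, "changed")
})

test_that("raw tracks are rejected and outputs are disjoint and sorted", {
  sw <- mk_track(c1 = rep(10, 50), norm = "raw")
  expect_error(call_candidates(sw, sw, sw, sw,
                               annotation_set(empty_annotation_records())),
               "RPKM")
  sg <- small_dataset()
  rw <- simulate_reads(sg, "wild_type"); rm <- simulate_reads(sg, "mutant")
  out <- call_candidates(
    simulate_coverage(sg, "sRNA", "wild_type", reads = rw),
    simulate_coverage(sg, "sRNA", "mutant", reads = rm),
    simulate_coverage(sg, "mRNA", "wild_type"),
    simulate_coverage(sg, "mRNA", "mutant"),
    sg$annotations)
  for (cn in unique(out$contig)) {
    d <- out[out$contig == cn, ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  # none overlaps the supplied annotation set
  for (i in seq_len(nrow(out))) {
    expect_length(annotation_overlaps(sg$annotations, out$contig[i],
                                      out$start[i], out$end[i]), 0)
  }
})

test_that("raising the mRNA-gain fold never adds a region", {
  sg <- small_dataset()
  rw <- simulate_reads(sg, "wild_type"); rm <- simulate_reads(sg, "mutant")
  sw <- simulate_coverage(sg, "sRNA", "wild_type", reads = rw)
  sm <- simulate_coverage(sg, "sRNA", "mutant", reads = rm)
  mw <- simulate_coverage(sg, "mRNA", "wild_type")
  mm <- simulate_coverage(sg, "mRNA", "mutant")
  prev <- NULL
  for (fold in c(2, 3, 5, 9)) {
    out <- call_candidates(sw, sm, mw, mm, sg$annotations,
                           signature_thresholds(mrna_gain_fold = fold))
    if (!is.null(prev)) {
      # every region at the stricter fold lies within a region at the
      # looser fold
      for (i in seq_len(nrow(out))) {
        expect_true(any(prev$contig == out$contig[i] &
                          prev$start <= out$start[i] + 50 &
                          prev$end >= out$end[i] - 50))
      }
      expect_lte(nrow(out), nrow(prev))
    }
    prev <- out
  }
})

test_that("on the reduced synthetic dataset every transcribed element is recovered", {
  sg <- small_dataset()
  rw <- simulate_reads(sg, "wild_type"); rm <- simulate_reads(sg, "mutant")
  out <- call_candidates(
    simulate_coverage(sg, "sRNA", "wild_type", reads = rw),
    simulate_coverage(sg, "sRNA", "mutant", reads = rm),
    simulate_coverage(sg, "mRNA", "wild_type"),
    simulate_coverage(sg, "mRNA", "mutant"),
    sg$annotations)
  tr <- sg$truth[sg$truth$class != "solo_LTR", ]
  hit <- vapply(seq_len(nrow(tr)), function(i) {
    any(out$contig == tr$contig[i] & out$start < tr$end[i] &
          out$end > tr$start[i])
  }, TRUE)
  expect_true(all(hit))
  # called bases sit on planted elements
  expect_gte(called_base_precision_helper(out, tr), 0.9)
})
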