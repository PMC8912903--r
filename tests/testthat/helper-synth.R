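# Reduced generator configuration for module tests: five families, one
# copy per class, a 0.9 Mb genome.  (Five families keeps the wild-type /
# mutant sRNA library-size ratio at 5, comfortably past the 4-fold
# "changed" criterion, just as in the full study-condition configuration.)
# The acceptance tests use the full default configuration.

small_config <- function(seed = 11L, ...) {
  synth_config(seed = seed,
               contig_lengths = c(chrI = 350000L, chrII = 300000L,
                                  chrIII = 250000L),
               n_families = 5L, full_per_family = 1L,
               partial_per_family = 1L, solo_per_family = 1L,
               sirna_per_element = 800L, degradation_reads = 800L,
               n_decoy_genes = 9L, ...)
}

empty_annotation_records <- function() {
  data.frame(seqid = character(), source = character(), type = character(),
             start = integer(), end = integer(), score = character(),
             strand = character(), phase = character(),
             attributes = character())
}

called_base_precision_helper <- function(calls, truth) {
  tot <- 0; ins <- 0
  for (i in seq_len(nrow(calls))) {
    tot <- tot + calls$end[i] - calls$start[i]
    t <- truth[truth$contig == calls$contig[i], ]
    ins <- ins + sum(pmax(0, pmin(t$end, calls$end[i]) -
                            pmax(t$start, calls$start[i])))
  }
  ins / tot
}

# cached small dataset shared within a test file
.small_cache <- new.env(parent = emptyenv())
small_dataset <- function() {
  if (is.null(.small_cache$sg)) {
    .small_cache$sg <- build_genome(small_config())
  }
  .small_cache$sg
}
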