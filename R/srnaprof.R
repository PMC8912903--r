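# Per-element small-RNA population summaries (size profile, strand bias,
# 5' nucleotide preference) and classification into siRNA-like versus
# sense-degradation-like species.

PROFILE_LEN_RANGE <- 15:35

#' Parameters for siRNA-likeness classification
#'
#' Codifies the qualitative signature of bona fide siRNAs: a modal length in
#' the Dicer-product range, reads from both strands, and a 5' uridine bias;
#' sense-degradation products are nearly sense-exclusive.
#'
#' @param modal_lengths Admissible modal lengths (default 22-24 nt).
#' @param min_antisense Minimum antisense read fraction (default 0.2).
#' @param min_five_prime_u Minimum 5'U fraction (default 0.5).
#' @param sense_only_cutoff Sense fraction at or above which a non-siRNA
#'   profile is degradation-like (default 0.95).
#' @param min_reads Minimum read total for a confident call (default 50).
#' @return A `sirna_class_params` list.
#' @export
sirna_class_params <- function(modal_lengths = c(22L, 23L, 24L),
                               min_antisense = 0.2, min_five_prime_u = 0.5,
                               sense_only_cutoff = 0.95, min_reads = 50L) {
  stopifnot(min_antisense >= 0, min_antisense <= 1,
            min_five_prime_u >= 0, min_five_prime_u <= 1,
            sense_only_cutoff >= 0, sense_only_cutoff <= 1)
  structure(list(modal_lengths = modal_lengths,
                 min_antisense = min_antisense,
                 min_five_prime_u = min_five_prime_u,
                 sense_only_cutoff = sense_only_cutoff,
                 min_reads = min_reads),
            class = "sirna_class_params")
}

#' Profile the small RNAs over one element
#'
#' Reads are assigned to the element when they overlap it by at least half
#' the read length; sense is defined relative to the element's strand.
#' Counts accumulate with multiplicity; lengths outside 15-35 nt are dropped
#' and tallied.
#'
#' @param reads A `read_set` data.frame (with `five_prime_nt`).
#' @param element List/one-row data.frame with `contig, start, end, strand`
#'   (strand `+`/`-`; `.` treated as `+`).
#' @param min_overlap_frac Minimum read overlap fraction (default 0.5).
#' @return A `smallrna_profile`: element interval plus `length_hist`
#'   (2 x 21 matrix, rows sense/antisense, columns 15..35), `strand_bias`
#'   (sense fraction), `five_prime_u` (global 5'U fraction),
#'   `five_prime_by_length` (4 x 21 proportion matrix), `modal_length`,
#'   `total_reads`, `dropped_out_of_range`.
#' @export
profile_small_rnas <- function(reads, element, min_overlap_frac = 0.5) {
  el_strand <- if (identical(element$strand, "-")) "-" else "+"
  ov <- pmin(reads$end, element$end) - pmax(reads$start, element$start)
  sel <- reads$contig == as.character(element$contig) &
    ov >= min_overlap_frac * reads$length
  r <- reads[sel, , drop = FALSE]
  hist <- matrix(0, nrow = 2, ncol = length(PROFILE_LEN_RANGE),
                 dimnames = list(c("sense", "antisense"),
                                 as.character(PROFILE_LEN_RANGE)))
  comp <- matrix(0, nrow = 4, ncol = length(PROFILE_LEN_RANGE),
                 dimnames = list(c("A", "C", "G", "U"),
                                 as.character(PROFILE_LEN_RANGE)))
  base <- list(contig = as.character(element$contig),
               start = element$start, end = element$end,
               strand = el_strand)
  if (nrow(r) == 0L) {
    return(structure(c(base, list(length_hist = hist, strand_bias = NA_real_,
                                  five_prime_u = NA_real_,
                                  five_prime_by_length = comp,
                                  modal_length = NA_integer_,
                                  total_reads = 0,
                                  dropped_out_of_range = 0)),
                     class = "smallrna_profile"))
  }
  in_range <- r$length >= min(PROFILE_LEN_RANGE) &
    r$length <= max(PROFILE_LEN_RANGE)
  dropped <- sum(r$count[!in_range])
  r <- r[in_range, , drop = FALSE]
  sense <- r$strand == el_strand
  li <- match(r$length, PROFILE_LEN_RANGE)
  for (i in seq_len(nrow(r))) {
    row <- if (sense[i]) 1L else 2L
    hist[row, li[i]] <- hist[row, li[i]] + r$count[i]
    if (!is.null(r$five_prime_nt)) {
      b <- r$five_prime_nt[i]
      if (b %in% rownames(comp)) comp[b, li[i]] <- comp[b, li[i]] + r$count[i]
    }
  }
  total <- sum(hist)
  csum <- colSums(comp)
  comp_prop <- sweep(comp, 2, pmax(csum, 1), "/")
  comp_prop[, csum == 0] <- 0
  len_tot <- colSums(hist)
  modal <- if (total > 0) {
    PROFILE_LEN_RANGE[which.max(len_tot)]  # ties break to the smaller length
  } else NA_integer_
  structure(c(base, list(
    length_hist = hist,
    strand_bias = if (total > 0) sum(hist["sense", ]) / total else NA_real_,
    five_prime_u = if (sum(csum) > 0) sum(comp["U", ]) / sum(csum)
                   else NA_real_,
    five_prime_by_length = comp_prop,
    modal_length = modal,
    total_reads = total,
    dropped_out_of_range = dropped)),
    class = "smallrna_profile")
}

#' @export
print.smallrna_profile <- function(x, ...) {
  cat(sprintf("smallrna_profile %s:%d-%d(%s): %g reads, bias %.2f, 5'U %.2f, mode %s nt\n",
              x$contig, x$start, x$end, x$strand, x$total_reads,
              x$strand_bias, x$five_prime_u, x$modal_length))
  invisible(x)
}

#' Classify a small-RNA profile
#'
#' `siRNA_like` requires a modal length in the admissible set, at least the
#' minimum antisense fraction, and at least the minimum 5'U fraction;
#' `sense_degradation_like` requires near-exclusive sense reads (and not
#' being siRNA-like); anything else, or a profile below the minimum read
#' count, is `ambiguous` (low-coverage profiles carry the attribute
#' `low_coverage`).
#'
#' @param profile A `smallrna_profile`.
#' @param params A `sirna_class_params`.
#' @return Character label in
#'   `{siRNA_like, sense_degradation_like, ambiguous}`.
#' @export
classify_profile <- function(profile, params = sirna_class_params()) {
  stopifnot(inherits(profile, "smallrna_profile"),
            inherits(params, "sirna_class_params"))
  if (profile$total_reads < params$min_reads) {
    out <- "ambiguous"
    attr(out, "low_coverage") <- TRUE
    return(out)
  }
  antisense_frac <- 1 - profile$strand_bias
  is_sirna <- profile$modal_length %in% params$modal_lengths &&
    antisense_frac >= params$min_antisense &&
    !is.na(profile$five_prime_u) &&
    profile$five_prime_u >= params$min_five_prime_u
  if (is_sirna) return("siRNA_like")
  if (profile$strand_bias >= params$sense_only_cutoff) {
    return("sense_degradation_like")
  }
  "ambiguous"
}
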