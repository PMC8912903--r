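# Direct-repeat (LTR) detection around a domain-anchored span, and element
# classification into full-length / partial / solo-LTR.

#' Find flanking direct repeats (candidate LTR pairs)
#'
#' Searches the sequence upstream and downstream of an anchor span (normally
#' the envelope of the protein-domain hits) for direct repeats: shared
#' k-mers between the two flanks are chained by diagonal and extended by
#' banded local alignment (match +1, mismatch -1, gap open -5, extend -1).
#' Pairs meeting the minimum length and identity are returned sorted by
#' `length * identity` descending, ties broken towards the smaller enclosed
#' span.
#'
#' @param seq Nucleotide string (or `DNAString`) containing the anchor span.
#' @param anchor_start,anchor_end Anchor span, 0-based half-open within
#'   `seq`.
#' @param flank Flank length searched on each side (default 5000 bp); flanks
#'   truncated at the sequence edge are searched as-is with a warning.
#' @param k Seed k-mer length (default 12).
#' @param min_len Minimum repeat alignment length in bp (default 100).
#' @param min_identity Minimum repeat identity (default 0.80).
#' @return data.frame of LTR pairs: `left_start, left_end, right_start,
#'   right_end, identity, length, score, span` (coordinates within `seq`,
#'   0-based half-open).
#' @export
find_direct_repeats <- function(seq, anchor_start, anchor_end, flank = 5000L,
                                k = 12L, min_len = 100L,
                                min_identity = 0.80) {
  seq <- as.character(seq)[1]
  L <- nchar(seq)
  stopifnot(anchor_start >= 0, anchor_end <= L, anchor_start < anchor_end)
  up_s <- anchor_start - flank
  dn_e <- anchor_end + flank
  if (up_s < 0 || dn_e > L) {
    warning("flank truncated at sequence edge; searching available sequence")
    up_s <- max(0L, up_s)
    dn_e <- min(L, dn_e)
  }
  up <- substr(seq, up_s + 1L, anchor_start)
  dn <- substr(seq, anchor_end + 1L, dn_e)
  empty <- data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      identity = numeric(), length = integer(),
                      score = numeric(), span = integer())
  if (nchar(up) < k || nchar(dn) < k) return(empty)
  hits <- kmer_hits_cpp(up, dn, as.integer(k))
  if (nrow(hits) == 0L) return(empty)
  chains <- chain_seed_hits(hits, k, band_tol = 40L, max_gap = 600L)
  pairs <- list()
  for (ch in chains) {
    al <- extend_chain(up, dn, ch, k, pad = 120L,
                       match = 1, mismatch = -1, gap_open = 5, gap_extend = 1)
    if (is.null(al)) next
    if (al$columns < min_len) next
    identity <- al$matches / al$columns
    if (identity < min_identity) next
    pairs[[length(pairs) + 1L]] <- data.frame(
      left_start = up_s + al$a_start, left_end = up_s + al$a_end,
      right_start = anchor_end + al$b_start,
      right_end = anchor_end + al$b_end,
      identity = identity, length = al$columns, score = al$score,
      span = (anchor_end + al$b_end) - (up_s + al$a_start))
  }
  if (!length(pairs)) return(empty)
  out <- do.call(rbind, pairs)
  out <- dedupe_pairs(out)
  out <- out[order(-(out$length * out$identity), out$span,
                   out$left_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# group seed hits into chains by diagonal proximity and positional gap
chain_seed_hits <- function(hits, k, band_tol = 40L, max_gap = 600L) {
  diag <- hits[, "tpos"] - hits[, "qpos"]
  o <- order(diag, hits[, "tpos"])
  q <- hits[o, "qpos"]; t <- hits[o, "tpos"]; d <- diag[o]
  n <- length(d)
  grp <- cumsum(c(1L, (diff(d) > band_tol) | (abs(diff(t)) > max_gap)))
  lapply(split(seq_len(n), grp), function(ix) {
    list(qpos = q[ix], tpos = t[ix])
  })
}

# banded local alignment around a seed chain; coordinates are relative to
# the two input strings (0-based half-open)
extend_chain <- function(a, b, chain, k, pad = 120L, match = 1,
                         mismatch = -1, gap_open = 5, gap_extend = 1) {
  qlo <- max(0L, min(chain$qpos) - pad)
  qhi <- min(nchar(a), max(chain$qpos) + k + pad)
  tlo <- max(0L, min(chain$tpos) - pad)
  thi <- min(nchar(b), max(chain$tpos) + k + pad)
  if (qhi - qlo < k || thi - tlo < k) return(NULL)
  sub_a <- substr(a, qlo + 1L, qhi)
  sub_b <- substr(b, tlo + 1L, thi)
  dmin <- min(chain$tpos - chain$qpos) - (tlo - qlo)
  dmax <- max(chain$tpos - chain$qpos) - (tlo - qlo)
  al <- sw_band_cpp(sub_a, sub_b, match, mismatch, gap_open, gap_extend,
                    band_lo = dmin - pad, band_hi = dmax + pad)
  if (al$columns == 0L) return(NULL)
  al$a_start <- al$a_start + qlo; al$a_end <- al$a_end + qlo
  al$b_start <- al$b_start + tlo; al$b_end <- al$b_end + tlo
  al
}

# drop pairs whose left or right interval overlaps a better pair
dedupe_pairs <- function(pairs) {
  pairs <- pairs[order(-(pairs$length * pairs$identity), pairs$span), ,
                 drop = FALSE]
  kept <- pairs[0, , drop = FALSE]
  for (r in seq_len(nrow(pairs))) {
    row <- pairs[r, , drop = FALSE]
    ov <- nrow(kept) > 0L &&
      any((kept$left_start < row$left_end & row$left_start < kept$left_end) |
          (kept$right_start < row$right_end &
             row$right_start < kept$right_end))
    if (!ov) kept <- rbind(kept, row)
  }
  kept
}

#' Classify a candidate region as full-length, partial, or solo-LTR
#'
#' Applies the structural rules: a full-length element requires a direct
#' repeat (LTR) pair plus reverse-transcriptase and integrase hits, and its
#' interval spans the outer LTR bounds; a region with at least one domain
#' hit but no accepted pair is partial, spanning the domain envelope; a lone
#' LTR match with no domain hit within the exclusion distance is a solo-LTR.
#' `TG...CA` termini are reported (`tg_ca`) but never required.
#'
#' @param region List/one-row data.frame with `contig`, `start`, `end`.
#' @param domain_hits data.frame from [scan_domains()] (genomic
#'   coordinates); hits outside the region still count for the solo
#'   exclusion rule.
#' @param ltr_pairs data.frame from [find_direct_repeats()] with coordinates
#'   already lifted to genomic positions (columns as returned, plus the
#'   caller's offset applied).
#' @param genome Optional [Biostrings::DNAStringSet], used only for the
#'   `TG...CA` flag.
#' @param is_ltr_match Set `TRUE` when the region itself is a bare LTR copy
#'   found by sequence search (enables the solo-LTR class).
#' @param exclusion Distance (bp) within which a domain hit disqualifies a
#'   solo-LTR call (default 1000).
#' @param partial_interval For unpaired (partial) calls, report the domain
#'   hit envelope (`"domains"`, default) or the supplied region bounds
#'   (`"region"`; used by the pipeline, where the region is the refined
#'   differential-signal interval and estimates the element extent better
#'   than the coding envelope).
#' @return One-row data.frame `contig, start, end, class, tg_ca, left_start,
#'   left_end, right_start, right_end, ltr_identity, n_domains`, or `NULL`
#'   when there is no evidence to call.
#' @export
classify_element <- function(region, domain_hits, ltr_pairs, genome = NULL,
                             is_ltr_match = FALSE, exclusion = 1000L,
                             partial_interval = c("domains", "region")) {
  partial_interval <- match.arg(partial_interval)
  contig <- as.character(region$contig)
  in_region <- domain_hits[domain_hits$contig == contig &
                             domain_hits$start < region$end &
                             domain_hits$end > region$start, , drop = FALSE]
  has_pair <- !is.null(ltr_pairs) && nrow(ltr_pairs) > 0L
  mk <- function(class, s, e, pair = NULL) {
    tg_ca <- FALSE
    ls <- le <- rs <- re <- NA_integer_; id <- NA_real_
    if (!is.null(pair)) {
      ls <- pair$left_start; le <- pair$left_end
      rs <- pair$right_start; re <- pair$right_end; id <- pair$identity
      if (!is.null(genome)) {
        left2 <- as.character(Biostrings::subseq(genome[[contig]], ls + 1L,
                                                 ls + 2L))
        right2 <- as.character(Biostrings::subseq(genome[[contig]], re - 1L,
                                                  re))
        tg_ca <- identical(left2, "TG") && identical(right2, "CA")
      }
    }
    data.frame(contig = contig, start = as.integer(s), end = as.integer(e),
               class = class, tg_ca = tg_ca, left_start = ls, left_end = le,
               right_start = rs, right_end = re, ltr_identity = id,
               n_domains = nrow(in_region), stringsAsFactors = FALSE)
  }
  has_rt <- any(in_region$model == "reverse_transcriptase")
  has_in <- any(in_region$model == "integrase")
  if (nrow(in_region) > 0L) {
    if (has_pair && has_rt && has_in) {
      best <- ltr_pairs[1, , drop = FALSE]
      return(mk("full_length", best$left_start, best$right_end, best))
    }
    if (partial_interval == "region") {
      return(mk("partial", min(region$start, min(in_region$start)),
                max(region$end, max(in_region$end))))
    }
    return(mk("partial", min(in_region$start), max(in_region$end)))
  }
  if (is_ltr_match) {
    near <- domain_hits[domain_hits$contig == contig &
                          domain_hits$start < region$end + exclusion &
                          domain_hits$end > region$start - exclusion, ,
                        drop = FALSE]
    if (nrow(near) == 0L) return(mk("solo_LTR", region$start, region$end))
    return(NULL)
  }
  NULL
}
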