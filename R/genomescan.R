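# Genome-wide copy search: exact k-mer seeds on both strands, diagonal
# chaining, banded Smith-Waterman extension.  A nucleotide-space
# BLAST-substitute sized for desk-scale genomes.

#' Find genomic copies of a query sequence
#'
#' Seeds exact k-mers of the query against every contig on both strands,
#' chains seeds lying on nearby diagonals and extends each chain with banded
#' local alignment (match +1, mismatch -1, gap open -5, extend -1).
#' Overlapping matches are reduced to the best-scoring one.
#'
#' @param query Nucleotide string or `DNAString`.
#' @param genome A [Biostrings::DNAStringSet].
#' @param k Seed length (default 15).
#' @param min_len Minimum alignment length in bp (default 200).
#' @param min_identity Minimum identity (default 0.70).
#' @param exclude Optional list/one-row data.frame `contig, start, end`: the
#'   query's own locus; any overlapping match is dropped.
#' @param pad Band/window padding for the extension step (default 100).
#' @param chain_band Diagonal tolerance when chaining seeds (default 40).
#' @param max_gap Maximum positional gap between chained seeds (default 600).
#' @return data.frame of matches: `contig, start, end, strand, identity,
#'   length, score` sorted by contig name then start; coordinates 0-based
#'   half-open on the forward strand.
#' @export
find_copies <- function(query, genome, k = 15L, min_len = 200L,
                        min_identity = 0.70, exclude = NULL, pad = 100L,
                        chain_band = 40L, max_gap = 600L) {
  query <- as.character(query)[1]
  stopifnot(nchar(query) >= k)
  out <- list()
  for (cn in sort_c(names(genome))) {
    tgt_fwd <- as.character(genome[[cn]])
    L <- nchar(tgt_fwd)
    for (strand in c("+", "-")) {
      tgt <- if (strand == "+") tgt_fwd else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(tgt_fwd)))
      hits <- kmer_hits_cpp(query, tgt, as.integer(k))
      if (nrow(hits) == 0L) next
      chains <- chain_seed_hits(hits, k, band_tol = chain_band,
                                max_gap = max_gap)
      for (ch in chains) {
        al <- extend_chain(query, tgt, ch, k, pad = pad,
                           match = 1, mismatch = -1, gap_open = 5,
                           gap_extend = 1)
        if (is.null(al) || al$columns < min_len) next
        identity <- al$matches / al$columns
        if (identity < min_identity) next
        if (strand == "+") {
          s <- al$b_start; e <- al$b_end
        } else {
          s <- L - al$b_end; e <- L - al$b_start
        }
        out[[length(out) + 1L]] <- data.frame(
          contig = cn, start = s, end = e, strand = strand,
          identity = identity, length = al$columns, score = al$score,
          stringsAsFactors = FALSE)
      }
    }
  }
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      identity = numeric(), length = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (!length(out)) return(empty)
  m <- do.call(rbind, out)
  if (!is.null(exclude)) {
    keep <- !(m$contig == as.character(exclude$contig) &
                m$start < exclude$end & m$end > exclude$start)
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) == 0L) return(empty)
  m <- dedupe_matches(m)
  m <- m[order(m$contig, m$start, method = "radix"), , drop = FALSE]
  rownames(m) <- NULL
  m
}

# greedy reduction of overlapping matches (any strand) to the best score
dedupe_matches <- function(m, min_frac = 0.5) {
  m <- m[order(-m$score, m$contig, m$start, method = "radix"), ,
         drop = FALSE]
  kept <- m[0, , drop = FALSE]
  for (r in seq_len(nrow(m))) {
    row <- m[r, , drop = FALSE]
    drop <- FALSE
    if (nrow(kept) > 0L) {
      same <- kept$contig == row$contig
      if (any(same)) {
        ov <- pmin(kept$end[same], row$end) - pmax(kept$start[same], row$start)
        shorter <- pmin(kept$end[same] - kept$start[same],
                        row$end - row$start)
        drop <- any(ov > min_frac * shorter)
      }
    }
    if (!drop) kept <- rbind(kept, row)
  }
  kept
}

#' Find genome-wide solo-LTRs from an LTR consensus
#'
#' Runs [find_copies()] with the LTR sequence alone, removes matches within
#' the exclusion distance of any domain-bearing element call, and emits the
#' remainder as solo-LTR calls.
#'
#' @param ltr_consensus LTR nucleotide sequence (from a family's LTR pair).
#' @param genome A [Biostrings::DNAStringSet].
#' @param element_calls data.frame of existing calls with `contig, start,
#'   end, class` (classes `full_length`/`partial` carry domains).
#' @param exclusion Exclusion distance in bp (default 1000).
#' @param min_identity Minimum identity (default 0.80).
#' @param min_len Minimum match length (default 100).
#' @param k Seed length (default 12).
#' @return data.frame of solo-LTR calls: `contig, start, end, strand,
#'   identity, class`.
#' @export
find_solo_ltrs <- function(ltr_consensus, genome, element_calls,
                           exclusion = 1000L, min_identity = 0.80,
                           min_len = 100L, k = 12L) {
  m <- find_copies(ltr_consensus, genome, k = k, min_len = min_len,
                   min_identity = min_identity)
  if (nrow(m) == 0L) {
    return(cbind(m[, c("contig", "start", "end", "strand", "identity")],
                 data.frame(class = character())))
  }
  bearing <- element_calls[element_calls$class %in%
                             c("full_length", "partial"), , drop = FALSE]
  keep <- rep(TRUE, nrow(m))
  if (nrow(bearing) > 0L) {
    for (r in seq_len(nrow(m))) {
      same <- bearing$contig == m$contig[r]
      if (any(same)) {
        near <- bearing$start[same] < m$end[r] + exclusion &
          bearing$end[same] > m$start[r] - exclusion
        if (any(near)) keep[r] <- FALSE
      }
    }
  }
  m <- m[keep, , drop = FALSE]
  out <- m[, c("contig", "start", "end", "strand", "identity"), drop = FALSE]
  out$class <- rep("solo_LTR", nrow(out))
  rownames(out) <- NULL
  out
}
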