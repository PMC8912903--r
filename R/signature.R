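# Differential-coverage candidate calling: unannotated regions with lost or
# changed small-RNA signal plus increased mRNA signal in the mutant.

#' Thresholds for the discovery signature
#'
#' @param srna_loss_fold Minimum sRNA fold-change (default 4).
#' @param min_wt_srna Minimum wild-type sRNA density in RPKM for the "lost"
#'   class (default 5), guarding against calling noise.
#' @param mrna_gain_fold Minimum mutant/wild-type mRNA fold (default 2).
#' @param pseudocount Pseudocount in RPKM added to every ratio (default 1).
#' @param window Sliding-window width in bp (default 500).
#' @param step Window step in bp (default 100; must divide into the window
#'   and be >= the bin size).
#' @param merge_gap Maximum gap between flagged windows merged into one
#'   region (default 500 bp).
#' @param min_region_length Minimum region length retained downstream
#'   (default 1000 bp; short regions are kept here but flagged).
#' @return A `signature_thresholds` list.
#' @export
signature_thresholds <- function(srna_loss_fold = 4, min_wt_srna = 5,
                                 mrna_gain_fold = 2, pseudocount = 1,
                                 window = 500L, step = 100L,
                                 merge_gap = 500L,
                                 min_region_length = 1000L) {
  stopifnot(srna_loss_fold > 1, mrna_gain_fold > 1, pseudocount > 0,
            step <= window)
  structure(list(srna_loss_fold = srna_loss_fold, min_wt_srna = min_wt_srna,
                 mrna_gain_fold = mrna_gain_fold, pseudocount = pseudocount,
                 window = as.integer(window), step = as.integer(step),
                 merge_gap = as.integer(merge_gap),
                 min_region_length = as.integer(min_region_length)),
            class = "signature_thresholds")
}

#' Per-bin ratio of two coverage tracks
#'
#' `(mut + p) / (wt + p)` per bin, the same arithmetic used for IP/input
#' comparison tracks.
#'
#' @param mut,wt `coverage_track`s with identical binning and contigs.
#' @param pseudocount Pseudocount added to numerator and denominator.
#' @return A `coverage_track` with `normalization = "ratio"`.
#' @export
ratio_track <- function(mut, wt, pseudocount = 1) {
  check_same_binning(mut, wt)
  vals <- lapply(names(mut$values), function(cn) {
    (mut$values[[cn]] + pseudocount) / (wt$values[[cn]] + pseudocount)
  })
  names(vals) <- names(mut$values)
  coverage_track(vals, mut$bin_size, normalization = "ratio",
                 molecule = mut$molecule,
                 condition = paste0(mut$condition, "/", wt$condition),
                 contig_lengths = mut$contig_lengths)
}

check_same_binning <- function(a, b) {
  if (a$bin_size != b$bin_size) stop("tracks have different bin sizes")
  if (!identical(sort_c(names(a$values)), sort_c(names(b$values)))) {
    stop("tracks cover different contigs")
  }
  for (cn in names(a$values)) {
    if (length(a$values[[cn]]) != length(b$values[[cn]])) {
      stop("tracks have different bin counts on ", cn)
    }
  }
  invisible(TRUE)
}

#' Call candidate regions with the discovery signature
#'
#' Slides windows over RPKM-normalised tracks and flags a window when the
#' small-RNA signal is lost (wild-type density at least `min_wt_srna` and
#' wild-type/mutant fold at least `srna_loss_fold`) or changed (fold at
#' least `srna_loss_fold` in either direction) AND the mRNA
#' mutant/wild-type fold is at least `mrna_gain_fold`.  Flagged windows are
#' merged across gaps up to `merge_gap`, region edges are refined to the
#' outermost bin individually passing the mRNA-gain criterion, and regions
#' overlapping the supplied annotation set are discarded.  Regions shorter
#' than `min_region_length` are retained but marked (`long_enough =
#' FALSE`); the final ">= 1 kb and >= 1 domain" acceptance rule is applied
#' in the annotation stage of the pipeline.
#'
#' @param srna_wt,srna_mut,mrna_wt,mrna_mut RPKM-normalised
#'   `coverage_track`s sharing binning.
#' @param annotations An `annotation_set` of existing features to exclude.
#' @param th A `signature_thresholds`.
#' @return data.frame of candidate regions: `contig, start, end, srna_fold,
#'   mrna_fold, class, long_enough`, disjoint and sorted.
#' @export
call_candidates <- function(srna_wt, srna_mut, mrna_wt, mrna_mut,
                            annotations, th = signature_thresholds()) {
  tracks <- list(srna_wt, srna_mut, mrna_wt, mrna_mut)
  for (tr in tracks) {
    if (!identical(tr$normalization, "RPKM")) {
      stop("call_candidates requires RPKM-normalised tracks (got '",
           tr$normalization, "')")
    }
  }
  for (tr in tracks[-1]) check_same_binning(tracks[[1]], tr)
  bs <- srna_wt$bin_size
  wbins <- max(1L, th$window %/% bs)
  sbins <- max(1L, th$step %/% bs)
  p <- th$pseudocount
  out <- list()
  for (cn in names(srna_wt$values)) {
    sw <- srna_wt$values[[cn]]; sm <- srna_mut$values[[cn]]
    mw <- mrna_wt$values[[cn]]; mm <- mrna_mut$values[[cn]]
    nb <- length(sw)
    if (nb == 0L) next
    starts <- seq.int(1L, max(1L, nb - wbins + 1L), by = sbins)
    wmean <- function(v) {
      cs <- c(0, cumsum(v))
      ends <- pmin(starts + wbins - 1L, nb)
      (cs[ends + 1L] - cs[starts]) / (ends - starts + 1L)
    }
    w_sw <- wmean(sw); w_sm <- wmean(sm); w_mw <- wmean(mw); w_mm <- wmean(mm)
    srna_ratio_loss <- (w_sw + p) / (w_sm + p)
    srna_ratio_gain <- (w_sm + p) / (w_sw + p)
    mrna_ratio <- (w_mm + p) / (w_mw + p)
    lost <- w_sw >= th$min_wt_srna & srna_ratio_loss >= th$srna_loss_fold
    changed <- pmax(srna_ratio_loss, srna_ratio_gain) >= th$srna_loss_fold
    flag <- (lost | changed) & mrna_ratio >= th$mrna_gain_fold
    if (!any(flag)) next
    # merge flagged windows across gaps <= merge_gap
    ws <- (starts[flag] - 1L) * bs
    we <- pmin((starts[flag] + wbins - 1L), nb) * bs
    o <- order(ws)
    ws <- ws[o]; we <- we[o]
    grp <- cumsum(c(1L, ws[-1] - cummax_head(we) > th$merge_gap))
    for (g in unique(grp)) {
      gs <- min(ws[grp == g]); ge <- max(we[grp == g])
      # refine edges to outermost bin passing the mRNA-gain criterion
      b0 <- gs %/% bs + 1L; b1 <- min(ge %/% bs, nb)
      if (ge %% bs != 0L) b1 <- min(b1 + 1L, nb)
      binpass <- (mm[b0:b1] + p) / (mw[b0:b1] + p) >= th$mrna_gain_fold
      if (any(binpass)) {
        first <- b0 + which(binpass)[1] - 1L
        last <- b0 + which(binpass)[length(which(binpass))] - 1L
        gs <- (first - 1L) * bs
        ge <- min(last * bs, contig_len_of(srna_wt, cn, nb))
      }
      if (ge <= gs) next
      rb0 <- gs %/% bs + 1L; rb1 <- min((ge - 1L) %/% bs + 1L, nb)
      r_sw <- mean(sw[rb0:rb1]); r_sm <- mean(sm[rb0:rb1])
      r_mw <- mean(mw[rb0:rb1]); r_mm <- mean(mm[rb0:rb1])
      loss_fold <- (r_sw + p) / (r_sm + p)
      gain_fold <- (r_sm + p) / (r_sw + p)
      cls <- if (r_sw >= th$min_wt_srna && loss_fold >= th$srna_loss_fold) {
        "lost"
      } else "changed"
      out[[length(out) + 1L]] <- data.frame(
        contig = cn, start = gs, end = ge,
        srna_fold = max(loss_fold, gain_fold),
        mrna_fold = (r_mm + p) / (r_mw + p),
        class = cls, stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), srna_fold = numeric(),
                      mrna_fold = numeric(), class = character(),
                      long_enough = logical(), stringsAsFactors = FALSE)
  if (!length(out)) return(empty)
  regions <- do.call(rbind, out)
  # exclude regions overlapping existing annotations
  keep <- vapply(seq_len(nrow(regions)), function(i) {
    length(annotation_overlaps(annotations, regions$contig[i],
                               regions$start[i], regions$end[i])) == 0L
  }, TRUE)
  regions <- regions[keep, , drop = FALSE]
  if (nrow(regions) == 0L) return(empty)
  regions$long_enough <- (regions$end - regions$start) >=
    th$min_region_length
  regions <- regions[order(regions$contig, regions$start, method = "radix"), ,
                     drop = FALSE]
  rownames(regions) <- NULL
  regions
}

# running maximum of interval ends, shifted by one (for merge grouping)
cummax_head <- function(we) {
  if (length(we) <= 1L) return(numeric(0))
  cummax(we)[-length(we)]
}

contig_len_of <- function(track, cn, nb) {
  if (!is.null(track$contig_lengths)) track$contig_lengths[[cn]]
  else nb * track$bin_size
}
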