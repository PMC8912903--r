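# Retrotransposon protein-domain detection: six-frame translation and
# ungapped log-odds profile (PSSM) scanning with an empirically calibrated
# score threshold.  The bundled profiles are synthetic stand-ins built from
# the reference cassettes that the synthetic-genome generator uses; the
# scanner is model-pluggable so externally derived profiles can be swapped in.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DOMAIN_NAMES <- c("gag", "protease", "reverse_transcriptase", "rnase_h",
                  "integrase", "chromodomain")

#' Six-frame translation with coordinate maps
#'
#' Translates a nucleotide sequence in all six reading frames using the
#' standard genetic code (stops rendered as `*`, ambiguous codons as `X`).
#'
#' @param seq A nucleotide string, [Biostrings::DNAString], or length-1
#'   `DNAStringSet`.
#' @return A list of six elements named `"+1"`, `"+2"`, `"+3"`, `"-1"`,
#'   `"-2"`, `"-3"`, each a list with `frame` (integer, signed), `aa`
#'   (amino-acid string) and `offset` (frame offset on the translated
#'   strand).  Use [frame_residue_interval()] to map a residue back to its
#'   nucleotide interval.
#' @export
six_frame_translate <- function(seq) {
  seq <- as.character(seq)[1]
  L <- nchar(seq)
  if (L < 3L) stop("sequence shorter than one codon")
  if (grepl("^N+$", seq)) {
    # degenerate input: nothing translatable
    frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
    out <- lapply(frames, function(f) list(frame = f, aa = "", offset = abs(f) - 1L))
    names(out) <- sprintf("%+d", frames)
    return(out)
  }
  fwd <- Biostrings::DNAString(seq)
  rev <- Biostrings::reverseComplement(fwd)
  tr <- function(s, off) {
    n <- length(s) - off
    n <- n - n %% 3L
    if (n < 3L) return("")
    as.character(suppressWarnings(
      Biostrings::translate(Biostrings::subseq(s, off + 1L, off + n),
                            if.fuzzy.codon = "X")))
  }
  out <- list()
  for (f in 1:3) {
    out[[sprintf("%+d", f)]] <- list(frame = f, aa = tr(fwd, f - 1L),
                                     offset = f - 1L)
  }
  for (f in 1:3) {
    out[[sprintf("%+d", -f)]] <- list(frame = -f, aa = tr(rev, f - 1L),
                                      offset = f - 1L)
  }
  out
}

#' Nucleotide interval of a translated residue
#'
#' @param frame Signed frame in `{+1,+2,+3,-1,-2,-3}`.
#' @param residue 0-based residue index within the frame's translation.
#' @param seq_len Length of the translated nucleotide sequence.
#' @param n_residues Number of consecutive residues (default 1).
#' @return `c(start, end)`, 0-based half-open, on the forward strand of the
#'   translated sequence.
#' @export
frame_residue_interval <- function(frame, residue, seq_len, n_residues = 1L) {
  off <- abs(frame) - 1L
  s_local <- off + 3L * residue
  e_local <- s_local + 3L * n_residues
  if (frame > 0) c(s_local, e_local) else c(seq_len - e_local, seq_len - s_local)
}

#' Build a position-specific scoring matrix from aligned reference proteins
#'
#' Per column, the score of residue `r` is
#' `log2(((count_r + pc) / (N + 20 pc)) / background_r)`.
#'
#' @param alignment Path to an aligned protein FASTA, an
#'   [Biostrings::AAStringSet], or a character vector of equal-length
#'   sequences.
#' @param name Model name (one of the retrotransposon domain classes, free
#'   text allowed).
#' @param pseudocount Smoothing pseudocount (default 0.5).
#' @param background Background amino-acid frequencies (default uniform 1/20).
#' @return A `domain_model`: list with `name`, `matrix` (20 x L log-odds),
#'   `length`, `threshold` (NA until calibrated), `background`.
#' @export
build_model <- function(alignment, name = "domain", pseudocount = 0.5,
                        background = rep(1 / 20, 20)) {
  if (is.character(alignment) && length(alignment) == 1 &&
      file.exists(alignment)) {
    alignment <- Biostrings::readAAStringSet(alignment)
  }
  seqs <- toupper(as.character(alignment))
  if (length(seqs) < 2L) stop("need at least 2 aligned sequences")
  if (length(unique(nchar(seqs))) != 1L) {
    stop("ragged alignment: sequences differ in length")
  }
  L <- nchar(seqs[1])
  if (L < 1L) stop("empty alignment")
  stopifnot(length(background) == 20, all(background > 0))
  chars <- do.call(rbind, strsplit(seqs, ""))
  N <- length(seqs)
  mat <- matrix(0, nrow = 20, ncol = L, dimnames = list(AA20, NULL))
  for (j in seq_len(L)) {
    cnt <- tabulate(match(chars[, j], AA20), nbins = 20)
    mat[, j] <- log2(((cnt + pseudocount) / (N + 20 * pseudocount)) / background)
  }
  structure(list(name = name, matrix = mat, length = L, threshold = NA_real_,
                 background = background),
            class = "domain_model")
}

#' @export
print.domain_model <- function(x, ...) {
  cat(sprintf("domain_model '%s': length %d, threshold %s\n", x$name,
              x$length,
              if (is.na(x$threshold)) "uncalibrated" else
                sprintf("%.2f bits", x$threshold)))
  invisible(x)
}

# score of a residue absent from the model alphabet (X, gaps): as if count 0
absent_score <- function(model) {
  min(model$matrix)
}

#' Calibrate a model's score threshold against a random-sequence null
#'
#' Draws `null_draws` random sequences of the model length from the
#' background distribution and sets the threshold at the `1 - alpha`
#' empirical quantile of their scores.
#'
#' @param model A `domain_model`.
#' @param null_draws Number of null sequences (default 1000).
#' @param alpha Upper tail mass (default 1e-3); `alpha = 1` gives the minimum
#'   null score.
#' @param seed RNG seed for the null draws.
#' @return The model with `threshold` set.
#' @export
calibrate_threshold <- function(model, null_draws = 1000L, alpha = 1e-3,
                                seed = 1L) {
  stopifnot(inherits(model, "domain_model"), alpha > 0, alpha <= 1)
  L <- model$length
  scores <- local_rng(seed, {
    draws <- matrix(sample.int(20L, L * null_draws, replace = TRUE,
                               prob = model$background),
                    nrow = null_draws)
    vapply(seq_len(null_draws), function(i) {
      sum(model$matrix[cbind(draws[i, ], seq_len(L))])
    }, 0.0)
  })
  model$threshold <- quantile(scores, probs = 1 - alpha, type = 1,
                              names = FALSE)
  model
}

#' Load the bundled domain models
#'
#' Builds and calibrates PSSMs from the synthetic reference alignments
#' shipped under `inst/extdata/synthetic_domains/` (stand-ins for externally
#' curated conserved-domain profiles).
#'
#' @param dir Directory of aligned protein FASTA files (`<name>.faa`).
#' @param alpha Calibration tail mass per model.
#' @param null_draws Null sequences per calibration.
#' @param calibration_seed Seed for the null draws (fixed default so that
#'   repeated loads are identical).
#' @return Named list of calibrated `domain_model`s.
#' @export
load_domain_models <- function(dir = system.file("extdata",
                                                 "synthetic_domains",
                                                 package = "retroscout"),
                               alpha = 1e-3, null_draws = 1000L,
                               calibration_seed = 97L) {
  files <- sort_c(list.files(dir, pattern = "\\.faa$", full.names = TRUE))
  if (!length(files)) stop("no .faa alignments found in ", dir)
  models <- list()
  for (f in files) {
    nm <- sub("^synthetic_", "", sub("\\.faa$", "", basename(f)))
    m <- build_model(f, name = nm)
    models[[nm]] <- calibrate_threshold(m, null_draws = null_draws,
                                        alpha = alpha,
                                        seed = calibration_seed)
  }
  models
}

# score every window of an amino-acid string against a model.
# Returns data.frame(residue0, score); windows containing '*' are rejected.
score_windows <- function(aa, model) {
  M <- nchar(aa)
  L <- model$length
  if (M < L) return(data.frame(residue = integer(), score = numeric()))
  letters <- strsplit(aa, "")[[1]]
  idx <- match(letters, AA20)
  sc_letter <- ifelse(is.na(idx), absent_score(model), 0)
  W <- M - L + 1L
  scores <- numeric(W)
  for (j in seq_len(L)) {
    pos <- idx[j:(j + W - 1L)]
    col <- model$matrix[, j]
    s <- unname(col[pos])
    s[is.na(pos)] <- absent_score(model)
    scores <- scores + s
  }
  # windows containing a stop are rejected outright
  stops <- which(letters == "*")
  if (length(stops)) {
    has_stop <- logical(W)
    for (p in stops) {
      lo <- max(1L, p - L + 1L)
      hi <- min(W, p)
      if (lo <= hi) has_stop[lo:hi] <- TRUE
    }
    scores[has_stop] <- -Inf
  }
  data.frame(residue = 0:(W - 1L), score = scores)
}

#' Scan a genomic region for retrotransposon protein domains
#'
#' Translates the region in six frames and scores every window of every
#' frame against every model; windows at or above a model's calibrated
#' threshold are reported, and overlapping hits of the same model are
#' reduced to the best-scoring one.
#'
#' @param region List or one-row data.frame with `contig`, `start`, `end`
#'   (0-based half-open).
#' @param genome A [Biostrings::DNAStringSet].
#' @param models Named list of calibrated `domain_model`s
#'   (see [load_domain_models()]).
#' @return data.frame of hits: `contig, start, end, frame, model, score`
#'   (nucleotide coordinates on the genome, 0-based half-open).
#' @export
scan_domains <- function(region, genome, models) {
  contig <- as.character(region$contig)
  rs <- as.integer(region$start)
  re <- as.integer(region$end)
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), frame = integer(),
                      model = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  min_model <- min(vapply(models, function(m) m$length, 0L))
  if (re - rs < 3L * min_model) return(empty)
  seq <- as.character(Biostrings::subseq(genome[[contig]], rs + 1L, re))
  frames <- six_frame_translate(seq)
  L_nt <- nchar(seq)
  hits <- list()
  for (fr in frames) {
    if (!nzchar(fr$aa)) next
    for (mn in names(models)) {
      model <- models[[mn]]
      if (is.na(model$threshold)) stop("model '", mn, "' is uncalibrated")
      sw <- score_windows(fr$aa, model)
      keep <- sw$score >= model$threshold
      if (!any(keep)) next
      sw <- sw[keep, , drop = FALSE]
      iv <- t(vapply(sw$residue, function(r) {
        frame_residue_interval(fr$frame, r, L_nt, model$length)
      }, c(0L, 0L)))
      hits[[length(hits) + 1L]] <-
        data.frame(contig = contig, start = rs + iv[, 1], end = rs + iv[, 2],
                   frame = fr$frame, model = mn, score = sw$score,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  reduce_same_model_hits(out)
}

# reduce overlapping hits of the same model to the best-scoring one
reduce_same_model_hits <- function(hits) {
  res <- list()
  for (mn in sort_c(unique(hits$model))) {
    h <- hits[hits$model == mn, , drop = FALSE]
    h <- h[order(-h$score, h$start, h$frame), , drop = FALSE]
    kept <- h[0, , drop = FALSE]
    for (r in seq_len(nrow(h))) {
      row <- h[r, , drop = FALSE]
      if (nrow(kept) == 0L ||
          !any(kept$contig == row$contig &
               kept$start < row$end & row$start < kept$end)) {
        kept <- rbind(kept, row)
      }
    }
    res[[mn]] <- kept
  }
  out <- do.call(rbind, res)
  out <- out[order(out$contig, out$start, out$model, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
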