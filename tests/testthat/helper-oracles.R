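# Independent oracles used across the suite.  These are deliberately plain
# matrix-DP / enumeration implementations, separate from the package's
# compiled alignment code paths.

# global alignment (linear gap) by full-matrix DP with the tie preference
# diagonal > up > left; returns score, matches, and aligned columns
# excluding terminal gap runs
oracle_nw <- function(a, b, match = 1, mismatch = -1, gap = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  P <- matrix(0L, n + 1, m + 1)       # 1 diag, 2 up, 3 left
  H[, 1] <- -gap * (0:n);  P[-1, 1] <- 2L
  H[1, ] <- -gap * (0:m);  P[1, -1] <- 3L
  mm <- function(x, y) x == y && x %in% c("A", "C", "G", "T")
  for (i in 1:n) for (j in 1:m) {
    sc <- c(H[i, j] + if (mm(A[i], B[j])) match else mismatch,
            H[i, j + 1] - gap, H[i + 1, j] - gap)
    k <- which.max(sc)                 # which.max takes the first maximum
    H[i + 1, j + 1] <- sc[k]; P[i + 1, j + 1] <- k
  }
  i <- n + 1; j <- m + 1; ops <- integer(0); matches <- 0
  while (i > 1 || j > 1) {
    d <- P[i, j]; ops <- c(d, ops)
    if (d == 1L) { if (mm(A[i - 1], B[j - 1])) matches <- matches + 1
                   i <- i - 1; j <- j - 1 }
    else if (d == 2L) i <- i - 1 else j <- j - 1
  }
  keep <- which(ops == 1L)
  columns <- if (length(keep)) max(keep) - min(keep) + 1L else 0L
  list(score = H[n + 1, m + 1], matches = matches, columns = columns)
}

# brute-force best ungapped direct repeat between an upstream and a
# downstream flank: every diagonal (start-pair offset) is scanned
# exhaustively for its score-maximal contiguous window under the local
# alignment scoring (match +1, mismatch -1); the global best window is then
# subjected to the min_len / min_identity filters (NULL when it fails them,
# matching a finder that reports no pair)
oracle_best_repeat <- function(up, dn, min_len, min_identity) {
  U <- strsplit(up, "")[[1]]; D <- strsplit(dn, "")[[1]]
  nu <- length(U); nd <- length(D)
  best <- NULL; best_score <- 0
  for (off in (-(nu - 1)):(nd - 1)) {
    i0 <- max(1, 1 - off); i1 <- min(nu, nd - off)
    if (i1 < i0) next
    val <- ifelse(U[i0:i1] == D[(i0 + off):(i1 + off)], 1, -1)
    # maximum-subarray scan with explicit window tracking
    run <- 0; run_start <- 1
    for (p in seq_along(val)) {
      if (run <= 0) { run <- 0; run_start <- p }
      run <- run + val[p]
      if (run > best_score) {
        best_score <- run
        s <- i0 + run_start - 1L; e <- i0 + p - 1L
        len <- e - s + 1L
        best <- list(u_start = s - 1L, u_end = e,
                     d_start = s + off - 1L, d_end = e + off,
                     identity = sum(val[run_start:p] == 1) / len,
                     length = len, score = run)
      }
    }
  }
  if (is.null(best) || best$length < min_len ||
      best$identity < min_identity) return(NULL)
  best
}

# naive all-window PSSM rescoring of every frame of a region
oracle_scan <- function(seq, model) {
  frames <- six_frame_translate(seq)
  hits <- list()
  for (fr in frames) {
    aa <- strsplit(fr$aa, "")[[1]]
    M <- length(aa); L <- model$length
    if (M < L) next
    for (s in 1:(M - L + 1)) {
      win <- aa[s:(s + L - 1)]
      if (any(win == "*")) next
      sc <- 0
      for (j in 1:L) {
        r <- match(win[j], rownames(model$matrix))
        sc <- sc + if (is.na(r)) min(model$matrix) else model$matrix[r, j]
      }
      if (sc >= model$threshold) {
        iv <- frame_residue_interval(fr$frame, s - 1L, nchar(seq), L)
        hits[[length(hits) + 1L]] <- data.frame(
          start = iv[1], end = iv[2], frame = fr$frame, score = sc)
      }
    }
  }
  if (!length(hits)) return(data.frame(start = integer(), end = integer(),
                                       frame = integer(), score = numeric()))
  do.call(rbind, hits)
}

random_seq <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_at <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}
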