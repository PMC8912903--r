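# End-to-end discovery pipeline: simulate/load -> call candidate regions ->
# domain scan (with the ">1 kb and >= 1 protein motif" acceptance rule) ->
# LTR search and classification -> genome-wide copies and solo-LTRs ->
# family clustering and lineage assignment -> small-RNA profiling ->
# evaluation against ground truth.

#' Pipeline configuration
#'
#' Bundles every stage's threshold block.  Unknown keys in any block are
#' rejected.
#'
#' @param synth A [synth_config()] describing the simulated input (set to
#'   `NULL` when `inputs` supplies real files).
#' @param inputs Optional named list of file paths: `genome`, `annotations`,
#'   `srna_wt`, `srna_mut`, `mrna_wt`, `mrna_mut`, `reads_wt`, `reads_mut`,
#'   and optionally `truth` (a GFF3 written by [write_truth_gff3()]).
#' @param signature A [signature_thresholds()].
#' @param domains List: `alpha`, `null_draws`, `calibration_seed`.
#' @param ltr List: `k`, `min_len`, `min_identity`, `margin` (flank margin
#'   beyond the candidate region searched for repeats).
#' @param copies List: `k`, `min_len`, `min_identity`.
#' @param solo List: `k`, `min_len`, `min_identity`, `exclusion`.
#' @param family List: `threshold`.
#' @param srna A [sirna_class_params()].
#' @param evaluation List: `reciprocal` (overlap fraction for call/truth
#'   matching).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(), inputs = NULL,
                            signature = signature_thresholds(),
                            domains = list(), ltr = list(), copies = list(),
                            solo = list(), family = list(), srna = sirna_class_params(),
                            evaluation = list()) {
  fill <- function(given, defaults, block) {
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown)) {
      stop("unknown key(s) in pipeline config block '", block, "': ",
           paste(unknown, collapse = ", "))
    }
    utils::modifyList(defaults, given)
  }
  cfg <- list(
    synth = synth, inputs = inputs, signature = signature,
    domains = fill(domains, list(alpha = 1e-3, null_draws = 1000L,
                                 calibration_seed = 97L), "domains"),
    ltr = fill(ltr, list(k = 12L, min_len = 100L, min_identity = 0.80,
                         margin = 500L), "ltr"),
    copies = fill(copies, list(k = 15L, min_len = 200L,
                               min_identity = 0.70), "copies"),
    solo = fill(solo, list(k = 12L, min_len = 100L, min_identity = 0.80,
                           exclusion = 1000L), "solo"),
    family = fill(family, list(threshold = 0.95), "family"),
    srna = srna,
    evaluation = fill(evaluation, list(reciprocal = 0.5), "evaluation"))
  if (is.null(cfg$synth) && is.null(cfg$inputs)) {
    stop("pipeline needs either a synth config or input paths")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full discovery pipeline
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory; receives `candidates.bed`,
#'   `elements.gff3`, `families.tsv`, `tree.nwk`, `profiles.tsv`,
#'   `report.tsv` (when truth is available) and `log.txt`.
#' @return A list of class `pipeline_result`: `calls`, `candidates`,
#'   `families`, `lineages`, `profiles`, `report` (or `NULL`), `log`.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))

  # ---- inputs -------------------------------------------------------------
  if (!is.null(config$synth)) {
    sg <- build_genome(config$synth)
    genome <- sg$genome
    annotations <- sg$annotations
    truth <- sg$truth
    reads_wt <- simulate_reads(sg, "wild_type")
    reads_mut <- simulate_reads(sg, "mutant")
    srna_wt <- simulate_coverage(sg, "sRNA", "wild_type", reads = reads_wt)
    srna_mut <- simulate_coverage(sg, "sRNA", "mutant", reads = reads_mut)
    mrna_wt <- simulate_coverage(sg, "mRNA", "wild_type")
    mrna_mut <- simulate_coverage(sg, "mRNA", "mutant")
    say("input: simulated genome, seed %d, %d planted elements",
        config$synth$seed, nrow(truth))
  } else {
    inp <- config$inputs
    genome <- read_fasta(inp$genome)
    lens <- setNames(Biostrings::width(genome), names(genome))
    annotations <- read_gff3(inp$annotations)
    bs <- config$synth$bin_size %||% 50L
    srna_wt <- read_bedgraph(inp$srna_wt, bs, lens, "RPKM", "sRNA", "wild_type")
    srna_mut <- read_bedgraph(inp$srna_mut, bs, lens, "RPKM", "sRNA", "mutant")
    mrna_wt <- read_bedgraph(inp$mrna_wt, bs, lens, "RPKM", "mRNA", "wild_type")
    mrna_mut <- read_bedgraph(inp$mrna_mut, bs, lens, "RPKM", "mRNA", "mutant")
    reads_wt <- read_reads(inp$reads_wt, genome)
    reads_mut <- read_reads(inp$reads_mut, genome)
    truth <- if (!is.null(inp$truth)) read_truth_gff3(inp$truth)$truth else NULL
    say("input: files from disk (%d contigs)", length(genome))
  }

  # ---- stage 1: candidate regions ----------------------------------------
  cands <- call_candidates(srna_wt, srna_mut, mrna_wt, mrna_mut,
                           annotations, config$signature)
  say("signature: %d candidate regions (%d >= %d bp)", nrow(cands),
      sum(cands$long_enough), config$signature$min_region_length)

  # ---- stage 2: domain scan + acceptance rule ----------------------------
  models <- load_domain_models(alpha = config$domains$alpha,
                               null_draws = config$domains$null_draws,
                               calibration_seed = config$domains$calibration_seed)
  region_hits <- vector("list", nrow(cands))
  accepted <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    h <- scan_domains(cands[i, ], genome, models)
    region_hits[[i]] <- h
    accepted[i] <- cands$long_enough[i] && nrow(h) > 0L
    say("region %s:%d-%d %s (%d bp, %d domain hits)", cands$contig[i],
        cands$start[i], cands$end[i],
        if (accepted[i]) "kept" else "dropped: needs > 1 kb and >= 1 motif",
        cands$end[i] - cands$start[i], nrow(h))
  }
  all_hits <- if (any(accepted)) do.call(rbind, region_hits[accepted]) else
    data.frame(contig = character(), start = integer(), end = integer(),
               frame = integer(), model = character(), score = numeric())

  # ---- stage 3: LTR search and classification ----------------------------
  calls <- list(); call_hits <- list()
  for (i in which(accepted)) {
    reg <- cands[i, ]
    hits <- region_hits[[i]]
    # anchor the repeat search on positive log-odds hits: a hit whose total
    # log-odds is negative is weaker than background and must not drag the
    # cassette envelope into the (repeated, hence doubly-hit) LTRs
    strong <- hits[hits$score > 0, , drop = FALSE]
    if (nrow(strong) == 0L) strong <- hits
    anchor <- c(min(strong$start), max(strong$end))
    # flanks truncated at the candidate region (+ margin) so that repeats of
    # neighbouring elements cannot pair across regions
    L <- Biostrings::width(genome)[match(reg$contig, names(genome))]
    win_s <- max(0L, reg$start - config$ltr$margin)
    win_e <- min(L, reg$end + config$ltr$margin)
    win_seq <- as.character(Biostrings::subseq(genome[[reg$contig]],
                                               win_s + 1L, win_e))
    pairs <- suppressWarnings(find_direct_repeats(
      win_seq, anchor[1] - win_s, anchor[2] - win_s,
      flank = max(anchor[1] - win_s, win_e - anchor[2]),
      k = config$ltr$k, min_len = config$ltr$min_len,
      min_identity = config$ltr$min_identity))
    if (nrow(pairs)) {
      for (col in c("left_start", "left_end", "right_start", "right_end")) {
        pairs[[col]] <- pairs[[col]] + win_s
      }
    }
    cl <- classify_element(reg, hits, pairs, genome,
                           partial_interval = "region")
    if (is.null(cl)) next
    say("element %s:%d-%d classified %s", cl$contig, cl$start, cl$end,
        cl$class)
    calls[[length(calls) + 1L]] <- cl
    call_hits[[length(calls)]] <- hits
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(contig = character(), start = integer(), end = integer(),
               class = character(), tg_ca = logical(),
               left_start = integer(), left_end = integer(),
               right_start = integer(), right_end = integer(),
               ltr_identity = numeric(), n_domains = integer(),
               stringsAsFactors = FALSE)

  # ---- stage 4: genome-wide copies ---------------------------------------
  full_idx <- which(calls$class == "full_length")
  for (i in full_idx) {
    qseq <- as.character(Biostrings::subseq(genome[[calls$contig[i]]],
                                            calls$start[i] + 1L,
                                            calls$end[i]))
    m <- find_copies(qseq, genome, k = config$copies$k,
                     min_len = config$copies$min_len,
                     min_identity = config$copies$min_identity,
                     exclude = calls[i, ])
    if (!nrow(m)) next
    novel <- vapply(seq_len(nrow(m)), function(r) {
      !any(calls$contig == m$contig[r] & calls$start < m$end[r] &
             calls$end > m$start[r])
    }, TRUE)
    for (r in which(novel)) {
      h <- scan_domains(m[r, ], genome, models)
      # a novel copy is only upgraded to an element on a positive-log-odds
      # motif; weak (below-background) windows on short matches would turn
      # bare LTR copies into spurious partials
      h <- h[h$score > 0, , drop = FALSE]
      if (nrow(h) == 0L) next   # domainless matches are left for the solo stage
      cl <- classify_element(m[r, ], h, ltr_pairs = NULL, genome = genome,
                             partial_interval = "region")
      if (is.null(cl)) next
      say("copy search: novel element %s:%d-%d (%s)", cl$contig, cl$start,
          cl$end, cl$class)
      calls <- rbind(calls, cl)
      call_hits[[nrow(calls)]] <- h
      all_hits <- rbind(all_hits, h)
    }
  }

  # ---- stage 5: solo-LTRs ------------------------------------------------
  solos <- list()
  for (i in which(calls$class == "full_length")) {
    if (is.na(calls$left_start[i])) next
    ltr_seq <- as.character(Biostrings::subseq(genome[[calls$contig[i]]],
                                               calls$left_start[i] + 1L,
                                               calls$left_end[i]))
    s <- find_solo_ltrs(ltr_seq, genome, calls,
                        exclusion = config$solo$exclusion,
                        min_identity = config$solo$min_identity,
                        min_len = config$solo$min_len, k = config$solo$k)
    if (nrow(s)) solos[[length(solos) + 1L]] <- s
  }
  if (length(solos)) {
    s <- do.call(rbind, solos)
    s$score <- s$identity
    s$length <- s$end - s$start
    s <- dedupe_matches(s)
    say("solo search: %d solo-LTR loci", nrow(s))
    for (r in seq_len(nrow(s))) {
      calls <- rbind(calls, data.frame(
        contig = s$contig[r], start = s$start[r], end = s$end[r],
        class = "solo_LTR", tg_ca = FALSE, left_start = NA_integer_,
        left_end = NA_integer_, right_start = NA_integer_,
        right_end = NA_integer_, ltr_identity = s$identity[r],
        n_domains = 0L, stringsAsFactors = FALSE))
      call_hits[[nrow(calls)]] <-
        data.frame(contig = character(), start = integer(),
                   end = integer(), frame = integer(), model = character(),
                   score = numeric())
    }
  }
  key <- order(calls$contig, calls$start, method = "radix")
  calls <- calls[key, , drop = FALSE]
  call_hits <- call_hits[key]
  calls$element_id <- sprintf("call%03d", seq_len(nrow(calls)))
  rownames(calls) <- NULL
  # orientation from the coding frames of the domain hits
  calls$strand <- vapply(seq_len(nrow(calls)), function(i) {
    h <- call_hits[[i]]
    if (nrow(h) == 0L) return(".")
    if (sum(sign(h$frame)) < 0) "-" else "+"
  }, "")

  # ---- stage 6: family clustering + lineages -----------------------------
  triplets <- list()
  for (i in seq_len(nrow(calls))) {
    h <- call_hits[[i]]
    doms <- setNames(rep(NA_character_, 3), CORE_DOMAINS)
    for (d in CORE_DOMAINS) {
      hd <- h[h$model == d, , drop = FALSE]
      if (!nrow(hd)) next
      best <- hd[which.max(hd$score), ]
      seq <- as.character(Biostrings::subseq(genome[[best$contig]],
                                             best$start + 1L, best$end))
      if (best$frame < 0) {
        seq <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(seq)))
      }
      doms[[d]] <- seq
    }
    triplets[[i]] <- domain_triplet(calls$element_id[i],
                                    doms[["reverse_transcriptase"]],
                                    doms[["rnase_h"]], doms[["integrase"]],
                                    contig = calls$contig[i],
                                    start = calls$start[i])
  }
  has_core <- vapply(triplets, function(t) {
    any(!is.na(unlist(t[CORE_DOMAINS])))
  }, TRUE)
  fams <- NULL; lineage <- NULL
  calls$family <- rep(NA_character_, nrow(calls))
  calls$lineage <- rep(NA_character_, nrow(calls))
  if (any(has_core)) {
    fams <- cluster_families(triplets[has_core],
                             threshold = config$family$threshold)
    calls$family <- fams$families$family[match(calls$element_id,
                                               fams$families$element_id)]
    references <- load_reference_triplets()
    lineage <- assign_lineages(fams, references)
    fam_lin <- lineage$lineages
    calls$lineage <- unname(fam_lin[calls$family])
    say("clustering: %d families over %d elements",
        length(unique(fams$families$family)), nrow(fams$families))
    # propagate family to solo-LTRs via best-matching full-length LTR
    calls <- propagate_solo_families(calls, genome, fam_lin)
  }

  # ---- stage 7: small-RNA profiles ---------------------------------------
  profiles <- list()
  for (i in which(calls$class %in% c("full_length", "partial"))) {
    el <- calls[i, ]
    if (el$strand == ".") el$strand <- "+"
    for (cond in c("wild_type", "mutant")) {
      rr <- if (cond == "wild_type") reads_wt else reads_mut
      pr <- profile_small_rnas(rr, el)
      lab <- if (pr$total_reads > 0) classify_profile(pr, config$srna) else NA_character_
      profiles[[length(profiles) + 1L]] <- data.frame(
        element_id = el$element_id, condition = cond,
        total_reads = pr$total_reads, strand_bias = pr$strand_bias,
        five_prime_u = pr$five_prime_u, modal_length = pr$modal_length,
        label = as.character(lab), stringsAsFactors = FALSE)
    }
  }
  profiles <- if (length(profiles)) do.call(rbind, profiles) else
    data.frame(element_id = character(), condition = character(),
               total_reads = numeric(), strand_bias = numeric(),
               five_prime_u = numeric(), modal_length = integer(),
               label = character(), stringsAsFactors = FALSE)

  # ---- evaluation ---------------------------------------------------------
  report <- NULL
  if (!is.null(truth) && nrow(truth)) {
    report <- evaluate_calls(calls, truth,
                             reciprocal = config$evaluation$reciprocal)
    say("evaluation: base precision %.3f, families ARI %s",
        report$base_precision,
        formatC(report$ari, digits = 3, format = "f"))
  }

  # ---- outputs ------------------------------------------------------------
  write_candidates_bed(cands, file.path(outdir, "candidates.bed"))
  write_calls_gff3(calls, file.path(outdir, "elements.gff3"))
  if (!is.null(fams)) {
    write.table(fams$families, file.path(outdir, "families.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(lineage$newick, file.path(outdir, "tree.nwk"))
  }
  write.table(profiles, file.path(outdir, "profiles.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(report)) write_report_tsv(report, file.path(outdir, "report.tsv"))
  writeLines(log, file.path(outdir, "log.txt"))
  structure(list(calls = calls, candidates = cands,
                 families = fams, lineages = lineage, profiles = profiles,
                 report = report, log = log),
            class = "pipeline_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# assign each solo-LTR call the family of the best-matching full-length LTR
propagate_solo_families <- function(calls, genome, fam_lin) {
  full <- which(calls$class == "full_length" & !is.na(calls$family) &
                  !is.na(calls$left_start))
  if (!length(full)) return(calls)
  ltr_seqs <- lapply(full, function(i) {
    as.character(Biostrings::subseq(genome[[calls$contig[i]]],
                                    calls$left_start[i] + 1L,
                                    calls$left_end[i]))
  })
  for (s in which(calls$class == "solo_LTR")) {
    sseq <- as.character(Biostrings::subseq(genome[[calls$contig[s]]],
                                            calls$start[s] + 1L,
                                            calls$end[s]))
    # solo orientation is unknown: compare both strands
    sseq_rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(sseq)))
    best <- NA_integer_; best_id <- -1
    for (k in seq_along(full)) {
      idv <- max(vapply(c(sseq, sseq_rc), function(x) {
        al <- nw_global_cpp(x, ltr_seqs[[k]], 1, -1, 2)
        if (al$columns > 0) al$matches / al$columns else 0
      }, 0.0))
      if (idv > best_id) { best_id <- idv; best <- full[k] }
    }
    if (!is.na(best) && best_id >= 0.8) {
      calls$family[s] <- calls$family[best]
      calls$lineage[s] <- calls$lineage[best]
    }
  }
  calls
}

write_candidates_bed <- function(cands, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%.4f", cands$contig, cands$start,
                   cands$end, cands$class, cands$mrna_fold)
  writeLines(lines, path)
}

write_calls_gff3 <- function(calls, path) {
  recs <- list()
  for (i in seq_len(nrow(calls))) {
    attrs <- sprintf("ID=%s;class=%s", calls$element_id[i], calls$class[i])
    if (!is.na(calls$family[i])) {
      attrs <- paste0(attrs, ";family=", calls$family[i])
    }
    if (!is.na(calls$lineage[i])) {
      attrs <- paste0(attrs, ";lineage=", calls$lineage[i])
    }
    recs[[length(recs) + 1L]] <- data.frame(
      seqid = calls$contig[i], source = "retroscout",
      type = "retrotransposon", start = calls$start[i], end = calls$end[i],
      score = ".",
      strand = if (!is.null(calls$strand)) calls$strand[i] else ".",
      phase = ".", attributes = attrs,
      stringsAsFactors = FALSE)
    if (!is.na(calls$left_start[i])) {
      for (side in c("left", "right")) {
        recs[[length(recs) + 1L]] <- data.frame(
          seqid = calls$contig[i], source = "retroscout",
          type = "long_terminal_repeat",
          start = calls[[paste0(side, "_start")]][i],
          end = calls[[paste0(side, "_end")]][i],
          score = sprintf("%.4f", calls$ltr_identity[i]), strand = ".",
          phase = ".",
          attributes = sprintf("Parent=%s", calls$element_id[i]),
          stringsAsFactors = FALSE)
      }
    }
  }
  set <- annotation_set(if (length(recs)) do.call(rbind, recs) else
    data.frame(seqid = character(), source = character(), type = character(),
               start = integer(), end = integer(), score = character(),
               strand = character(), phase = character(),
               attributes = character(), stringsAsFactors = FALSE))
  write_gff3(set, path)
}

write_report_tsv <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("metric\tvalue", con)
  emit <- function(k, v) writeLines(sprintf("%s\t%s", k, v), con)
  for (r in seq_len(nrow(report$per_class))) {
    pc <- report$per_class[r, ]
    emit(paste0("recall_", pc$class), sprintf("%.6f", pc$recall))
    emit(paste0("precision_", pc$class), sprintf("%.6f", pc$precision))
  }
  emit("base_precision", sprintf("%.6f", report$base_precision))
  emit("max_boundary_error_bp",
       sprintf("%d", if (length(report$boundary_errors))
         max(report$boundary_errors) else NA_integer_))
  emit("ari", sprintf("%.6f", report$ari))
  invisible(path)
}

#' Evaluate element calls against a ground truth
#'
#' A call matches a truth element when their reciprocal overlap is at least
#' `reciprocal` of each interval.  Per-class precision and recall, per-edge
#' absolute boundary errors for matched full-length calls, called-base
#' precision, a class confusion matrix, and (when both sides carry family
#' labels) the adjusted Rand index of the family partitions.
#'
#' @param calls data.frame with `contig, start, end, class` (optionally
#'   `family`).
#' @param truth Truth data.frame as in `synth_genome$truth`.
#' @param reciprocal Minimum reciprocal overlap fraction (default 0.5).
#' @return A list of class `evaluation_report`.
#' @export
evaluate_calls <- function(calls, truth, reciprocal = 0.5) {
  if (is.null(truth) || nrow(truth) == 0L) stop("empty truth set")
  classes <- c("full_length", "partial", "solo_LTR")
  match_of_truth <- rep(NA_integer_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    ov <- pmin(calls$end, truth$end[i]) - pmax(calls$start, truth$start[i])
    okc <- calls$contig == truth$contig[i] & ov > 0
    frac_call <- ov / (calls$end - calls$start)
    frac_truth <- ov / (truth$end[i] - truth$start[i])
    cand <- which(okc & frac_call >= reciprocal & frac_truth >= reciprocal)
    if (length(cand)) match_of_truth[i] <- cand[which.max(ov[cand])]
  }
  matched_calls <- stats::na.omit(unique(match_of_truth))
  confusion <- table(
    truth = factor(truth$class, levels = classes),
    call = factor(ifelse(is.na(match_of_truth), "unmatched",
                         calls$class[match_of_truth]),
                  levels = c(classes, "unmatched")))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    t_idx <- truth$class == cl
    rec <- if (any(t_idx)) {
      mean(!is.na(match_of_truth[t_idx]) &
             calls$class[match_of_truth[t_idx]] == cl)
    } else NA_real_
    c_idx <- which(calls$class == cl)
    prec <- if (length(c_idx)) {
      hit <- vapply(c_idx, function(ci) {
        any(match_of_truth == ci & truth$class == cl, na.rm = TRUE)
      }, TRUE)
      mean(hit)
    } else NA_real_
    data.frame(class = cl, n_truth = sum(t_idx), n_calls = length(c_idx),
               recall = rec, precision = prec, stringsAsFactors = FALSE)
  }))
  # boundary errors for matched full-length calls
  fl <- which(truth$class == "full_length" & !is.na(match_of_truth))
  boundary <- unlist(lapply(fl, function(i) {
    ci <- match_of_truth[i]
    c(abs(calls$start[ci] - truth$start[i]),
      abs(calls$end[ci] - truth$end[i]))
  }))
  # called-base precision vs planted element bases
  base_precision <- called_base_precision(calls, truth)
  # family partition agreement over matched calls with family labels
  ari <- NA_real_
  if ("family" %in% names(calls)) {
    ok <- !is.na(match_of_truth)
    ci <- match_of_truth[ok]
    lab_call <- calls$family[ci]
    lab_truth <- truth$family[ok]
    keep <- !is.na(lab_call)
    if (sum(keep) >= 2) {
      ari <- mclust::adjustedRandIndex(lab_call[keep], lab_truth[keep])
    }
  }
  structure(list(per_class = per_class, confusion = confusion,
                 boundary_errors = as.integer(boundary),
                 base_precision = base_precision, ari = ari,
                 match_of_truth = match_of_truth),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  print(x$per_class, row.names = FALSE)
  cat(sprintf("base precision %.3f; ARI %s; max boundary error %s bp\n",
              x$base_precision, formatC(x$ari, digits = 3, format = "f"),
              if (length(x$boundary_errors)) max(x$boundary_errors) else "-"))
  invisible(x)
}

# fraction of called bases lying inside planted element bases
called_base_precision <- function(calls, truth) {
  if (nrow(calls) == 0L) return(NA_real_)
  total <- 0; inside <- 0
  for (i in seq_len(nrow(calls))) {
    total <- total + (calls$end[i] - calls$start[i])
    t <- truth[truth$contig == calls$contig[i], , drop = FALSE]
    if (!nrow(t)) next
    ov <- pmax(0, pmin(t$end, calls$end[i]) - pmax(t$start, calls$start[i]))
    inside <- inside + sum(ov)   # truth elements are disjoint
  }
  inside / total
}
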