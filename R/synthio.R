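# Synthetic planted-retroelement genome generator with ground truth.
#
# Families are built from bundled lineage cassettes (synthetic stand-ins for
# the two fission-yeast retrotransposon lineages); copies diverge by
# per-site substitution; wild-type siRNA reads carry the dual-strand,
# 23-24 nt, 5'U-biased signature, which collapses in the mutant except for
# sense-only broad-length degradation reads over one mobilizing family.
#
# One RNG stream per artifact (background seed+0, element ancestry seed+1,
# placement seed+2, wild-type reads seed+3, mutant reads seed+4, wild-type
# mRNA seed+5, mutant mRNA seed+6) so that, e.g., changing read simulation
# never perturbs the genome.

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe the study conditions the analysis assumes: a 2 Mb
#' three-contig genome, five families split across two lineages, 2 full /
#' 3 partial / 3 solo-LTR copies per family, 2% within- and 20%
#' between-family pairwise divergence, 2,000 siRNA reads per transcribed
#' element in wild type (modal lengths 23-24, half antisense, 75% 5'U),
#' sense-only 18-30 nt degradation reads over one mobilizing family in the
#' mutant, and an 8-fold mRNA increase over elements in the mutant on an
#' RPKM-5 background.
#'
#' @param seed Integer master seed.
#' @param contig_lengths Named integer vector of contig lengths.
#' @param gc GC fraction of the background sequence.
#' @param n_families Number of planted families (alternately assigned to
#'   the `tf_like` and `ty3_like` lineages).
#' @param full_per_family,partial_per_family,solo_per_family Copies per
#'   family by class.
#' @param element_length Full-length element size in bp (LTRs included).
#' @param ltr_length LTR size in bp.
#' @param within_divergence Expected pairwise divergence between two
#'   same-family copies (each copy is mutated from the family ancestor at
#'   half this rate).
#' @param between_divergence Expected pairwise divergence between two
#'   families of the same lineage (family ancestors are mutated from the
#'   lineage cassette at half this rate).
#' @param sirna_per_element Wild-type siRNA reads per transcribed element.
#' @param sirna_length_probs Named probability vector over read lengths.
#' @param antisense_fraction Probability a wild-type siRNA is antisense.
#' @param five_prime_u Target fraction of wild-type siRNAs with a 5' U.
#' @param degradation_reads Mutant degradation reads per element of the
#'   mobilizing family (sense-only, uniform `deg_length_range`).
#' @param deg_length_range Length range of degradation reads.
#' @param mobilizing_family Index of the family that mobilises in the
#'   mutant.
#' @param mrna_fold mRNA fold-increase over transcribed elements in the
#'   mutant.
#' @param mrna_background_rpkm Background mRNA level (RPKM).
#' @param mrna_depth_per_bin Expected read count per background bin (sets
#'   the Poisson noise level of the mRNA tracks).
#' @param bin_size Coverage bin size in bp.
#' @param minus_strand_prob Probability an element is planted on the minus
#'   strand.
#' @param n_decoy_genes Pre-existing (non-element) gene annotations planted
#'   outside the element clusters.
#' @return A validated `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         contig_lengths = c(chrI = 800000L, chrII = 700000L,
                                            chrIII = 500000L),
                         gc = 0.40,
                         n_families = 5L,
                         full_per_family = 2L,
                         partial_per_family = 3L,
                         solo_per_family = 3L,
                         element_length = 5000L,
                         ltr_length = 300L,
                         within_divergence = 0.02,
                         between_divergence = 0.20,
                         sirna_per_element = 2000L,
                         sirna_length_probs = c(`20` = 0.05, `21` = 0.05,
                                                `22` = 0.05, `23` = 0.35,
                                                `24` = 0.35, `25` = 0.05,
                                                `26` = 0.05, `27` = 0.05),
                         antisense_fraction = 0.5,
                         five_prime_u = 0.75,
                         degradation_reads = 2000L,
                         deg_length_range = c(18L, 30L),
                         mobilizing_family = 1L,
                         mrna_fold = 8,
                         mrna_background_rpkm = 5,
                         mrna_depth_per_bin = 20,
                         bin_size = 50L,
                         minus_strand_prob = 0.2,
                         n_decoy_genes = 20L) {
  cfg <- as.list(environment())
  stopifnot(gc > 0, gc < 1, element_length > 2 * ltr_length,
            within_divergence >= 0, between_divergence >= 0,
            antisense_fraction >= 0, antisense_fraction <= 1,
            five_prime_u >= 0, five_prime_u <= 1,
            abs(sum(sirna_length_probs) - 1) < 1e-9,
            mobilizing_family >= 1,
            all(contig_lengths > 0), n_families >= 0)
  planted <- n_families * (full_per_family * element_length +
                             partial_per_family * element_length +
                             solo_per_family * ltr_length)
  if (planted > 0.4 * sum(contig_lengths)) {
    stop("planted sequence would exceed 40% of the genome")
  }
  class(cfg) <- "synth_config"
  cfg
}

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n, gc) {
  paste(sample(BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# per-site substitution at `rate`; codons in `dom_spans` (0-based half-open,
# relative coordinates) that would become stops are reverted.
mutate_seq <- function(seq, rate, dom_spans = NULL) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  orig <- chars
  n <- length(chars)
  idx <- which(runif(n) < rate)
  if (!length(idx)) return(seq)
  alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                nrow = 4, byrow = TRUE, dimnames = list(BASES, NULL))
  pick <- sample.int(3L, length(idx), replace = TRUE)
  chars[idx] <- alt[cbind(match(orig[idx], BASES), pick)]
  if (!is.null(dom_spans) && nrow(dom_spans)) {
    for (r in seq_len(nrow(dom_spans))) {
      s <- dom_spans$start[r]; e <- dom_spans$end[r]
      ncod <- (e - s) %/% 3L
      if (ncod < 1L) next
      pos <- s + seq_len(ncod * 3L)   # 1-based indices of codon bases
      cod <- matrix(chars[pos], nrow = 3L)
      codons <- paste0(cod[1, ], cod[2, ], cod[3, ])
      bad <- which(codons %in% STOP_CODONS)
      for (b in bad) {
        cpos <- pos[(b - 1L) * 3L + 1:3]
        chars[cpos] <- orig[cpos]   # revert the whole codon
      }
    }
  }
  paste(chars, collapse = "")
}

# bundled lineage cassettes: named nucleotide domain sequences per lineage
load_cassette_refs <- function(dir = system.file("extdata",
                                                 "synthetic_references",
                                                 package = "retroscout")) {
  files <- sort_c(list.files(dir, pattern = "^synthetic_cassette_.*\\.fa$",
                             full.names = TRUE))
  if (!length(files)) stop("no cassette references found in ", dir)
  out <- list()
  for (f in files) {
    lineage <- sub("\\.fa$", "", sub("^synthetic_cassette_", "", basename(f)))
    x <- Biostrings::readDNAStringSet(f)
    out[[lineage]] <- as.character(x)
  }
  out
}

# assemble one family ancestor; returns seq + relative feature spans
make_ancestor <- function(domains_nt, ltr, cfg) {
  ltr_len <- cfg$ltr_length
  internal <- cfg$element_length - 2L * ltr_len
  dom_len <- nchar(domains_nt)
  k <- length(domains_nt)
  lead <- 300L; inter <- 100L
  trailing <- internal - lead - sum(dom_len) - inter * (k - 1L)
  if (trailing < 0L) stop("element_length too small for the domain cassette")
  parts <- c(ltr, random_dna(lead, cfg$gc))
  spans <- data.frame(name = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  pos <- ltr_len + lead
  for (i in seq_len(k)) {
    parts <- c(parts, domains_nt[[i]])
    spans <- rbind(spans, data.frame(name = names(domains_nt)[i],
                                     start = pos, end = pos + dom_len[i],
                                     stringsAsFactors = FALSE))
    pos <- pos + dom_len[i]
    if (i < k) { parts <- c(parts, random_dna(inter, cfg$gc)); pos <- pos + inter }
  }
  parts <- c(parts, random_dna(trailing, cfg$gc), ltr)
  seq <- paste(parts, collapse = "")
  stopifnot(nchar(seq) == cfg$element_length)
  ltr_spans <- data.frame(name = "LTR",
                          start = c(0L, cfg$element_length - ltr_len),
                          end = c(ltr_len, cfg$element_length),
                          stringsAsFactors = FALSE)
  list(seq = seq, dom_spans = spans, ltr_spans = ltr_spans)
}

#' Build a synthetic genome with planted retroelements
#'
#' @param cfg A [synth_config()].
#' @return A list of class `synth_genome`: `genome`
#'   ([Biostrings::DNAStringSet]), `truth` (data.frame `element_id, contig,
#'   start, end, strand, class, family, lineage`), `features` (data.frame
#'   `element_id, feature, start, end` with LTR and domain sub-intervals in
#'   genomic coordinates), `annotations` (an `annotation_set` of decoy
#'   genes), and `config`.
#' @export
build_genome <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  contigs <- local_rng(cfg$seed + 0L, {
    lapply(cfg$contig_lengths, function(L) random_dna(L, cfg$gc))
  })
  empty_truth <- data.frame(element_id = character(), contig = character(),
                            start = integer(), end = integer(),
                            strand = character(), class = character(),
                            family = integer(), lineage = character(),
                            stringsAsFactors = FALSE)
  empty_feat <- data.frame(element_id = character(), feature = character(),
                           start = integer(), end = integer(),
                           stringsAsFactors = FALSE)
  if (cfg$n_families == 0L) {
    genome <- Biostrings::DNAStringSet(unlist(contigs))
    names(genome) <- names(cfg$contig_lengths)
    ann <- local_rng(cfg$seed + 2L,
                     decoy_annotations(cfg, names(genome), list()))
    return(structure(list(genome = genome, truth = empty_truth,
                          features = empty_feat, annotations = ann,
                          config = cfg),
                     class = "synth_genome"))
  }
  refs <- load_cassette_refs()
  lineage_names <- sort_c(names(refs))
  # ancestry stream: lineage LTR bases, family ancestors, per-copy sequences
  elements <- local_rng(cfg$seed + 1L, {
    ltr_bases <- lapply(lineage_names, function(l) random_dna(cfg$ltr_length,
                                                              cfg$gc))
    names(ltr_bases) <- lineage_names
    els <- list()
    for (f in seq_len(cfg$n_families)) {
      lineage <- lineage_names[(f - 1L) %% length(lineage_names) + 1L]
      half_between <- cfg$between_divergence / 2
      ltr_f <- mutate_seq(ltr_bases[[lineage]], half_between)
      doms_f <- refs[[lineage]]
      doms_f[] <- vapply(seq_along(doms_f), function(i) {
        mutate_seq(doms_f[[i]], half_between,
                   data.frame(start = 0L, end = nchar(doms_f[[i]])))
      }, "")
      anc <- make_ancestor(doms_f, ltr_f, cfg)
      half_within <- cfg$within_divergence / 2
      core_present <- intersect(anc$dom_spans$name, CORE_DOMAINS)
      for (i in seq_len(cfg$full_per_family)) {
        seq <- mutate_seq(anc$seq, half_within, anc$dom_spans)
        els[[length(els) + 1L]] <- list(
          family = f, lineage = lineage, class = "full_length", seq = seq,
          dom_spans = anc$dom_spans, ltr_spans = anc$ltr_spans)
      }
      for (i in seq_len(cfg$partial_per_family)) {
        seq <- mutate_seq(anc$seq, half_within, anc$dom_spans)
        runs <- valid_domain_runs(anc$dom_spans, core_present)
        run <- runs[[sample.int(length(runs), 1L)]]
        d <- anc$dom_spans[run, , drop = FALSE]
        m1 <- sample(20:200, 1L); m2 <- sample(20:200, 1L)
        ws <- max(cfg$ltr_length, min(d$start) - m1)
        we <- min(cfg$element_length - cfg$ltr_length, max(d$end) + m2)
        sub <- substr(seq, ws + 1L, we)
        d$start <- d$start - ws; d$end <- d$end - ws
        els[[length(els) + 1L]] <- list(
          family = f, lineage = lineage, class = "partial", seq = sub,
          dom_spans = d,
          ltr_spans = data.frame(name = character(), start = integer(),
                                 end = integer(), stringsAsFactors = FALSE))
      }
      for (i in seq_len(cfg$solo_per_family)) {
        seq <- mutate_seq(ltr_f, half_within)
        els[[length(els) + 1L]] <- list(
          family = f, lineage = lineage, class = "solo_LTR", seq = seq,
          dom_spans = data.frame(name = character(), start = integer(),
                                 end = integer(), stringsAsFactors = FALSE),
          ltr_spans = data.frame(name = "LTR", start = 0L,
                                 end = nchar(seq),
                                 stringsAsFactors = FALSE))
      }
    }
    els
  })
  # placement stream: strand choice, clustered placement, decoy genes
  placed <- local_rng(cfg$seed + 2L, {
    place_elements(contigs, elements, cfg)
  })
  genome <- Biostrings::DNAStringSet(placed$contigs)
  names(genome) <- names(cfg$contig_lengths)
  structure(list(genome = genome, truth = placed$truth,
                 features = placed$features,
                 annotations = placed$annotations, config = cfg),
            class = "synth_genome")
}

#' @export
print.synth_genome <- function(x, ...) {
  cat(sprintf("synth_genome: %d contigs (%.2f Mb), %d planted elements\n",
              length(x$genome), sum(Biostrings::width(x$genome)) / 1e6,
              nrow(x$truth)))
  invisible(x)
}

# all contiguous domain runs that retain >= 1 core domain
valid_domain_runs <- function(dom_spans, core_present) {
  k <- nrow(dom_spans)
  runs <- list()
  for (i in 1:k) for (j in i:k) {
    if (any(dom_spans$name[i:j] %in% core_present)) {
      runs[[length(runs) + 1L]] <- i:j
    }
  }
  runs
}

# place elements in clustered "centromeric" windows, round-robin over
# contigs, with gaps >= 2 kb; runs inside the placement RNG stream
place_elements <- function(contigs, elements, cfg) {
  contig_names <- names(cfg$contig_lengths)
  nc <- length(contig_names)
  strand <- ifelse(runif(length(elements)) < cfg$minus_strand_prob, "-", "+")
  assign_to <- (seq_along(elements) - 1L) %% nc + 1L
  truth <- list(); features <- list()
  windows <- list()
  chars_by_contig <- lapply(contigs, function(s) strsplit(s, "")[[1]])
  for (ci in seq_len(nc)) {
    cn <- contig_names[ci]
    idx <- which(assign_to == ci)
    if (!length(idx)) next
    lens <- vapply(elements[idx], function(e) nchar(e$seq), 0L)
    gaps <- sample(2000:3500, length(idx) + 1L, replace = TRUE)
    span <- sum(lens) + sum(gaps)
    L <- cfg$contig_lengths[[ci]]
    if (span > 0.9 * L) stop("placement impossible without overlap on ", cn)
    base <- (L - span) %/% 2L
    jitter <- sample.int(min(5000L, max(1L, base)), 1L) - 1L
    pos <- base + jitter
    win_start <- pos
    for (m in seq_along(idx)) {
      e <- elements[[idx[m]]]
      pos <- pos + gaps[m]
      elen <- nchar(e$seq)
      eseq <- e$seq
      if (strand[idx[m]] == "-") {
        eseq <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(eseq)))
      }
      chars_by_contig[[ci]][(pos + 1L):(pos + elen)] <-
        strsplit(eseq, "")[[1]]
      eid <- sprintf("el%03d", idx[m])
      truth[[length(truth) + 1L]] <- data.frame(
        element_id = eid, contig = cn, start = pos, end = pos + elen,
        strand = strand[idx[m]], class = e$class, family = e$family,
        lineage = e$lineage, stringsAsFactors = FALSE)
      feat <- rbind(e$ltr_spans, e$dom_spans)
      if (nrow(feat)) {
        if (strand[idx[m]] == "-") {
          new_start <- elen - feat$end; new_end <- elen - feat$start
          feat$start <- new_start; feat$end <- new_end
        }
        features[[length(features) + 1L]] <- data.frame(
          element_id = eid, feature = feat$name,
          start = pos + feat$start, end = pos + feat$end,
          stringsAsFactors = FALSE)
      }
      pos <- pos + elen
    }
    windows[[cn]] <- c(win_start, pos + gaps[length(gaps)])
  }
  annotations <- decoy_annotations(cfg, contig_names, windows)
  contigs_out <- vapply(chars_by_contig, paste, "", collapse = "")
  truth <- do.call(rbind, truth)
  features <- if (length(features)) do.call(rbind, features) else
    data.frame(element_id = character(), feature = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  truth <- truth[order(truth$contig, truth$start, method = "radix"), ,
                 drop = FALSE]
  rownames(truth) <- NULL
  list(contigs = contigs_out, truth = truth, features = features,
       annotations = annotations)
}

# decoy gene annotations outside the element cluster windows
decoy_annotations <- function(cfg, contig_names, windows) {
  recs <- list()
  n <- cfg$n_decoy_genes
  if (n > 0L) {
    per <- rep(n %/% length(contig_names), length(contig_names))
    per[seq_len(n %% length(contig_names))] <-
      per[seq_len(n %% length(contig_names))] + 1L
    g <- 0L
    for (ci in seq_along(contig_names)) {
      cn <- contig_names[ci]
      L <- cfg$contig_lengths[[ci]]
      win <- windows[[cn]]
      placed <- 0L; tries <- 0L
      while (placed < per[ci] && tries < 1000L) {
        tries <- tries + 1L
        glen <- sample(500:2000, 1L)
        gs <- sample.int(L - glen, 1L) - 1L
        if (!is.null(win) && gs < win[2] + 3000L && gs + glen > win[1] - 3000L) {
          next
        }
        ok <- TRUE
        for (r in recs) {
          if (r$seqid == cn && gs < r$end && gs + glen > r$start) {
            ok <- FALSE; break
          }
        }
        if (!ok) next
        g <- g + 1L; placed <- placed + 1L
        recs[[length(recs) + 1L]] <- data.frame(
          seqid = cn, source = "synth", type = "gene", start = gs,
          end = gs + glen, score = ".", strand = "+", phase = ".",
          attributes = sprintf("ID=gene%03d", g), stringsAsFactors = FALSE)
      }
    }
  }
  recs <- if (length(recs)) do.call(rbind, recs) else
    data.frame(seqid = character(), source = character(), type = character(),
               start = integer(), end = integer(), score = character(),
               strand = character(), phase = character(),
               attributes = character(), stringsAsFactors = FALSE)
  recs <- recs[order(recs$seqid, recs$start, method = "radix"), ,
               drop = FALSE]
  rownames(recs) <- NULL
  annotation_set(recs)
}

#' Write the ground truth as GFF3
#'
#' Elements become `retrotransposon` parent records (attributes `ID`,
#' `class`, `family`, `lineage`); LTR and domain sub-intervals become child
#' records.
#'
#' @param sg A `synth_genome` (or a list with `truth` and `features`).
#' @param path Output path.
#' @export
write_truth_gff3 <- function(sg, path) {
  tr <- sg$truth; ft <- sg$features
  recs <- list()
  for (i in seq_len(nrow(tr))) {
    recs[[length(recs) + 1L]] <- data.frame(
      seqid = tr$contig[i], source = "retroscout_synth",
      type = "retrotransposon", start = tr$start[i], end = tr$end[i],
      score = ".", strand = tr$strand[i], phase = ".",
      attributes = sprintf("ID=%s;class=%s;family=%d;lineage=%s",
                           tr$element_id[i], tr$class[i], tr$family[i],
                           tr$lineage[i]),
      stringsAsFactors = FALSE)
    f <- ft[ft$element_id == tr$element_id[i], , drop = FALSE]
    for (j in seq_len(nrow(f))) {
      type <- if (f$feature[j] == "LTR") "long_terminal_repeat"
              else "protein_match"
      recs[[length(recs) + 1L]] <- data.frame(
        seqid = tr$contig[i], source = "retroscout_synth", type = type,
        start = f$start[j], end = f$end[j], score = ".",
        strand = tr$strand[i], phase = ".",
        attributes = sprintf("Parent=%s;Name=%s", tr$element_id[i],
                             f$feature[j]),
        stringsAsFactors = FALSE)
    }
  }
  set <- annotation_set(do.call(rbind, recs))
  write_gff3(set, path)
}

#' Read a truth GFF3 back into truth/feature tables
#' @param path Path written by [write_truth_gff3()].
#' @return List with `truth` and `features` data.frames.
#' @export
read_truth_gff3 <- function(path) {
  set <- read_gff3(path)
  r <- set$records
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
    sub(paste0("^;?", key, "="), "", m)
  }
  parents <- r[r$type == "retrotransposon", , drop = FALSE]
  truth <- data.frame(
    element_id = attr_field(parents$attributes, "ID"),
    contig = parents$seqid, start = parents$start, end = parents$end,
    strand = parents$strand,
    class = attr_field(parents$attributes, "class"),
    family = as.integer(attr_field(parents$attributes, "family")),
    lineage = attr_field(parents$attributes, "lineage"),
    stringsAsFactors = FALSE)
  kids <- r[r$type != "retrotransposon", , drop = FALSE]
  features <- data.frame(
    element_id = attr_field(kids$attributes, "Parent"),
    feature = attr_field(kids$attributes, "Name"),
    start = kids$start, end = kids$end, stringsAsFactors = FALSE)
  list(truth = truth, features = features)
}

transcribed_elements <- function(truth) {
  truth[truth$class %in% c("full_length", "partial"), , drop = FALSE]
}

#' Simulate mapped small-RNA reads
#'
#' Wild type: per transcribed element, reads with the configured length
#' distribution, Bernoulli antisense strand, and a 5'U bias realised by
#' biased start-site selection (reads stay consistent with the genome).
#' Mutant: no siRNA reads; sense-only degradation reads with uniform
#' lengths over the mobilizing family only, with no 5' preference.
#'
#' @param sg A `synth_genome`.
#' @param condition `"wild_type"` or `"mutant"`.
#' @return A `read_set` data.frame (count = 1 rows, `five_prime_nt`
#'   annotated).
#' @export
simulate_reads <- function(sg, condition = c("wild_type", "mutant")) {
  condition <- match.arg(condition)
  cfg <- sg$config
  seed <- cfg$seed + if (condition == "wild_type") 3L else 4L
  tr <- transcribed_elements(sg$truth)
  chars_by_contig <- lapply(names(sg$genome), function(cn) {
    strsplit(as.character(sg$genome[[cn]]), "")[[1]]
  })
  names(chars_by_contig) <- names(sg$genome)
  rows <- local_rng(seed, {
    out <- list()
    for (i in seq_len(nrow(tr))) {
      el <- tr[i, ]
      if (condition == "mutant" && el$family != cfg$mobilizing_family) next
      chars <- chars_by_contig[[el$contig]]
      n <- if (condition == "wild_type") cfg$sirna_per_element else
        cfg$degradation_reads
      if (n == 0L) next
      if (condition == "wild_type") {
        n <- cfg$sirna_per_element
        lens <- as.integer(sample(names(cfg$sirna_length_probs), n,
                                  replace = TRUE,
                                  prob = cfg$sirna_length_probs))
        anti <- runif(n) < cfg$antisense_fraction
        rs <- ifelse(anti, flip_strand(el$strand), el$strand)
        want_u <- runif(n) < cfg$five_prime_u
      } else {
        n <- cfg$degradation_reads
        lens <- sample(cfg$deg_length_range[1]:cfg$deg_length_range[2], n,
                       replace = TRUE)
        rs <- rep(el$strand, n)
        want_u <- rep(NA, n)   # no 5' preference
      }
      if (el$end - el$start < max(lens)) {
        warning("element ", el$element_id,
                " shorter than the longest read; skipped")
        next
      }
      starts <- pick_read_starts(chars, el$start, el$end, lens, rs, want_u)
      out[[length(out) + 1L]] <- data.frame(
        contig = el$contig, start = starts, end = starts + lens,
        strand = rs, count = 1L, stringsAsFactors = FALSE)
    }
    out
  })
  if (!length(rows)) {
    df <- data.frame(contig = character(), start = integer(),
                     end = integer(), strand = character(),
                     count = integer(), stringsAsFactors = FALSE)
    return(validate_read_table(df, sg$genome))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$contig, df$start, df$end, df$strand, method = "radix"), ,
           drop = FALSE]
  rownames(df) <- NULL
  validate_read_table(df, sg$genome)
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

# choose read start positions inside [el_start, el_end); when want_u is
# TRUE the start is drawn from positions whose 5' base is U (T on the read
# strand), when FALSE from the complement set, when NA uniformly.
pick_read_starts <- function(chars, el_start, el_end, lens, strands,
                             want_u) {
  n <- length(lens)
  starts <- integer(n)
  for (key in unique(paste(lens, strands, want_u))) {
    ix <- which(paste(lens, strands, want_u) == key)
    l <- lens[ix[1]]; st <- strands[ix[1]]; w <- want_u[ix[1]]
    lo <- el_start; hi <- el_end - l          # admissible starts (0-based)
    cand <- lo:hi
    if (!is.na(w)) {
      fp <- if (st == "+") chars[cand + 1L] else chars[cand + l]
      is_u <- if (st == "+") fp == "T" else fp == "A"
      pool <- if (w) cand[is_u] else cand[!is_u]
      if (!length(pool)) pool <- cand
    } else {
      pool <- cand
    }
    starts[ix] <- pool[sample.int(length(pool), length(ix), replace = TRUE)]
  }
  starts
}

#' Simulate a coverage track
#'
#' mRNA: Poisson bin counts around the configured background level, with
#' the fold-increase applied over transcribed elements in the mutant.
#' sRNA: rasterised from [simulate_reads()] for the same condition.  Both
#' are reported in RPKM.
#'
#' @param sg A `synth_genome`.
#' @param molecule `"mRNA"` or `"sRNA"`.
#' @param condition `"wild_type"` or `"mutant"`.
#' @param reads Optional pre-simulated `read_set` (sRNA only); simulated
#'   internally when missing.
#' @return A `coverage_track` (`normalization = "RPKM"`).
#' @export
simulate_coverage <- function(sg, molecule = c("mRNA", "sRNA"),
                              condition = c("wild_type", "mutant"),
                              reads = NULL) {
  molecule <- match.arg(molecule)
  condition <- match.arg(condition)
  cfg <- sg$config
  bs <- cfg$bin_size
  if (molecule == "sRNA") {
    if (is.null(reads)) reads <- simulate_reads(sg, condition)
    return(rasterize_reads(reads, cfg$contig_lengths, bs,
                           molecule = "sRNA", condition = condition))
  }
  seed <- cfg$seed + if (condition == "wild_type") 5L else 6L
  tr <- transcribed_elements(sg$truth)
  vals <- local_rng(seed, {
    v <- list()
    for (cn in names(cfg$contig_lengths)) {
      L <- cfg$contig_lengths[[cn]]
      nb <- ceiling(L / bs)
      factor <- rep(1, nb)
      if (condition == "mutant" && nrow(tr)) {
        te <- tr[tr$contig == cn, , drop = FALSE]
        for (r in seq_len(nrow(te))) {
          b0 <- te$start[r] %/% bs; b1 <- (te$end[r] - 1L) %/% bs
          for (b in b0:b1) {
            ov <- min(te$end[r], (b + 1) * bs) - max(te$start[r], b * bs)
            frac <- ov / min(bs, L - b * bs)
            factor[b + 1L] <- factor[b + 1L] + (cfg$mrna_fold - 1) * frac
          }
        }
      }
      counts <- rpois(nb, cfg$mrna_depth_per_bin * factor)
      v[[cn]] <- counts * (cfg$mrna_background_rpkm / cfg$mrna_depth_per_bin)
    }
    v
  })
  coverage_track(vals, bs, normalization = "RPKM", molecule = "mRNA",
                 condition = condition,
                 contig_lengths = cfg$contig_lengths)
}

#' Rasterise a read table to an RPKM coverage track
#'
#' Each read contributes its per-bin overlap fraction (of its own length)
#' times its count; bin values are then scaled to RPKM using the total read
#' count as library size.
#'
#' @param reads A `read_set` data.frame.
#' @param contig_lengths Named contig lengths.
#' @param bin_size Bin size in bp.
#' @param molecule,condition Track labels.
#' @return A `coverage_track` (`normalization = "RPKM"`).
#' @export
rasterize_reads <- function(reads, contig_lengths, bin_size,
                            molecule = "sRNA", condition = "unknown") {
  total <- max(sum(reads$count), 1)
  scale <- 1 / (bin_size / 1000) / (total / 1e6)
  vals <- list()
  for (cn in names(contig_lengths)) {
    L <- contig_lengths[[cn]]
    nb <- ceiling(L / bin_size)
    acc <- numeric(nb)
    r <- reads[reads$contig == cn, , drop = FALSE]
    if (nrow(r)) {
      b0 <- r$start %/% bin_size
      b1 <- (r$end - 1L) %/% bin_size
      ov1 <- (pmin(r$end, (b0 + 1) * bin_size) - r$start) / r$length
      acc <- acc + tabulate_weighted(b0 + 1L, r$count * ov1, nb)
      multi <- which(b1 > b0)
      if (length(multi)) {
        for (i in multi) {
          bins <- (b0[i] + 1L):b1[i]
          ovs <- pmin(r$end[i], (bins + 1) * bin_size) -
            pmax(r$start[i], bins * bin_size)
          acc[bins + 1L] <- acc[bins + 1L] +
            r$count[i] * ovs / r$length[i]
        }
      }
    }
    vals[[cn]] <- acc * scale
  }
  coverage_track(vals, bin_size, normalization = "RPKM",
                 molecule = molecule, condition = condition,
                 contig_lengths = contig_lengths)
}

tabulate_weighted <- function(bin, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, bin)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Write a complete synthetic dataset to disk
#'
#' Writes `genome.fa`, `truth.gff3`, `annotations.gff3`,
#' `reads_{wt,mut}.tsv` and `{srna,mrna}_{wt,mut}.bedgraph`.
#'
#' @param cfg A [synth_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the `synth_genome`.
#' @export
write_synth_dataset <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sg <- build_genome(cfg)
  write_fasta(sg$genome, file.path(outdir, "genome.fa"))
  write_truth_gff3(sg, file.path(outdir, "truth.gff3"))
  write_gff3(sg$annotations, file.path(outdir, "annotations.gff3"))
  for (cond in c("wild_type", "mutant")) {
    tag <- if (cond == "wild_type") "wt" else "mut"
    reads <- simulate_reads(sg, cond)
    write_reads(reads, file.path(outdir, sprintf("reads_%s.tsv", tag)))
    write_bedgraph(simulate_coverage(sg, "sRNA", cond, reads = reads),
                   file.path(outdir, sprintf("srna_%s.bedgraph", tag)))
    write_bedgraph(simulate_coverage(sg, "mRNA", cond),
                   file.path(outdir, sprintf("mrna_%s.bedgraph", tag)))
  }
  invisible(sg)
}
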