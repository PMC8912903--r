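# Readers/writers for external formats and the shared interval arithmetic.
#
# Coordinate convention: every interval inside the package is 0-based
# half-open [start, end).  GFF3 (1-based inclusive) is converted at the I/O
# boundary; bedGraph is already 0-based half-open.

#' Read a genome FASTA file
#'
#' Sequences are uppercased, `U` is mapped to `T`, and any character outside
#' `{A,C,G,T,N}` (including alignment gaps) raises a parse error naming the
#' offending line.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique, non-empty names.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("FASTA file contains no records: ", path)
  nm <- names(x)
  nm <- sub("\\s.*$", "", nm)
  if (any(!nzchar(nm))) stop("FASTA record with empty name in ", path)
  if (anyDuplicated(nm)) stop("duplicate FASTA record names in ", path)
  seqs <- toupper(as.character(x))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    .fasta_char_error(path, record = nm[which(bad)[1]])
  }
  if (any(nchar(seqs) == 0L)) stop("empty sequence in FASTA record of ", path)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- nm
  out
}

# locate the first illegal character in a FASTA file and report its line
.fasta_char_error <- function(path, record) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) next
    up <- chartr("U", "T", toupper(ln))
    if (grepl("[^ACGTN]", up)) {
      ch <- regmatches(up, regexpr("[^ACGTN]", up))
      stop(sprintf("illegal character '%s' at line %d of %s", ch, i, path))
    }
  }
  stop("illegal character in FASTA record '", record, "' of ", path)
}

#' Write a FASTA file
#' @param x A [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @param width Line width.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

# ---------------------------------------------------------------------------
# GFF3

#' Read a GFF3 annotation file
#'
#' The nine mandatory columns are kept verbatim (as strings for
#' source/score/phase so that a read/write round trip is byte-stable);
#' coordinates are converted from 1-based inclusive to the internal 0-based
#' half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @return An `annotation_set`: a list with element `records`, a data.frame
#'   with columns `seqid, source, type, start, end, score, strand, phase,
#'   attributes` (`start`/`end` 0-based half-open).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0L) {
    rec <- data.frame(seqid = character(), source = character(),
                      type = character(), start = integer(), end = integer(),
                      score = character(), strand = character(),
                      phase = character(), attributes = character(),
                      stringsAsFactors = FALSE)
    return(annotation_set(rec))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 9L)) {
    stop("malformed GFF3 record (fewer than 9 columns) at data line ",
         which(nf < 9L)[1], " of ", path)
  }
  m <- do.call(rbind, lapply(parts, function(p) p[1:9]))
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start1) || anyNA(end1)) stop("non-numeric coordinates in ", path)
  if (any(end1 < start1)) {
    stop("GFF3 record with end < start at data line ", which(end1 < start1)[1],
         " of ", path)
  }
  rec <- data.frame(seqid = m[, 1], source = m[, 2], type = m[, 3],
                    start = start1 - 1L, end = end1, score = m[, 6],
                    strand = m[, 7], phase = m[, 8], attributes = m[, 9],
                    stringsAsFactors = FALSE)
  annotation_set(rec)
}

#' Construct an annotation set
#'
#' @param records data.frame with columns `seqid, source, type, start, end,
#'   score, strand, phase, attributes`; coordinates 0-based half-open.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(records) {
  needed <- c("seqid", "source", "type", "start", "end", "score", "strand",
              "phase", "attributes")
  miss <- setdiff(needed, names(records))
  if (length(miss)) stop("annotation records missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(records$end < records$start)) stop("annotation with end < start")
  if (!all(records$strand %in% c("+", "-", "."))) {
    stop("annotation strand outside {+,-,.}")
  }
  structure(list(records = records[, needed, drop = FALSE]),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set with", nrow(x$records), "records on",
      length(unique(x$records$seqid)), "contigs\n")
  invisible(x)
}

#' @export
length.annotation_set <- function(x) nrow(x$records)

#' Write an annotation set as GFF3
#' @param set An `annotation_set`.
#' @param path Output path.
#' @export
write_gff3 <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  r <- set$records
  lines <- c("##gff-version 3",
             if (nrow(r)) paste(r$seqid, r$source, r$type, r$start + 1L, r$end,
                                r$score, r$strand, r$phase, r$attributes,
                                sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Overlap query on an annotation set
#'
#' Returns indices of records overlapping the query interval, computed with
#' an interval index ([GenomicRanges::findOverlaps]) rather than a linear
#' scan.
#'
#' @param set An `annotation_set`.
#' @param contig Contig name.
#' @param start,end Query interval, 0-based half-open.
#' @return Integer vector of row indices into `set$records`.
#' @export
annotation_overlaps <- function(set, contig, start, end) {
  stopifnot(inherits(set, "annotation_set"), end > start)
  r <- set$records
  if (nrow(r) == 0L) return(integer())
  gr <- GenomicRanges::GRanges(r$seqid,
                               IRanges::IRanges(r$start + 1L, r$end))
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(start + 1L, end))
  suppressWarnings(
    S4Vectors::queryHits(GenomicRanges::findOverlaps(gr, q))
  )
}

# ---------------------------------------------------------------------------
# Coverage tracks

#' Construct a coverage track
#'
#' @param values Named list of per-contig numeric vectors (one value per bin).
#' @param bin_size Bin size in bp.
#' @param normalization One of `"raw"`, `"RPKM"`, `"ratio"`.
#' @param molecule One of `"sRNA"`, `"mRNA"`.
#' @param condition Free-text condition label.
#' @param contig_lengths Optional named integer vector of contig lengths; when
#'   supplied, `length(values[[c]]) == ceiling(len/bin_size)` is enforced.
#' @return A `coverage_track`.
#' @export
coverage_track <- function(values, bin_size, normalization = "raw",
                           molecule = "mRNA", condition = "unknown",
                           contig_lengths = NULL) {
  stopifnot(is.list(values), !is.null(names(values)), bin_size >= 1)
  for (v in values) {
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("coverage values must be finite and >= 0")
    }
  }
  if (!is.null(contig_lengths)) {
    for (cn in names(values)) {
      expected <- ceiling(contig_lengths[[cn]] / bin_size)
      if (length(values[[cn]]) != expected) {
        stop("bin count mismatch for contig ", cn)
      }
    }
  }
  structure(list(values = values, bin_size = as.integer(bin_size),
                 normalization = normalization, molecule = molecule,
                 condition = condition,
                 contig_lengths = contig_lengths),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track (%s, %s, %s): %d contigs, bin %d bp\n",
              x$molecule, x$condition, x$normalization,
              length(x$values), x$bin_size))
  invisible(x)
}

#' Read a bedGraph file into fixed-size bins
#'
#' Sparse 0-based half-open bedGraph intervals are rasterised onto fixed bins
#' by length-weighted contribution (a bin half-covered by density 4 receives
#' 2); positions without an interval contribute zero.  Overlapping input
#' intervals are rejected as an ambiguous density.
#'
#' @param path Path to a bedGraph file.
#' @param bin_size Bin size in bp.
#' @param contig_lengths Named integer vector giving the length of every
#'   contig the track should span.
#' @inheritParams coverage_track
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, bin_size, contig_lengths,
                          normalization = "raw", molecule = "mRNA",
                          condition = "unknown") {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  vals <- lapply(contig_lengths, function(L) numeric(ceiling(L / bin_size)))
  names(vals) <- names(contig_lengths)
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 4L)) stop("malformed bedGraph line in ", path)
    df <- data.frame(contig = vapply(parts, `[`, "", 1L),
                     start = as.integer(vapply(parts, `[`, "", 2L)),
                     end = as.integer(vapply(parts, `[`, "", 3L)),
                     value = as.numeric(vapply(parts, `[`, "", 4L)),
                     stringsAsFactors = FALSE)
    if (any(df$end <= df$start)) stop("bedGraph interval with end <= start")
    unknown <- setdiff(unique(df$contig), names(contig_lengths))
    if (length(unknown)) stop("bedGraph contig not in contig_lengths: ",
                              unknown[1])
    for (cn in unique(df$contig)) {
      d <- df[df$contig == cn, , drop = FALSE]
      d <- d[order(d$start), , drop = FALSE]
      if (nrow(d) > 1L && any(d$start[-1] < d$end[-nrow(d)])) {
        stop("overlapping bedGraph intervals on ", cn,
             " (ambiguous density)")
      }
      L <- contig_lengths[[cn]]
      if (any(d$end > L)) stop("bedGraph interval beyond contig end on ", cn)
      v <- vals[[cn]]
      nb <- length(v)
      widths <- pmin(seq_len(nb) * bin_size, L) - (seq_len(nb) - 1L) * bin_size
      for (r in seq_len(nrow(d))) {
        b0 <- d$start[r] %/% bin_size
        b1 <- (d$end[r] - 1L) %/% bin_size
        for (b in b0:b1) {
          ov <- min(d$end[r], (b + 1) * bin_size) - max(d$start[r], b * bin_size)
          v[b + 1L] <- v[b + 1L] + d$value[r] * ov / widths[b + 1L]
        }
      }
      vals[[cn]] <- v
    }
  }
  coverage_track(vals, bin_size, normalization, molecule, condition,
                 contig_lengths = contig_lengths)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal bin values are merged; zero bins are omitted.
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, "w")
  on.exit(close(con))
  bs <- track$bin_size
  for (cn in names(track$values)) {
    v <- track$values[[cn]]
    if (!length(v)) next
    L <- if (!is.null(track$contig_lengths)) track$contig_lengths[[cn]] else
      length(v) * bs
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    s <- starts_bin[keep] * bs
    e <- pmin(ends_bin[keep] * bs, L)
    writeLines(sprintf("%s\t%d\t%d\t%.17g", cn, s, e, r$values[keep]), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Mapped small-RNA reads

#' Read mapped reads from a TSV table or SAM file
#'
#' The TSV format has a header line `contig start end strand count` with
#' 0-based half-open coordinates.  SAM input uses the aligned reference span
#' (CIGAR operations M/D/N/=/X) and the 0x10 flag for strand; unmapped
#' records are skipped.  The 5' nucleotide of each read is derived from the
#' genome: for a minus-strand read it is the complement of the base at
#' `end - 1` (the biological 5' end).
#'
#' @param path Path to the read file.
#' @param genome Optional [Biostrings::DNAStringSet]; required to annotate
#'   5' nucleotides.
#' @param format `"auto"` (by extension), `"tsv"` or `"sam"`.
#' @return A `read_set` data.frame with columns `contig, start, end, strand,
#'   length, count` and, when a genome is given, `five_prime_nt`.
#' @export
read_reads <- function(path, genome = NULL, format = c("auto", "tsv", "sam")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  }
  if (format == "tsv") {
    df <- read.delim(path, header = TRUE, sep = "\t",
                     colClasses = c("character", "integer", "integer",
                                    "character", "integer"),
                     stringsAsFactors = FALSE)
    names(df) <- c("contig", "start", "end", "strand", "count")
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    flag <- as.integer(vapply(parts, `[`, "", 2L))
    rname <- vapply(parts, `[`, "", 3L)
    pos <- as.integer(vapply(parts, `[`, "", 4L))
    cigar <- vapply(parts, `[`, "", 6L)
    mapped <- !bitwAnd(flag, 4L) & rname != "*" & cigar != "*"
    rw <- vapply(cigar[mapped], cigar_ref_width, 0L)
    df <- data.frame(contig = rname[mapped], start = pos[mapped] - 1L,
                     end = pos[mapped] - 1L + rw,
                     strand = ifelse(bitwAnd(flag[mapped], 16L) > 0L, "-", "+"),
                     count = 1L, stringsAsFactors = FALSE)
  }
  validate_read_table(df, genome)
}

# reference-space width of a CIGAR string
cigar_ref_width <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (!length(ops)) stop("malformed CIGAR: ", cigar)
  len <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  sum(len[op %in% c("M", "D", "N", "=", "X")])
}

# shared validation + 5' annotation for read tables
validate_read_table <- function(df, genome = NULL) {
  if (!all(df$strand %in% c("+", "-"))) {
    stop("unknown strand symbol in read table: ",
         paste(unique(setdiff(df$strand, c("+", "-"))), collapse = ", "))
  }
  if (any(df$end <= df$start)) stop("read with end <= start")
  if (any(df$count < 1L)) stop("read with count < 1")
  df$length <- df$end - df$start
  if (!is.null(genome)) {
    df$five_prime_nt <- five_prime_base(df, genome)
  }
  class(df) <- c("read_set", "data.frame")
  df
}

# 5' base of each read (RNA alphabet: T reported as U)
five_prime_base <- function(df, genome) {
  out <- character(nrow(df))
  for (cn in unique(df$contig)) {
    idx <- which(df$contig == cn)
    chars <- strsplit(as.character(genome[[cn]]), "")[[1]]
    plus <- idx[df$strand[idx] == "+"]
    minus <- idx[df$strand[idx] == "-"]
    out[plus] <- chars[df$start[plus] + 1L]
    out[minus] <- chartr("ACGT", "TGCA", chars[df$end[minus]])
  }
  chartr("T", "U", out)
}

#' Write a read table TSV
#' @param reads A `read_set` data.frame.
#' @param path Output path.
#' @export
write_reads <- function(reads, path) {
  df <- reads[, c("contig", "start", "end", "strand", "count")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
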