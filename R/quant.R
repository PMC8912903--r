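# Relative-quantification arithmetic: delta-delta-Ct expression / copy
# number, and ChIP enrichment (target vs control product, IP over input).
# Amplification efficiency is fixed at 2 (no efficiency correction).

#' Read a Ct table
#'
#' TSV with header columns `sample, replicate, target, ct` and, for ChIP
#' tables, an additional `fraction` column with values `IP`/`input`.
#'
#' @param path Path to the TSV file.
#' @return A `ct_table` data.frame.
#' @export
read_ct_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  ct_table(df)
}

#' Construct/validate a Ct table
#' @param df data.frame with columns `sample, replicate, target, ct`
#'   (optionally `fraction`).
#' @return A `ct_table` data.frame.
#' @export
ct_table <- function(df) {
  needed <- c("sample", "replicate", "target", "ct")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("Ct table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(df$ct))) stop("non-finite Ct value")
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Relative quantity by the delta-delta-Ct method
#'
#' Per replicate, `dCt = Ct(target) - Ct(reference)`; the fold is
#' `2^-(dCt - mean dCt of the calibrator replicates)`, exponentiated per
#' replicate and summarised as mean and SD on the fold scale.  Identical
#' arithmetic serves expression (cDNA Ct) and copy number (genomic DNA Ct).
#'
#' @param ct A `ct_table`.
#' @param target Target product name.
#' @param reference Reference product (default `"his3"`).
#' @param calibrator Calibrator sample (default `"wild_type"`).
#' @param average_ddct If `TRUE`, average dCt across replicates before
#'   exponentiation instead (alternative convention).
#' @return data.frame `sample, mean_fold, sd_fold, n_replicates`.
#' @export
relative_quantity <- function(ct, target, reference = "his3",
                              calibrator = "wild_type",
                              average_ddct = FALSE) {
  stopifnot(inherits(ct, "ct_table"))
  d <- delta_ct(ct, target, reference)
  cal <- d$dct[d$sample == calibrator]
  if (!length(cal)) stop("calibrator sample '", calibrator,
                         "' absent from Ct table")
  cal_mean <- mean(cal)
  out <- lapply(split(d, d$sample), function(g) {
    ddct <- g$dct - cal_mean
    if (average_ddct) {
      data.frame(sample = g$sample[1], mean_fold = 2^(-mean(ddct)),
                 sd_fold = NA_real_, n_replicates = nrow(g),
                 stringsAsFactors = FALSE)
    } else {
      folds <- 2^(-ddct)
      data.frame(sample = g$sample[1], mean_fold = mean(folds),
                 sd_fold = if (length(folds) > 1) sd(folds) else NA_real_,
                 n_replicates = length(folds), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# per-(sample, replicate) dCt, with an error naming the offender when a
# reference row is missing
delta_ct <- function(ct, target, reference) {
  tg <- ct[ct$target == target, c("sample", "replicate", "ct")]
  rf <- ct[ct$target == reference, c("sample", "replicate", "ct")]
  if (!nrow(tg)) stop("target '", target, "' absent from Ct table")
  m <- merge(tg, rf, by = c("sample", "replicate"),
             suffixes = c("_target", "_ref"), all.x = TRUE)
  if (any(is.na(m$ct_ref))) {
    bad <- m[is.na(m$ct_ref), ][1, ]
    stop(sprintf("missing reference ('%s') Ct for sample '%s' replicate %s",
                 reference, bad$sample, bad$replicate))
  }
  data.frame(sample = m$sample, replicate = m$replicate,
             dct = m$ct_target - m$ct_ref, stringsAsFactors = FALSE)
}

#' ChIP enrichment relative to a control product
#'
#' `enrichment = 2^-(Ct_IP(target) - Ct_input(target)) /
#'               2^-(Ct_IP(control) - Ct_input(control))`
#' per sample and replicate, summarised as mean and SD.
#'
#' @param ct A `ct_table` with a `fraction` column (`IP`/`input`).
#' @param target Target product name.
#' @param control Control product (default `"his3"`).
#' @return data.frame `sample, mean_enrichment, sd_enrichment,
#'   n_replicates`.
#' @export
chip_enrichment <- function(ct, target, control = "his3") {
  stopifnot(inherits(ct, "ct_table"))
  if (!"fraction" %in% names(ct)) stop("ChIP Ct table needs a 'fraction' column")
  get_ct <- function(tg, fr) {
    x <- ct[ct$target == tg & ct$fraction == fr,
            c("sample", "replicate", "ct")]
    names(x)[3] <- paste(tg, fr, sep = "_")
    x
  }
  m <- Reduce(function(a, b) merge(a, b, by = c("sample", "replicate"),
                                   all = TRUE),
              list(get_ct(target, "IP"), get_ct(target, "input"),
                   get_ct(control, "IP"), get_ct(control, "input")))
  if (any(is.na(m[, 3:6]))) {
    bad <- m[!stats::complete.cases(m), ][1, ]
    stop(sprintf("missing IP/input Ct for sample '%s' replicate %s",
                 bad$sample, bad$replicate))
  }
  enr <- 2^-(m[[paste0(target, "_IP")]] - m[[paste0(target, "_input")]]) /
    2^-(m[[paste0(control, "_IP")]] - m[[paste0(control, "_input")]])
  per <- data.frame(sample = m$sample, replicate = m$replicate,
                    enrichment = enr, stringsAsFactors = FALSE)
  out <- lapply(split(per, per$sample), function(g) {
    data.frame(sample = g$sample[1], mean_enrichment = mean(g$enrichment),
               sd_enrichment = if (nrow(g) > 1) sd(g$enrichment) else NA_real_,
               n_replicates = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Ratio of a chromatin-mark enrichment to a histone-occupancy enrichment
#'
#' E.g. input-normalised H3K9me2 over input-normalised H3, optionally
#' renormalised to a calibrator sample.
#'
#' @param enrichment_mark,enrichment_histone Positive numeric vectors (named
#'   by sample when `calibrator` is used).
#' @param calibrator Optional sample name; when given, ratios are divided by
#'   the calibrator's ratio.
#' @return Numeric vector of ratios.
#' @export
normalized_mark_ratio <- function(enrichment_mark, enrichment_histone,
                                  calibrator = NULL) {
  if (any(enrichment_histone <= 0)) {
    stop("histone enrichment must be strictly positive")
  }
  if (any(enrichment_mark <= 0)) {
    stop("mark enrichment must be strictly positive")
  }
  ratio <- enrichment_mark / enrichment_histone
  if (!is.null(calibrator)) {
    if (!calibrator %in% names(ratio)) {
      stop("calibrator '", calibrator, "' not found among samples")
    }
    ratio <- ratio / ratio[[calibrator]]
  }
  ratio
}
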