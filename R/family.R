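# Family definition by pairwise identity over the reverse-transcriptase,
# RNase H and integrase domains (single-linkage at >95% identity), and
# lineage assignment via a neighbour-joining distance tree against
# reference elements.

CORE_DOMAINS <- c("reverse_transcriptase", "rnase_h", "integrase")

#' Construct a domain triplet
#'
#' @param id Element identifier.
#' @param reverse_transcriptase,rnase_h,integrase Nucleotide sequences of
#'   the respective domains (`NA`/`NULL` when absent).
#' @param contig,start Optional genomic position of the element (used for
#'   deterministic family numbering).
#' @param lineage Optional lineage tag (used for reference triplets).
#' @return A `domain_triplet`.
#' @export
domain_triplet <- function(id, reverse_transcriptase = NA,
                           rnase_h = NA, integrase = NA,
                           contig = NA, start = NA, lineage = NA) {
  doms <- list(reverse_transcriptase = reverse_transcriptase,
               rnase_h = rnase_h, integrase = integrase)
  doms <- lapply(doms, function(x) {
    if (is.null(x) || length(x) == 0L || is.na(x[1]) || !nzchar(x[1]))
      NA_character_ else toupper(as.character(x)[1])
  })
  structure(c(list(id = as.character(id)), doms,
              list(contig = contig, start = start,
                   lineage = as.character(lineage))),
            class = "domain_triplet")
}

n_shared_domains <- function(a, b) {
  sum(vapply(CORE_DOMAINS,
             function(d) !is.na(a[[d]]) && !is.na(b[[d]]), TRUE))
}

#' Pairwise identity between two domain triplets
#'
#' Each shared domain is globally aligned (match +1, mismatch -1, gap -2)
#' and identity is matches over aligned columns excluding terminal gaps; the
#' overall value is the column-count-weighted mean over shared domains.
#' Returns `NA` when the triplets share no domain (an undefined comparison,
#' not zero identity).
#'
#' @param a,b `domain_triplet`s.
#' @return Identity in `[0, 1]`, or `NA_real_`.
#' @export
pairwise_identity <- function(a, b) {
  matches <- 0; columns <- 0
  for (d in CORE_DOMAINS) {
    if (is.na(a[[d]]) || is.na(b[[d]])) next
    al <- nw_global_cpp(a[[d]], b[[d]], match = 1, mismatch = -1, gap = 2)
    matches <- matches + al$matches
    columns <- columns + al$columns
  }
  if (columns == 0) return(NA_real_)
  matches / columns
}

#' Cluster elements into families by domain identity
#'
#' Single-linkage transitive closure of the relation
#' `identity > threshold`, realised as `hclust(method = "single")` on
#' `1 - identity` cut strictly below `1 - threshold`.  Elements lacking all
#' three core domains are excluded (returned under `$excluded`); elements
#' sharing no domain with anything form singleton families.  Families are
#' numbered by the leftmost genomic coordinate of their representative (the
#' member with the largest total domain length), so the labelling is
#' invariant to input order.
#'
#' @param triplets List of `domain_triplet`s.
#' @param threshold Identity threshold (default 0.95; membership requires
#'   identity strictly greater).
#' @return A list of class `family_set`: `families` (data.frame `family,
#'   element_id, representative`), `membership` (named integer vector),
#'   `identity` (matrix), `excluded` (character).
#' @export
cluster_families <- function(triplets, threshold = 0.95) {
  has_core <- vapply(triplets, function(t) {
    any(!is.na(unlist(t[CORE_DOMAINS])))
  }, TRUE)
  excluded <- vapply(triplets[!has_core], `[[`, "", "id")
  triplets <- triplets[has_core]
  n <- length(triplets)
  if (n == 0L) stop("no clusterable elements (all lack core domains)")
  ids <- vapply(triplets, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate element ids")
  # order-canonical processing
  ord <- order(ids, method = "radix")
  triplets <- triplets[ord]; ids <- ids[ord]
  I <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(I) <- 1
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      I[i, j] <- I[j, i] <- pairwise_identity(triplets[[i]], triplets[[j]])
    }
  }
  D <- 1 - I
  D[is.na(D)] <- 2   # incomparable pairs can never link
  comp <- if (n == 1) 1L else {
    tree <- hclust(as.dist(D), method = "single")
    cutree(tree, h = (1 - threshold) - 1e-9)
  }
  # representative = largest total domain length; ties by id
  dom_len <- vapply(triplets, function(t) {
    sum(nchar(unlist(t[CORE_DOMAINS])[!is.na(unlist(t[CORE_DOMAINS]))]))
  }, 0)
  reps <- vapply(split(seq_len(n), comp), function(ix) {
    ix[order(-dom_len[ix], ids[ix])][1]
  }, 0L)
  # number families by representative genomic position, else by id
  rep_contig <- vapply(triplets[reps], function(t) as.character(t$contig), "")
  rep_start <- vapply(triplets[reps], function(t) {
    s <- suppressWarnings(as.numeric(t$start)); if (is.na(s)) Inf else s
  }, 0.0)
  fam_order <- order(rep_contig, rep_start, ids[reps], method = "radix")
  fam_label <- integer(length(reps))
  fam_label[fam_order] <- seq_along(reps)
  membership <- setNames(fam_label[comp], ids)
  families <- data.frame(
    family = sprintf("Tj%d", membership),
    element_id = ids,
    representative = ids[reps][match(membership, fam_label)],
    stringsAsFactors = FALSE)
  families <- families[order(membership, families$element_id,
                             method = "radix"), , drop = FALSE]
  rownames(families) <- NULL
  structure(list(families = families, membership = membership,
                 identity = I, excluded = excluded,
                 representatives = setNames(ids[reps][order(fam_label)],
                                            sprintf("Tj%d", sort(fam_label))),
                 triplets = setNames(triplets, ids)),
            class = "family_set")
}

#' @export
print.family_set <- function(x, ...) {
  cat("family_set:", length(unique(x$families$family)), "families over",
      nrow(x$families), "elements;", length(x$excluded), "excluded\n")
  invisible(x)
}

#' Assign families to reference lineages via a neighbour-joining tree
#'
#' Distances are `1 - pairwise_identity` between family representatives and
#' reference triplets; the tree is built with [ape::nj()] and each family is
#' labelled with the lineage of its nearest reference by patristic distance.
#'
#' @param fams A `family_set` from [cluster_families()].
#' @param references List of `domain_triplet`s carrying a `lineage` tag.
#' @return A list of class `lineage_tree`: `tree` ([ape::phylo]), `newick`
#'   (string), `lineages` (named character, one per family; `NA` with a
#'   warning for incomparable families).
#' @export
assign_lineages <- function(fams, references) {
  stopifnot(inherits(fams, "family_set"), length(references) >= 2)
  rep_ids <- fams$representatives
  fam_names <- names(rep_ids)
  taxa <- c(lapply(rep_ids, function(id) fams$triplets[[id]]), references)
  labels <- c(fam_names, vapply(references, `[[`, "", "id"))
  if (anyDuplicated(labels)) stop("duplicate taxon labels in lineage tree")
  n <- length(taxa)
  D <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  diag(D) <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    id <- pairwise_identity(taxa[[i]], taxa[[j]])
    D[i, j] <- D[j, i] <- if (is.na(id)) NA_real_ else 1 - id
  }
  incomparable <- fam_names[vapply(seq_along(fam_names), function(i) {
    all(is.na(D[i, length(fam_names) + seq_along(references)]))
  }, TRUE)]
  if (length(incomparable)) {
    warning("families incomparable with all references left unlabeled: ",
            paste(incomparable, collapse = ", "))
  }
  Dfill <- D
  Dfill[is.na(Dfill)] <- max(D, na.rm = TRUE) * 2
  tree <- ape::nj(as.dist(Dfill))
  pat <- ape::cophenetic.phylo(tree)
  ref_lineage <- setNames(vapply(references, `[[`, "", "lineage"),
                          vapply(references, `[[`, "", "id"))
  lineages <- setNames(rep(NA_character_, length(fam_names)), fam_names)
  for (f in setdiff(fam_names, incomparable)) {
    dref <- pat[f, names(ref_lineage)]
    lineages[f] <- ref_lineage[[names(which.min(dref))]]
  }
  structure(list(tree = tree, newick = ape::write.tree(tree),
                 lineages = lineages),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("lineage_tree over", length(x$tree$tip.label), "taxa\n")
  print(x$lineages)
  invisible(x)
}

#' Load the bundled synthetic reference triplets
#'
#' Reads the synthetic lineage reference elements shipped under
#' `inst/extdata/synthetic_references/` (stand-ins for the Tf1/Tf2- and
#' Ty3-type reference domains).  File naming:
#' `synthetic_ref_<lineage>_<n>.fa`, records named by domain.
#'
#' @param dir Directory of reference FASTA files.
#' @return List of `domain_triplet`s with `lineage` set.
#' @export
load_reference_triplets <- function(dir = system.file(
                                      "extdata", "synthetic_references",
                                      package = "retroscout")) {
  files <- sort_c(list.files(dir, pattern = "^synthetic_ref_.*\\.fa$",
                             full.names = TRUE))
  if (!length(files)) stop("no reference triplets found in ", dir)
  lapply(files, function(f) {
    base <- sub("\\.fa$", "", sub("^synthetic_ref_", "", basename(f)))
    lineage <- sub("_[0-9]+$", "", base)
    x <- Biostrings::readDNAStringSet(f)
    seqs <- as.character(x)
    domain_triplet(id = base,
                   reverse_transcriptase = seqs[["reverse_transcriptase"]],
                   rnase_h = seqs[["rnase_h"]],
                   integrase = seqs[["integrase"]],
                   lineage = lineage)
  })
}
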