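# Core-gene quantification of metagenomic species (MGS).
#
# An MGS is a cluster of co-abundant catalog genes quantified through a
# designated set of "core" genes. The MGS count for a sample is the sum of
# read-pair counts over its core genes, zeroed unless read pairs hit at
# least `min_core_hits` distinct core genes.

#' MGS counts from per-sample gene counts
#'
#' @param gene_counts Named integer vector (one sample) or a samples x genes
#'   matrix with gene ids as column names.
#' @param catalog Gene catalog data frame from [generate_catalog()] (columns
#'   `gene_id`, `length_bp`, `mgs_id`, `is_core`).
#' @param min_core_hits Minimum number of distinct core genes with nonzero
#'   counts for an MGS to be called detected (default 3). Undetected MGS
#'   counts are set to zero.
#' @param unknown_genes `"error"` (default) to fail on gene ids absent from
#'   the catalog, `"ignore"` to drop them with a message.
#' @return List with `counts` (samples x MGS integer matrix) and `detected`
#'   (logical matrix of the same shape).
#' @examples
#' cat <- generate_catalog(n_mgs = 2, k_core = 3, seed = 1)
#' counts <- setNames(rep(1L, 3), cat$gene_id[1:3])
#' mgs_counts(counts, cat)$counts
#' @export
mgs_counts <- function(gene_counts, catalog, min_core_hits = 3,
                       unknown_genes = c("error", "ignore")) {
  unknown_genes <- match.arg(unknown_genes)
  if (is.null(dim(gene_counts))) {
    gene_counts <- matrix(gene_counts, nrow = 1,
                          dimnames = list("sample1", names(gene_counts)))
  }
  genes <- colnames(gene_counts)
  if (is.null(genes)) stop("gene_counts must carry gene ids as names")
  unknown <- setdiff(genes, catalog$gene_id)
  if (length(unknown)) {
    if (unknown_genes == "error") {
      stop("gene ids absent from catalog: ", paste(head(unknown, 5), collapse = ", "))
    }
    message("ignoring ", length(unknown), " gene ids absent from the catalog")
    gene_counts <- gene_counts[, !genes %in% unknown, drop = FALSE]
    genes <- colnames(gene_counts)
  }
  core <- catalog[catalog$is_core & !is.na(catalog$mgs_id), , drop = FALSE]
  mgs_ids <- sort(unique(catalog$mgs_id[!is.na(catalog$mgs_id)]))
  n_samp <- nrow(gene_counts)
  counts <- matrix(0L, n_samp, length(mgs_ids),
                   dimnames = list(rownames(gene_counts), mgs_ids))
  detected <- matrix(FALSE, n_samp, length(mgs_ids),
                     dimnames = dimnames(counts))
  idx <- match(core$gene_id, genes)  # NA for core genes with no counts column
  for (m in seq_along(mgs_ids)) {
    ci <- idx[core$mgs_id == mgs_ids[m]]
    ci <- ci[!is.na(ci)]
    if (length(ci) == 0L) next
    sub <- gene_counts[, ci, drop = FALSE]
    hits <- rowSums(sub > 0)
    tot <- as.integer(rowSums(sub))
    det <- hits >= min_core_hits
    counts[, m] <- ifelse(det, tot, 0L)
    detected[, m] <- det
  }
  list(counts = counts, detected = detected)
}

#' Length-normalized relative MGS abundances
#'
#' Divides each MGS count by the total length (in kb) of its core genes and
#' renormalizes each sample to sum to one over all MGSs. Samples with no
#' detected MGS yield an all-zero row with a warning.
#'
#' @param counts Samples x MGS count matrix, or the list returned by
#'   [mgs_counts()].
#' @param catalog Gene catalog data frame.
#' @return Samples x MGS matrix of relative abundances (rows sum to 1).
#' @export
relative_abundance <- function(counts, catalog) {
  if (is.list(counts) && !is.null(counts$counts)) counts <- counts$counts
  core <- catalog[catalog$is_core & !is.na(catalog$mgs_id), , drop = FALSE]
  len_kb <- tapply(core$length_bp, core$mgs_id, sum) / 1000
  mgs_ids <- colnames(counts)
  miss <- setdiff(mgs_ids, names(len_kb))
  if (length(miss)) stop("catalog lacks core genes for MGS: ",
                         paste(head(miss, 5), collapse = ", "))
  ab <- sweep(counts, 2, as.numeric(len_kb[mgs_ids]), "/")
  tot <- rowSums(ab)
  empty <- tot <= 0
  if (any(empty)) {
    warning(sum(empty), " sample(s) with no detected MGS; returning zero rows")
    tot[empty] <- 1
  }
  ab / tot
}

#' One-call MGS profile from gene counts
#'
#' Convenience wrapper: [mgs_counts()] followed by length normalization.
#' `method = "total_length"` (default) divides each MGS core-count sum by the
#' MGS's total core-gene length; `method = "per_gene"` sums count/length over
#' the core genes before the detection rule zeroes undetected MGSs.
#'
#' @inheritParams mgs_counts
#' @param method Length-normalization variant, see Details.
#' @return Samples x MGS relative-abundance matrix.
#' @export
mgs_profile <- function(gene_counts, catalog, min_core_hits = 3,
                        method = c("total_length", "per_gene")) {
  method <- match.arg(method)
  mc <- mgs_counts(gene_counts, catalog, min_core_hits = min_core_hits)
  if (method == "total_length") return(relative_abundance(mc, catalog))
  # per-gene variant: sum of length-normalized gene counts over core genes
  if (is.null(dim(gene_counts))) {
    gene_counts <- matrix(gene_counts, nrow = 1,
                          dimnames = list("sample1", names(gene_counts)))
  }
  core <- catalog[catalog$is_core & !is.na(catalog$mgs_id), , drop = FALSE]
  mgs_ids <- colnames(mc$counts)
  ab <- matrix(0, nrow(gene_counts), length(mgs_ids),
               dimnames = list(rownames(gene_counts), mgs_ids))
  idx <- match(core$gene_id, colnames(gene_counts))
  for (m in seq_along(mgs_ids)) {
    sel <- core$mgs_id == mgs_ids[m] & !is.na(idx)
    if (!any(sel)) next
    w <- 1000 / core$length_bp[sel]
    ab[, m] <- as.numeric(gene_counts[, idx[sel], drop = FALSE] %*% w)
  }
  ab[!mc$detected] <- 0
  tot <- rowSums(ab)
  tot[tot <= 0] <- 1
  ab / tot
}

#' Rarefy a count table to a fixed depth
#'
#' Subsamples each sample's read pairs without replacement (multivariate
#' hypergeometric) to exactly `depth` pairs. Samples whose total is below
#' `depth` are dropped with a warning.
#'
#' @param counts Samples x features count matrix, or a named vector for a
#'   single sample.
#' @param depth Target depth in read pairs (positive integer).
#' @param seed Optional integer seed for reproducibility.
#' @return Rarefied count matrix with every retained row summing to `depth`.
#' @export
rarefy_counts <- function(counts, depth, seed = NULL) {
  if (depth <= 0) stop("`depth` must be positive")
  if (is.null(dim(counts))) {
    counts <- matrix(counts, nrow = 1,
                     dimnames = list("sample1", names(counts)))
  }
  tot <- rowSums(counts)
  low <- tot < depth
  if (any(low)) {
    warning(sum(low), " sample(s) below depth ", depth, " dropped: ",
            paste(head(rownames(counts)[low], 5), collapse = ", "))
    counts <- counts[!low, , drop = FALSE]
  }
  with_seed_(seed, {
    out <- counts
    for (i in seq_len(nrow(counts))) {
      out[i, ] <- hyper_subsample(as.numeric(counts[i, ]), depth)
    }
    storage.mode(out) <- "integer"
    out
  })
}

#' @rdname rarefy_counts
#' @export
rarefy_gene_counts <- rarefy_counts

# Sequential multivariate hypergeometric draw: for each cell, draw the number
# of retained pairs from the remaining pool. Exact and O(#features) memory.
hyper_subsample <- function(x, depth) {
  remaining <- sum(x)
  take <- depth
  out <- numeric(length(x))
  for (j in seq_along(x)) {
    if (take == 0) break
    remaining <- remaining - x[j]
    out[j] <- rhyper(1, x[j], remaining, take)
    take <- take - out[j]
  }
  out
}
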