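# Functional-potential analysis: aggregate gene counts to KEGG orthology
# (KO) and module abundances, filter modules by cohort prevalence, and run
# the pathway association battery.

#' Aggregate gene counts to KO abundances
#'
#' Sums counts of all genes mapped to each KO (genes without a KO are
#' dropped), then closes each sample to relative abundance.
#'
#' @param gene_counts Named vector (one sample) or samples x genes matrix
#'   with gene ids as column names.
#' @param gene_to_ko Two-column data frame `gene_id`, `ko`.
#' @return List with `counts` (samples x KO) and `abundance` (row-closed).
#' @export
aggregate_ko <- function(gene_counts, gene_to_ko) {
  if (is.null(dim(gene_counts))) {
    gene_counts <- matrix(gene_counts, nrow = 1,
                          dimnames = list("sample1", names(gene_counts)))
  }
  ko <- gene_to_ko$ko[match(colnames(gene_counts), gene_to_ko$gene_id)]
  keep <- !is.na(ko)
  kos <- sort(unique(ko[keep]))
  sub <- gene_counts[, keep, drop = FALSE]
  grp <- factor(ko[keep], levels = kos)
  counts <- t(rowsum(t(sub), group = grp))  # column-group sums per KO
  dimnames(counts) <- list(rownames(gene_counts), kos)
  tot <- rowSums(counts)
  tot[tot <= 0] <- 1
  list(counts = counts, abundance = counts / tot)
}

#' Aggregate KO abundances to KEGG-module abundances
#'
#' Module abundance is the sum of its member KOs' abundances. A KO
#' belonging to several modules contributes to each (`multi = "all"`,
#' default) or only to its first listed module (`multi = "first"`).
#' Per-module prevalence (fraction of samples with nonzero abundance) is
#' computed alongside.
#'
#' @param ko_abundance Samples x KO abundance matrix (e.g.
#'   `aggregate_ko(...)$abundance`).
#' @param ko_to_module Two-column data frame `ko`, `module`.
#' @param multi Multi-module KO handling, `"all"` or `"first"`.
#' @return List with `abundance` (samples x module) and `prevalence`
#'   (named vector in \[0, 1\]).
#' @export
aggregate_module <- function(ko_abundance, ko_to_module,
                             multi = c("all", "first")) {
  multi <- match.arg(multi)
  map <- ko_to_module
  if (multi == "first") map <- map[!duplicated(map$ko), , drop = FALSE]
  map <- map[map$ko %in% colnames(ko_abundance), , drop = FALSE]
  mods <- sort(unique(map$module))
  ab <- matrix(0, nrow(ko_abundance), length(mods),
               dimnames = list(rownames(ko_abundance), mods))
  for (m in mods) {
    member <- map$ko[map$module == m]
    ab[, m] <- rowSums(ko_abundance[, member, drop = FALSE])
  }
  list(abundance = ab, prevalence = colMeans(ab > 0))
}

#' Prevalence filter for pathway modules
#'
#' Retains modules observed (nonzero) in strictly more than `threshold` of
#' the samples.
#'
#' @param modules List from [aggregate_module()].
#' @param threshold Prevalence threshold (default 0.40, strict inequality).
#' @return Filtered list (`abundance`, `prevalence`) plus `n_retained` and
#'   `n_total`.
#' @export
prevalence_filter <- function(modules, threshold = 0.40) {
  keep <- modules$prevalence > threshold
  list(abundance = modules$abundance[, keep, drop = FALSE],
       prevalence = modules$prevalence[keep],
       n_retained = sum(keep), n_total = length(keep))
}

#' Pathway association battery
#'
#' For every retained module: Spearman correlation of its abundance with
#' the diet-quality score, and a rank-sum (Mann-Whitney/Wilcoxon) test
#' between the two BMI groups; Benjamini-Hochberg correction within each
#' of the two families.
#'
#' @param modules Filtered list from [prevalence_filter()] (or an
#'   abundance matrix).
#' @param idq_scores Numeric IDQ score per sample.
#' @param bmi_groups Two-level group labels per sample.
#' @return Data frame: `module`, `test` (`"idq_spearman"` or
#'   `"bmi_wilcoxon"`), `statistic`, `p_raw`, `p_adj`, `family_size`,
#'   `tier`.
#' @export
pathway_associations <- function(modules, idq_scores, bmi_groups) {
  ab <- if (is.list(modules)) modules$abundance else modules
  mods <- colnames(ab)
  lev <- unique(as.character(bmi_groups))
  if (length(lev) != 2) stop("`bmi_groups` must have exactly two levels")
  idq <- do.call(rbind, lapply(mods, function(m) {
    st <- spearman_test(ab[, m], idq_scores)
    data.frame(module = m, test = "idq_spearman", statistic = st$rho,
               p_raw = st$p_value, stringsAsFactors = FALSE)
  }))
  bmi <- do.call(rbind, lapply(mods, function(m) {
    mw <- mann_whitney_test(ab[bmi_groups == lev[1], m],
                            ab[bmi_groups == lev[2], m])
    data.frame(module = m, test = "bmi_wilcoxon", statistic = mw$u,
               p_raw = mw$p_value, stringsAsFactors = FALSE)
  }))
  idq$p_adj <- adjust_family(idq$p_raw, "bh")
  bmi$p_adj <- adjust_family(bmi$p_raw, "bh")
  res <- rbind(idq, bmi)
  res$family_size <- length(mods)
  res$tier <- tier_(res$p_adj)
  res
}
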