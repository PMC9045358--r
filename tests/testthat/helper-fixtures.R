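# Shared fixtures and independent oracles, built in code.

# A record that passes every mapping filter with room to spare.
perfect_record <- function() {
  data.frame(mapq_mate1 = 60L, mapq_mate2 = 60L, aligned_len_bp = 140L,
             identity_pct = 99, overhang5 = 0L, overhang3 = 0L,
             n_candidate_genes = 1L, stringsAsFactors = FALSE)
}

# 24 alignment records exercising every accept/reject boundary, with the
# hand-derived expected accept vector.
boundary_records <- function() {
  base <- perfect_record()
  mk <- function(...) {
    r <- base
    args <- list(...)
    for (nm in names(args)) r[[nm]] <- args[[nm]]
    r
  }
  recs <- rbind(
    mk(),                                                    #  1 perfect
    mk(mapq_mate1 = 19L),                                    #  2 mate1 below
    mk(mapq_mate1 = 20L),                                    #  3 mate1 at bound
    mk(mapq_mate2 = 19L),                                    #  4 mate2 below
    mk(mapq_mate1 = 20L, mapq_mate2 = 20L),                  #  5 both at bound
    mk(aligned_len_bp = 99L),                                #  6 length below
    mk(aligned_len_bp = 100L),                               #  7 length at bound
    mk(identity_pct = 94.9),                                 #  8 identity below
    mk(identity_pct = 95.0),                                 #  9 identity at bound
    mk(overhang5 = 10L),                                     # 10 5' at bound
    mk(overhang5 = 11L),                                     # 11 5' over
    mk(overhang3 = 10L),                                     # 12 3' at bound
    mk(overhang3 = 11L),                                     # 13 3' over
    mk(n_candidate_genes = 2L),                              # 14 multi-gene
    mk(mapq_mate1 = 20L, mapq_mate2 = 20L, aligned_len_bp = 100L,
       identity_pct = 95.0, overhang5 = 10L, overhang3 = 10L), # 15 all bounds
    mk(mapq_mate1 = 19L, aligned_len_bp = 100L, identity_pct = 95.0),  # 16
    mk(aligned_len_bp = 99L, identity_pct = 99),             # 17
    mk(identity_pct = 90),                                   # 18
    mk(overhang3 = 15L),                                     # 19
    mk(mapq_mate1 = 0L),                                     # 20
    mk(aligned_len_bp = 150L, identity_pct = 100),           # 21
    mk(n_candidate_genes = 3L),                              # 22
    mk(overhang5 = 20L),                                     # 23
    mk(mapq_mate1 = 20L, mapq_mate2 = 20L, aligned_len_bp = 100L,
       identity_pct = 95.0, overhang5 = 10L)                 # 24
  )
  expected <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE,
                TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                FALSE, FALSE, TRUE, FALSE, FALSE, TRUE)
  list(records = recs, expected = expected)
}

# Brute-force per-MGS oracle for core-gene counting and the detection rule.
mgs_counts_oracle <- function(gene_counts, catalog, min_core_hits = 3) {
  mgs_ids <- sort(unique(catalog$mgs_id[!is.na(catalog$mgs_id)]))
  out <- setNames(integer(length(mgs_ids)), mgs_ids)
  for (m in mgs_ids) {
    total <- 0L
    hit_genes <- 0L
    for (g in catalog$gene_id[!is.na(catalog$mgs_id) & catalog$mgs_id == m &
                              catalog$is_core]) {
      cnt <- if (g %in% names(gene_counts)) gene_counts[[g]] else 0L
      total <- total + cnt
      if (cnt > 0) hit_genes <- hit_genes + 1L
    }
    out[m] <- if (hit_genes >= min_core_hits) total else 0L
  }
  out
}

# All permutations of 1..n, generated independently of the package
# (filtering tuples), for the exhaustive PERMANOVA oracle. n <= 6.
perms_by_filter <- function(n) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  grid[apply(grid, 1, function(r) length(unique(r)) == n), , drop = FALSE]
}

# Direct pseudo-F from a distance matrix and covariate via explicit
# projection matrices (independent of the package's trace shortcut).
pseudo_f_oracle <- function(d, covariate) {
  d <- as.matrix(d)
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (d^2) %*% J
  X <- cbind(1, covariate)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  ssm <- sum(diag(H %*% G %*% H))
  ssr <- sum(diag((diag(n) - H) %*% G %*% (diag(n) - H)))
  list(f = ssm / (ssr / (n - 2)), r2 = ssm / sum(diag(G)))
}

# Definitional multiple-testing oracles.
bonferroni_oracle <- function(p) pmin(1, length(p) * p)
bh_oracle <- function(p) {
  k <- length(p)
  o <- order(p)
  adj <- p[o] * k / seq_len(k)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(k)
  out[o] <- pmin(1, adj)
  out
}

# Small cohort + microbiome replicate for battery-level tests.
simulate_small_dataset <- function(seed, n_ow = 30, n_ob = 20, n_mgs = 60,
                                   effects = effect_registry_default(),
                                   depth = 5e4) {
  co <- generate_cohort(n_ow, n_ob, effects = effects, seed = seed)
  prof <- generate_profiles(co, n_mgs = n_mgs, richness_center = 40,
                            richness_sd = 8, shannon_center = 2.5,
                            shannon_sd = 0.25, n_dominant = 25,
                            seed = seed + 1)
  cnt <- generate_mgs_counts(prof, mean_depth = depth * 1.5, depth_cv = 0.1,
                             min_depth = depth, seed = seed + 2)
  rare <- rarefy_counts(cnt, depth, seed = seed + 3)
  list(cohort = co$cohort, truth = co$truth, profiles = prof,
       counts = cnt, rarefied = rare, diversity = alpha_diversity(rare))
}
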