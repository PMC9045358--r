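# Univariate association battery: Spearman correlations, Mann-Whitney
# contrasts (diversity quartiles, BMI groups, IDQ dichotomy), serum-marker
# derivations, and a simplified negative-binomial differential-abundance
# test for taxa against a continuous covariate.

#' Spearman rank correlation with p-value
#'
#' Midranks for ties; exact p by enumeration for n <= 9 without ties,
#' otherwise the t-approximation. Pairs with missing values are dropped
#' listwise.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `rho`, `p_value`, `n`. `rho` is `NA` (with a warning)
#'   when either vector is constant.
#' @export
spearman_test <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = (n <= 9 && !ties)))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Mann-Whitney U test
#'
#' Midranks for ties. The U statistic counts pairs where a value from `a`
#' exceeds one from `b` (ties count half). Exact enumeration is used for
#' `length(a) + length(b) <= 12` without ties, otherwise the normal
#' approximation with tie correction (no continuity correction).
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return List with `u`, `p_value`, `n_a`, `n_b`.
#' @export
mann_whitney_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  small <- length(a) + length(b) <= 12
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = (small && !ties), correct = FALSE))
  list(u = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(a), n_b = length(b))
}

#' Dichotomize a diet-quality (IDQ) score
#'
#' Poor diet quality below 10 points (of the 15-point maximum), good at 10
#' or more.
#'
#' @param score Numeric IDQ scores in \[0, 15\].
#' @return Factor with levels `poor`, `good`.
#' @export
dichotomize_idq <- function(score) {
  if (any(score < 0 | score > 15, na.rm = TRUE)) {
    stop("IDQ scores must lie in [0, 15]")
  }
  factor(ifelse(score < 10, "poor", "good"), levels = c("poor", "good"))
}

#' Quantitative insulin sensitivity check index (QUICKI)
#'
#' `1 / (log10(insulin) + log10(glucose))` with fasting insulin in mU/l
#' (equivalently uU/ml) and fasting glucose converted from mmol/l to mg/dl
#' (x 18.016), the unit convention under which the index takes its familiar
#' 0.3-0.4 range.
#'
#' @param insulin_mU_per_l Fasting insulin, mU/l (> 0).
#' @param glucose_mmol_per_l Fasting glucose, mmol/l (> 0).
#' @return Numeric QUICKI values; inputs making the denominator
#'   non-positive raise an error.
#' @examples
#' quicki(10, 5.0)  # ~0.338
#' @export
quicki <- function(insulin_mU_per_l, glucose_mmol_per_l) {
  if (any(insulin_mU_per_l <= 0) || any(glucose_mmol_per_l <= 0)) {
    stop("insulin and glucose must be positive")
  }
  den <- log10(insulin_mU_per_l) + log10(glucose_mmol_per_l * 18.016)
  if (any(den <= 0)) stop("invalid arguments: QUICKI denominator <= 0")
  1 / den
}

tier_ <- function(p_adj) {
  ifelse(p_adj < 0.05, "significant",
         ifelse(p_adj < 0.1, "borderline", "ns"))
}

#' Quartile contrast of serum markers (lowest vs highest diversity quartile)
#'
#' For every marker and stratum, compares marker values between the lowest
#' (Q1) and highest (Q4) quartile of a diversity index with the
#' Mann-Whitney U test; p-values are corrected within each stratum family.
#'
#' @param cohort Cohort data frame (see [generate_cohort()]).
#' @param quartiles Factor of `Q1`..`Q4` labels, one per cohort row (from
#'   [quartile_groups()], computed per stratum by the caller or on all
#'   subjects).
#' @param markers Marker column names (default the six serum markers).
#' @param stratum Character vector of stratum labels per row, or `NULL` to
#'   analyze all subjects as one stratum.
#' @param method Family correction method (default `"bh"`).
#' @return Data frame: one row per marker x stratum with Q1/Q4 medians and
#'   IQRs, `u`, `p_raw`, `p_adj`, `tier`.
#' @export
quartile_contrast <- function(cohort, quartiles,
                              markers = c("insulin", "glucose", "homa2_ir",
                                          "quicki", "hscrp", "glyca"),
                              stratum = NULL, method = "bh") {
  if (is.null(stratum)) stratum <- rep("all", nrow(cohort))
  out <- list()
  for (s in unique(stratum)) {
    rows <- lapply(markers, function(m) {
      in_s <- stratum == s
      q1 <- cohort[[m]][in_s & quartiles == "Q1"]
      q4 <- cohort[[m]][in_s & quartiles == "Q4"]
      if (length(q1) == 0 || length(q4) == 0) {
        stop("empty quartile group for ", m, " in stratum ", s)
      }
      mw <- mann_whitney_test(q1, q4)
      data.frame(stratum = s, marker = m,
                 q1_n = length(q1), q4_n = length(q4),
                 q1_median = median(q1),
                 q1_iqr_lo = unname(quantile(q1, 0.25)),
                 q1_iqr_hi = unname(quantile(q1, 0.75)),
                 q4_median = median(q4),
                 q4_iqr_lo = unname(quantile(q4, 0.25)),
                 q4_iqr_hi = unname(quantile(q4, 0.75)),
                 u = mw$u, p_raw = mw$p_value,
                 stringsAsFactors = FALSE)
    })
    fam <- do.call(rbind, rows)
    fam$p_adj <- adjust_family(fam$p_raw, method)
    fam$method <- method
    out[[s]] <- fam
  }
  res <- do.call(rbind, out)
  res$tier <- tier_(res$p_adj)
  rownames(res) <- NULL
  res
}

#' Per-taxon group comparison of relative abundances
#'
#' Mann-Whitney test of every taxon's relative abundance between two
#' groups, Benjamini-Hochberg corrected over the taxon family.
#'
#' @param abundance Samples x taxa relative-abundance matrix.
#' @param group Two-level factor or character vector, one per sample.
#' @param method Correction method (default `"bh"`).
#' @return Data frame: `taxon`, `u`, `p_raw`, `p_adj`, `tier`.
#' @export
group_compare_taxa <- function(abundance, group, method = "bh") {
  lev <- unique(as.character(group))
  if (length(lev) != 2) stop("`group` must have exactly two levels")
  res <- do.call(rbind, lapply(colnames(abundance), function(tx) {
    mw <- mann_whitney_test(abundance[group == lev[1], tx],
                            abundance[group == lev[2], tx])
    data.frame(taxon = tx, u = mw$u, p_raw = mw$p_value,
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- adjust_family(res$p_raw, method)
  res$tier <- tier_(res$p_adj)
  res
}

#' Median-of-ratios size factors
#'
#' For each sample, the median across reference taxa (those with strictly
#' positive counts in every sample) of the ratio between the sample's count
#' and the taxon's geometric mean.
#'
#' @param counts Samples x taxa integer count matrix.
#' @return Numeric size-factor vector (one per sample).
#' @export
size_factors <- function(counts) {
  allpos <- colSums(counts <= 0) == 0
  if (!any(allpos)) {
    stop("no taxa with all-positive counts: size factors undefined")
  }
  ref <- counts[, allpos, drop = FALSE]
  geo <- exp(colMeans(log(ref)))
  apply(sweep(ref, 2, geo, "/"), 1, median)
}

#' Simplified negative-binomial differential abundance test
#'
#' Per-taxon negative-binomial regression of raw counts on a continuous
#' covariate, `log mu = b0 + b1 * covariate + log(size factor)`, with
#' median-of-ratios size factors, per-taxon maximum-likelihood dispersion
#' and a Wald test on `b1` (t reference with `n - 2` degrees of freedom,
#' the usual small-sample guard), Bonferroni-corrected over the tested
#' taxa.
#' This is a deliberately plain version of the negative-binomial
#' differential-abundance framework: no dispersion shrinkage across taxa,
#' no fold-change moderation, no independent filtering. Taxa observed in
#' fewer than `min_prevalence` of samples are excluded before testing, and
#' non-convergent fits are reported but excluded from the correction family.
#'
#' @param counts Samples x taxa matrix of raw (unrarefied, un-normalized)
#'   counts.
#' @param covariate Continuous covariate, one value per sample.
#' @param min_prevalence Minimum fraction of samples with a nonzero count
#'   (default 0.25).
#' @param sf Optional precomputed size factors (default median-of-ratios).
#' @return Data frame: `taxon`, `log_fc` (natural log per covariate unit),
#'   `log2_fc`, `se`, `wald_z`, `p_raw`, `p_adj`, `converged`, `tier`.
#' @export
nb_differential_abundance <- function(counts, covariate, min_prevalence = 0.25,
                                      sf = NULL) {
  if (length(covariate) != nrow(counts)) {
    stop("covariate length must match the number of samples")
  }
  if (is.null(sf)) sf <- size_factors(counts)
  df_resid <- nrow(counts) - 2L
  prev <- colMeans(counts > 0)
  keep <- prev >= min_prevalence
  if (!any(keep)) stop("no taxa pass the prevalence filter")
  off <- log(sf)
  fits <- lapply(colnames(counts)[keep], function(tx) {
    y <- counts[, tx]
    est <- tryCatch({
      fit <- suppressWarnings(
        MASS::glm.nb(y ~ covariate + offset(off),
                     control = glm.control(maxit = 50)))
      if (!fit$converged) stop("IWLS did not converge")
      s <- summary(fit)$coefficients
      list(b = s["covariate", 1], se = s["covariate", 2], ok = TRUE)
    }, error = function(e) {
      # dispersion -> 0 boundary (underdispersed fit): Poisson limit
      tryCatch({
        fit <- suppressWarnings(
          glm(y ~ covariate + offset(off), family = poisson()))
        if (!fit$converged) stop("no convergence")
        s <- summary(fit)$coefficients
        list(b = s["covariate", 1], se = s["covariate", 2], ok = TRUE)
      }, error = function(e2) list(b = NA_real_, se = NA_real_, ok = FALSE))
    })
    data.frame(taxon = tx, log_fc = est$b, log2_fc = est$b / log(2),
               se = est$se, wald_z = est$b / est$se,
               # t reference; guarded against underflow to exactly zero
               p_raw = pmax(2 * stats::pt(-abs(est$b / est$se), df_resid),
                            1e-300),
               converged = est$ok, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, fits)
  res$p_adj <- NA_real_
  ok <- res$converged
  res$p_adj[ok] <- adjust_family(res$p_raw[ok], "bonferroni")
  res$tier <- ifelse(ok, tier_(res$p_adj), NA_character_)
  res
}

#' Correlation grid between diversity indices and serum markers
#'
#' Spearman correlation of each diversity index against each serum marker,
#' per stratum, corrected within each stratum family.
#'
#' @param cohort Cohort data frame.
#' @param diversity Data frame from [alpha_diversity()] aligned to cohort
#'   rows.
#' @param markers Marker columns (default the six serum markers).
#' @param indices Diversity columns (default richness and Shannon).
#' @param strata Stratum labels per row; `"all"` rows are added
#'   automatically.
#' @param method Family correction method (default `"bh"`).
#' @return Data frame: `stratum`, `index`, `marker`, `rho`, `p_raw`,
#'   `p_adj`, `tier`.
#' @export
correlation_grid <- function(cohort, diversity,
                             markers = c("insulin", "glucose", "homa2_ir",
                                         "quicki", "hscrp", "glyca"),
                             indices = c("richness", "shannon"),
                             strata = cohort$bmi_group, method = "bh") {
  groups <- c(list(all = rep(TRUE, nrow(cohort))),
              lapply(setNames(nm = unique(strata)), function(s) strata == s))
  out <- list()
  for (g in names(groups)) {
    sel <- groups[[g]]
    rows <- list()
    for (ix in indices) {
      for (m in markers) {
        st <- spearman_test(diversity[[ix]][sel], cohort[[m]][sel])
        rows[[paste(ix, m)]] <- data.frame(
          stratum = g, index = ix, marker = m,
          rho = st$rho, p_raw = st$p_value, stringsAsFactors = FALSE)
      }
    }
    fam <- do.call(rbind, rows)
    fam$p_adj <- adjust_family(fam$p_raw, method)
    out[[g]] <- fam
  }
  res <- do.call(rbind, out)
  res$tier <- tier_(res$p_adj)
  rownames(res) <- NULL
  res
}

#' Assemble the full cohort result-table battery
#'
#' Runs the complete analysis battery on one cohort and returns the four
#' standard result tables: baseline medians with a between-group test
#' (table 1 analogue), the PERMANOVA grid over a covariate family per
#' stratum on the Aitchison distance of unrarefied counts (table 2
#' analogue, Bonferroni within each stratum), lowest-vs-highest diversity
#' quartile contrasts of serum markers (table 3 analogue), the diversity x
#' marker Spearman grid (table 4 analogue), and the IDQ correlation with
#' both diversity indices per stratum.
#'
#' @param cohort Cohort data frame.
#' @param diversity Data frame from [alpha_diversity()] aligned to cohort
#'   rows (computed on rarefied counts).
#' @param counts Samples x MGS matrix of raw counts (for beta diversity).
#' @param permanova_covariates Covariate family for the PERMANOVA grid
#'   (default `c("idq_score", "insulin", "homa2_ir", "glyca")`).
#' @param n_perm Permutations per PERMANOVA (default 999).
#' @param pseudocount CLR pseudocount on counts (default 1).
#' @param seed Optional integer seed (fanned out across PERMANOVA calls).
#' @return List of data frames: `baseline`, `permanova`, `quartile_shannon`,
#'   `quartile_richness`, `correlations`, `idq_diversity`.
#' @export
replicate_result_tables <- function(cohort, diversity, counts,
                                    permanova_covariates =
                                      c("idq_score", "insulin",
                                        "homa2_ir", "glyca"),
                                    n_perm = 999, pseudocount = 1,
                                    seed = NULL) {
  strata <- cohort$bmi_group
  markers <- c("insulin", "glucose", "homa2_ir", "quicki", "hscrp", "glyca")

  baseline <- do.call(rbind, lapply(c(markers, "idq_score"), function(m) {
    ow <- cohort[[m]][strata == "overweight"]
    ob <- cohort[[m]][strata == "obese"]
    mw <- mann_whitney_test(ow, ob)
    data.frame(variable = m,
               overweight_median = median(ow), obese_median = median(ob),
               p_raw = mw$p_value, stringsAsFactors = FALSE)
  }))

  clr <- clr_transform(counts, pseudocount = pseudocount)
  perm_rows <- list()
  k <- 0L
  for (g in c("all", "overweight", "obese")) {
    sel <- if (g == "all") rep(TRUE, nrow(cohort)) else strata == g
    d <- aitchison_distance(clr[sel, , drop = FALSE])
    fam <- lapply(permanova_covariates, function(cv) {
      k <<- k + 1L
      pr <- permanova(d, cohort[[cv]][sel], n_perm = n_perm,
                      seed = if (is.null(seed)) NULL else seed + k)
      data.frame(stratum = g, covariate = cv, f = pr$f,
                 r_squared = pr$r_squared, p_raw = pr$p_value,
                 n_perm = pr$n_perm, stringsAsFactors = FALSE)
    })
    fam <- do.call(rbind, fam)
    fam$p_adj <- adjust_family(fam$p_raw, "bonferroni")
    perm_rows[[g]] <- fam
  }
  perm_tab <- do.call(rbind, perm_rows)
  perm_tab$tier <- tier_(perm_tab$p_adj)
  rownames(perm_tab) <- NULL

  qc <- function(index) {
    out <- list()
    for (g in c("all", "overweight", "obese")) {
      sel <- if (g == "all") rep(TRUE, nrow(cohort)) else strata == g
      q <- quartile_groups(diversity[[index]][sel])
      sub <- quartile_contrast(cohort[sel, , drop = FALSE], q,
                               markers = markers)
      sub$stratum <- g
      out[[g]] <- sub
    }
    do.call(rbind, out)
  }

  idq_rows <- list()
  for (g in c("all", "overweight", "obese")) {
    sel <- if (g == "all") rep(TRUE, nrow(cohort)) else strata == g
    fam <- do.call(rbind, lapply(c("shannon", "richness"), function(ix) {
      st <- spearman_test(cohort$idq_score[sel], diversity[[ix]][sel])
      data.frame(stratum = g, index = ix, rho = st$rho, p_raw = st$p_value,
                 stringsAsFactors = FALSE)
    }))
    fam$p_adj <- adjust_family(fam$p_raw, "bh")
    idq_rows[[g]] <- fam
  }
  idq_tab <- do.call(rbind, idq_rows)
  idq_tab$tier <- tier_(idq_tab$p_adj)
  rownames(idq_tab) <- NULL

  list(baseline = baseline,
       permanova = perm_tab,
       quartile_shannon = qc("shannon"),
       quartile_richness = qc("richness"),
       correlations = correlation_grid(cohort, diversity, markers = markers),
       idq_diversity = idq_tab)
}
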