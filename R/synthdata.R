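# Synthetic cohort generator.
#
# Emulates the data structure of a metagenomics cohort of overweight and
# obese pregnant women: a gene catalog with per-MGS core-gene sets,
# per-sample read-pair alignment records with tunable noise, and a cohort
# table of diet-quality scores and serum markers whose marginals are
# matched to published median/IQR scales. Rank correlations between any
# latent pair (including the latent drivers of Shannon diversity and
# richness) are injected through a Gaussian copula, per stratum, so the
# downstream analysis battery can be validated against known ground truth.

#' Generate a gene catalog
#'
#' Builds a catalog of genes grouped into metagenomic species (MGS), each
#' with `k_core` designated core genes, optional non-core genes, and orphan
#' genes belonging to no MGS. Core membership is declared at generation
#' time.
#'
#' @param n_mgs Number of MGSs (>= 1).
#' @param k_core Core genes per MGS (>= 3; the detection rule needs at
#'   least three core genes to be meaningful). Default 100.
#' @param n_noncore_per_mgs Additional non-core genes per MGS (default 0).
#' @param n_orphan Genes not assigned to any MGS (default 0).
#' @param length_range Gene length bounds in bp, within \[100, 10000\].
#' @param seed Optional integer seed.
#' @return Data frame with columns `gene_id`, `length_bp`, `mgs_id`
#'   (`NA` for orphans), `is_core`.
#' @examples
#' cat <- generate_catalog(n_mgs = 5, k_core = 100, n_orphan = 10, seed = 1)
#' nrow(cat)  # 510
#' @export
generate_catalog <- function(n_mgs, k_core = 100, n_noncore_per_mgs = 0,
                             n_orphan = 0, length_range = c(100, 5000),
                             seed = NULL) {
  if (n_mgs < 1) stop("`n_mgs` must be >= 1")
  if (k_core < 3) stop("`k_core` must be >= 3 (detection rule would be vacuous)")
  if (length_range[1] < 100 || length_range[2] > 10000 ||
      length_range[1] > length_range[2]) {
    stop("`length_range` must lie within [100, 10000]")
  }
  with_seed_(seed, {
    per_mgs <- k_core + n_noncore_per_mgs
    n_genes <- n_mgs * per_mgs + n_orphan
    mgs_id <- c(rep(sprintf("MGS%04d", seq_len(n_mgs)), each = per_mgs),
                rep(NA_character_, n_orphan))
    is_core <- c(rep(c(rep(TRUE, k_core), rep(FALSE, n_noncore_per_mgs)), n_mgs),
                 rep(FALSE, n_orphan))
    data.frame(
      gene_id = sprintf("gene%06d", seq_len(n_genes)),
      length_bp = sample(length_range[1]:length_range[2], n_genes, replace = TRUE),
      mgs_id = mgs_id,
      is_core = is_core,
      stringsAsFactors = FALSE
    )
  })
}

#' Default serum-marker marginals
#'
#' Per-stratum median and interquartile range, on the scale of an
#' overweight/obese early-pregnancy cohort, for the log-normal (markers)
#' and normal (IDQ, age) marginal distributions used by [generate_cohort()].
#'
#' @return Data frame with columns `marker`, `stratum`, `median`, `q1`, `q3`.
#' @export
marker_defaults <- function() {
  rbind(
    data.frame(marker = "insulin", stratum = c("overweight", "obese"),
               median = c(8.0, 13.0), q1 = c(7.0, 9.0), q3 = c(10.75, 17.0)),
    data.frame(marker = "glucose", stratum = c("overweight", "obese"),
               median = c(4.7, 4.8), q1 = c(4.5, 4.6), q3 = c(4.9, 5.1)),
    data.frame(marker = "hscrp", stratum = c("overweight", "obese"),
               median = c(4.5, 6.7), q1 = c(2.6, 4.0), q3 = c(7.2, 10.7)),
    data.frame(marker = "glyca", stratum = c("overweight", "obese"),
               median = c(1.2, 1.2), q1 = c(1.1, 1.1), q3 = c(1.3, 1.3)),
    data.frame(marker = "idq", stratum = c("overweight", "obese"),
               median = c(9.7, 9.6), q1 = c(8.0, 7.7), q3 = c(11.0, 11.0)),
    data.frame(marker = "age", stratum = c("overweight", "obese"),
               median = c(30.3, 30.8), q1 = c(27.6, 27.3), q3 = c(33.7, 34.4))
  )
}

#' Default injected-effect registry
#'
#' The stratum-specific ground-truth effects the generator injects by
#' default: a diet-quality/diversity correlation in the obese stratum only,
#' richness/marker correlations in the overweight stratum only, a
#' Shannon-richness coupling in both strata, and a GlycA-driven shift of a
#' subset of taxa (composition effect) in the overweight stratum only.
#' Effect magnitudes sit at the upper end of the correlation scale reported
#' for comparable cohorts so that a single cohort at the default group
#' sizes has high power; all are configurable.
#'
#' @return List with elements `correlations` (data frame `stratum`, `var1`,
#'   `var2`, `rho` of target Spearman correlations; stratum `"all"` applies
#'   in both) and `composition` (list `stratum`, `covariate`, `n_taxa`,
#'   `beta`: per-taxon log-abundance shift per standard-normal unit of the
#'   covariate's latent).
#' @export
effect_registry_default <- function() {
  list(
    correlations = data.frame(
      stratum = c("obese", "overweight", "overweight", "all"),
      var1 = c("idq", "insulin", "glyca", "shannon"),
      var2 = c("shannon", "richness", "richness", "richness"),
      rho = c(0.35, -0.32, -0.32, 0.50),
      stringsAsFactors = FALSE
    ),
    composition = list(stratum = "overweight", covariate = "glyca",
                       n_taxa = 30, beta = 0.6)
  )
}

#' Null effect registry (no injected associations)
#' @return An effect registry with every correlation zero and no
#'   composition effect.
#' @export
effect_registry_null <- function() {
  list(correlations = data.frame(stratum = character(), var1 = character(),
                                 var2 = character(), rho = numeric(),
                                 stringsAsFactors = FALSE),
       composition = NULL)
}

latent_vars_ <- c("shannon", "richness", "idq", "insulin", "glucose",
                  "hscrp", "glyca", "age")

# Per-stratum latent correlation matrix from the effect registry.
# Spearman targets are converted to the Pearson correlation of the latent
# normals via 2 sin(pi rho / 6), the exact Gaussian-copula relation.
latent_sigma_ <- function(effects, stratum) {
  k <- length(latent_vars_)
  S <- diag(k)
  dimnames(S) <- list(latent_vars_, latent_vars_)
  cors <- effects$correlations
  if (!is.null(cors) && nrow(cors)) {
    use <- cors$stratum == stratum | cors$stratum == "all"
    for (i in which(use)) {
      r <- 2 * sin(pi * cors$rho[i] / 6)
      v1 <- cors$var1[i]; v2 <- cors$var2[i]
      if (!v1 %in% latent_vars_ || !v2 %in% latent_vars_) {
        stop("unknown effect variable: ", v1, " or ", v2)
      }
      S[v1, v2] <- r
      S[v2, v1] <- r
    }
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("infeasible correlation matrix (not positive semi-definite)")
  }
  S
}

#' Generate a synthetic cohort table with ground truth
#'
#' Draws a cohort of overweight (25 <= BMI < 30) and obese (BMI >= 30)
#' subjects. Serum markers are log-normal, moment-matched to the configured
#' median/IQR per stratum; IDQ and age are normal (IDQ clamped to
#' \[0, 15\] and reported to 0.1 points). Requested Spearman correlations
#' (including those involving the latent Shannon and richness drivers) are
#' injected via a Gaussian copula within the designated stratum only. QUICKI
#' is computed from insulin and glucose; HOMA2-IR is generated as a
#' monotone function of insulin x glucose with multiplicative noise
#' (synthetic stand-in for the external calculator model).
#'
#' @param n_overweight,n_obese Group sizes (each >= 4).
#' @param markers Marker marginal table, see [marker_defaults()].
#' @param effects Effect registry, see [effect_registry_default()].
#' @param seed Optional integer seed.
#' @return List with `cohort` (data frame: `subject_id`, `age_yr`,
#'   `prepregnancy_bmi`, `bmi_group`, `idq_score`, `idq_class`, `insulin`,
#'   `glucose`, `homa2_ir`, `quicki`, `hscrp`, `glyca`) and `truth` (list:
#'   `latents` matrix, `effects`, `realized` data frame of realized sample
#'   Spearman correlations for every registered pair).
#' @export
generate_cohort <- function(n_overweight = 234, n_obese = 152,
                            markers = marker_defaults(),
                            effects = effect_registry_default(),
                            seed = NULL) {
  if (n_overweight < 4 || n_obese < 4) stop("group sizes must be >= 4")
  cors <- effects$correlations
  if (!is.null(cors) && nrow(cors) && any(abs(cors$rho) >= 1)) {
    stop("effect sizes must be correlations in (-1, 1)")
  }
  with_seed_(seed, {
    n <- n_overweight + n_obese
    stratum <- rep(c("overweight", "obese"), c(n_overweight, n_obese))
    lat <- matrix(NA_real_, n, length(latent_vars_),
                  dimnames = list(NULL, latent_vars_))
    for (s in c("overweight", "obese")) {
      S <- latent_sigma_(effects, s)
      idx <- which(stratum == s)
      z <- matrix(rnorm(length(idx) * ncol(S)), length(idx))
      lat[idx, ] <- z %*% chol(S)
    }
    mk <- function(var, dist = "lognormal") {
      out <- numeric(n)
      for (s in c("overweight", "obese")) {
        row <- markers[markers$marker == var & markers$stratum == s, ]
        if (nrow(row) != 1) stop("marker table lacks ", var, " for ", s)
        idx <- which(stratum == s)
        if (dist == "lognormal") {
          sigma <- (log(row$q3) - log(row$q1)) / (2 * qnorm(0.75))
          out[idx] <- exp(log(row$median) + sigma * lat[idx, var])
        } else {
          sigma <- (row$q3 - row$q1) / (2 * qnorm(0.75))
          out[idx] <- row$median + sigma * lat[idx, var]
        }
      }
      out
    }
    insulin <- mk("insulin")
    glucose <- mk("glucose")
    hscrp <- mk("hscrp")
    glyca <- mk("glyca")
    idq <- round(pmin(15, pmax(0, mk("idq", "normal"))), 1)
    age <- round(mk("age", "normal"), 1)
    bmi <- numeric(n)
    bmi[stratum == "overweight"] <- round(runif(n_overweight, 25, 29.9), 1)
    bmi[stratum == "obese"] <-
      round(pmin(55, 30 + stats::rgamma(n_obese, shape = 2, scale = 1.8)), 1)
    homa2 <- insulin * glucose / 36.2 * exp(rnorm(n, 0, 0.1))
    cohort <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      age_yr = age,
      prepregnancy_bmi = bmi,
      bmi_group = stratum,
      idq_score = idq,
      idq_class = dichotomize_idq(idq),
      insulin = insulin,
      glucose = glucose,
      homa2_ir = homa2,
      quicki = quicki(insulin, glucose),
      hscrp = hscrp,
      glyca = glyca,
      stringsAsFactors = FALSE
    )
    realized <- NULL
    if (!is.null(cors) && nrow(cors)) {
      realized <- cors
      realized$realized_rho <- vapply(seq_len(nrow(cors)), function(i) {
        idx <- if (cors$stratum[i] == "all") seq_len(n) else
          which(stratum == cors$stratum[i])
        suppressWarnings(
          stats::cor(lat[idx, cors$var1[i]], lat[idx, cors$var2[i]],
                     method = "spearman"))
      }, numeric(1))
    }
    list(cohort = cohort,
         truth = list(latents = lat, effects = effects, realized = realized))
  })
}

#' Generate per-sample true MGS abundance profiles
#'
#' Maps each subject's latent richness and Shannon drivers to an abundance
#' vector over `n_mgs` species: the richness latent sets the number of
#' present species (nested presence structure), and the Shannon latent sets
#' a per-sample target Shannon index that is hit exactly on the true
#' profile by solving for the spread of truncated-log-normal weights. A
#' registered composition effect multiplies the weights of the affected
#' taxa by `exp(beta_j * covariate_latent)` within its stratum.
#'
#' @param cohort_obj List from [generate_cohort()].
#' @param n_mgs Total species in the pool (default 450).
#' @param richness_center,richness_sd Median and spread of the number of
#'   present species (defaults 237 and 62, the published cohort scale).
#' @param shannon_center,shannon_sd Median and spread of the per-sample
#'   Shannon target in nats (defaults 2.7 and 0.297).
#' @param n_dominant Size of the dominant block carrying most of the mass
#'   (default 50; must not exceed the smallest possible present count).
#' @param tail_mass Total relative abundance shared by the rare tail
#'   (default 0.02). Tail shares span one decade, so every present species
#'   stays well above the detection limit at realistic depths.
#' @param seed Optional integer seed.
#' @return Samples x MGS matrix of true relative abundances (rows sum to 1),
#'   with attributes `present_species` (integer vector), `shannon_target`,
#'   `affected_taxa` and `betas` (composition effect bookkeeping).
#' @export
generate_profiles <- function(cohort_obj, n_mgs = 450,
                              richness_center = 237, richness_sd = 62,
                              shannon_center = 2.7, shannon_sd = 0.297,
                              n_dominant = 50, tail_mass = 0.02,
                              seed = NULL) {
  lat <- cohort_obj$truth$latents
  effects <- cohort_obj$truth$effects
  stratum <- cohort_obj$cohort$bmi_group
  n <- nrow(lat)
  with_seed_(seed, {
    S_i <- pmin(n_mgs, pmax(as.integer(n_dominant), as.integer(round(
      richness_center + richness_sd * lat[, "richness"]))))
    H_i <- shannon_center + shannon_sd * lat[, "shannon"]
    H_i <- pmin(pmax(H_i, 1.0), 0.97 * log(n_dominant))
    comp <- effects$composition
    affected <- integer(0); betas <- numeric(0)
    if (!is.null(comp)) {
      n_aff <- min(comp$n_taxa, n_dominant)  # capped at the dominant block
      affected <- sample.int(n_dominant, n_aff)
      betas <- comp$beta * sample(c(-1, 1), n_aff, replace = TRUE)
    }
    prof <- matrix(0, n, n_mgs,
                   dimnames = list(cohort_obj$cohort$subject_id,
                                   sprintf("MGS%04d", seq_len(n_mgs))))
    for (i in seq_len(n)) {
      s <- S_i[i]
      # Dominant block of `n_dominant` species carries 1 - tail_mass of the
      # abundance; its spread sets the Shannon index. The rare tail spreads
      # tail_mass over all present species across a single decade, keeping
      # every species far above the detection limit at realistic depth.
      z <- qnorm(runif(n_dominant, pnorm(-2), pnorm(2)))  # truncated normal
      shift <- numeric(n_dominant)
      if (!is.null(comp) && stratum[i] == comp$stratum) {
        shift[affected] <- betas * lat[i, comp$covariate]
      }
      tail_share <- 10^runif(s)
      tail_p <- tail_mass * tail_share / sum(tail_share)
      p_of <- function(sig) {
        w <- exp(sig * (z - max(z)) + shift)
        p <- numeric(s)
        p[seq_len(n_dominant)] <- (1 - tail_mass) * w / sum(w)
        p + tail_p
      }
      h_of <- function(sig) {
        p <- p_of(sig)
        -sum(p * log(p))
      }
      # a strong composition shift can lower the entropy ceiling at sig = 0;
      # clamp the target just below the achievable maximum
      target <- min(H_i[i], h_of(0) - 0.02)
      H_i[i] <- target
      sig <- uniroot(function(sg) h_of(sg) - target, c(0, 30),
                     extendInt = "downX", tol = 1e-10)$root
      prof[i, seq_len(s)] <- p_of(sig)
    }
    attr(prof, "present_species") <- S_i
    attr(prof, "shannon_target") <- H_i
    attr(prof, "affected_taxa") <- affected
    attr(prof, "betas") <- betas
    prof
  })
}

#' Multinomial MGS count table from true profiles
#'
#' Allocates each sample's read pairs multinomially over species according
#' to its true abundance vector. Per-sample totals are log-normal around
#' `mean_depth`, floored at `min_depth` so every sample supports the
#' default rarefaction depth.
#'
#' @param profiles Matrix from [generate_profiles()].
#' @param mean_depth Geometric-mean read-pair total (default 1.2e7).
#' @param depth_cv Log-scale standard deviation of totals (default 0.2).
#' @param min_depth Floor for totals (default 7,281,907 read pairs, the
#'   reference rarefaction depth).
#' @param seed Optional integer seed.
#' @return Samples x MGS integer count matrix.
#' @export
generate_mgs_counts <- function(profiles, mean_depth = 1.2e7, depth_cv = 0.2,
                                min_depth = 7281907, seed = NULL) {
  with_seed_(seed, {
    n <- nrow(profiles)
    depth <- pmax(min_depth, round(rlnorm(n, log(mean_depth), depth_cv)))
    out <- matrix(0L, n, ncol(profiles), dimnames = dimnames(profiles))
    for (i in seq_len(n)) {
      out[i, ] <- as.integer(rmultinom(1, depth[i], profiles[i, ]))
    }
    out
  })
}

#' Noise configuration for alignment-record generation
#'
#' All fractions default to zero (a noise-free sample passes every filter).
#'
#' @param low_quality_frac Fraction of pairs failing quality trimming.
#' @param host_frac Fraction of (quality-passing) pairs flagged host.
#' @param unmapped_frac Fraction not mapping to the catalog at all.
#' @param orphan_frac Fraction mapping to orphan genes (no MGS).
#' @param duplicate_frac Fraction that are PCR/optical duplicates of
#'   another pair.
#' @param low_mapq_frac,short_alen_frac,low_identity_frac,overhang_frac,
#'   multi_gene_frac Fractions of mapped pairs failing the corresponding
#'   mapping-acceptance rule.
#' @return Named list of fractions.
#' @export
noise_config <- function(low_quality_frac = 0, host_frac = 0,
                         unmapped_frac = 0, orphan_frac = 0,
                         duplicate_frac = 0, low_mapq_frac = 0,
                         short_alen_frac = 0, low_identity_frac = 0,
                         overhang_frac = 0, multi_gene_frac = 0) {
  cfg <- list(low_quality_frac = low_quality_frac, host_frac = host_frac,
              unmapped_frac = unmapped_frac, orphan_frac = orphan_frac,
              duplicate_frac = duplicate_frac, low_mapq_frac = low_mapq_frac,
              short_alen_frac = short_alen_frac,
              low_identity_frac = low_identity_frac,
              overhang_frac = overhang_frac, multi_gene_frac = multi_gene_frac)
  bad <- vapply(cfg, function(v) v < 0 || v > 1, logical(1))
  if (any(bad)) stop("noise fractions must lie in [0, 1]")
  cfg
}

#' Generate read-pair alignment records for one sample
#'
#' Emulates the output of an (out-of-scope) aligner: read pairs are
#' allocated multinomially to catalog genes with probability proportional
#' to MGS abundance times gene length, and the noise configuration controls
#' the fractions of low-quality, host, unmapped, orphan-gene, duplicate,
#' and filter-failing records so that every filter stage has a known
#' expected pass rate.
#'
#' @param catalog Gene catalog from [generate_catalog()].
#' @param abundance Named MGS relative-abundance vector (sums to 1).
#' @param n_read_pairs Number of read pairs (>= 1).
#' @param noise List from [noise_config()].
#' @param seed Optional integer seed.
#' @return Data frame of alignment records: `read_pair_id`, `gene_id`
#'   (`NA` when unmapped), `mapq_mate1`, `mapq_mate2`, `aligned_len_bp`,
#'   `identity_pct`, `overhang5`, `overhang3`, `n_candidate_genes`,
#'   `is_host`, `read1_kept`, `read2_kept`, `dup_key`.
#' @export
generate_sample_alignments <- function(catalog, abundance, n_read_pairs,
                                       noise = noise_config(), seed = NULL) {
  if (n_read_pairs < 1) stop("`n_read_pairs` must be >= 1")
  if (abs(sum(abundance) - 1) > 1e-8) stop("`abundance` must sum to 1")
  with_seed_(seed, {
    n <- as.integer(n_read_pairs)
    lowq <- runif(n) < noise$low_quality_frac
    host <- !lowq & runif(n) < noise$host_frac
    unmapped <- !lowq & !host & runif(n) < noise$unmapped_frac
    orphan <- !lowq & !host & !unmapped & runif(n) < noise$orphan_frac
    mapped <- !lowq & !host & !unmapped & !orphan

    gene_id <- rep(NA_character_, n)
    mgs_genes <- catalog[!is.na(catalog$mgs_id), , drop = FALSE]
    w <- abundance[mgs_genes$mgs_id] * mgs_genes$length_bp
    if (any(mapped)) {
      gene_id[mapped] <- sample(mgs_genes$gene_id, sum(mapped),
                                replace = TRUE, prob = w)
    }
    orph <- catalog[is.na(catalog$mgs_id), , drop = FALSE]
    if (any(orphan)) {
      if (nrow(orph) == 0L) stop("orphan_frac > 0 but catalog has no orphan genes")
      gene_id[orphan] <- sample(orph$gene_id, sum(orphan), replace = TRUE,
                                prob = orph$length_bp)
    }
    hit <- mapped | orphan
    mapq1 <- mapq2 <- rep(60L, n)
    flip <- hit & runif(n) < noise$low_mapq_frac
    mapq1[flip] <- 10L
    alen <- ifelse(hit & runif(n) < noise$short_alen_frac, 80L, 140L)
    ident <- ifelse(hit & runif(n) < noise$low_identity_frac, 90, 99)
    over3 <- ifelse(hit & runif(n) < noise$overhang_frac, 15L, 0L)
    ncand <- ifelse(hit & runif(n) < noise$multi_gene_frac, 2L, 1L)
    # duplicates copy the key of a uniformly chosen non-duplicate record,
    # so the distinct-key count is Binomial(n, 1 - duplicate_frac)
    dup_key <- sprintf("key%07d", seq_len(n))
    is_dup <- runif(n) < noise$duplicate_frac
    if (any(is_dup) && any(!is_dup)) {
      dup_key[is_dup] <- sample(dup_key[!is_dup], sum(is_dup), replace = TRUE)
    }
    data.frame(
      read_pair_id = sprintf("pair%07d", seq_len(n)),
      gene_id = gene_id,
      mapq_mate1 = mapq1, mapq_mate2 = mapq2,
      aligned_len_bp = as.integer(alen),
      identity_pct = ident,
      overhang5 = 0L, overhang3 = as.integer(over3),
      n_candidate_genes = as.integer(ncand),
      is_host = host,
      read1_kept = !lowq, read2_kept = TRUE,
      dup_key = dup_key,
      stringsAsFactors = FALSE
    )
  })
}

#' Write a FASTQ fixture with designed quality profiles
#'
#' Builds a well-formed Phred+33 FASTQ file whose reads carry the supplied
#' quality strings over random nucleotide sequences, for exercising the
#' trimming stage with known outcomes.
#'
#' @param quality_strings Character vector of Phred+33 quality strings
#'   (may be empty, yielding an empty valid FASTQ).
#' @param path Output file path.
#' @param ids Optional read ids (defaults to `read1`, `read2`, ...).
#' @param expected Optional character vector recording the designed trim
#'   outcome per read, echoed in the returned manifest.
#' @param seed Optional integer seed (for the random sequences).
#' @return Invisibly, a manifest data frame (`read_id`, `length`,
#'   `expected`).
#' @export
generate_fastq_fixture <- function(quality_strings, path, ids = NULL,
                                   expected = NA_character_, seed = NULL) {
  for (q in quality_strings) decode_phred(q)  # validates Phred+33
  n <- length(quality_strings)
  if (is.null(ids)) ids <- sprintf("read%d", seq_len(n))
  with_seed_(seed, {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(n)) {
      len <- nchar(quality_strings[i])
      seqs <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                    collapse = "")
      writeLines(c(paste0("@", ids[i]), seqs, "+", quality_strings[i]), con)
    }
  })
  invisible(data.frame(read_id = ids,
                       length = if (n) nchar(quality_strings) else integer(0),
                       expected = if (n) rep_len(expected, n) else character(0),
                       stringsAsFactors = FALSE))
}

#' Read a FASTQ file written by [generate_fastq_fixture()]
#'
#' Minimal four-line-record FASTQ reader returning ids, sequences and
#' quality strings.
#'
#' @param path FASTQ file path.
#' @return Data frame with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) stop("malformed FASTQ: line count not divisible by 4")
  if (length(lines) == 0L) {
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  ix <- seq(1, length(lines), by = 4)
  data.frame(read_id = sub("^@", "", lines[ix]),
             sequence = lines[ix + 1],
             quality = lines[ix + 3],
             stringsAsFactors = FALSE)
}

#' Generate synthetic gene-to-KO and KO-to-module mapping tables
#'
#' @param catalog Gene catalog data frame.
#' @param n_ko Number of KEGG orthology groups.
#' @param n_module Number of KEGG modules.
#' @param ko_coverage Fraction of genes assigned a KO (default 0.7).
#' @param kos_per_module Mean KOs per module (default 5).
#' @param multi_module_frac Fraction of KOs belonging to two modules
#'   (default 0.1).
#' @param seed Optional integer seed.
#' @return List with `gene_to_ko` and `ko_to_module` two-column data frames.
#' @export
generate_function_maps <- function(catalog, n_ko = 50, n_module = 15,
                                   ko_coverage = 0.7, kos_per_module = 5,
                                   multi_module_frac = 0.1, seed = NULL) {
  with_seed_(seed, {
    kos <- sprintf("K%05d", seq_len(n_ko))
    mods <- sprintf("M%05d", seq_len(n_module))
    has_ko <- runif(nrow(catalog)) < ko_coverage
    gene_to_ko <- data.frame(
      gene_id = catalog$gene_id[has_ko],
      ko = sample(kos, sum(has_ko), replace = TRUE),
      stringsAsFactors = FALSE
    )
    primary <- sample(mods, n_ko, replace = TRUE)
    ko_to_module <- data.frame(ko = kos, module = primary,
                               stringsAsFactors = FALSE)
    extra <- runif(n_ko) < multi_module_frac
    if (any(extra)) {
      second <- vapply(primary[extra], function(m) {
        sample(setdiff(mods, m), 1)
      }, character(1))
      ko_to_module <- rbind(ko_to_module,
                            data.frame(ko = kos[extra], module = second,
                                       stringsAsFactors = FALSE))
    }
    list(gene_to_ko = gene_to_ko, ko_to_module = ko_to_module)
  })
}
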