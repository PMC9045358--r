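# The synthetic cohort generator: catalogs, cohorts with injected effects,
# abundance profiles, alignment records and FASTQ fixtures.

test_that("catalog generation honors the requested structure", {
  cat <- generate_catalog(n_mgs = 5, k_core = 100, n_noncore_per_mgs = 0,
                          n_orphan = 10, seed = 1)
  expect_equal(nrow(cat), 510L)
  expect_equal(sum(is.na(cat$mgs_id)), 10L)
  core_per_mgs <- table(cat$mgs_id[cat$is_core])
  expect_equal(length(core_per_mgs), 5L)
  expect_true(all(core_per_mgs == 100))
  expect_false(any(duplicated(cat$gene_id)))
  expect_true(all(cat$length_bp >= 100))

  small <- generate_catalog(n_mgs = 1, k_core = 3, seed = 1)
  expect_equal(nrow(small), 3L)
  expect_true(all(small$is_core))

  expect_error(generate_catalog(n_mgs = 1, k_core = 2), "k_core")
  expect_error(generate_catalog(n_mgs = 0), "n_mgs")
  expect_error(generate_catalog(1, length_range = c(50, 500)), "length_range")
})

test_that("generators are bit-reproducible for a fixed seed", {
  expect_identical(generate_catalog(3, 10, 2, 5, seed = 9),
                   generate_catalog(3, 10, 2, 5, seed = 9))
  a <- generate_cohort(10, 10, seed = 4)
  b <- generate_cohort(10, 10, seed = 4)
  expect_identical(a, b)
  pa <- generate_profiles(a, n_mgs = 80, richness_center = 40,
                          richness_sd = 8, n_dominant = 25, seed = 5)
  pb <- generate_profiles(b, n_mgs = 80, richness_center = 40,
                          richness_sd = 8, n_dominant = 25, seed = 5)
  expect_identical(pa, pb)
})

test_that("cohort marginals match the configured medians", {
  # n chosen so 3 Monte-Carlo SEs of a sample median sit inside the 5% band
  co <- generate_cohort(5000, 5000, seed = 21)$cohort
  md <- marker_defaults()
  for (s in c("overweight", "obese")) {
    sub <- co[co$bmi_group == s, ]
    for (m in c("insulin", "glucose", "hscrp", "glyca")) {
      conf <- md[md$marker == m & md$stratum == s, ]
      expect_lt(abs(median(sub[[m]]) - conf$median) / conf$median, 0.05,
                label = sprintf("median of %s (%s)", m, s))
    }
  }
  # structural invariants
  expect_true(all(co$idq_score >= 0 & co$idq_score <= 15))
  expect_true(all(co$insulin > 0 & co$glucose > 0 & co$hscrp > 0 & co$glyca > 0))
  ow <- co$bmi_group == "overweight"
  expect_true(all(co$prepregnancy_bmi[ow] >= 25 & co$prepregnancy_bmi[ow] < 30))
  expect_true(all(co$prepregnancy_bmi[!ow] >= 30))
  expect_equal(co$idq_class, dichotomize_idq(co$idq_score))
  expect_equal(co$quicki, quicki(co$insulin, co$glucose))
})

test_that("null effect configuration yields null realized correlations", {
  co <- generate_cohort(234, 152, effects = effect_registry_null(), seed = 8)
  div_lat <- co$truth$latents[, "shannon"]
  rho <- cor(co$cohort$idq_score, div_lat, method = "spearman")
  expect_lt(abs(rho), 3 / sqrt(386))  # 3 SE of a null Spearman at n = 386
})

test_that("the copula recovers a requested stratum-specific correlation", {
  # Monte-Carlo oracle: mean realized Spearman over 200 cohorts at n = 152
  # must sit within 3 standard errors of the requested 0.3
  eff <- effect_registry_null()
  eff$correlations <- data.frame(stratum = "obese", var1 = "idq",
                                 var2 = "shannon", rho = 0.3)
  reps <- vapply(1:200, function(i) {
    co <- generate_cohort(4, 152, effects = eff, seed = 3000 + i)
    co$truth$realized$realized_rho
  }, numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 0.3), 3 * se + 0.01)
})

test_that("an infeasible correlation request is a configuration error", {
  eff <- effect_registry_null()
  eff$correlations <- data.frame(
    stratum = "obese", var1 = c("idq", "shannon", "idq"),
    var2 = c("shannon", "richness", "richness"), rho = c(0.95, 0.95, -0.95))
  expect_error(generate_cohort(10, 10, effects = eff, seed = 1),
               "positive semi-definite")
  eff$correlations$rho <- c(1, 0.5, 0.5)
  expect_error(generate_cohort(10, 10, effects = eff, seed = 1),
               "correlations in")
})

test_that("profiles hit their diversity targets exactly", {
  co <- generate_cohort(40, 30, seed = 14)
  prof <- generate_profiles(co, n_mgs = 300, seed = 15)
  expect_true(all(abs(rowSums(prof) - 1) < 1e-12))
  expect_equal(shannon(prof), attr(prof, "shannon_target"), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(unname(richness(prof)), unname(attr(prof, "present_species")))
})

test_that("alignment noise fractions control filter pass rates", {
  cat <- generate_catalog(n_mgs = 3, k_core = 4, n_orphan = 2, seed = 31)
  ab <- setNames(c(0.5, 0.3, 0.2), sprintf("MGS%04d", 1:3))

  # all-zero noise: every pair passes every filter
  recs <- generate_sample_alignments(cat, ab, 3000, seed = 32)
  expect_true(all(keep_pair_hqnh(recs$read1_kept, recs$read2_kept, recs$is_host)))
  expect_true(all(accept_mapping(recs)))
  expect_false(any(is.na(recs$gene_id)))
  expect_equal(nrow(dedup(recs)), 3000L)

  # 10% duplication: post-dedup count within binomial error of 9,000
  dup <- generate_sample_alignments(
    cat, ab, 10000, noise = noise_config(duplicate_frac = 0.1), seed = 33)
  survivors <- nrow(dedup(dup))
  se <- sqrt(10000 * 0.1 * 0.9)
  expect_lt(abs(survivors - 9000), 4 * se)

  # degenerate abundance: every mapped pair hits the single live MGS
  solo <- generate_sample_alignments(cat, setNames(c(1, 0, 0), names(ab)),
                                     2000, seed = 34)
  hit_mgs <- cat$mgs_id[match(solo$gene_id, cat$gene_id)]
  expect_true(all(hit_mgs == "MGS0001"))

  expect_error(generate_sample_alignments(cat, ab, 0), "n_read_pairs")
  expect_error(generate_sample_alignments(cat, ab / 2, 10), "sum to 1")
  expect_error(noise_config(duplicate_frac = 1.2), "fractions")
})

test_that("FASTQ fixtures are well-formed and validated", {
  path <- withr::local_tempfile(fileext = ".fastq")
  qs <- c(strrep("I", 150),                        # Q40 throughout
          paste0(strrep("I", 90), strrep("#", 60)))  # designed discard
  man <- generate_fastq_fixture(qs, path, expected = c("unchanged", "discard"),
                                seed = 2)
  fq <- read_fastq(path)
  expect_equal(nrow(fq), 2L)
  expect_equal(nchar(fq$sequence), nchar(fq$quality))
  expect_equal(fq$quality, qs)

  # designed outcomes hold under the trimmer
  expect_true(trim_read(fq$quality[1])$keep)
  expect_equal(trim_read(fq$quality[1])$length, 150L)
  expect_false(trim_read(fq$quality[2])$keep)

  # empty request: valid empty FASTQ
  generate_fastq_fixture(character(0), path)
  expect_equal(nrow(read_fastq(path)), 0L)

  expect_error(generate_fastq_fixture("II\x01", path), "Phred")
})
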