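# The univariate statistical battery and the simplified negative-binomial
# differential-abundance test.

test_that("Spearman correlation handles monotone, tied and degenerate input", {
  x <- 1:10
  expect_equal(spearman_test(x, x^3)$rho, 1)
  expect_equal(spearman_test(x, -sqrt(x))$rho, -1)

  # midrank oracle: rho equals the Pearson correlation of midranks
  xt <- c(1, 2, 2, 3, 5, 5, 5, 8)
  yt <- c(1, 3, 2, 4, 4, 6, 5, 5)
  expect_equal(spearman_test(xt, yt)$rho, cor(rank(xt), rank(yt)),
               tolerance = 1e-12)

  # exact small-sample p equals full rank-permutation enumeration
  withr::local_seed(21)
  for (i in 1:5) {
    x <- sample(100, 6)
    y <- sample(100, 6)
    got <- spearman_test(x, y)
    perms <- perms_by_filter(6)
    rhos <- apply(perms, 1, function(ix) cor(rank(x), rank(y[ix])))
    p_exact <- mean(abs(rhos) >= abs(got$rho) - 1e-12)
    expect_equal(got$p_value, p_exact, tolerance = 1e-10)
  }

  # missing pairs dropped listwise
  expect_equal(spearman_test(c(1, 2, 3, 4, NA), c(2, 4, 6, 8, 1))$n, 4L)
  expect_warning(out <- spearman_test(rep(1, 6), 1:6), "constant")
  expect_true(is.na(out$rho))
})

test_that("Mann-Whitney U handles separation, identity and matches enumeration", {
  sep <- mann_whitney_test(c(1, 2), c(3, 4))
  expect_equal(unname(sep$u), 0)

  same <- mann_whitney_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  # exhaustive permutation oracle on small untied groups
  withr::local_seed(22)
  for (i in 1:5) {
    pool <- sample(1000, 9)
    a <- pool[1:4]; b <- pool[5:9]
    got <- mann_whitney_test(a, b)
    combs <- utils::combn(9, 4)
    us <- apply(combs, 2, function(ix) {
      aa <- pool[ix]; bb <- pool[-ix]
      sum(outer(aa, bb, ">"))
    })
    u0 <- sum(outer(a, b, ">"))
    p_exact <- mean(us <= min(u0, 20 - u0)) + mean(us >= max(u0, 20 - u0))
    expect_equal(unname(got$u), u0)
    expect_equal(got$p_value, min(1, p_exact), tolerance = 1e-10)
  }
  expect_error(mann_whitney_test(numeric(0), 1:3), "non-empty")
})

test_that("IDQ dichotomization splits at 10 of 15 points", {
  expect_equal(as.character(dichotomize_idq(c(9.9, 10, 15, 0))),
               c("poor", "good", "good", "poor"))
  expect_error(dichotomize_idq(16), "0, 15")
})

test_that("QUICKI follows the mg/dl base-10 convention", {
  # insulin 10 mU/l, glucose 5.0 mmol/l (~90 mg/dl): 1/(1 + log10(90.08))
  expect_equal(quicki(10, 5.0), 1 / (1 + log10(5 * 18.016)), tolerance = 1e-12)
  expect_equal(quicki(10, 5.0), 0.3385, tolerance = 2e-4)
  # unit check: insulin 1 uU/ml and glucose 10 mg/dl give exactly 1
  expect_equal(quicki(1, 10 / 18.016), 1, tolerance = 1e-12)
  expect_error(quicki(0, 5), "positive")
  expect_error(quicki(0.1, 1 / 18.016), "denominator")
})

test_that("generated cohorts land in the published QUICKI band", {
  co <- generate_cohort(234, 152, seed = 77)$cohort
  expect_gt(median(co$quicki), 0.30)
  expect_lt(median(co$quicki), 0.40)
})

test_that("quartile contrasts report the full marker-by-stratum grid", {
  sim <- simulate_small_dataset(seed = 400, n_ow = 40, n_ob = 40)
  q <- quartile_groups(sim$diversity$shannon)
  tab <- quartile_contrast(sim$cohort, q, stratum = sim$cohort$bmi_group)
  expect_equal(nrow(tab), 12L)  # 6 markers x 2 strata
  expect_true(all(tab$p_adj >= tab$p_raw))
  expect_true(all(tab$q1_n > 0 & tab$q4_n > 0))

  # an injected monotone diversity -> marker association surfaces as a
  # Q1-vs-Q4 median difference with the expected direction
  eff <- effect_registry_null()
  eff$correlations <- data.frame(stratum = "all", var1 = "insulin",
                                 var2 = "shannon", rho = 0.8)
  hits <- vapply(1:10, function(i) {
    sim <- simulate_small_dataset(seed = 500 + 13 * i, n_ow = 60, n_ob = 40,
                                  effects = eff)
    q <- quartile_groups(sim$diversity$shannon)
    tab <- quartile_contrast(sim$cohort, q)
    row <- tab[tab$marker == "insulin", ]
    row$q1_median < row$q4_median && row$tier == "significant"
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("per-taxon group comparison flags only injected shifts", {
  withr::local_seed(31)
  n <- 80
  ab <- matrix(rlnorm(n * 20), nrow = n,
               dimnames = list(NULL, paste0("t", 1:20)))
  grp <- rep(c("a", "b"), each = n / 2)

  null_res <- group_compare_taxa(ab / rowSums(ab), grp)
  expect_false(any(null_res$p_adj < 0.05))

  ab2 <- ab
  ab2[grp == "b", "t1"] <- ab2[grp == "b", "t1"] * 4
  res <- group_compare_taxa(ab2 / rowSums(ab2), grp)
  expect_lt(res$p_adj[res$taxon == "t1"], 0.05)

  # BH preserves the p-value ordering
  expect_equal(order(res$p_raw), order(res$p_adj, res$p_raw))
})

test_that("median-of-ratios size factors behave like library-size scalers", {
  m <- matrix(5L, nrow = 4, ncol = 6)
  expect_equal(unname(size_factors(m)), rep(1, 4))

  withr::local_seed(32)
  base <- matrix(rpois(5 * 30, 50) + 1L, nrow = 5)
  scaled <- rbind(base, 3L * base[1, , drop = FALSE])
  sf <- size_factors(scaled)
  expect_equal(sf[[6]] / sf[[1]], 3, tolerance = 1e-9)

  expect_error(size_factors(matrix(c(0L, 1L, 1L, 0L), 2)), "all-positive")
})

test_that("the NB test reduces to Poisson regression for equidispersed data", {
  withr::local_seed(33)
  n <- 500
  x <- rnorm(n)
  y <- rpois(n, exp(5 + 0.5 * x))
  counts <- cbind(taxon1 = y, ref = rpois(n, 100) + 1L)
  res <- nb_differential_abundance(counts, x, sf = rep(1, n))
  pois <- glm(y ~ x, family = poisson())
  expect_equal(res$log_fc[res$taxon == "taxon1"], unname(coef(pois)[2]),
               tolerance = 1e-4)
})

test_that("the NB test recovers a known covariate effect", {
  withr::local_seed(34)
  n <- 150
  x <- rnorm(n)
  mu <- exp(4 + 1.5 * x)
  counts <- cbind(hit = rnbinom(n, size = 5, mu = mu),
                  matrix(rnbinom(n * 10, size = 5, mu = 80), nrow = n,
                         dimnames = list(NULL, paste0("bg", 1:10))))
  res <- nb_differential_abundance(counts, x)
  row <- res[res$taxon == "hit", ]
  expect_true(row$converged)
  expect_lt(abs(row$log_fc - 1.5), 3 * row$se)
  expect_equal(row$log2_fc, row$log_fc / log(2))
  expect_lt(row$p_adj, 0.05)

  # prevalence filter removes near-absent taxa from the family
  counts2 <- cbind(counts, rare = ifelse(seq_len(n) <= 5, 1L, 0L))
  res2 <- nb_differential_abundance(counts2, x, min_prevalence = 0.25)
  expect_false("rare" %in% res2$taxon)
})

test_that("the result-table battery has the published shape and coherent corrections", {
  sim <- simulate_small_dataset(seed = 600, n_ow = 40, n_ob = 30)
  tabs <- replicate_result_tables(sim$cohort, sim$diversity, sim$counts,
                                  n_perm = 49, seed = 601)
  expect_equal(nrow(tabs$correlations), 36L)  # 6 markers x 2 indices x 3 strata
  expect_equal(nrow(tabs$permanova), 12L)     # 4 covariates x 3 strata
  expect_equal(nrow(tabs$quartile_shannon), 18L)
  expect_equal(nrow(tabs$quartile_richness), 18L)
  expect_equal(nrow(tabs$idq_diversity), 6L)
  for (tb in list(tabs$permanova, tabs$correlations, tabs$idq_diversity)) {
    expect_true(all(tb$p_adj >= tb$p_raw - 1e-12))
  }
  # Bonferroni family of four covariates per stratum
  expect_equal(tabs$permanova$p_adj,
               pmin(1, unlist(tapply(tabs$permanova$p_raw,
                                     tabs$permanova$stratum, function(p) 4 * p,
                                     simplify = FALSE)[c("all", "overweight", "obese")]),
                    1), ignore_attr = TRUE)
})
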