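# MGS quantification: the core-gene detection rule, length normalization
# and rarefaction.

# a small catalog whose ids are easy to address in tests
toy_catalog <- function() {
  data.frame(
    gene_id = c(paste0("a", 1:4), paste0("b", 1:4), "x1"),
    length_bp = c(1000, 1000, 1000, 1000, 2000, 2000, 2000, 2000, 500),
    mgs_id = c(rep("MGS_A", 4), rep("MGS_B", 4), NA),
    is_core = c(rep(TRUE, 3), FALSE, rep(TRUE, 3), FALSE, FALSE))
}

test_that("the detection rule zeroes MGSs with too few distinct core genes", {
  cat <- toy_catalog()
  # two distinct core genes with plenty of reads: still undetected
  mc <- mgs_counts(c(a1 = 10L, a2 = 10L), cat)
  expect_equal(unname(mc$counts[1, "MGS_A"]), 0L)
  expect_false(mc$detected[1, "MGS_A"])

  # three distinct core genes, sparse counts: detected with the full sum
  mc <- mgs_counts(c(a1 = 5L, a2 = 1L, a3 = 1L), cat)
  expect_equal(unname(mc$counts[1, "MGS_A"]), 7L)
  expect_true(mc$detected[1, "MGS_A"])

  # non-core genes never contribute
  mc <- mgs_counts(c(a4 = 50L), cat)
  expect_equal(unname(mc$counts[1, "MGS_A"]), 0L)
  mc <- mgs_counts(c(a1 = 2L, a2 = 2L, a3 = 2L, a4 = 50L), cat)
  expect_equal(unname(mc$counts[1, "MGS_A"]), 6L)

  expect_error(mgs_counts(c(zz = 1L), cat), "absent from catalog")
  expect_message(mgs_counts(c(zz = 1L, a1 = 1L), cat, unknown_genes = "ignore"),
                 "ignoring")
})

test_that("mgs_counts equals the brute-force oracle on random catalogs", {
  withr::local_seed(101)
  for (rep in 1:30) {
    n_mgs <- sample(1:10, 1)
    k_core <- sample(3:10, 1)
    cat <- generate_catalog(n_mgs, k_core,
                            n_noncore_per_mgs = sample(0:3, 1),
                            n_orphan = sample(0:5, 1))
    hit <- sample(cat$gene_id, sample(1:nrow(cat), 1))
    counts <- setNames(as.integer(rpois(length(hit), 2)), hit)
    mch <- sample(1:5, 1)
    mc <- mgs_counts(counts, cat, min_core_hits = mch)$counts
    got <- setNames(as.integer(mc[1, ]), colnames(mc))
    want <- mgs_counts_oracle(as.list(counts), cat, min_core_hits = mch)
    expect_equal(got, want)
  }
})

test_that("detection at min_core_hits = 1 reduces to plain core summation, and raising the threshold is monotone", {
  withr::local_seed(55)
  cat <- generate_catalog(5, 6, n_noncore_per_mgs = 2)
  hit <- sample(cat$gene_id, 20)
  counts <- setNames(as.integer(rpois(20, 3) + 1L), hit)
  core_sum <- mgs_counts(counts, cat, min_core_hits = 1)$counts[1, ]
  core <- cat[cat$is_core, ]
  manual <- tapply(
    vapply(core$gene_id, function(g) if (g %in% names(counts)) counts[[g]] else 0L,
           integer(1)),
    core$mgs_id, sum)
  expect_equal(core_sum, setNames(as.integer(manual), names(manual)))

  prev <- core_sum
  for (mch in 2:6) {
    cur <- mgs_counts(counts, cat, min_core_hits = mch)$counts[1, ]
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("length normalization weights counts by core-gene kilobases", {
  cat <- toy_catalog()  # core totals: A = 3 kb, B = 6 kb
  mc <- mgs_counts(c(a1 = 4L, a2 = 4L, a3 = 4L, b1 = 4L, b2 = 4L, b3 = 4L), cat)
  ab <- relative_abundance(mc, cat)
  expect_equal(unname(ab[1, ]), c(2 / 3, 1 / 3))

  # single detected MGS gets abundance 1
  mc <- mgs_counts(c(a1 = 1L, a2 = 1L, a3 = 1L), cat)
  ab <- relative_abundance(mc, cat)
  expect_equal(unname(ab[1, ]), c(1, 0))

  # undetected everywhere: zero row with a warning
  mc <- mgs_counts(c(a1 = 5L), cat)
  expect_warning(ab <- relative_abundance(mc, cat), "no detected MGS")
  expect_equal(unname(ab[1, ]), c(0, 0))

  # per-gene variant agrees for equal-length cores and still closes to 1
  pg <- mgs_profile(c(a1 = 4L, a2 = 4L, a3 = 4L, b1 = 4L, b2 = 4L, b3 = 4L),
                    cat, method = "per_gene")
  expect_equal(sum(pg[1, ]), 1)
  expect_equal(unname(pg[1, ]), c(2 / 3, 1 / 3))
})

test_that("row sums of multi-sample profiles equal one", {
  withr::local_seed(77)
  cat <- generate_catalog(6, 5)
  gc <- matrix(rpois(5 * nrow(cat), 3), nrow = 5,
               dimnames = list(paste0("s", 1:5), cat$gene_id))
  prof <- mgs_profile(gc, cat)
  expect_true(all(abs(rowSums(prof) - 1) < 1e-9))
})

test_that("rarefaction conserves depth exactly and matches the hypergeometric mean", {
  x <- c(A = 50L, B = 50L)
  # depth equal to the total: identity
  expect_equal(rarefy_counts(x, 100, seed = 1)[1, ], x)

  # depth conservation across a random matrix
  withr::local_seed(5)
  m <- matrix(rpois(60, 40), nrow = 6,
              dimnames = list(paste0("s", 1:6), paste0("g", 1:10)))
  r <- rarefy_counts(m, 100, seed = 2)
  expect_true(all(rowSums(r) == 100))
  expect_true(all(r <= m))

  # hypergeometric oracle on the mean (reduced replicate count; the full
  # 2,000-replicate check lives in the acceptance suite)
  reps <- vapply(1:400, function(i) rarefy_counts(x, 50, seed = 100 + i)[1, "A"],
                 numeric(1))
  sd_hyper <- sqrt(50 * 0.5 * 0.5 * 50 / 99)
  expect_lt(abs(mean(reps) - 25), 3 * sd_hyper / sqrt(400))

  # sub-depth samples are dropped with a warning
  expect_warning(out <- rarefy_counts(rbind(m, shallow = rep(1L, 10)), 100,
                                      seed = 3), "below depth")
  expect_false("shallow" %in% rownames(out))
  expect_error(rarefy_counts(x, 0), "depth")
})

test_that("rarefying then quantifying agrees in expectation with quantifying unrarefied data", {
  # the detection rule aside, rarefaction preserves expected proportions:
  # compare mean rarefied MGS shares against the unrarefied shares
  withr::local_seed(500)
  cat <- generate_catalog(4, 3)
  gc <- setNames(as.integer(rpois(nrow(cat), 30) + 1L), cat$gene_id)
  full <- mgs_counts(gc, cat, min_core_hits = 1)$counts[1, ]
  reps <- vapply(1:300, function(i) {
    r <- rarefy_counts(gc, 120)[1, ]
    mgs_counts(r, cat, min_core_hits = 1)$counts[1, ]
  }, numeric(length(full)))
  got <- rowMeans(reps) / 120
  want <- full / sum(gc)
  expect_lt(max(abs(got - want)), 0.03)
})
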