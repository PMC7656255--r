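test_that("fisher_exact_2x2 matches worked examples", {
  sym <- fisher_exact_2x2(5, 5, 5, 5)
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_value, 1)
  # perfectly separated 10/10 table: only the two extreme tables are as or
  # less probable, each with probability 1/C(20,10)
  sep <- fisher_exact_2x2(10, 0, 0, 10)
  expect_equal(sep$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(sep$odds_ratio, Inf)
  expect_equal(fisher_exact_2x2(20, 80, 10, 90)$odds_ratio, 2.25)
  expect_equal(fisher_exact_2x2(0, 10, 5, 5)$odds_ratio, 0)
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
})

test_that("fisher_exact_2x2 equals exhaustive hypergeometric enumeration (sampled grid)", {
  set.seed(42)
  for (rep in 1:300) {
    cells <- as.integer(rmultinom(1, sample(1:30, 1), runif(4, 0.05, 1)))
    if (sum(cells) == 0) next
    got <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got$p_value,
                 oracle_fisher_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
    # and agrees with the reference implementation in stats
    m <- matrix(cells, 2, byrow = TRUE)
    expect_equal(got$p_value, stats::fisher.test(m)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("or_confidence_interval reproduces the hand-evaluated Woolf interval", {
  ci <- or_confidence_interval(20, 80, 10, 90)
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 90)
  expect_equal(ci, exp(log(2.25) + c(-1, 1) * qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_equal(round(ci, 2), c(0.99, 5.09))
  # symmetric table: interval contains 1
  ci_sym <- or_confidence_interval(5, 5, 5, 5)
  expect_true(ci_sym[1] < 1 && ci_sym[2] > 1)
  # zero cell: Haldane-Anscombe keeps the interval finite
  ci_zero <- or_confidence_interval(10, 0, 3, 7)
  expect_true(all(is.finite(ci_zero)))
})

test_that("bh_fdr is the step-up adjustment, stable under permutation", {
  expect_equal(bh_fdr(0.03), 0.03)                    # m = 1 identity
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(9)
  p <- runif(50)
  expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  perm <- sample(50)
  q_perm <- bh_fdr(p[perm])
  expect_equal(q_perm[order(perm)], bh_fdr(p), tolerance = 1e-12)
  # q-values are monotone along the sorted-p order
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("subtype_enrichment flags a strongly enriched gene and not a flat one", {
  n_a <- 50; n_b <- 150
  samples <- make_samples(n_a + n_b,
                          subtype = c(rep("triple_negative", n_a),
                                      rep("luminal_A", n_b)))
  ids <- samples$sample_id
  som <- rbind(
    make_somatic(ids[1:30], "GENEX", pos = 1),          # 30/50 in TN
    make_somatic(ids[n_a + (1:5)], "GENEX", pos = 2),   # 5/150 elsewhere
    make_somatic(ids[c(1:10, n_a + (1:30))], "FLAT", pos = 3))
  cohort <- bc_cohort(samples, som)
  mat <- build_alteration_matrix(cohort, "gene")
  res <- subtype_enrichment(mat, samples, fdr_threshold = 0.25)
  hit <- res[res$feature == "GENEX" & res$group_label == "triple_negative", ]
  # the 2x2 cells are (a, b, c, d) = (30, 20, 5, 145); p and q recomputed
  # through the package's own Fisher/BH machinery on that family
  expect_equal(unlist(hit[, c("a", "b", "c", "d")], use.names = FALSE),
               c(30, 20, 5, 145))
  p_oracle <- oracle_fisher_p(30, 20, 5, 145)
  expect_equal(hit$p_value, p_oracle, tolerance = 1e-10)
  expect_true(hit$significant)
  flat <- res[res$feature == "FLAT" & res$group_label == "triple_negative", ]
  expect_false(flat$significant)
  # single feature, single (pairwise) family: q = p
  res1 <- subtype_enrichment(mat[, "GENEX", drop = FALSE],
                             samples[samples$subtype %in%
                                       c("triple_negative", "luminal_A"), ])
  expect_equal(res1$q_value, bh_fdr(res1$p_value))
})

test_that("cohort_compare builds 2x2s from counts and routes unshared features", {
  fa <- data.frame(feature = c("p53", "Wnt", "onlyA"),
                   n_altered = c(20, 5, 1), n_total = 100)
  fb <- data.frame(feature = c("p53", "Wnt", "onlyB"),
                   n_altered = c(5, 5, 2), n_total = 100)
  cmp <- cohort_compare(fa, fb)
  p53 <- cmp$results[cmp$results$feature == "p53", ]
  expect_equal(p53$odds_ratio, (20 * 95) / (80 * 5))  # 4.75
  expect_equal(p53$p_value, oracle_fisher_p(20, 80, 5, 95), tolerance = 1e-10)
  expect_setequal(cmp$unshared, c("onlyA", "onlyB"))
  # identical cohorts: OR 1 everywhere, nothing significant
  self <- cohort_compare(fa, fa)
  expect_true(all(self$results$odds_ratio == 1))
  expect_true(all(!self$results$significant))
  # zero-denominator features are excluded with a report
  fz <- data.frame(feature = "p53", n_altered = 0, n_total = 0)
  cmp_z <- cohort_compare(fz, fb[fb$feature == "p53", ])
  expect_equal(cmp_z$excluded, "p53")
})

test_that("covariate_enrichment excludes missing values pairwise and needs 2 groups", {
  samples <- make_samples(60, menopause = c(rep("post", 30), rep("pre", 25),
                                            rep("missing", 5)))
  mat <- matrix(0L, 60, 1, dimnames = list(samples$sample_id, "PI3Kgene"))
  mat[1:24, 1] <- 1L   # 24/30 post carriers vs 0/25 pre
  res <- covariate_enrichment(mat, samples, "menopause")
  expect_equal(attr(res, "n_missing_excluded"), 5L)
  post <- res[res$group_label == "post", ]
  expect_equal(post$a + post$b, 30)  # denominators exclude missing
  expect_true(post$significant)
  samples_all_missing <- make_samples(10, menopause = "missing")
  expect_error(covariate_enrichment(mat[1:10, , drop = FALSE],
                                    samples_all_missing, "menopause"),
               "fewer than 2")
})

test_that("FDR is controlled on null cohorts", {
  frac <- vapply(1:10, function(s) {
    mat <- null_cohort(200, 300, 0.3, seed = 1000 + s)
    half <- rownames(mat)[1:100]
    fa <- data.frame(feature = colnames(mat),
                     n_altered = colSums(mat[half, ]), n_total = 100)
    fb <- data.frame(feature = colnames(mat),
                     n_altered = colSums(mat[!rownames(mat) %in% half, ]),
                     n_total = 100)
    mean(cohort_compare(fa, fb)$results$significant)
  }, numeric(1))
  se <- stats::sd(frac) / sqrt(length(frac))
  expect_lte(mean(frac), 0.05 + 3 * se + 1e-12)
})
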