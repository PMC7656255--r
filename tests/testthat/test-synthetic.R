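test_that("cohort_spec validates its inputs and demands a seed", {
  expect_error(cohort_spec(n_samples = 10), "seed is mandatory")
  expect_error(cohort_spec(seed = 1, subtype_proportions = c(
    luminal_A = 0.5, luminal_B_HER2neg = 0.2, luminal_B_HER2pos = 0.1,
    HER2pos = 0.1, triple_negative = 0.2)), "sum to 1")
})

test_that("generation is deterministic: same spec and seed give identical cohorts and files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  c1 <- simulate_cohort(d1, seed = 33, n_samples = 100)
  c2 <- simulate_cohort(d2, seed = 33, n_samples = 100)
  expect_identical(c1$somatic, c2$somatic)
  expect_identical(c1$samples, c2$samples)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(unname(tools::md5sum(sort(f1))),
                   unname(tools::md5sum(sort(f2))))
  # a different seed changes the cohort
  c3 <- generate_cohort(cohort_spec(n_samples = 100, seed = 34))
  expect_false(identical(c1$somatic, c3$somatic))
})

test_that("generated clinical covariates respect the subtype derivation invariant", {
  cohort <- generate_cohort(tiny_spec(seed = 3, n = 200))
  s <- cohort$samples
  ok <- !is.na(s$ki67_fraction) | !(s$er_positive | s$pr_positive) |
    s$her2_positive
  expect_true(all(ok))
  expect_equal(derive_subtype(s$er_positive, s$pr_positive, s$her2_positive,
                              s$ki67_fraction), s$subtype)
  expect_equal(coarse_subtype(s$subtype), s$coarse_subtype)
})

test_that("per-gene marginal frequencies are recovered within binomial bands", {
  spec <- cohort_spec(n_samples = 1134, seed = 88)
  cohort <- generate_cohort(spec)
  cohort$somatic <- pon_filter(cohort$somatic, attr(cohort, "pon"), 0)$kept
  truth <- attr(cohort, "true_gene_freq")
  f <- gene_frequency(cohort, genes = names(truth))
  inside <- vapply(names(truth), function(g) {
    x <- f$n_altered[f$feature == g]
    ci <- stats::binom.test(x, 1134, conf.level = 0.99)$conf.int
    truth[g] >= ci[1] && truth[g] <= ci[2]
  }, logical(1))
  expect_gte(mean(inside), 0.95)
})

test_that("injected coupling is realised in the generated indicators", {
  # full exclusivity: ARID1A/PTEN never co-mutated, in every seed
  for (s in 1:5) {
    cohort <- generate_cohort(tiny_spec(seed = 400 + s, n = 300))
    mat <- build_alteration_matrix(cohort, "gene")
    if (all(c("ARID1A", "PTEN") %in% colnames(mat))) {
      expect_equal(sum(mat[, "ARID1A"] & mat[, "PTEN"]), 0)
    }
  }
  # infeasible coupling errors with the pair named
  bad <- cohort_spec(n_samples = 50, seed = 1,
                     gene_freqs = data.frame(
                       gene = c("G1", "G2"), luminal_A = 0.9,
                       luminal_B_HER2neg = 0.9, luminal_B_HER2pos = 0.9,
                       HER2pos = 0.9, triple_negative = 0.9),
                     hotspots = default_hotspots()[0, ],
                     coupling = data.frame(gene_i = "G1", gene_j = "G2",
                                           odds_ratio = 0),
                     cnv_freqs = default_cnv_freqs()[0, ],
                     germline_counts = default_germline_counts()[0, ],
                     pon_artifacts = 0)
  expect_error(generate_cohort(bad), "infeasible coupling.*G1-G2")
})

test_that("make_reference_cohort rounds counts as documented", {
  rf <- make_reference_cohort(data.frame(feature = c("a", "b", "c"),
                                         frequency = c(0.31, 0, 1)), 869)
  expect_equal(rf$n_altered, c(269L, 0L, 869L))
  expect_equal(rf$n_total, rep(869L, 3))
})

test_that("null_cohort has no structure and honours edge frequencies", {
  expect_true(all(null_cohort(20, 5, 0, seed = 1) == 0))
  expect_true(all(null_cohort(20, 5, 1, seed = 1) == 1))
  m <- null_cohort(200, 50, 0.3, seed = 12)
  # column means inside the 99.9% binomial band around 0.3
  band <- stats::qbinom(c(5e-4, 1 - 5e-4), 200, 0.3) / 200
  cm <- colMeans(m)
  expect_true(all(cm >= band[1] & cm <= band[2]))
})

test_that("germline layer realises the configured carrier structure", {
  spec <- cohort_spec(n_samples = 1134, seed = 55)
  cohort <- generate_cohort(spec)
  ctx <- attr(cohort, "gene_context")
  pf <- prefilter_rare(cohort$germline)
  cls <- classify_germline(score_evidence(pf$kept, ctx))
  cs <- carrier_summary(cls, 1134)
  expect_equal(cs$n_carriers, 66)
  expect_equal(cs$pct, 5.8)
  expect_equal(cs$per_gene$n_patients[cs$per_gene$gene_symbol == "BRCA1"], 22L)
  # common benign background is removed by the prefilter, never classified P/LP
  expect_true(all(pf$removed$af_eas >= 0.005))
})
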