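test_that("prefilter_rare applies the strict 0.5% East-Asian rule", {
  v <- make_germline(sprintf("P%d", 1:4), "BRCA1",
                     af_eas = c(0.006, 0.004, 0.005, NA))
  res <- prefilter_rare(v)
  expect_equal(res$removed$af_eas, c(0.006, 0.005))  # >= threshold removed
  expect_true(0.004 %in% res$kept$af_eas)            # strictly rare kept
  expect_true(any(is.na(res$kept$af_eas)))           # missing AF kept
  expect_equal(attr(res$kept, "n_missing_af"), 1L)
  # prefilter-then-score is invariant to input shuffling
  ctx <- make_gene_context("BRCA1")
  set.seed(4)
  shuf <- v[sample(nrow(v)), ]
  a <- classify_germline(score_evidence(prefilter_rare(v)$kept, ctx))
  b <- classify_germline(score_evidence(prefilter_rare(shuf)$kept, ctx))
  b <- b[match(a$pos, b$pos), ]
  expect_equal(a$classification, b$classification, ignore_attr = TRUE)
})

test_that("evidence scoring applies PVS1/PS1/PM4/PM5 and never PM2", {
  ctx <- make_gene_context(c("BRCA1", "TP53"), is_cancer_gene = TRUE,
                           lof_mechanism = TRUE)
  # frameshift in a LOF-mechanism cancer gene: PVS1 fires, score >= 8
  v1 <- score_evidence(make_germline("P1", "BRCA1", "frameshift"), ctx)
  expect_equal(v1$evidence, "PVS1")
  expect_gte(v1$score, 8)
  # missense without any ClinVar relation: no evidence
  v2 <- score_evidence(make_germline("P1", "BRCA1", "missense"), ctx)
  expect_equal(v2$evidence, "")
  expect_equal(v2$score, 0)
  # novel missense at a residue with a known cancer pathogenic missense:
  # PM5 (2 points) fires, PS1 does not
  v3 <- score_evidence(make_germline("P1", "TP53", "missense",
                                     same_residue = TRUE), ctx)
  expect_equal(v3$evidence, "PM5")
  expect_equal(v3$score, 2)
  # same amino-acid change: PS1 (7) supersedes PM5
  v4 <- score_evidence(make_germline("P1", "TP53", "missense",
                                     same_aa = TRUE, same_residue = TRUE), ctx)
  expect_equal(v4$evidence, "PS1")
  expect_equal(v4$score, 7)
  # inframe event: PM4
  v5 <- score_evidence(make_germline("P1", "BRCA1", "inframe_indel"), ctx)
  expect_equal(v5$evidence, "PM4")
  # unknown consequence contributes nothing and is counted
  v6 <- score_evidence(make_germline("P1", "BRCA1", "odd_string"), ctx)
  expect_equal(v6$score, 0)
  expect_equal(attr(v6, "n_unknown_consequence"), 1L)
})

test_that("classification uses ClinVar for pathogenic and a strict score cut for LP", {
  ctx <- make_gene_context("BRCA1")
  # known cancer pathogenic with zero score is still pathogenic
  v <- classify_germline(score_evidence(
    make_germline("P1", "BRCA1", "missense",
                  clinvar_status = "pathogenic_cancer"), ctx))
  expect_equal(v$classification, "pathogenic")
  # score 8, unreported: likely pathogenic
  v <- classify_germline(score_evidence(
    make_germline("P1", "BRCA1", "frameshift"), ctx))
  expect_equal(v$classification, "likely_pathogenic")
  # score exactly 7 stays uncertain (strict inequality)
  v <- classify_germline(score_evidence(
    make_germline("P1", "BRCA1", "missense", same_aa = TRUE), ctx))
  expect_equal(v$score, 7)
  expect_equal(v$classification, "uncertain")
  # monotone in score: raising the score never demotes the class
  expect_equal(classify_germline(data.frame(score = c(0, 7, 7.5, 8, 20),
                                            clinvar_status = "unreported"))$classification,
               c("uncertain", "uncertain", "likely_pathogenic",
                 "likely_pathogenic", "likely_pathogenic"))
})

test_that("golden set of 20 constructed variants classifies exactly as hand-derived", {
  gs <- golden_germline_set()
  out <- classify_germline(score_evidence(gs$variants, gs$context))
  expect_equal(out$classification, gs$expected)
  # the population-rarity module is disabled: PM2 never appears
  expect_false(any(grepl("PM2", out$evidence)))
})

test_that("carrier_summary counts patients, not variants", {
  v <- classify_germline(score_evidence(
    make_germline(c("P1", "P1", "P2", "P3"),
                  c("BRCA1", "TP53", "BRCA1", "CHEK2"),
                  consequence = "frameshift"),
    make_gene_context(c("BRCA1", "TP53", "CHEK2"))))
  cs <- carrier_summary(v, n_patients = 10)
  expect_equal(cs$n_carriers, 3)             # P1 counts once overall
  expect_equal(cs$per_gene$n_patients[cs$per_gene$gene_symbol == "BRCA1"], 2L)
  expect_equal(cs$per_gene$n_patients[cs$per_gene$gene_symbol == "TP53"], 1L)
  # headline arithmetic at the reference scale
  expect_equal(round(100 * 66 / 1134, 1), 5.8)
  empty <- carrier_summary(v[0, ], 10)
  expect_equal(empty$pct, 0)
})

test_that("population comparison matches the hand-computed chi-square", {
  freqs <- data.frame(gene = "BRCA2",
                      population = c("chinese", "caucasian", "african_american"),
                      n_carriers = c(5, 23, 10),
                      n_total = c(1134, 1122, 515))
  res <- germline_cohort_compare(freqs)
  tab <- rbind(freqs$n_carriers, freqs$n_total - freqs$n_carriers)
  if (res$method == "chisq") {
    expect_equal(res$p_value, oracle_chisq(tab)$p_value, tolerance = 1e-10)
  }
  expect_lt(res$p_value, 0.05)
  # identical frequencies: p near 1
  same <- data.frame(gene = "CHEK2", population = c("a", "b", "c"),
                     n_carriers = c(10, 10, 10), n_total = c(1000, 1000, 1000))
  expect_gt(germline_cohort_compare(same)$p_value, 0.99)
  expect_error(germline_cohort_compare(same[1, ]), ">= 2 populations")
  bad <- same; bad$n_total[2] <- 0
  expect_error(germline_cohort_compare(bad), "n_total = 0")
})
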