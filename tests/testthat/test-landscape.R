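test_that("gene_frequency uses group sizes as denominators and keeps zero rows", {
  samples <- make_samples(6, subtype = c(rep("luminal_A", 3),
                                         rep("triple_negative", 3)))
  som <- make_somatic(c("S001", "S002", "S004", "S004"),
                      c("TP53", "TP53", "TP53", "PIK3CA"), pos = 1:4)
  cohort <- bc_cohort(samples, som)
  f <- gene_frequency(cohort)
  expect_equal(f$n_total, rep(6L, 2))
  expect_equal(f$frequency[f$feature == "TP53"], 3 / 6)
  # requested gene with no carriers is retained at frequency zero
  f0 <- gene_frequency(cohort, genes = c("TP53", "PIK3CA", "ESR1"))
  expect_equal(f0$frequency[f0$feature == "ESR1"], 0)
  # grouped: denominators are subtype sizes
  fs <- gene_frequency(cohort, "subtype")
  tp53_tn <- fs[fs$feature == "TP53" & fs$group == "triple_negative", ]
  expect_equal(tp53_tn$n_altered, 1L)
  expect_equal(tp53_tn$n_total, 3L)
  # one-subtype cohort: grouping is the same as ungrouped
  cohort_la <- bc_cohort(samples[1:3, ], som[1:2, ])
  fa <- gene_frequency(cohort_la, "none")
  fb <- gene_frequency(cohort_la, "subtype")
  expect_equal(fa$frequency, fb$frequency)
  expect_error(gene_frequency(bc_cohort(samples[0, ], som[0, ])), "empty")
  # headline arithmetic: 601 carriers of 1134 is 53.0% at one decimal
  expect_equal(round(100 * 601 / 1134, 1), 53.0)
})

test_that("frequencies are invariant under input row permutation", {
  spec <- tiny_spec(seed = 5, n = 80)
  cohort <- generate_cohort(spec)
  f1 <- gene_frequency(cohort)
  set.seed(1)
  cohort2 <- cohort
  cohort2$somatic <- cohort$somatic[sample(nrow(cohort$somatic)), ]
  f2 <- gene_frequency(cohort2)
  expect_equal(f1, f2, ignore_attr = TRUE)
})

test_that("detect_hotspots applies the distinct-sample rule and threshold", {
  mut <- make_somatic(
    c(sprintf("S%03d", 1:30), "S001", sprintf("S%03d", 1:10)),
    c(rep("PIK3CA", 31), rep("TP53", 10)),
    protein_change = c(rep("p.H1047R", 31), rep("p.R175H", 10)),
    pos = 1)
  hs <- detect_hotspots(mut, n_samples = 1000, min_frequency = 0.02)
  # duplicate call in S001 counts once: 30 distinct carriers -> 3%
  expect_equal(nrow(hs), 1)
  expect_equal(hs$n_samples, 30L)
  expect_equal(hs$frequency, 0.03)
  # 10/1000 = 1% stays below the threshold
  expect_false("p.R175H" %in% hs$protein_change)
  # monotonicity: the hotspot set shrinks as the threshold rises
  h1 <- detect_hotspots(mut, 1000, 0.005)
  h2 <- detect_hotspots(mut, 1000, 0.02)
  expect_true(all(paste(h2$gene_symbol, h2$protein_change) %in%
                    paste(h1$gene_symbol, h1$protein_change)))
  # missing protein changes are skipped with a logged count
  mut2 <- rbind(mut, make_somatic("S500", "GATA3", protein_change = NA))
  h3 <- detect_hotspots(mut2, 1000, 0.02)
  expect_equal(attr(h3, "n_missing_protein_change"), 1L)
})

test_that("hotspot ordering is frequency-descending with lexicographic ties", {
  mut <- make_somatic(
    c(sprintf("A%02d", 1:5), sprintf("B%02d", 1:5), sprintf("C%02d", 1:9)),
    c(rep("TP53", 5), rep("AKT1", 5), rep("PIK3CA", 9)),
    protein_change = c(rep("p.R175H", 5), rep("p.E17K", 5),
                       rep("p.H1047R", 9)), pos = 1)
  hs <- detect_hotspots(mut, 100, 0.02)
  expect_equal(hs$gene_symbol, c("PIK3CA", "AKT1", "TP53"))
})

test_that("mutation_load counts per sample and compares groups by Kruskal-Wallis", {
  samples <- make_samples(6, subtype = c(rep("luminal_A", 3),
                                         rep("triple_negative", 3)))
  # {1,1,1} vs {10,10,10}: statistic must match the hand-evaluated
  # tie-corrected H
  som <- make_somatic(
    c("S001", "S002", "S003", rep(c("S004", "S005", "S006"), each = 10)),
    "TP53", pos = 1:33)
  cohort <- bc_cohort(samples, som)
  ml <- mutation_load(cohort)
  expect_equal(sort(ml$per_sample$n_mutations), c(1, 1, 1, 10, 10, 10))
  oracle <- oracle_kw(ml$per_sample$n_mutations, ml$per_sample$group)
  expect_equal(ml$statistic, oracle$statistic, tolerance = 1e-12)
  expect_equal(ml$p_value, oracle$p_value, tolerance = 1e-12)
  # identical count distributions: p = 1 under tie handling
  som_eq <- make_somatic(rep(sprintf("S%03d", 1:6), each = 2), "TP53",
                         pos = 1:12)
  ml_eq <- mutation_load(bc_cohort(samples, som_eq))
  expect_equal(ml_eq$p_value, 1)
  # single group: comparison marked not applicable
  ml_one <- mutation_load(bc_cohort(samples[1:3, ], som[1:3, ]))
  expect_true(is.na(ml_one$p_value))
  expect_equal(ml_one$comparison, "not applicable")
  expect_error(mutation_load(bc_cohort(make_samples(0), som[0, ])), "empty")
})

test_that("vaf_summary reports quartiles and the across-gene H test", {
  mut <- make_somatic(sprintf("S%03d", 1:9),
                      rep(c("PIK3CA", "TP53", "GATA3"), each = 3),
                      t_alt_count = c(10, 30, 50, 10, 30, 50, 20, 40, 60),
                      t_ref_count = c(90, 70, 50, 90, 70, 50, 80, 60, 40),
                      pos = 1:9)
  vs <- vaf_summary(mut, c("PIK3CA", "TP53", "GATA3"))
  expect_equal(vs$summary$median[vs$summary$gene_symbol == "PIK3CA"], 0.3)
  oracle <- oracle_kw(mut$vaf, mut$gene_symbol)
  expect_equal(vs$statistic, oracle$statistic, tolerance = 1e-12)
  expect_equal(vs$p_value, oracle$p_value, tolerance = 1e-12)
  # identical VAF multisets across genes: p = 1
  vs_eq <- vaf_summary(mut[1:6, ], c("PIK3CA", "TP53"))
  expect_equal(vs_eq$p_value, 1)
  # a gene with no calls is excluded from the test but listed empty
  vs0 <- vaf_summary(mut, c("PIK3CA", "TP53", "ESR1"))
  expect_equal(vs0$summary$n[vs0$summary$gene_symbol == "ESR1"], 0L)
})

test_that("cnv_frequency uses the CNV-evaluable denominator", {
  samples <- make_samples(10)
  cnv <- data.frame(sample_id = sprintf("S%03d", 1:2),
                    gene_symbol = "ERBB2", call = "amplification",
                    stringsAsFactors = FALSE)
  cohort <- bc_cohort(samples, make_somatic("S001", "TP53"), cnv = cnv,
                      cnv_evaluable = sprintf("S%03d", 1:8))
  cf <- cnv_frequency(cohort)
  amp <- cf[cf$call == "amplification" & cf$feature == "ERBB2", ]
  expect_equal(amp$n_total, 8L)   # evaluable subset, not cohort size
  expect_equal(amp$frequency, 0.25)
  # deletion row for the same gene exists at frequency 0
  del <- cf[cf$call == "deletion" & cf$feature == "ERBB2", ]
  expect_equal(del$frequency, 0)
})
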