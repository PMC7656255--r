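test_that("load_catalog validates names, dedupes and keeps off-panel genes", {
  cat9 <- load_catalog()
  expect_length(cat9, 9)
  expect_setequal(names(cat9), pathway_names())
  expect_true("TP53" %in% cat9$p53)
  expect_true(all(lengths(cat9) > 0))
  # a gene may belong to multiple pathways
  expect_true("CDKN2A" %in% cat9$cell_cycle && "CDKN2A" %in% cat9$p53)

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pathway\tgene", "p53\tTP53", "p53\tTP53", "Hippo\tNF2",
               "cell_cycle\tRB1", "Notch\tNOTCH1", "PI3K\tPIK3CA",
               "Wnt\tAPC", "RTK_RAS\tKRAS", "TGF_beta\tSMAD4", "Myc\tMYC"),
             path)
  cat2 <- load_catalog(path, panel_genes = c("TP53", "NF2"))
  expect_equal(attr(cat2, "n_duplicates"), 1L)
  expect_true("RB1" %in% attr(cat2, "off_panel_genes"))
  writeLines(c("pathway\tgene", "WNT5\tAPC"), path)
  expect_error(load_catalog(path), "unknown pathway.*WNT5")
})

test_that("pathway_matrix propagates memberships and is monotone", {
  genes <- c("TP53", "PIK3CA", "CDKN2A")
  mat <- matrix(0L, 3, 3, dimnames = list(c("S1", "S2", "S3"), genes))
  mat["S1", "TP53"] <- 1L
  mat["S3", "CDKN2A"] <- 1L
  cat9 <- load_catalog()
  pm <- pathway_matrix(mat, cat9)
  expect_equal(pm["S1", "p53"], 1L)
  expect_equal(sum(pm["S1", ]), 1L)          # single membership, one pathway
  expect_equal(sum(pm["S2", ]), 0L)          # all-zero row preserved
  # CDKN2A sits in both cell_cycle and p53
  expect_equal(pm["S3", "cell_cycle"], 1L)
  expect_equal(pm["S3", "p53"], 1L)
  # monotonicity: adding an alteration never unsets a pathway cell
  mat2 <- mat; mat2["S2", "PIK3CA"] <- 1L
  pm2 <- pathway_matrix(mat2, cat9)
  expect_true(all(pm2 >= pm))
})

test_that("pathway frequency dominates member-gene frequency", {
  spec <- tiny_spec(seed = 21, n = 120)
  cohort <- generate_cohort(spec)
  gmat <- build_alteration_matrix(cohort, "gene")
  cat9 <- load_catalog()
  pm <- pathway_matrix(gmat, cat9)
  pf <- pathway_frequency(pm, cohort$samples, "none")
  gf <- gene_frequency(cohort)
  for (pw in pathway_names()) {
    members <- intersect(cat9[[pw]], gf$feature)
    if (length(members) == 0) next
    expect_gte(pf$frequency[pf$feature == pw] + 1e-12,
               max(gf$frequency[gf$feature %in% members]))
  }
})

test_that("pairwise_association caps log-OR and labels patterns", {
  n <- 60
  mat <- matrix(0L, n, 4,
                dimnames = list(sprintf("S%02d", 1:n),
                                c("excl_a", "excl_b", "nest_a", "nest_b")))
  mat[1:25, "excl_a"] <- 1L
  mat[26:50, "excl_b"] <- 1L       # common but never together
  mat[1:20, "nest_a"] <- 1L
  mat[1:20, "nest_b"] <- 1L        # identical carriers
  res <- pairwise_association(mat, fdr_threshold = 0.05)
  excl <- res[res$feature_i == "excl_a" & res$feature_j == "excl_b", ]
  expect_equal(excl$n11, 0L)
  expect_equal(excl$odds_ratio, 0)
  expect_equal(excl$log10_or, -3)
  expect_equal(excl$pattern, "mutually_exclusive")
  nest <- res[res$feature_i == "nest_a" & res$feature_j == "nest_b", ]
  expect_equal(nest$odds_ratio, Inf)
  expect_equal(nest$log10_or, 3)
  expect_equal(nest$pattern, "co_occurring")
  # p-values agree with the enumeration oracle on every pair
  for (k in seq_len(nrow(res))) {
    expect_equal(res$p_value[k],
                 oracle_fisher_p(res$n11[k], res$n10[k],
                                 res$n01[k], res$n00[k]),
                 tolerance = 1e-10)
  }
  # q over all pairs as one family
  expect_equal(res$q_value, bh_fdr(res$p_value))
})

test_that("degenerate features are skipped and independence yields 'none'", {
  mat <- null_cohort(50, 3, 0.4, seed = 3)
  mat[, 3] <- 1L   # altered in all samples: degenerate margin
  colnames(mat)[3] <- "allalt"
  res <- pairwise_association(mat)
  expect_equal(attr(res, "skipped_features"), "allalt")
  expect_false("allalt" %in% c(res$feature_i, res$feature_j))
  # independent 30% features at n = 200: pattern 'none' for >= 95% of
  # pairs across seeds
  labels <- unlist(lapply(1:20, function(s) {
    m <- null_cohort(200, 6, 0.3, seed = 7000 + s)
    pairwise_association(m)$pattern
  }))
  expect_gte(mean(labels == "none"), 0.95)
  expect_error(pairwise_association(mat[, 1, drop = FALSE]), ">= 2 features")
})

test_that("disjoint carrier sets reproduce full mutual exclusivity (ARID1A/PTEN style)", {
  samples <- make_samples(100)
  ids <- samples$sample_id
  som <- rbind(make_somatic(ids[1:30], "ARID1A", pos = 1),
               make_somatic(ids[31:55], "PTEN", pos = 2))
  cohort <- bc_cohort(samples, som)
  mat <- build_alteration_matrix(cohort, "gene")
  res <- pairwise_association(mat)
  row <- res[res$feature_i == "ARID1A" & res$feature_j == "PTEN", ]
  expect_equal(row$n11, 0L)
  expect_equal(row$odds_ratio, 0)
})

test_that("cooccurrence_adjacency counts co-altered samples per pathway pair", {
  pm <- matrix(c(1L, 1L, 0L,
                 1L, 0L, 0L,
                 0L, 1L, 1L), nrow = 3, byrow = TRUE,
               dimnames = list(c("S1", "S2", "S3"), c("p53", "PI3K", "Wnt")))
  adj <- cooccurrence_adjacency(pm)
  expect_equal(adj$n_co_altered[adj$pathway_i == "p53" & adj$pathway_j == "PI3K"], 1)
  expect_equal(adj$n_co_altered[adj$pathway_i == "PI3K" & adj$pathway_j == "Wnt"], 1)
  expect_equal(nrow(adj), 3)
})
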