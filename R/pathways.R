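#' Canonical oncogenic pathway names
#' @return Character vector of the nine pathway names.
#' @export
pathway_names <- function() {
  c("cell_cycle", "Hippo", "Notch", "PI3K", "Wnt", "RTK_RAS",
    "p53", "TGF_beta", "Myc")
}

#' Load a pathway catalog
#'
#' TSV with columns `pathway`, `gene`.  Exactly the nine canonical
#' oncogenic signalling pathways are allowed; a gene may belong to several
#' pathways; duplicate rows are deduplicated (count recorded in the
#' `n_duplicates` attribute).  Genes outside the sequencing panel are
#' retained — they simply never match an alteration — and are listed in
#' the `off_panel_genes` attribute when a panel is supplied.
#'
#' The default catalog shipped with the package
#' (`system.file("extdata", "pathway_catalog.tsv", package = "bcpanel")`)
#' is a curated membership table for the nine pathways restricted to genes
#' commonly found on breast-cancer panels; it is replaceable input, not a
#' fixed constant.
#'
#' @param path Catalog TSV; defaults to the shipped catalog.
#' @param panel_genes Optional character vector of panel genes.
#' @return Named list mapping pathway name to character vector of genes.
#' @export
load_catalog <- function(path = system.file("extdata", "pathway_catalog.tsv",
                                            package = "bcpanel"),
                         panel_genes = NULL) {
  raw <- read_tsv_meta(path)
  require_columns(raw, c("pathway", "gene"), "pathway catalog")
  bad <- setdiff(unique(raw$pathway), pathway_names())
  if (length(bad) > 0) {
    stop("load_catalog: unknown pathway name(s): ", paste(bad, collapse = ", "))
  }
  n_dup <- sum(duplicated(raw[, c("pathway", "gene")]))
  raw <- unique(raw[, c("pathway", "gene")])
  cat <- split(raw$gene, factor(raw$pathway, levels = pathway_names()))
  cat <- lapply(cat, sort)
  if (any(lengths(cat) == 0)) {
    stop("load_catalog: empty pathway(s): ",
         paste(names(cat)[lengths(cat) == 0], collapse = ", "))
  }
  attr(cat, "n_duplicates") <- n_dup
  if (!is.null(panel_genes)) {
    attr(cat, "off_panel_genes") <- sort(setdiff(raw$gene, panel_genes))
  }
  cat
}

#' Collapse a gene-level matrix to pathway level
#'
#' A pathway cell is 1 iff at least one member gene cell is 1; genes
#' belonging to several pathways contribute to each.  The operation is
#' monotone: adding a gene alteration can never unset a pathway cell.
#'
#' @param gene_matrix Binary samples x genes matrix.
#' @param catalog Pathway catalog from [load_catalog()].
#' @return Binary samples x pathways matrix (all nine pathways as columns).
#' @export
pathway_matrix <- function(gene_matrix, catalog) {
  out <- sapply(names(catalog), function(pw) {
    members <- intersect(catalog[[pw]], colnames(gene_matrix))
    if (length(members) == 0) return(rep(0L, nrow(gene_matrix)))
    as.integer(rowSums(gene_matrix[, members, drop = FALSE]) > 0)
  })
  out <- matrix(as.integer(out), nrow = nrow(gene_matrix),
                dimnames = list(rownames(gene_matrix), names(catalog)))
  out
}

#' Pairwise mutual exclusivity / co-occurrence analysis
#'
#' For every unordered pair of features in a binary alteration matrix,
#' builds the joint-presence 2x2 table, tests association by two-sided
#' Fisher's exact test and adjusts over all pairs as one BH family.  The
#' odds ratio `(n11 * n00) / (n10 * n01)` is reported with `log10_or`
#' capped to +/- `log10_cap` when a cell is zero, so downstream colour
#' scales stay finite.  Significant pairs (q below `fdr_threshold`) are
#' labelled `co_occurring` when OR > 1 and `mutually_exclusive` when
#' OR < 1; all other pairs are labelled `none`.  Features altered in zero
#' or all samples have a degenerate margin and are skipped; they are
#' listed in the `skipped_features` attribute.
#'
#' @param matrix Binary samples x features matrix with >= 2 features.
#' @param fdr_threshold FDR threshold for pattern assignment, default 0.05.
#' @param log10_cap Cap for `log10_or`, default 3.
#' @return Data frame with one row per tested pair: `feature_i`,
#'   `feature_j`, `n11`, `n10`, `n01`, `n00`, `odds_ratio`, `log10_or`,
#'   `p_value`, `q_value`, `pattern`.
#' @export
pairwise_association <- function(matrix, fdr_threshold = 0.05, log10_cap = 3) {
  if (ncol(matrix) < 2) stop("pairwise_association: need >= 2 features")
  cs <- colSums(matrix)
  degenerate <- colnames(matrix)[cs == 0 | cs == nrow(matrix)]
  feats <- setdiff(colnames(matrix), degenerate)
  pairs <- if (length(feats) >= 2) utils::combn(feats, 2) else
    matrix(character(), nrow = 2)
  n_pairs <- ncol(pairs)
  out <- data.frame(feature_i = character(n_pairs),
                    feature_j = character(n_pairs),
                    n11 = integer(n_pairs), n10 = integer(n_pairs),
                    n01 = integer(n_pairs), n00 = integer(n_pairs),
                    odds_ratio = numeric(n_pairs),
                    log10_or = numeric(n_pairs),
                    p_value = numeric(n_pairs),
                    stringsAsFactors = FALSE)
  for (k in seq_len(n_pairs)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    xi <- matrix[, i] == 1; xj <- matrix[, j] == 1
    n11 <- sum(xi & xj); n10 <- sum(xi & !xj)
    n01 <- sum(!xi & xj); n00 <- sum(!xi & !xj)
    ft <- fisher_exact_2x2(n11, n10, n01, n00)
    l10 <- if (is.nan(ft$odds_ratio)) NA_real_
           else if (ft$odds_ratio == 0) -log10_cap
           else if (is.infinite(ft$odds_ratio)) log10_cap
           else max(-log10_cap, min(log10_cap, log10(ft$odds_ratio)))
    out[k, c("feature_i", "feature_j")] <- c(i, j)
    out[k, c("n11", "n10", "n01", "n00")] <- c(n11, n10, n01, n00)
    out$odds_ratio[k] <- ft$odds_ratio
    out$log10_or[k] <- l10
    out$p_value[k] <- ft$p_value
  }
  out$q_value <- bh_fdr(out$p_value)
  out$pattern <- "none"
  sig <- out$q_value < fdr_threshold
  out$pattern[sig & out$odds_ratio > 1] <- "co_occurring"
  out$pattern[sig & out$odds_ratio < 1] <- "mutually_exclusive"
  attr(out, "skipped_features") <- degenerate
  out
}

#' Pathway alteration frequencies
#'
#' [gene_frequency()]-style table on a pathway-level matrix.
#'
#' @param pw_matrix Binary samples x pathways matrix.
#' @param samples Clinical data frame.
#' @param group_by Grouping, as in [gene_frequency()].
#' @return Frequency data frame.
#' @export
pathway_frequency <- function(pw_matrix, samples,
                              group_by = c("none", "subtype", "coarse_subtype",
                                           "stage", "cohort_arm")) {
  group_by <- match.arg(group_by)
  long <- matrix_to_long(pw_matrix)
  frequency_core(long$sample_id, long$feature, samples, group_by,
                 features = colnames(pw_matrix))
}

#' Pathway co-alteration adjacency
#'
#' Circos-ready adjacency: for each unordered pathway pair, the number of
#' samples altered in both.
#'
#' @param pw_matrix Binary samples x pathways matrix.
#' @return Data frame `pathway_i`, `pathway_j`, `n_co_altered`.
#' @export
cooccurrence_adjacency <- function(pw_matrix) {
  pairs <- utils::combn(colnames(pw_matrix), 2)
  data.frame(
    pathway_i = pairs[1, ],
    pathway_j = pairs[2, ],
    n_co_altered = apply(pairs, 2, function(p)
      sum(pw_matrix[, p[1]] == 1 & pw_matrix[, p[2]] == 1)),
    stringsAsFactors = FALSE)
}
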