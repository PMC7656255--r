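#' Clinical actionability evidence levels
#'
#' OncoKB-style tiers in decreasing clinical significance: L1
#' (FDA-recognised biomarker of response to an approved therapy), L2A/L2B
#' (standard-of-care evidence in the same / a different tumour type),
#' L3A/L3B (clinical evidence for investigational agents, same / different
#' tumour type), L4 (biological evidence).
#'
#' @return Character vector ordered from most to least significant.
#' @export
actionability_levels <- function() {
  c("L1", "L2A", "L2B", "L3A", "L3B", "L4")
}

#' Load an actionability knowledge base
#'
#' TSV columns: `gene_symbol`, `alteration_matcher` (one of
#' `any_oncogenic`, `exact_protein_change`, `truncating`,
#' `amplification`), `protein_change` (required for
#' `exact_protein_change`), `tumor_context` (`breast` or `other`),
#' `level` (see [actionability_levels()]), `drugs` (comma-separated) and
#' optionally `oncogenic_classes`, the per-gene allowlist of variant
#' classes that qualify for `any_oncogenic` matching (defaults to all
#' non-silent classes).  Distinct gene and drug counts are recorded in the
#' `audit` attribute for bookkeeping against the source knowledge base.
#'
#' @param path KB TSV; defaults to the curated breast-cancer table shipped
#'   with the package, seeded from well-established drug-gene pairs.
#' @return Data frame of records with a parsed `drug_list` column.
#' @export
load_kb <- function(path = system.file("extdata", "actionability_kb.tsv",
                                       package = "bcpanel")) {
  raw <- read_tsv_meta(path)
  require_columns(raw, c("gene_symbol", "alteration_matcher", "tumor_context",
                         "level", "drugs"), "actionability KB")
  bad <- setdiff(unique(raw$level), actionability_levels())
  if (length(bad) > 0) {
    stop("load_kb: unknown level string(s): ", paste(bad, collapse = ", "))
  }
  matchers <- c("any_oncogenic", "exact_protein_change", "truncating",
                "amplification")
  bad <- setdiff(unique(raw$alteration_matcher), matchers)
  if (length(bad) > 0) {
    stop("load_kb: unknown alteration_matcher(s): ", paste(bad, collapse = ", "))
  }
  if (!"protein_change" %in% names(raw)) raw$protein_change <- NA_character_
  need_pc <- raw$alteration_matcher == "exact_protein_change"
  if (any(need_pc & (is.na(raw$protein_change) | raw$protein_change == ""))) {
    stop("load_kb: exact_protein_change records must carry a protein_change")
  }
  if (!"oncogenic_classes" %in% names(raw)) raw$oncogenic_classes <- NA_character_
  raw$drug_list <- strsplit(as.character(raw$drugs), ",", fixed = TRUE)
  raw$record_id <- seq_len(nrow(raw))
  attr(raw, "audit") <- list(
    n_genes = length(unique(raw$gene_symbol)),
    n_drugs = length(unique(trimws(unlist(raw$drug_list)))))
  raw
}

#' Match alterations against the knowledge base
#'
#' One row per (alteration, KB record) match with provenance:
#' `exact_protein_change` matches on (gene, protein change); `truncating`
#' matches nonsense/frameshift/splice-site calls; `any_oncogenic` matches
#' the record's allowlisted non-silent classes in the gene; `amplification`
#' matches CNV amplification calls.
#'
#' @param somatic Somatic mutation data frame.
#' @param cnv CNV call data frame (or `NULL`).
#' @param kb Knowledge base from [load_kb()].
#' @return Data frame of matches (`sample_id`, `alteration`, `gene_symbol`,
#'   `matcher`, `level`, `drugs`, `record_id`).
#' @export
match_alterations <- function(somatic, cnv, kb) {
  matches <- list()
  som <- somatic[somatic$variant_class != "silent", , drop = FALSE]
  for (i in seq_len(nrow(kb))) {
    rec <- kb[i, ]
    hit <- NULL
    if (rec$alteration_matcher == "amplification") {
      if (!is.null(cnv) && nrow(cnv) > 0) {
        sel <- cnv$gene_symbol == rec$gene_symbol & cnv$call == "amplification"
        if (any(sel)) {
          hit <- data.frame(sample_id = cnv$sample_id[sel],
                            alteration = paste0(rec$gene_symbol, " amplification"),
                            stringsAsFactors = FALSE)
        }
      }
    } else {
      sel <- som$gene_symbol == rec$gene_symbol
      sel <- sel & switch(
        rec$alteration_matcher,
        exact_protein_change = !is.na(som$protein_change) &
          som$protein_change == rec$protein_change,
        truncating = som$variant_class %in%
          c("nonsense", "frameshift", "splice_site"),
        any_oncogenic = {
          classes <- if (is.na(rec$oncogenic_classes)) nonsilent_classes()
                     else strsplit(rec$oncogenic_classes, ",", fixed = TRUE)[[1]]
          som$variant_class %in% trimws(classes)
        })
      if (any(sel)) {
        hit <- data.frame(
          sample_id = som$sample_id[sel],
          alteration = paste0(rec$gene_symbol, " ",
                              ifelse(is.na(som$protein_change[sel]),
                                     som$variant_class[sel],
                                     som$protein_change[sel])),
          stringsAsFactors = FALSE)
      }
    }
    if (!is.null(hit) && nrow(hit) > 0) {
      hit$gene_symbol <- rec$gene_symbol
      hit$matcher <- rec$alteration_matcher
      hit$level <- rec$level
      hit$drugs <- rec$drugs
      hit$record_id <- rec$record_id
      matches[[length(matches) + 1]] <- hit
    }
  }
  if (length(matches) == 0) {
    return(data.frame(sample_id = character(), alteration = character(),
                      gene_symbol = character(), matcher = character(),
                      level = character(), drugs = character(),
                      record_id = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, matches)
  unique(out)
}

#' Highest evidence level among a set of matches
#'
#' Maximum over the level ordering L1 > L2A > L2B > L3A > L3B > L4;
#' `"none"` for an empty match set.  Idempotent and invariant to the order
#' of the input.
#'
#' @param levels Character vector of level labels (possibly empty).
#' @return Single level label or `"none"`.
#' @export
assign_best_level <- function(levels) {
  levels <- levels[!is.na(levels)]
  if (length(levels) == 0) return("none")
  ord <- actionability_levels()
  bad <- setdiff(levels, ord)
  if (length(bad) > 0) stop("assign_best_level: unknown level(s): ",
                            paste(bad, collapse = ", "))
  ord[min(match(levels, ord))]
}

#' Per-sample actionability rollup
#'
#' Matches every sample's somatic and CNV alterations against the
#' knowledge base and assigns each sample the level of its most
#' significant match.
#'
#' @param cohort A [bc_cohort()] object.
#' @param kb Knowledge base from [load_kb()].
#' @return List with `matches` (long match table with provenance) and
#'   `per_sample` (data frame `sample_id`, `n_matches`, `best_level`).
#' @export
sample_actionability <- function(cohort, kb) {
  m <- match_alterations(cohort$somatic, cohort$cnv, kb)
  sids <- cohort$samples$sample_id
  best <- vapply(sids, function(s)
    assign_best_level(m$level[m$sample_id == s]), character(1))
  n_matches <- vapply(sids, function(s) sum(m$sample_id == s), integer(1))
  list(matches = m,
       per_sample = data.frame(sample_id = sids, n_matches = n_matches,
                               best_level = unname(best),
                               stringsAsFactors = FALSE))
}

#' Group-level actionability summary
#'
#' Fractions of samples at each best evidence level (including the
#' `"none"` bucket, so fractions sum to 1 within a group), the fraction
#' of samples with at least one knowledge-base match, and the
#' distribution of per-sample match counts.
#'
#' @param per_sample `per_sample` table from [sample_actionability()].
#' @param samples Clinical data frame.
#' @param group_by Grouping column, default `"subtype"`.
#' @return List with `level_fractions` (group x level data frame),
#'   `frac_actionable` (named vector per group) and `multi_alteration`
#'   (data frame of match-count distribution per group).
#' @export
actionability_summary <- function(per_sample, samples, group_by = "subtype") {
  grp <- as.character(samples[[group_by]][match(per_sample$sample_id,
                                                samples$sample_id)])
  lv <- c(actionability_levels(), "none")
  tab <- table(factor(grp), factor(per_sample$best_level, levels = lv))
  fr <- sweep(tab, 1, rowSums(tab), "/")
  level_fractions <- as.data.frame.matrix(fr)
  level_fractions <- cbind(group = rownames(level_fractions), level_fractions,
                           stringsAsFactors = FALSE)
  rownames(level_fractions) <- NULL
  frac_actionable <- tapply(per_sample$best_level != "none", grp, mean)
  multi <- aggregate(list(n_samples = per_sample$sample_id),
                     by = list(group = grp, n_matches = per_sample$n_matches),
                     FUN = length)
  list(level_fractions = level_fractions,
       frac_actionable = frac_actionable,
       multi_alteration = multi[order(multi$group, multi$n_matches), ])
}
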