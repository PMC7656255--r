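#' Per-gene mutation frequencies
#'
#' Fraction of samples carrying at least one non-silent somatic mutation in
#' each gene, overall or stratified.  Denominators are group sizes (all
#' sequenced samples in the group), never just the mutated ones; genes from
#' `genes` with no carriers are kept as zero-frequency rows.
#'
#' @param cohort A [bc_cohort()] object with at least one sample.
#' @param group_by `"none"`, `"subtype"`, `"coarse_subtype"`, `"stage"` or
#'   `"cohort_arm"`.
#' @param genes Optional gene universe; defaults to genes observed in the
#'   somatic calls.
#' @return Data frame with columns `feature`, `group`, `n_altered`,
#'   `n_total`, `frequency`, `frequency_pct` (nearest-percent rounding used
#'   in report annotations; the raw proportion is always retained).
#' @export
gene_frequency <- function(cohort,
                           group_by = c("none", "subtype", "coarse_subtype",
                                        "stage", "cohort_arm"),
                           genes = NULL) {
  group_by <- match.arg(group_by)
  if (nrow(cohort$samples) == 0) stop("gene_frequency: empty cohort")
  som <- cohort$somatic
  som <- som[som$variant_class != "silent", , drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(som$gene_symbol))
  frequency_core(som$sample_id, som$gene_symbol, cohort$samples, group_by,
                 features = genes)
}

# Kruskal-Wallis wrapper: a completely tied sample (every observation
# identical) carries no rank information, so H = 0 and p = 1 instead of
# the 0/0 the raw tie correction would produce.
kruskal_safe <- function(values, groups) {
  if (length(unique(values)) == 1) {
    return(list(statistic = 0, p_value = 1))
  }
  kw <- stats::kruskal.test(values, groups)
  list(statistic = unname(kw$statistic), p_value = kw$p.value)
}

# Shared counting core for gene/CNV/pathway frequency tables.  `ids` and
# `feats` are parallel vectors of (sample, feature) alteration events;
# duplicates collapse to one carrier.
frequency_core <- function(ids, feats, samples, group_by, features,
                           denominator_ids = NULL) {
  if (is.null(denominator_ids)) denominator_ids <- samples$sample_id
  grp_of <- if (group_by == "none") {
    setNames(rep("all", nrow(samples)), samples$sample_id)
  } else {
    setNames(as.character(samples[[group_by]]), samples$sample_id)
  }
  denom_grp <- grp_of[denominator_ids]
  keep_den <- !is.na(denom_grp)
  denom_grp <- denom_grp[keep_den]
  groups <- sort(unique(denom_grp))
  n_total <- table(factor(denom_grp, groups))

  keep <- ids %in% denominator_ids[keep_den] & feats %in% features
  ids <- ids[keep]; feats <- feats[keep]
  ev <- unique(data.frame(sample_id = ids, feature = feats,
                          stringsAsFactors = FALSE))
  ev$group <- grp_of[ev$sample_id]
  out <- expand.grid(feature = features, group = groups,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  cnt <- table(factor(ev$feature, features), factor(ev$group, groups))
  out$n_altered <- as.integer(cnt[cbind(match(out$feature, features),
                                        match(out$group, groups))])
  out$n_total <- as.integer(n_total[out$group])
  out$frequency <- ifelse(out$n_total > 0, out$n_altered / out$n_total, NA)
  out$frequency_pct <- round(100 * out$frequency)
  out[order(out$group, -out$frequency, out$feature), , drop = FALSE]
}

#' Detect hotspot mutations
#'
#' A hotspot is a recurrent identical protein change whose cohort frequency
#' reaches the threshold (2\% by default).  Samples are counted once per
#' (gene, protein change) even with duplicate calls; calls without a
#' protein change are skipped, with the skipped count recorded in the
#' `n_missing_protein_change` attribute.  To match report conventions in
#' which frequencies are annotated at whole percents, a protein change
#' whose raw frequency rounds up to the threshold at one decimal of a
#' percent is admitted: the effective cutoff is `min_frequency - 5e-4`.
#'
#' @param mutations Somatic mutation data frame.
#' @param n_samples Cohort size used as the denominator.
#' @param min_frequency Hotspot threshold as a proportion, default 0.02.
#' @return Data frame (`gene_symbol`, `protein_change`, `n_samples`,
#'   `frequency`), sorted by descending frequency then gene and protein
#'   change.
#' @export
detect_hotspots <- function(mutations, n_samples, min_frequency = 0.02) {
  stopifnot(n_samples > 0)
  has_pc <- !is.na(mutations$protein_change) & mutations$protein_change != ""
  n_missing <- sum(!has_pc)
  mut <- mutations[has_pc, , drop = FALSE]
  ev <- unique(data.frame(sample_id = mut$sample_id,
                          gene_symbol = mut$gene_symbol,
                          protein_change = mut$protein_change,
                          stringsAsFactors = FALSE))
  key <- paste(ev$gene_symbol, ev$protein_change, sep = "|")
  cnt <- table(key)
  freq <- as.numeric(cnt) / n_samples
  keep <- freq >= min_frequency - 5e-4
  parts <- strsplit(names(cnt)[keep], "|", fixed = TRUE)
  out <- data.frame(
    gene_symbol = vapply(parts, `[`, character(1), 1),
    protein_change = vapply(parts, `[`, character(1), 2),
    n_samples = as.integer(cnt[keep]),
    frequency = freq[keep],
    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$gene_symbol, out$protein_change), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_missing_protein_change") <- n_missing
  out
}

#' Per-sample mutation load and across-group comparison
#'
#' Counts somatic mutation records per sample (zero for samples without
#' calls) and compares the counts across groups (the five molecular
#' subtypes by default) with the tie-corrected Kruskal-Wallis test.
#'
#' @param cohort A [bc_cohort()] object.
#' @param group_by Grouping column of the clinical table, default
#'   `"subtype"`.
#' @return List with `per_sample` (data frame `sample_id`, `group`,
#'   `n_mutations`), `group_medians`, and `p_value` (`NA` with
#'   `comparison = "not applicable"` when fewer than two groups are
#'   present).
#' @export
mutation_load <- function(cohort, group_by = "subtype") {
  if (nrow(cohort$samples) == 0) stop("mutation_load: empty cohort")
  counts <- table(factor(cohort$somatic$sample_id,
                         levels = cohort$samples$sample_id))
  per_sample <- data.frame(sample_id = cohort$samples$sample_id,
                           group = as.character(cohort$samples[[group_by]]),
                           n_mutations = as.integer(counts),
                           stringsAsFactors = FALSE)
  ok <- !is.na(per_sample$group)
  groups <- unique(per_sample$group[ok])
  medians <- tapply(per_sample$n_mutations[ok], per_sample$group[ok],
                    stats::median)
  if (length(groups) < 2) {
    return(list(per_sample = per_sample, group_medians = medians,
                p_value = NA_real_, comparison = "not applicable"))
  }
  kw <- kruskal_safe(per_sample$n_mutations[ok],
                     factor(per_sample$group[ok]))
  list(per_sample = per_sample, group_medians = medians,
       p_value = kw$p_value, statistic = kw$statistic,
       comparison = "Kruskal-Wallis")
}

#' Per-gene VAF summaries and across-gene comparison
#'
#' Median and quartiles of the variant allele fraction per gene, restricted
#' to the listed genes, with a tie-corrected Kruskal-Wallis comparison of
#' the VAF distributions across genes.  Genes with no mutations are
#' excluded from the test but listed with `n = 0` in the summary.
#'
#' @param mutations Somatic mutation data frame.
#' @param genes Nonempty character vector of genes to summarise.
#' @return List with `summary` (per-gene n/quartiles) and `p_value`
#'   (`NA` when fewer than two genes carry data).
#' @export
vaf_summary <- function(mutations, genes) {
  if (length(genes) == 0) stop("vaf_summary: genes must be nonempty")
  mut <- mutations[mutations$gene_symbol %in% genes & !is.na(mutations$vaf), ,
                   drop = FALSE]
  sum_one <- function(g) {
    v <- mut$vaf[mut$gene_symbol == g]
    if (length(v) == 0) {
      data.frame(gene_symbol = g, n = 0L, q1 = NA_real_, median = NA_real_,
                 q3 = NA_real_, stringsAsFactors = FALSE)
    } else {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(gene_symbol = g, n = length(v), q1 = q[1], median = q[2],
                 q3 = q[3], stringsAsFactors = FALSE)
    }
  }
  summ <- do.call(rbind, lapply(genes, sum_one))
  tested <- summ$gene_symbol[summ$n > 0]
  p <- NA_real_; stat <- NA_real_
  if (length(tested) >= 2) {
    sub <- mut[mut$gene_symbol %in% tested, , drop = FALSE]
    kw <- kruskal_safe(sub$vaf, factor(sub$gene_symbol))
    p <- kw$p_value; stat <- kw$statistic
  }
  list(summary = summ, p_value = p, statistic = stat)
}

#' Per-gene CNV frequencies
#'
#' One row per (gene, call type, group).  Denominators are the samples in
#' which copy number was successfully determined (`cohort$cnv_evaluable`),
#' which may be fewer than the full cohort.
#'
#' @param cohort A [bc_cohort()] object with CNV calls.
#' @param group_by As in [gene_frequency()].
#' @param genes Optional gene universe; defaults to genes observed in CNV
#'   calls.
#' @return Frequency data frame with a `call` column.
#' @export
cnv_frequency <- function(cohort,
                          group_by = c("none", "subtype", "coarse_subtype",
                                       "stage", "cohort_arm"),
                          genes = NULL) {
  group_by <- match.arg(group_by)
  cnv <- cohort$cnv
  if (is.null(cnv)) cnv <- data.frame(sample_id = character(),
                                      gene_symbol = character(),
                                      call = character())
  if (is.null(genes)) genes <- sort(unique(cnv$gene_symbol))
  out <- lapply(c("amplification", "deletion"), function(ct) {
    sub <- cnv[cnv$call == ct, , drop = FALSE]
    tab <- frequency_core(sub$sample_id, sub$gene_symbol, cohort$samples,
                          group_by, features = genes,
                          denominator_ids = cohort$cnv_evaluable)
    tab$call <- rep(ct, nrow(tab))
    tab
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
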