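#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with the usual two-sided definition: the
#' p-value sums the probabilities of all tables (with the observed margins)
#' whose point probability does not exceed that of the observed table, up
#' to a small relative tolerance guarding floating-point ties.  The odds
#' ratio is the sample cross-product `(a*d)/(b*c)`, reported as `+Inf` when
#' `b*c == 0` with `a*d > 0` and as 0 when `a*d == 0` with `b*c > 0`
#' (and `NaN` if both products vanish).
#'
#' Table orientation:
#' \preformatted{            in group   not in group
#'   altered        a            c
#'   unaltered      b            d}
#'
#' @param a,b,c,d Nonnegative integer cell counts; at least one must be
#'   positive.
#' @return List with `odds_ratio` and `p_value`.
#' @examples
#' fisher_exact_2x2(5, 5, 5, 5)    # OR 1, p 1
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("fisher_exact_2x2: cells must be nonnegative integers")
  }
  if (sum(cells) == 0) stop("fisher_exact_2x2: all-zero table")
  ad <- a * d; bc <- b * c
  or <- if (bc == 0 && ad == 0) NaN
        else if (bc == 0) Inf
        else if (ad == 0) 0
        else ad / bc
  n_tot <- a + b + c + d
  r1 <- a + c          # altered margin
  c1 <- a + b          # group margin
  lo <- max(0, r1 + c1 - n_tot)
  hi <- min(r1, c1)
  if (lo == hi) return(list(odds_ratio = or, p_value = 1))
  support <- lo:hi
  dens <- stats::dhyper(support, c1, n_tot - c1, r1)
  p_obs <- dens[support == a]
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  list(odds_ratio = or, p_value = min(1, p))
}

#' Woolf logit confidence interval for a 2x2 odds ratio
#'
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.  When any cell is
#' zero the Haldane-Anscombe correction adds 0.5 to every cell so that the
#' interval stays finite.
#'
#' @inheritParams fisher_exact_2x2
#' @param level Confidence level, default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @export
or_confidence_interval <- function(a, b, c, d, level = 0.95) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("or_confidence_interval: negative cell")
  if (any(cells == 0)) cells <- cells + 0.5
  lor <- log(cells[1] * cells[4] / (cells[2] * cells[3]))
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - level) / 2)
  exp(lor + c(-1, 1) * z * se)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (via [stats::p.adjust()]); q-values are
#' returned in input order, so the adjustment is stable under permutation
#' of the inputs.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (`NA` allowed;
#'   propagated).
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("bh_fdr: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

# Shared core: given per-feature 2x2 cells, assemble the EnrichmentResult
# table with OR, CI, exact p, BH q over the whole family and a significance
# flag.  Orientation: a = altered in group, b = unaltered in group,
# c = altered elsewhere, d = unaltered elsewhere, so OR > 1 means enriched
# in the named group.
enrichment_table <- function(feature, group_label, a, b, c, d, fdr_threshold) {
  n <- length(feature)
  or <- p <- lo <- hi <- numeric(n)
  for (i in seq_len(n)) {
    ft <- fisher_exact_2x2(a[i], b[i], c[i], d[i])
    ci <- or_confidence_interval(a[i], b[i], c[i], d[i])
    or[i] <- ft$odds_ratio; p[i] <- ft$p_value
    lo[i] <- ci[1]; hi[i] <- ci[2]
  }
  q <- bh_fdr(p)
  data.frame(feature = feature, group_label = group_label,
             a = a, b = b, c = c, d = d,
             odds_ratio = or, ci_low = lo, ci_high = hi,
             p_value = p, q_value = q,
             significant = q < fdr_threshold,
             stringsAsFactors = FALSE)
}

#' Subtype enrichment of alterations (one-vs-rest)
#'
#' For every (feature, subtype) pair, tests whether alteration of the
#' feature is associated with membership of that subtype against the rest
#' of the cohort, by two-sided Fisher's exact test.  All (feature, subtype)
#' pairs form one BH family; a pair is flagged significant when its
#' q-value falls below `fdr_threshold` (default 0.25, the conventional
#' exploratory FDR for subtype association screens).
#'
#' @param matrix Binary gene-level alteration matrix (samples x features).
#' @param samples Clinical data frame with `sample_id` and the grouping
#'   column.
#' @param fdr_threshold FDR significance threshold, default 0.25.
#' @param group_col Column of `samples` holding the grouping, default
#'   `"subtype"`.
#' @return Data frame of enrichment results (one row per feature x group).
#' @export
subtype_enrichment <- function(matrix, samples, fdr_threshold = 0.25,
                               group_col = "subtype") {
  stopifnot(group_col %in% names(samples))
  samples <- samples[match(rownames(matrix), samples$sample_id), , drop = FALSE]
  grp <- samples[[group_col]]
  keep <- !is.na(grp)
  n_excluded <- sum(!keep)
  mat <- matrix[keep, , drop = FALSE]
  grp <- grp[keep]
  groups <- sort(unique(grp))
  groups <- groups[tabulate(factor(grp, groups)) > 0]
  feats <- colnames(mat)
  rows <- expand.grid(feature = feats, group_label = groups,
                      stringsAsFactors = FALSE)
  a <- b <- cc <- d <- integer(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    ing <- grp == rows$group_label[i]
    alt <- mat[, rows$feature[i]] == 1
    a[i] <- sum(ing & alt);  b[i] <- sum(ing & !alt)
    cc[i] <- sum(!ing & alt); d[i] <- sum(!ing & !alt)
  }
  out <- enrichment_table(rows$feature, rows$group_label, a, b, cc, d,
                          fdr_threshold)
  attr(out, "n_missing_excluded") <- n_excluded
  out
}

#' Clinical covariate enrichment
#'
#' Same machinery as [subtype_enrichment()] with groups defined by a
#' clinical covariate (`stage`, `menopause` or `cohort_arm`).  Samples with
#' a missing covariate value are excluded pairwise; the excluded count is
#' recorded in the `n_missing_excluded` attribute.
#'
#' @inheritParams subtype_enrichment
#' @param covariate One of `"stage"`, `"menopause"`, `"cohort_arm"`.
#' @export
covariate_enrichment <- function(matrix, samples,
                                 covariate = c("stage", "menopause", "cohort_arm"),
                                 fdr_threshold = 0.05) {
  covariate <- match.arg(covariate)
  grp <- samples[[covariate]][match(rownames(matrix), samples$sample_id)]
  grp[grp %in% c("", "missing")] <- NA
  n_groups <- length(unique(grp[!is.na(grp)]))
  if (n_groups < 2) {
    stop("covariate_enrichment: fewer than 2 nonempty covariate groups")
  }
  samples2 <- data.frame(sample_id = rownames(matrix), covariate_group = grp,
                         stringsAsFactors = FALSE)
  subtype_enrichment(matrix, samples2, fdr_threshold,
                     group_col = "covariate_group")
}

#' Compare per-feature alteration frequencies between two cohorts
#'
#' Both cohorts enter as frequency tables of `(feature, n_altered,
#' n_total)`; for each feature shared by the two tables a 2x2 table
#' (altered/unaltered x cohort A/cohort B) is tested by Fisher's exact
#' test, with BH adjustment over all shared features as one family.  The
#' odds ratio is oriented A over B, so OR > 1 means the feature is more
#' frequently altered in cohort A.  Features present in only one table
#' (panel overlap caveat) are reported in the `unshared` element rather
#' than tested; features with `n_total == 0` in either cohort are excluded
#' and listed in `excluded`.
#'
#' @param freq_a,freq_b Data frames with columns `feature`, `n_altered`,
#'   `n_total`.
#' @param fdr_threshold FDR threshold, default 0.05.
#' @return List with `results` (enrichment data frame), `unshared`
#'   (character vector) and `excluded` (character vector).
#' @export
cohort_compare <- function(freq_a, freq_b, fdr_threshold = 0.05) {
  for (nm in list(freq_a, freq_b)) {
    require_columns(nm, c("feature", "n_altered", "n_total"), "frequency table")
  }
  shared <- intersect(freq_a$feature, freq_b$feature)
  unshared <- c(setdiff(freq_a$feature, freq_b$feature),
                setdiff(freq_b$feature, freq_a$feature))
  ia <- match(shared, freq_a$feature); ib <- match(shared, freq_b$feature)
  bad <- freq_a$n_total[ia] == 0 | freq_b$n_total[ib] == 0
  excluded <- shared[bad]
  shared <- shared[!bad]; ia <- ia[!bad]; ib <- ib[!bad]
  a <- freq_a$n_altered[ia]
  b <- freq_a$n_total[ia] - a
  cc <- freq_b$n_altered[ib]
  d <- freq_b$n_total[ib] - cc
  res <- if (length(shared) > 0) {
    enrichment_table(shared, "A_vs_B", a, b, cc, d, fdr_threshold)
  } else {
    enrichment_table(character(), character(), integer(), integer(),
                     integer(), integer(), fdr_threshold)
  }
  list(results = res, unshared = unshared, excluded = excluded)
}
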