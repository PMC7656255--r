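#' Germline consequence vocabulary
#' @return Character vector of consequence labels.
#' @export
germline_consequences <- function() {
  c("stop_gained", "frameshift", "canonical_splice", "start_lost",
    "missense", "inframe_indel", "other")
}

truncating_consequences <- function() {
  c("stop_gained", "frameshift", "canonical_splice", "start_lost")
}

#' Evidence-point weights of the germline classifier
#'
#' Published CharGer-style point weights per ACMG evidence strength:
#' very strong (PVS1) 8, strong (PS1) 7, moderate (PM4, PM5) 2,
#' supporting (PP) 1.  Exposed so the scoring scheme is configurable.
#'
#' @return Named numeric vector.
#' @export
charger_weights <- function() {
  c(PVS1 = 8, PS1 = 7, PM4 = 2, PM5 = 2, PP = 1)
}

#' Read an annotated germline variant table
#'
#' TSV with columns `patient_id`, `gene_symbol`, `chrom`, `pos`, `ref`,
#' `alt`, `consequence` (see [germline_consequences()]), `af_eas`
#' (gnomAD East-Asian allele frequency, may be missing), `af_overall`,
#' `clinvar_status` (`pathogenic_cancer`, `pathogenic_other`, `benign`,
#' `vus`, `unreported`), `same_aa_change_pathogenic` and
#' `same_residue_pathogenic` (logical flags against cancer-related ClinVar
#' pathogenic records, driving the PS1/PM5 modules).
#'
#' @param path Path to the germline TSV.
#' @return Data frame of germline variants.
#' @export
read_germline_table <- function(path) {
  if (!file.exists(path)) stop("read_germline_table: file not found: ", path)
  raw <- read_tsv_meta(path)
  require_columns(raw, c("patient_id", "gene_symbol", "consequence",
                         "clinvar_status"), "germline table")
  for (col in c("af_eas", "af_overall")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_real_
    raw[[col]] <- as.numeric(raw[[col]])
  }
  for (col in c("same_aa_change_pathogenic", "same_residue_pathogenic")) {
    if (!col %in% names(raw)) raw[[col]] <- FALSE
    raw[[col]] <- as.logical(raw[[col]])
    raw[[col]][is.na(raw[[col]])] <- FALSE
  }
  raw
}

#' Read the gene-context table for germline scoring
#'
#' TSV with columns `gene`, `is_cancer_gene`, `lof_mechanism` (is
#' loss-of-function an established disease mechanism for the gene).
#'
#' @param path Path to the gene-context TSV.
#' @return Data frame.
#' @export
read_gene_context <- function(path) {
  raw <- read_tsv_meta(path)
  require_columns(raw, c("gene", "is_cancer_gene", "lof_mechanism"),
                  "gene context table")
  raw$is_cancer_gene <- as.logical(raw$is_cancer_gene)
  raw$lof_mechanism <- as.logical(raw$lof_mechanism)
  raw
}

#' Rare-variant prefilter on East-Asian population frequency
#'
#' Retains only rare variants: a variant is removed iff its East-Asian
#' allele frequency is at or above the threshold (strict "rare" means
#' `af_eas < max_eas_af`).  Variants absent from the population database
#' (`af_eas` missing) are treated as rare and kept; the number of such
#' variants is recorded in the `n_missing_af` attribute so the choice is
#' auditable.
#'
#' @param variants Germline variant data frame.
#' @param max_eas_af Frequency threshold, default 0.005 (0.5\%).
#' @return List with data frames `kept` and `removed`.
#' @export
prefilter_rare <- function(variants, max_eas_af = 0.005) {
  stopifnot(max_eas_af > 0, max_eas_af <= 1)
  missing_af <- is.na(variants$af_eas)
  drop <- !missing_af & variants$af_eas >= max_eas_af
  kept <- variants[!drop, , drop = FALSE]
  attr(kept, "n_missing_af") <- sum(missing_af)
  list(kept = kept, removed = variants[drop, , drop = FALSE])
}

#' Score ACMG evidence for germline variants
#'
#' Applies the active evidence modules and sums their points:
#' \describe{
#'   \item{PVS1 (8)}{truncating consequence (stop gained, frameshift,
#'     canonical splice, start lost) in a cancer-susceptibility gene whose
#'     disease mechanism is loss of function.}
#'   \item{PS1 (7)}{same amino-acid change as a cancer-related ClinVar
#'     pathogenic variant.}
#'   \item{PM4 (2)}{protein-length-changing inframe event.}
#'   \item{PM5 (2)}{novel missense at a residue carrying a cancer-related
#'     ClinVar pathogenic missense (does not fire when PS1 fires).}
#'   \item{PP (1 each)}{supporting modules; config-gated and off by
#'     default, since the required in-silico annotations are not part of
#'     the input contract.}
#' }
#' The population-rarity module PM2 is disabled by construction — rarity is
#' enforced upstream by [prefilter_rare()] instead — and never appears in
#' any evidence trail.  Unknown consequence strings are treated as
#' `"other"` (contributing nothing); their count is recorded in the
#' `n_unknown_consequence` attribute.
#'
#' @param variants Germline variant data frame.
#' @param gene_context Data frame from [read_gene_context()].
#' @param weights Named point weights, see [charger_weights()].
#' @return `variants` with `evidence` (comma-separated fired codes) and
#'   `score` columns added.
#' @export
score_evidence <- function(variants, gene_context, weights = charger_weights()) {
  cons <- variants$consequence
  unknown <- !(cons %in% germline_consequences())
  cons[unknown] <- "other"
  ctx <- gene_context[match(variants$gene_symbol, gene_context$gene), ]
  lof_gene <- !is.na(ctx$gene) & ctx$is_cancer_gene & ctx$lof_mechanism

  pvs1 <- (cons %in% truncating_consequences()) & lof_gene
  ps1 <- variants$same_aa_change_pathogenic
  pm4 <- cons == "inframe_indel"
  pm5 <- cons == "missense" & variants$same_residue_pathogenic & !ps1

  fired <- cbind(PVS1 = pvs1, PS1 = ps1, PM4 = pm4, PM5 = pm5)
  variants$score <- as.numeric(fired %*% weights[colnames(fired)])
  variants$evidence <- apply(fired, 1, function(f)
    paste(colnames(fired)[f], collapse = ","))
  attr(variants, "n_unknown_consequence") <- sum(unknown)
  variants
}

#' Classify scored germline variants
#'
#' A variant is `pathogenic` iff it is a known cancer-related ClinVar
#' pathogenic record; otherwise `likely_pathogenic` iff its evidence score
#' strictly exceeds `score_cutoff` (default 7); otherwise `uncertain`.
#' Classification is monotone in the score: raising a score never demotes
#' the class.
#'
#' @param variants Scored germline data frame (see [score_evidence()]).
#' @param score_cutoff Likely-pathogenic score cutoff (strict), default 7.
#' @return `variants` with a `classification` column added.
#' @export
classify_germline <- function(variants, score_cutoff = 7) {
  cls <- rep("uncertain", nrow(variants))
  cls[variants$score > score_cutoff] <- "likely_pathogenic"
  cls[variants$clinvar_status == "pathogenic_cancer"] <- "pathogenic"
  variants$classification <- cls
  variants
}

#' Cohort carrier summary
#'
#' A carrier is a patient with at least one variant classified pathogenic
#' or likely pathogenic.  Per-gene counts count patients, not variants; a
#' patient with qualifying variants in two genes increments both genes but
#' counts once in the overall carrier total.
#'
#' @param variants Classified germline data frame.
#' @param n_patients Number of patients in the cohort (denominator).
#' @return List with `n_carriers`, `fraction`, `pct` (one-decimal percent),
#'   and `per_gene` (data frame `gene_symbol`, `n_patients`, `pct`).
#' @export
carrier_summary <- function(variants, n_patients) {
  stopifnot(n_patients > 0)
  plp <- variants[variants$classification %in%
                    c("pathogenic", "likely_pathogenic"), , drop = FALSE]
  carriers <- unique(plp$patient_id)
  per_gene_pairs <- unique(plp[, c("patient_id", "gene_symbol")])
  tab <- sort(table(per_gene_pairs$gene_symbol), decreasing = TRUE)
  per_gene <- data.frame(gene_symbol = names(tab),
                         n_patients = as.integer(tab),
                         pct = round(100 * as.integer(tab) / n_patients, 2),
                         stringsAsFactors = FALSE)
  list(n_carriers = length(carriers),
       fraction = length(carriers) / n_patients,
       pct = round(100 * length(carriers) / n_patients, 1),
       per_gene = per_gene)
}

#' Compare per-gene germline carrier frequencies across populations
#'
#' For each gene, tests homogeneity of carrier frequency across populations
#' with Pearson's chi-square on the carriers/non-carriers x population
#' table, falling back to Fisher's exact test when any expected cell count
#' is below 5.
#'
#' @param freqs Data frame with columns `gene`, `population`, `n_carriers`,
#'   `n_total`; at least two populations.
#' @return Data frame `gene`, `p_value`, `method`.
#' @export
germline_cohort_compare <- function(freqs) {
  require_columns(freqs, c("gene", "population", "n_carriers", "n_total"),
                  "population frequency table")
  if (length(unique(freqs$population)) < 2) {
    stop("germline_cohort_compare: need >= 2 populations")
  }
  if (any(freqs$n_total == 0)) {
    stop("germline_cohort_compare: population with n_total = 0")
  }
  genes <- unique(freqs$gene)
  res <- lapply(genes, function(g) {
    sub <- freqs[freqs$gene == g, ]
    tab <- rbind(sub$n_carriers, sub$n_total - sub$n_carriers)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      p <- stats::fisher.test(tab)$p.value
      method <- "fisher"
    } else {
      p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
      method <- "chisq"
    }
    data.frame(gene = g, p_value = p, method = method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
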