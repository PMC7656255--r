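#' Default per-subtype somatic gene mutation frequencies
#'
#' The generator's default mutation-frequency table: one row per panel
#' gene, one column per molecular subtype, entries being the probability
#' that a sample of that subtype carries at least one non-silent mutation
#' in the gene.  Values are calibrated so that the marginal cohort
#' frequencies under the default subtype mix reproduce the headline rates
#' of a large Chinese prospective panel-sequencing cohort (TP53 ~53\%,
#' PIK3CA ~32\%, NF1 ~10\%, with TP53 rising from luminal A through
#' triple-negative disease to ~80\%).
#'
#' @return Data frame with `gene` plus the five subtype columns.
#' @export
default_gene_freqs <- function() {
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
gene      luminal_A luminal_B_HER2neg luminal_B_HER2pos HER2pos triple_negative
TP53      0.25 0.40 0.63 0.74 0.80
PIK3CA    0.40 0.38 0.30 0.25 0.18
NF1       0.08 0.10 0.12 0.12 0.10
GATA3     0.10 0.13 0.06 0.01 0.01
KMT2C     0.09 0.08 0.08 0.07 0.07
AKT1      0.12 0.06 0.02 0.01 0.01
SF3B1     0.10 0.05 0.03 0.02 0.02
PTEN      0.02 0.03 0.03 0.04 0.10
ARID1A    0.05 0.05 0.04 0.04 0.05
MAP3K1    0.08 0.07 0.03 0.02 0.02
ERBB2     0.01 0.02 0.08 0.09 0.02
CDH1      0.08 0.06 0.02 0.01 0.01
RUNX1     0.04 0.04 0.03 0.02 0.03
NOTCH1    0.03 0.03 0.04 0.04 0.06
KMT2D     0.05 0.05 0.05 0.05 0.05
DNMT3A    0.03 0.03 0.03 0.03 0.03
ATRX      0.02 0.03 0.03 0.03 0.03
APC       0.03 0.03 0.03 0.02 0.02
MEN1      0.02 0.02 0.02 0.02 0.02
NF2       0.02 0.03 0.01 0.00 0.02
CDKN2A    0.01 0.01 0.02 0.05 0.02
FAM47C    0.01 0.01 0.02 0.02 0.06
KDM6A     0.01 0.01 0.02 0.02 0.05
CBFB      0.06 0.02 0.01 0.01 0.01
XDH       0.01 0.04 0.01 0.01 0.01
SMO       0.05 0.02 0.01 0.01 0.01
TBX3      0.05 0.04 0.02 0.01 0.01
ESR1      0.02 0.03 0.01 0.00 0.00
BRCA1     0.01 0.01 0.01 0.02 0.05
BRCA2     0.02 0.02 0.02 0.02 0.03
TSC2      0.02 0.02 0.02 0.02 0.02
KRAS      0.01 0.01 0.02 0.02 0.02
FBXW7     0.02 0.02 0.02 0.02 0.03
SMAD4     0.01 0.02 0.02 0.01 0.01
CREBBP    0.02 0.02 0.02 0.02 0.03
STK11     0.01 0.01 0.01 0.01 0.02
MAP2K4    0.07 0.07 0.05 0.04 0.05
ERBB3     0.03 0.04 0.05 0.05 0.03
ERBB4     0.03 0.03 0.03 0.03 0.03
BRAF      0.02 0.02 0.02 0.02 0.02
EGFR      0.01 0.02 0.02 0.03 0.03
FGFR2     0.02 0.02 0.02 0.02 0.02
RASA1     0.02 0.02 0.02 0.02 0.02
PTPN11    0.01 0.01 0.01 0.01 0.01
MAP2K1    0.01 0.01 0.01 0.01 0.01
NOTCH2    0.02 0.02 0.02 0.02 0.03
NOTCH3    0.02 0.02 0.02 0.02 0.03
NOTCH4    0.02 0.02 0.02 0.02 0.02
EP300     0.02 0.02 0.02 0.02 0.02
NCOR1     0.02 0.02 0.02 0.02 0.02
ATM       0.02 0.02 0.02 0.02 0.02
PIK3R1    0.03 0.03 0.03 0.03 0.03
MTOR      0.02 0.02 0.02 0.02 0.02
INPP4B    0.02 0.02 0.02 0.02 0.02
AKT2      0.01 0.01 0.01 0.01 0.01
TSC1      0.01 0.01 0.01 0.01 0.01
CTNNB1    0.015 0.015 0.015 0.015 0.015
AXIN1     0.01 0.01 0.01 0.01 0.01
AXIN2     0.01 0.01 0.01 0.01 0.01
GSK3B     0.005 0.005 0.005 0.005 0.005
AMER1     0.01 0.01 0.01 0.01 0.01
TGFBR2    0.01 0.01 0.01 0.01 0.01
MYC       0.005 0.005 0.005 0.005 0.005
MGA       0.005 0.005 0.005 0.005 0.005
RB1       0.01 0.02 0.02 0.02 0.03
")
  tab
}

#' Default hotspot shares
#'
#' For each recurrent protein change, the share of the gene's mutated
#' samples that carry exactly that change (the remainder is drawn from a
#' positional background model).  Shares are calibrated so the expected
#' cohort-level hotspot frequencies land near the recurrently reported
#' ones (PIK3CA p.H1047R ~13\%, AKT1 p.E17K ~4\%, KMT2C p.K2797fs ~2\%,
#' TP53 p.R248Q ~2\%).
#'
#' @return Data frame `gene`, `protein_change`, `fraction`, `class`.
#' @export
default_hotspots <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
gene   protein_change fraction class
PIK3CA p.H1047R 0.41 missense
PIK3CA p.E545K  0.15 missense
PIK3CA p.E542K  0.08 missense
AKT1   p.E17K   0.85 missense
KMT2C  p.K2797fs 0.25 frameshift
TP53   p.R248Q  0.040 missense
TP53   p.H179R  0.020 missense
TP53   p.R282W  0.020 missense
TP53   p.Y220C  0.020 missense
SF3B1  p.K700E  0.50 missense
SMO    p.L23del 0.50 inframe_indel
GATA3  p.P409fs 0.15 frameshift
ESR1   p.D538G  0.30 missense
")
}

#' Default gene-level CNV frequencies
#'
#' Cohort-level amplification/deletion probabilities, dominated by the
#' 17q12 (ERBB2/MIEN1/GRB7) amplicon as in clinical breast-cancer series.
#'
#' @return Data frame `gene`, `call`, `frequency`.
#' @export
default_cnv_freqs <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
gene   call frequency
ERBB2  amplification 0.25
MIEN1  amplification 0.25
GRB7   amplification 0.24
TRPS1  amplification 0.06
MYC    amplification 0.06
ERLIN2 amplification 0.06
PLPP5  amplification 0.06
NSD3   amplification 0.06
FGFR1  amplification 0.06
CCND1  amplification 0.05
PTEN   deletion      0.03
CDKN2A deletion      0.02
")
}

#' Default germline carrier structure
#'
#' Per-gene carrier counts at the reference cohort size of 1134 patients:
#' 72 pathogenic/likely-pathogenic events spread over 66 distinct carriers
#' (5.8\% of patients), led by BRCA1.
#'
#' @return Data frame `gene`, `n_carriers_at_1134`.
#' @export
default_germline_counts <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
gene    n_carriers_at_1134
BRCA1   22
ALK     5
BRCA2   5
CHEK2   5
ATR     4
RB1     4
TP53    3
TSC2    3
APC     3
ETV6    3
BRAF    2
NF1     2
PTEN    2
SMARCA4 2
STK11   2
KRAS    2
MTAP    2
SMAD4   1
")
}

#' Default reference-cohort pathway frequencies
#'
#' A Western-style reference frequency table at the pathway level
#' (n = 869 primary samples), used by the cross-cohort comparison stage in
#' place of any external download.
#'
#' @return Data frame `feature`, `frequency`, `n_total`.
#' @export
default_reference_pathway_freqs <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
feature   frequency n_total
p53       0.31 869
PI3K      0.42 869
RTK_RAS   0.18 869
Notch     0.11 869
cell_cycle 0.10 869
Wnt       0.01 869
Hippo     0.002 869
TGF_beta  0.04 869
Myc       0.02 869
")
}

#' Specification of a synthetic cohort
#'
#' Bundles every parameter of the generator with its seed.  The defaults
#' describe the study conditions the package is exercised under: 1134
#' samples split into neoadjuvant/surgical/advanced arms of 419/606/109,
#' a subtype mix dominated by HR+/HER2- disease, per-subtype gene
#' frequencies from [default_gene_freqs()], hotspot shares from
#' [default_hotspots()], per-gene Beta VAF models, CNV frequencies from
#' [default_cnv_freqs()] with copy number evaluable in 1114/1134 of
#' samples, an injected ARID1A-PTEN full mutual exclusivity plus an
#' NF1-RUNX1 co-occurrence, and the germline carrier structure of
#' [default_germline_counts()].
#'
#' @param n_samples Cohort size; default 1134.
#' @param seed Mandatory integer seed.
#' @param subtype_proportions Named 5-vector summing to 1.
#' @param arm_proportions Named 3-vector (neoadjuvant, surgical, advanced)
#'   summing to 1; arm counts are apportioned by largest remainder so the
#'   default cohort has exactly 419/606/109.
#' @param gene_freqs Per-subtype frequency table as in
#'   [default_gene_freqs()].
#' @param hotspots Hotspot share table as in [default_hotspots()].
#' @param vaf_params Named list per gene of `c(alpha, beta)` Beta
#'   parameters; `.default` applies to unlisted genes.
#' @param mean_depth,min_depth Sequencing depth model: total depth is
#'   Poisson(`mean_depth`) truncated at `min_depth`.
#' @param cnv_freqs CNV frequency table as in [default_cnv_freqs()].
#' @param cnv_evaluable_fraction Fraction of samples with determinable
#'   copy number (default 1114/1134).
#' @param coupling Data frame `gene_i`, `gene_j`, `odds_ratio` of injected
#'   pairwise couplings (0 = full mutual exclusivity, `Inf` = nesting).
#' @param germline_counts Per-gene carrier counts at n = 1134, scaled to
#'   `n_samples`.
#' @param pon_artifacts Number of recurrent artifact variants injected and
#'   catalogued in the panel of normals.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 1134, seed,
                        subtype_proportions = c(luminal_A = 0.12,
                                                luminal_B_HER2neg = 0.42,
                                                luminal_B_HER2pos = 0.13,
                                                HER2pos = 0.12,
                                                triple_negative = 0.21),
                        arm_proportions = c(neoadjuvant = 419 / 1134,
                                            surgical = 606 / 1134,
                                            advanced = 109 / 1134),
                        gene_freqs = default_gene_freqs(),
                        hotspots = default_hotspots(),
                        vaf_params = list(.default = c(2, 3),
                                          PIK3CA = c(3, 2),
                                          AKT1 = c(3, 2.2)),
                        mean_depth = 1000, min_depth = 30,
                        cnv_freqs = default_cnv_freqs(),
                        cnv_evaluable_fraction = 1114 / 1134,
                        coupling = data.frame(
                          gene_i = c("ARID1A", "NF1"),
                          gene_j = c("PTEN", "RUNX1"),
                          odds_ratio = c(0, 6),
                          stringsAsFactors = FALSE),
                        germline_counts = default_germline_counts(),
                        pon_artifacts = 5) {
  if (missing(seed) || is.null(seed)) stop("cohort_spec: seed is mandatory")
  stopifnot(n_samples >= 1)
  if (abs(sum(subtype_proportions) - 1) > 1e-9) {
    stop("cohort_spec: subtype_proportions must sum to 1")
  }
  if (abs(sum(arm_proportions) - 1) > 1e-9) {
    stop("cohort_spec: arm_proportions must sum to 1")
  }
  freqs <- as.matrix(gene_freqs[, subtype_levels()])
  if (any(freqs < 0 | freqs > 1)) stop("cohort_spec: frequencies outside [0, 1]")
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 subtype_proportions = subtype_proportions,
                 arm_proportions = arm_proportions,
                 gene_freqs = gene_freqs, hotspots = hotspots,
                 vaf_params = vaf_params, mean_depth = mean_depth,
                 min_depth = min_depth, cnv_freqs = cnv_freqs,
                 cnv_evaluable_fraction = cnv_evaluable_fraction,
                 coupling = coupling, germline_counts = germline_counts,
                 pon_artifacts = pon_artifacts),
            class = "cohort_spec")
}

#' Expected marginal gene frequencies under a spec
#'
#' The cohort-level mutation probability of each gene implied by the
#' subtype mix: the mixture `sum_s pi_s * f_{g,s}`.
#'
#' @param spec A [cohort_spec()].
#' @return Named numeric vector per gene.
#' @export
expected_gene_freqs <- function(spec) {
  freqs <- as.matrix(spec$gene_freqs[, subtype_levels()])
  setNames(as.numeric(freqs %*% spec$subtype_proportions[subtype_levels()]),
           spec$gene_freqs$gene)
}

# Largest-remainder apportionment of n into counts proportional to p.
apportion <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(p))
}

# Co-occurrence cell p11 of the 2x2 joint law with marginals (p1, p2) and
# odds ratio `or` (Plackett construction); errors when infeasible.
couple_p11 <- function(p1, p2, or, pair = "") {
  lo <- max(0, p1 + p2 - 1); hi <- min(p1, p2)
  p11 <- if (or == 0) 0
         else if (is.infinite(or)) hi
         else if (or == 1) p1 * p2
         else {
           s <- 1 + (p1 + p2) * (or - 1)
           disc <- s^2 - 4 * or * (or - 1) * p1 * p2
           (s - sqrt(disc)) / (2 * (or - 1))
         }
  if (is.nan(p11) || p11 < lo - 1e-12 || p11 > hi + 1e-12) {
    stop(sprintf("infeasible coupling for pair %s: OR=%g with marginals (%g, %g)",
                 pair, or, p1, p2))
  }
  min(max(p11, lo), hi)
}

rtrunc_pois <- function(n, lambda, lower) {
  x <- stats::rpois(n, lambda)
  while (any(x < lower)) {
    bad <- x < lower
    x[bad] <- stats::rpois(sum(bad), lambda)
  }
  x
}

# Deterministic pseudo-locus per gene so variant keys are stable.
gene_locus <- function(genes) {
  h <- vapply(genes, function(g)
    sum(utf8ToInt(g) * seq_along(utf8ToInt(g))), numeric(1))
  data.frame(gene = genes,
             chrom = as.character(1 + (h %% 22)),
             base = 1e6 + (h %% 999) * 1e4,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Draws a fully reproducible cohort from a [cohort_spec()]: per-sample
#' subtype from the mixture proportions, arm/stage/menopause/age clinical
#' covariates, per-gene mutation indicators from the subtype-specific
#' frequencies (with coupled pairs drawn jointly from the 2x2 law matching
#' the target odds ratio within each subtype), hotspot protein changes by
#' their configured shares with the remainder from a positional background
#' model, VAFs from per-gene Beta distributions with read counts from a
#' truncated-Poisson depth model, CNV calls, recurrent sequencing
#' artifacts catalogued in a panel of normals, and germline variants
#' realising the configured carrier structure (alternating known-pathogenic
#' ClinVar records and truncating loss-of-function events) on top of a
#' background of rare VUS and common benign variants.
#'
#' Identical `(spec, seed)` produce identical cohorts; [write_cohort()]
#' emits byte-identical files on rerun.
#'
#' @param spec A [cohort_spec()].
#' @return A [bc_cohort()] with attributes `spec`,
#'   `true_gene_freq` (expected marginal mutation frequency per gene),
#'   `true_hotspot_freq`, `pon` (the PON index) and `gene_context`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  sids <- sprintf("S%04d", seq_len(n))
  pids <- sprintf("P%04d", seq_len(n))

  ## clinical covariates -------------------------------------------------
  subtype <- sample(subtype_levels(), n, replace = TRUE,
                    prob = spec$subtype_proportions[subtype_levels()])
  arm_counts <- apportion(n, spec$arm_proportions)
  arm <- sample(rep(names(arm_counts), arm_counts))
  stage <- character(n)
  for (i in seq_len(n)) {
    stage[i] <- switch(arm[i],
      neoadjuvant = sample(c("II", "III"), 1, prob = c(0.45, 0.55)),
      surgical = sample(c("I", "II", "III"), 1, prob = c(0.45, 0.50, 0.05)),
      advanced = "IV")
  }
  origin <- ifelse(arm == "advanced",
                   ifelse(stats::runif(n) < 0.8, "metastatic", "primary"),
                   "primary")
  menopause <- sample(c("pre", "post", "missing"), n, replace = TRUE,
                      prob = c(0.45, 0.53, 0.02))
  age <- pmin(90, pmax(22, round(stats::rnorm(n, 50.5, 10.5))))

  er <- pr <- her2 <- logical(n)
  ki67 <- numeric(n)
  for (i in seq_len(n)) {
    switch(subtype[i],
      luminal_A = {
        er[i] <- TRUE; pr[i] <- TRUE; her2[i] <- FALSE
        ki67[i] <- round(stats::runif(1, 0.02, 0.14), 2)
      },
      luminal_B_HER2neg = {
        her2[i] <- FALSE
        if (stats::runif(1) < 0.75) { er[i] <- TRUE; pr[i] <- TRUE }
        else { er[i] <- TRUE; pr[i] <- FALSE }
        ki67[i] <- round(stats::runif(1, 0.15, 0.80), 2)
      },
      luminal_B_HER2pos = {
        her2[i] <- TRUE; er[i] <- TRUE
        pr[i] <- stats::runif(1) < 0.7
        ki67[i] <- round(stats::runif(1, 0.05, 0.80), 2)
      },
      HER2pos = {
        her2[i] <- TRUE; er[i] <- FALSE; pr[i] <- FALSE
        ki67[i] <- round(stats::runif(1, 0.10, 0.80), 2)
      },
      triple_negative = {
        er[i] <- FALSE; pr[i] <- FALSE; her2[i] <- FALSE
        ki67[i] <- if (stats::runif(1) < 0.05) NA_real_
                   else round(stats::runif(1, 0.10, 0.90), 2)
      })
  }
  samples <- data.frame(sample_id = sids, patient_id = pids,
                        er_positive = er, pr_positive = pr,
                        her2_positive = her2, ki67_fraction = ki67,
                        stage = stage, cohort_arm = arm,
                        sample_origin = origin, menopause = menopause,
                        age_years = age, subtype = subtype,
                        coarse_subtype = coarse_subtype(subtype),
                        stringsAsFactors = FALSE)

  ## gene mutation indicators -------------------------------------------
  gf <- spec$gene_freqs
  fmat <- as.matrix(gf[, subtype_levels()])
  rownames(fmat) <- gf$gene
  genes <- gf$gene
  coupled_genes <- unique(c(spec$coupling$gene_i, spec$coupling$gene_j))
  ind <- matrix(0L, n, length(genes), dimnames = list(sids, genes))
  sub_idx <- match(subtype, subtype_levels())
  for (g in setdiff(genes, coupled_genes)) {
    ind[, g] <- as.integer(stats::runif(n) < fmat[g, sub_idx])
  }
  if (nrow(spec$coupling) > 0) {
    for (k in seq_len(nrow(spec$coupling))) {
      gi <- spec$coupling$gene_i[k]; gj <- spec$coupling$gene_j[k]
      or <- spec$coupling$odds_ratio[k]
      p11s <- vapply(seq_along(subtype_levels()), function(s)
        couple_p11(fmat[gi, s], fmat[gj, s], or, paste(gi, gj, sep = "-")),
        numeric(1))
      # one uniform per sample over the four joint cells:
      # [0, p11) both | [p11, p1) i only | [p1, p1+p2-p11) j only | rest none
      u <- stats::runif(n)
      p11 <- p11s[sub_idx]
      p1 <- fmat[gi, sub_idx]; p2 <- fmat[gj, sub_idx]
      ind[, gi] <- as.integer(u < p1)
      ind[, gj] <- as.integer(u < p11 | (u >= p1 & u < p1 + p2 - p11))
    }
  }

  ## somatic call records -------------------------------------------------
  loci <- gene_locus(genes)
  hs <- spec$hotspots
  ev <- which(ind == 1L, arr.ind = TRUE)
  n_ev <- nrow(ev)
  gene_of <- genes[ev[, 2]]
  sample_of <- sids[ev[, 1]]
  protein_change <- character(n_ev)
  vclass <- character(n_ev)
  u <- stats::runif(n_ev)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  bg_pos <- 1 + floor(stats::runif(n_ev) * 1200)
  bg_aa1 <- sample(aa, n_ev, replace = TRUE)
  bg_aa2 <- sample(aa, n_ev, replace = TRUE)
  # gene-indicator events are always non-silent: the configured per-gene
  # frequencies are probabilities of a qualifying (non-synonymous) mutation
  bg_class <- sample(c("missense", "nonsense", "frameshift", "splice_site",
                       "inframe_indel", "other"), n_ev, replace = TRUE,
                     prob = c(0.60, 0.12, 0.14, 0.07, 0.04, 0.03))
  for (i in seq_len(n_ev)) {
    g <- gene_of[i]
    rows <- hs[hs$gene == g, , drop = FALSE]
    assigned <- FALSE
    if (nrow(rows) > 0) {
      cuts <- cumsum(rows$fraction)
      j <- which(u[i] < cuts)
      if (length(j) > 0) {
        protein_change[i] <- rows$protein_change[j[1]]
        vclass[i] <- rows$class[j[1]]
        assigned <- TRUE
      }
    }
    if (!assigned) {
      vclass[i] <- bg_class[i]
      protein_change[i] <- switch(bg_class[i],
        frameshift = sprintf("p.%s%dfs", bg_aa1[i], bg_pos[i]),
        nonsense = sprintf("p.%s%dX", bg_aa1[i], bg_pos[i]),
        splice_site = NA_character_,
        inframe_indel = sprintf("p.%s%ddel", bg_aa1[i], bg_pos[i]),
        sprintf("p.%s%d%s", bg_aa1[i], bg_pos[i], bg_aa2[i]))
    }
  }
  vaf <- numeric(n_ev)
  for (g in unique(gene_of)) {
    par <- spec$vaf_params[[g]] %||% spec$vaf_params$.default
    sel <- gene_of == g
    vaf[sel] <- stats::rbeta(sum(sel), par[1], par[2])
  }
  depth <- rtrunc_pois(n_ev, spec$mean_depth, spec$min_depth)
  alt <- pmax(1L, stats::rbinom(n_ev, depth, vaf))
  li <- match(gene_of, loci$gene)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_ev, replace = TRUE)
  alt_allele <- vapply(ref, function(r) sample(setdiff(bases, r), 1),
                       character(1))
  pos <- as.integer(loci$base[li] +
                      ifelse(is.na(protein_change), bg_pos * 3,
                             as.integer(gsub("\\D", "", protein_change)) * 3))
  somatic <- data.frame(
    sample_id = sample_of, gene_symbol = gene_of,
    chrom = loci$chrom[li], pos = pos,
    ref_allele = ref, alt_allele = unname(alt_allele),
    variant_class = vclass, protein_change = protein_change,
    t_alt_count = alt, t_ref_count = depth - alt,
    vaf = alt / depth, stringsAsFactors = FALSE)

  ## synonymous background ------------------------------------------------
  # a thin independent layer of silent calls, so downstream silent-call
  # exclusion has real work; it never touches the gene indicators above
  n_sil <- round(0.05 * n)
  if (n_sil > 0) {
    sil_gene <- sample(genes, n_sil, replace = TRUE)
    sil_pos <- 1 + floor(stats::runif(n_sil) * 1200)
    sil_aa <- sample(aa, n_sil, replace = TRUE)
    sil_vaf <- stats::rbeta(n_sil, 2, 3)
    sil_depth <- rtrunc_pois(n_sil, spec$mean_depth, spec$min_depth)
    sil_alt <- pmax(1L, stats::rbinom(n_sil, sil_depth, sil_vaf))
    sli <- match(sil_gene, loci$gene)
    somatic <- rbind(somatic, data.frame(
      sample_id = sample(sids, n_sil, replace = TRUE),
      gene_symbol = sil_gene, chrom = loci$chrom[sli],
      pos = as.integer(loci$base[sli] + sil_pos * 3 + 1),
      ref_allele = "C", alt_allele = "T", variant_class = "silent",
      protein_change = sprintf("p.%s%d=", sil_aa, sil_pos),
      t_alt_count = sil_alt, t_ref_count = sil_depth - sil_alt,
      vaf = sil_alt / sil_depth, stringsAsFactors = FALSE))
  }

  ## PON artifacts --------------------------------------------------------
  pon <- data.frame(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), n_normals = integer(),
                    stringsAsFactors = FALSE)
  if (spec$pon_artifacts > 0) {
    art_genes <- rep(c("ATM", "EGFR", "ROS1"),
                     length.out = spec$pon_artifacts)
    for (k in seq_len(spec$pon_artifacts)) {
      carriers <- sample(sids, max(2, round(0.02 * n)))
      art <- data.frame(
        sample_id = carriers, gene_symbol = art_genes[k],
        chrom = "7", pos = 1000000L + k,
        ref_allele = "G", alt_allele = "A",
        variant_class = "other", protein_change = NA_character_,
        t_alt_count = 5L, t_ref_count = 95L, vaf = 0.05,
        stringsAsFactors = FALSE)
      somatic <- rbind(somatic, art)
      pon <- rbind(pon, data.frame(chrom = "7", pos = 1000000L + k,
                                   ref = "G", alt = "A",
                                   n_normals = 3L + k,
                                   stringsAsFactors = FALSE))
    }
  }
  ord <- order(somatic$sample_id, somatic$gene_symbol, somatic$pos)
  somatic <- somatic[ord, , drop = FALSE]
  rownames(somatic) <- NULL

  ## CNV ------------------------------------------------------------------
  n_eval <- round(spec$cnv_evaluable_fraction * n)
  cnv_evaluable <- sort(sample(sids, n_eval))
  cnv_list <- list()
  for (k in seq_len(nrow(spec$cnv_freqs))) {
    row <- spec$cnv_freqs[k, ]
    hit <- cnv_evaluable[stats::runif(n_eval) < row$frequency]
    if (length(hit) > 0) {
      cnv_list[[k]] <- data.frame(sample_id = hit, gene_symbol = row$gene,
                                  call = row$call, stringsAsFactors = FALSE)
    }
  }
  cnv <- if (length(cnv_list) > 0) do.call(rbind, cnv_list) else
    data.frame(sample_id = character(), gene_symbol = character(),
               call = character(), stringsAsFactors = FALSE)
  cnv <- cnv[order(cnv$sample_id, cnv$gene_symbol, cnv$call), , drop = FALSE]
  rownames(cnv) <- NULL

  ## germline -------------------------------------------------------------
  gl <- generate_germline(spec, pids)

  cohort <- bc_cohort(samples, somatic, cnv = cnv, germline = gl$variants,
                      cnv_evaluable = cnv_evaluable)
  attr(cohort, "spec") <- spec
  attr(cohort, "true_gene_freq") <- expected_gene_freqs(spec)
  tg <- expected_gene_freqs(spec)
  attr(cohort, "true_hotspot_freq") <-
    setNames(tg[hs$gene] * hs$fraction,
             paste(hs$gene, hs$protein_change, sep = "|"))
  attr(cohort, "pon") <- setNames(as.integer(pon$n_normals),
                                  variant_key(pon$chrom, pon$pos,
                                              pon$ref, pon$alt))
  attr(cohort, "gene_context") <- gl$gene_context
  cohort
}

# Germline layer: deterministic carrier structure + stochastic background.
generate_germline <- function(spec, pids) {
  n <- length(pids)
  counts <- spec$germline_counts
  if (is.null(counts) || nrow(counts) == 0) {
    empty <- data.frame(patient_id = character(), gene_symbol = character(),
                        chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        consequence = character(), af_eas = numeric(),
                        af_overall = numeric(), clinvar_status = character(),
                        same_aa_change_pathogenic = logical(),
                        same_residue_pathogenic = logical(),
                        stringsAsFactors = FALSE)
    return(list(variants = empty,
                gene_context = data.frame(gene = character(),
                                          is_cancer_gene = logical(),
                                          lof_mechanism = logical(),
                                          stringsAsFactors = FALSE)))
  }
  scale <- n / 1134
  counts$n <- if (n == 1134) counts$n_carriers_at_1134 else
    pmax(0L, round(counts$n_carriers_at_1134 * scale))
  events <- rep(counts$gene, counts$n)
  n_carr <- min(n, round(66 * scale))
  carrier_pids <- sample(pids, n_carr)
  loci <- gene_locus(unique(counts$gene))
  rows <- list()
  for (k in seq_along(events)) {
    pid <- carrier_pids[((k - 1) %% n_carr) + 1]
    g <- events[k]
    li <- match(g, loci$gene)
    if (k %% 2 == 1) {
      # route 1: known cancer-related ClinVar pathogenic record
      rows[[k]] <- data.frame(
        patient_id = pid, gene_symbol = g,
        chrom = loci$chrom[li], pos = as.integer(loci$base[li] + k),
        ref = "C", alt = "T", consequence = "missense",
        af_eas = NA_real_, af_overall = 1e-5,
        clinvar_status = "pathogenic_cancer",
        same_aa_change_pathogenic = TRUE,
        same_residue_pathogenic = TRUE, stringsAsFactors = FALSE)
    } else {
      # route 2: truncating loss-of-function event, unreported in ClinVar
      rows[[k]] <- data.frame(
        patient_id = pid, gene_symbol = g,
        chrom = loci$chrom[li], pos = as.integer(loci$base[li] + k),
        ref = "CT", alt = "C", consequence = "frameshift",
        af_eas = NA_real_, af_overall = NA_real_,
        clinvar_status = "unreported",
        same_aa_change_pathogenic = FALSE,
        same_residue_pathogenic = FALSE, stringsAsFactors = FALSE)
    }
  }
  # background: rare VUS missense + common benign variants
  n_bg <- round(0.30 * n)
  bg_genes <- sample(counts$gene, n_bg, replace = TRUE)
  li <- match(bg_genes, loci$gene)
  bg <- data.frame(
    patient_id = sample(pids, n_bg, replace = TRUE),
    gene_symbol = bg_genes, chrom = loci$chrom[li],
    pos = as.integer(loci$base[li] + 5000 + seq_len(n_bg)),
    ref = "G", alt = "A", consequence = "missense",
    af_eas = round(stats::runif(n_bg, 0, 0.004), 6), af_overall = NA_real_,
    clinvar_status = "vus", same_aa_change_pathogenic = FALSE,
    same_residue_pathogenic = FALSE, stringsAsFactors = FALSE)
  n_common <- round(0.05 * n)
  cm_genes <- sample(counts$gene, n_common, replace = TRUE)
  li <- match(cm_genes, loci$gene)
  cm <- data.frame(
    patient_id = sample(pids, n_common, replace = TRUE),
    gene_symbol = cm_genes, chrom = loci$chrom[li],
    pos = as.integer(loci$base[li] + 9000 + seq_len(n_common)),
    ref = "A", alt = "G", consequence = "missense",
    af_eas = round(stats::runif(n_common, 0.005, 0.2), 6),
    af_overall = NA_real_, clinvar_status = "benign",
    same_aa_change_pathogenic = FALSE, same_residue_pathogenic = FALSE,
    stringsAsFactors = FALSE)
  variants <- rbind(do.call(rbind, rows), bg, cm)
  variants <- variants[order(variants$patient_id, variants$gene_symbol,
                             variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  gene_context <- data.frame(gene = sort(unique(counts$gene)),
                             is_cancer_gene = TRUE, lof_mechanism = TRUE,
                             stringsAsFactors = FALSE)
  list(variants = variants, gene_context = gene_context)
}

#' Build a reference frequency table from known frequencies
#'
#' Converts published per-feature frequencies into integer counts for a
#' reference cohort of size `n_total`, with `n_altered = round(freq *
#' n_total)` (round half to even, R's default).
#'
#' @param freq_table Data frame with `feature`, `frequency` columns (an
#'   `n_total` column, if present, is overridden).
#' @param n_total Reference cohort size.
#' @return Data frame `feature`, `n_altered`, `n_total`.
#' @export
make_reference_cohort <- function(freq_table, n_total) {
  stopifnot(all(freq_table$frequency >= 0 & freq_table$frequency <= 1))
  data.frame(feature = freq_table$feature,
             n_altered = as.integer(round(freq_table$frequency * n_total)),
             n_total = as.integer(n_total), stringsAsFactors = FALSE)
}

#' Structureless null alteration matrix
#'
#' Independent Bernoulli cells at a common base frequency; used for
#' false-discovery-rate control checks.
#'
#' @param n_samples,n_features Matrix dimensions.
#' @param base_freq Bernoulli probability per cell.
#' @param seed Mandatory seed.
#' @return Binary integer matrix.
#' @export
null_cohort <- function(n_samples, n_features, base_freq, seed) {
  if (missing(seed)) stop("null_cohort: seed is mandatory")
  set.seed(seed)
  matrix(stats::rbinom(n_samples * n_features, 1, base_freq),
         nrow = n_samples,
         dimnames = list(sprintf("S%04d", seq_len(n_samples)),
                         sprintf("F%04d", seq_len(n_features))))
}

#' Write a generated cohort to disk
#'
#' Emits the exact dialects the readers consume: `somatic.maf` (TCGA MAF
#' columns), `clinical.tsv`, `cnv.tsv`, `germline.tsv`, `pon.tsv`,
#' `gene_context.tsv` and a `manifest.yaml` recording the spec parameters
#' and seed.  Rerunning on the same spec produces byte-identical files.
#'
#' @param cohort Cohort from [generate_cohort()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  spec <- attr(cohort, "spec")
  meta <- list(seed = spec$seed, n_samples = spec$n_samples,
               config = config_hash(list(seed = spec$seed,
                                         n_samples = spec$n_samples)))
  class_rev <- c(missense = "Missense_Mutation", nonsense = "Nonsense_Mutation",
                 frameshift = "Frame_Shift_Del", splice_site = "Splice_Site",
                 inframe_indel = "In_Frame_Del", silent = "Silent",
                 other = "Translation_Start_Site")
  som <- cohort$somatic
  maf <- data.frame(
    Hugo_Symbol = som$gene_symbol, Chromosome = som$chrom,
    Start_Position = som$pos, Reference_Allele = som$ref_allele,
    Tumor_Seq_Allele2 = som$alt_allele,
    Variant_Classification = unname(class_rev[som$variant_class]),
    HGVSp_Short = som$protein_change,
    t_alt_count = som$t_alt_count, t_ref_count = som$t_ref_count,
    Tumor_Sample_Barcode = som$sample_id, stringsAsFactors = FALSE)
  pon_idx <- attr(cohort, "pon")
  keys <- strsplit(names(pon_idx), ":", fixed = TRUE)
  pon_df <- data.frame(
    chrom = vapply(keys, `[`, character(1), 1),
    pos = as.integer(vapply(keys, `[`, character(1), 2)),
    ref = vapply(keys, `[`, character(1), 3),
    alt = vapply(keys, `[`, character(1), 4),
    n_normals = as.integer(pon_idx), stringsAsFactors = FALSE)
  paths <- c(somatic = file.path(outdir, "somatic.maf"),
             clinical = file.path(outdir, "clinical.tsv"),
             cnv = file.path(outdir, "cnv.tsv"),
             germline = file.path(outdir, "germline.tsv"),
             pon = file.path(outdir, "pon.tsv"),
             gene_context = file.path(outdir, "gene_context.tsv"),
             cnv_evaluable = file.path(outdir, "cnv_evaluable.tsv"),
             manifest = file.path(outdir, "manifest.yaml"))
  write_tsv_meta(maf, paths["somatic"], meta)
  write_tsv_meta(cohort$samples, paths["clinical"], meta)
  write_tsv_meta(cohort$cnv, paths["cnv"], meta)
  write_tsv_meta(cohort$germline, paths["germline"], meta)
  write_tsv_meta(pon_df, paths["pon"], meta)
  write_tsv_meta(attr(cohort, "gene_context"), paths["gene_context"], meta)
  write_tsv_meta(data.frame(sample_id = cohort$cnv_evaluable,
                            stringsAsFactors = FALSE),
                 paths["cnv_evaluable"], meta)
  yaml::write_yaml(list(tool = paste0("bcpanel ", .bcpanel_version()),
                        seed = spec$seed, n_samples = spec$n_samples,
                        subtype_proportions = as.list(spec$subtype_proportions),
                        arm_proportions = as.list(spec$arm_proportions)),
                   paths["manifest"])
  invisible(paths)
}
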