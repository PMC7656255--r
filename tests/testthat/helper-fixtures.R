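# Small in-code fixtures shared across test files.

make_somatic <- function(sample_id, gene_symbol,
                         variant_class = "missense",
                         protein_change = NA_character_,
                         t_alt_count = 30L, t_ref_count = 70L,
                         chrom = "1", pos = seq_along(sample_id)) {
  data.frame(sample_id = sample_id, gene_symbol = gene_symbol,
             chrom = chrom, pos = as.integer(pos),
             ref_allele = "A", alt_allele = "T",
             variant_class = variant_class, protein_change = protein_change,
             t_alt_count = as.integer(t_alt_count),
             t_ref_count = as.integer(t_ref_count),
             vaf = t_alt_count / (t_alt_count + t_ref_count),
             stringsAsFactors = FALSE)
}

make_samples <- function(n, subtype = "luminal_A", stage = "II",
                         cohort_arm = "surgical", menopause = "post") {
  ids <- sprintf("S%03d", seq_len(n))
  ihc <- list(
    luminal_A = list(er = TRUE, pr = TRUE, her2 = FALSE, ki67 = 0.10),
    luminal_B_HER2neg = list(er = TRUE, pr = TRUE, her2 = FALSE, ki67 = 0.30),
    luminal_B_HER2pos = list(er = TRUE, pr = TRUE, her2 = TRUE, ki67 = 0.30),
    HER2pos = list(er = FALSE, pr = FALSE, her2 = TRUE, ki67 = 0.30),
    triple_negative = list(er = FALSE, pr = FALSE, her2 = FALSE, ki67 = 0.50))
  st <- rep_len(subtype, n)
  get <- function(field) vapply(st, function(s) ihc[[s]][[field]], numeric(1))
  data.frame(sample_id = ids, patient_id = sub("S", "P", ids),
             er_positive = as.logical(get("er")),
             pr_positive = as.logical(get("pr")),
             her2_positive = as.logical(get("her2")),
             ki67_fraction = get("ki67"),
             stage = rep_len(stage, n), cohort_arm = rep_len(cohort_arm, n),
             sample_origin = rep_len("primary", n),
             menopause = rep_len(menopause, n),
             age_years = rep_len(50L, n), subtype = st,
             coarse_subtype = coarse_subtype(st),
             stringsAsFactors = FALSE)
}

make_germline <- function(patient_id, gene_symbol,
                          consequence = "missense",
                          af_eas = NA_real_,
                          clinvar_status = "unreported",
                          same_aa = FALSE, same_residue = FALSE) {
  data.frame(patient_id = patient_id, gene_symbol = gene_symbol,
             chrom = "17", pos = seq_along(patient_id),
             ref = "C", alt = "T", consequence = consequence,
             af_eas = af_eas, af_overall = NA_real_,
             clinvar_status = clinvar_status,
             same_aa_change_pathogenic = same_aa,
             same_residue_pathogenic = same_residue,
             stringsAsFactors = FALSE)
}

make_gene_context <- function(genes, is_cancer_gene = TRUE,
                              lof_mechanism = TRUE) {
  data.frame(gene = genes, is_cancer_gene = is_cancer_gene,
             lof_mechanism = lof_mechanism, stringsAsFactors = FALSE)
}

# Twenty constructed germline variants with hand-derived evidence and
# expected classes (each annotated with the module arithmetic that leads
# to the class).  Returns the input table, gene context and expectations.
golden_germline_set <- function() {
  ctx <- make_gene_context(c("BRCA1", "BRCA2", "TP53", "CHEK2", "ATM",
                             "PALB2"))
  ctx <- rbind(ctx, data.frame(gene = "ODDGENE", is_cancer_gene = TRUE,
                               lof_mechanism = FALSE))
  cases <- list(
    # consequence, gene, clinvar, same_aa, same_residue, expected class
    list("frameshift", "BRCA1", "unreported", FALSE, FALSE, "likely_pathogenic"),   # PVS1=8>7
    list("frameshift", "BRCA1", "pathogenic_cancer", FALSE, FALSE, "pathogenic"),
    list("missense", "TP53", "pathogenic_cancer", TRUE, TRUE, "pathogenic"),
    list("missense", "TP53", "unreported", TRUE, TRUE, "uncertain"),                # PS1=7, not >7
    list("stop_gained", "CHEK2", "unreported", FALSE, FALSE, "likely_pathogenic"),  # PVS1
    list("canonical_splice", "ATM", "unreported", FALSE, FALSE, "likely_pathogenic"),
    list("start_lost", "PALB2", "unreported", FALSE, FALSE, "likely_pathogenic"),
    list("inframe_indel", "BRCA2", "unreported", FALSE, FALSE, "uncertain"),        # PM4=2
    list("missense", "BRCA2", "unreported", FALSE, TRUE, "uncertain"),              # PM5=2
    list("missense", "TP53", "vus", TRUE, FALSE, "uncertain"),                      # PS1=7
    list("frameshift", "BRCA1", "unreported", TRUE, FALSE, "likely_pathogenic"),    # PVS1+PS1=15
    list("missense", "BRCA1", "unreported", FALSE, FALSE, "uncertain"),             # no evidence
    list("frameshift", "ODDGENE", "unreported", FALSE, FALSE, "uncertain"),         # no LOF mechanism
    list("frameshift", "UNLISTED", "unreported", FALSE, FALSE, "uncertain"),        # gene not in context
    list("missense", "CHEK2", "pathogenic_cancer", FALSE, FALSE, "pathogenic"),     # ClinVar route only
    list("frameshift", "BRCA2", "pathogenic_other", FALSE, FALSE, "likely_pathogenic"), # not cancer-related
    list("inframe_indel", "TP53", "unreported", FALSE, TRUE, "uncertain"),          # PM5 needs missense
    list("stop_gained", "BRCA2", "benign", FALSE, FALSE, "likely_pathogenic"),      # PVS1 regardless
    list("missense", "ATM", "unreported", TRUE, TRUE, "uncertain"),                 # PS1 only
    list("weird_consequence", "BRCA1", "unreported", FALSE, FALSE, "uncertain"))    # unknown -> other
  variants <- make_germline(
    sprintf("P%02d", seq_along(cases)),
    vapply(cases, `[[`, character(1), 2),
    consequence = vapply(cases, `[[`, character(1), 1),
    clinvar_status = vapply(cases, `[[`, character(1), 3),
    same_aa = vapply(cases, `[[`, logical(1), 4),
    same_residue = vapply(cases, `[[`, logical(1), 5))
  list(variants = variants, context = ctx,
       expected = vapply(cases, `[[`, character(1), 6))
}

# A tiny generator spec used where full default scale is unnecessary.
tiny_spec <- function(seed, n = 60) {
  cohort_spec(n_samples = n, seed = seed,
              germline_counts = data.frame(gene = "BRCA1",
                                           n_carriers_at_1134 = 20L),
              pon_artifacts = 1)
}
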