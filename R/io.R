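#' Variant class vocabulary
#'
#' Internal consequence classes for somatic calls.  `"silent"` is carried
#' through ingestion so synonymous rows can be counted and excluded at
#' matrix construction rather than dropped silently.
#'
#' @return Character vector of class labels.
#' @export
variant_class_levels <- function() {
  c("missense", "nonsense", "frameshift", "splice_site",
    "inframe_indel", "silent", "other")
}

#' Non-silent classes that qualify a gene as altered
#' @rdname variant_class_levels
#' @export
nonsilent_classes <- function() {
  setdiff(variant_class_levels(), "silent")
}

# Documented mapping from TCGA MAF Variant_Classification strings to the
# internal vocabulary.  Unlisted strings map to "other".
maf_class_map <- function() {
  c(Missense_Mutation = "missense",
    Nonsense_Mutation = "nonsense",
    Frame_Shift_Del   = "frameshift",
    Frame_Shift_Ins   = "frameshift",
    Splice_Site       = "splice_site",
    Splice_Region     = "splice_site",
    In_Frame_Del      = "inframe_indel",
    In_Frame_Ins      = "inframe_indel",
    Silent            = "silent",
    Synonymous        = "silent")
}

somatic_columns <- function() {
  c("sample_id", "gene_symbol", "chrom", "pos", "ref_allele", "alt_allele",
    "variant_class", "protein_change", "t_alt_count", "t_ref_count", "vaf")
}

empty_somatic <- function() {
  df <- data.frame(sample_id = character(), gene_symbol = character(),
                   chrom = character(), pos = integer(),
                   ref_allele = character(), alt_allele = character(),
                   variant_class = character(), protein_change = character(),
                   t_alt_count = integer(), t_ref_count = integer(),
                   vaf = numeric(), stringsAsFactors = FALSE)
  df
}

#' Key identifying a variant position and allele change
#'
#' @param chrom,pos,ref,alt Vectors describing 1-based variant coordinates
#'   and alleles.
#' @return Character vector `"chrom:pos:ref:alt"`.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Validate a raw somatic data frame; returns list(mutations, rejects).
# VAF is always recomputed from counts when both are present.
validate_somatic <- function(df) {
  n <- nrow(df)
  reason <- character(n)
  df$t_alt_count <- suppressWarnings(as.integer(df$t_alt_count))
  df$t_ref_count <- suppressWarnings(as.integer(df$t_ref_count))
  df$pos <- suppressWarnings(as.integer(df$pos))
  have_counts <- !is.na(df$t_alt_count) & !is.na(df$t_ref_count)
  depth <- df$t_alt_count + df$t_ref_count

  bad_gene <- is.na(df$gene_symbol) | df$gene_symbol == ""
  reason[bad_gene] <- "missing gene symbol"
  bad_depth <- have_counts & depth == 0
  reason[bad_depth & reason == ""] <- "zero depth"
  bad_class <- !(df$variant_class %in% variant_class_levels())
  reason[bad_class & reason == ""] <- "unknown variant class"
  no_vaf <- !have_counts & (is.na(df$vaf) | df$vaf < 0 | df$vaf > 1)
  reason[no_vaf & reason == ""] <- "no usable VAF or read counts"

  ok <- reason == ""
  df$vaf[ok & have_counts] <-
    df$t_alt_count[ok & have_counts] / depth[ok & have_counts]
  rejects <- df[!ok, , drop = FALSE]
  rejects$reject_reason <- reason[!ok]
  rownames(rejects) <- NULL
  kept <- df[ok, , drop = FALSE]
  rownames(kept) <- NULL
  list(mutations = kept, rejects = rejects)
}

#' Read somatic mutation calls
#'
#' Ingests somatic calls in one of three dialects and validates every row.
#' Rows failing validation are returned in a rejects report with a reason,
#' never dropped silently; VAF is recomputed from read counts whenever both
#' counts are present.
#'
#' Dialects:
#' \describe{
#'   \item{`maf`}{standard TCGA MAF column names (`Hugo_Symbol`,
#'     `Chromosome`, `Start_Position`, `Reference_Allele`,
#'     `Tumor_Seq_Allele2`, `Variant_Classification`, `HGVSp_Short`,
#'     `t_alt_count`, `t_ref_count`, `Tumor_Sample_Barcode`);
#'     `Variant_Classification` strings are mapped to the internal
#'     vocabulary, unknown strings to `"other"`.}
#'   \item{`minimal_tsv`}{the package's own long format with the internal
#'     column names (see [variant_class_levels()]).}
#'   \item{`vcf`}{a single-sample somatic VCF 4.x read via \pkg{vcfR};
#'     gene, protein change and class are taken from the INFO keys `GENE`,
#'     `AACHANGE` and `CLASS`, allele depths from the `AD` FORMAT field and
#'     the sample id from the genotype column name.}
#' }
#'
#' @param path Path to the input file.
#' @param dialect One of `"maf"`, `"minimal_tsv"`, `"vcf"`.
#' @return List with elements `mutations` (validated data frame, one row
#'   per call) and `rejects` (failed rows plus a `reject_reason` column).
#' @export
read_somatic_table <- function(path, dialect = c("maf", "minimal_tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_somatic_table: file not found: ", path)
  if (dialect == "maf") {
    raw <- read_tsv_meta(path)
    require_columns(raw, c("Hugo_Symbol", "Chromosome", "Start_Position",
                           "Reference_Allele", "Tumor_Seq_Allele2",
                           "Variant_Classification", "t_alt_count",
                           "t_ref_count", "Tumor_Sample_Barcode"),
                    "MAF somatic table")
    if (nrow(raw) == 0) {
      return(list(mutations = empty_somatic(),
                  rejects = cbind(empty_somatic(),
                                  data.frame(reject_reason = character()))))
    }
    map <- maf_class_map()
    cls <- unname(map[raw$Variant_Classification])
    cls[is.na(cls)] <- "other"
    df <- data.frame(
      sample_id = as.character(raw$Tumor_Sample_Barcode),
      gene_symbol = as.character(raw$Hugo_Symbol),
      chrom = as.character(raw$Chromosome),
      pos = raw$Start_Position,
      ref_allele = as.character(raw$Reference_Allele),
      alt_allele = as.character(raw$Tumor_Seq_Allele2),
      variant_class = cls,
      protein_change = if ("HGVSp_Short" %in% names(raw))
        as.character(raw$HGVSp_Short) else NA_character_,
      t_alt_count = raw$t_alt_count,
      t_ref_count = raw$t_ref_count,
      vaf = NA_real_,
      stringsAsFactors = FALSE)
  } else if (dialect == "minimal_tsv") {
    raw <- read_tsv_meta(path)
    require_columns(raw, setdiff(somatic_columns(), c("vaf", "protein_change")),
                    "minimal somatic table")
    df <- raw
    if (!"vaf" %in% names(df)) df$vaf <- NA_real_
    if (!"protein_change" %in% names(df)) df$protein_change <- NA_character_
    df <- df[, somatic_columns()]
  } else {
    df <- read_somatic_vcf(path)
  }
  if (nrow(df) == 0) {
    return(list(mutations = empty_somatic(),
                rejects = cbind(empty_somatic(),
                                data.frame(reject_reason = character()))))
  }
  validate_somatic(df)
}

# Single-sample somatic VCF via vcfR; see read_somatic_table() docs for the
# expected INFO/FORMAT conventions.
read_somatic_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)  # always a matrix
  if (nrow(fix) == 0) return(empty_somatic())
  info_field <- function(key) {
    vcfR::extract.info(v, element = key)
  }
  gt_cols <- colnames(v@gt)
  sample_name <- if (length(gt_cols) >= 2) gt_cols[2] else "SAMPLE"
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  t_ref <- t_alt <- rep(NA_integer_, nrow(fix))
  if (!is.null(ad)) {
    parts <- strsplit(as.character(ad[, 1]), ",", fixed = TRUE)
    t_ref <- vapply(parts, function(p)
      suppressWarnings(as.integer(p[1])), integer(1))
    t_alt <- vapply(parts, function(p)
      if (length(p) >= 2) suppressWarnings(as.integer(p[2])) else NA_integer_,
      integer(1))
  }
  cls <- info_field("CLASS")
  cls[is.na(cls) | !(cls %in% variant_class_levels())] <- "other"
  data.frame(
    sample_id = sample_name,
    gene_symbol = as.character(info_field("GENE")),
    chrom = fix$CHROM,
    pos = fix$POS,
    ref_allele = fix$REF,
    alt_allele = fix$ALT,
    variant_class = cls,
    protein_change = as.character(info_field("AACHANGE")),
    t_alt_count = t_alt,
    t_ref_count = t_ref,
    vaf = NA_real_,
    stringsAsFactors = FALSE)
}

#' Read the clinical sample table
#'
#' Tab-separated with columns `sample_id`, `patient_id`, `er_positive`,
#' `pr_positive`, `her2_positive`, `ki67_fraction`, and optionally `stage`,
#' `cohort_arm`, `sample_origin`, `menopause`, `age_years`, `subtype`.  The
#' molecular subtype is derived from IHC when absent; when a `subtype`
#' column is present it is cross-checked against the derivation and
#' mismatches are reported in the `subtype_mismatches` attribute (with both
#' values) alongside a warning.  Duplicate sample ids are an error.
#'
#' @param path Path to the clinical TSV.
#' @return Data frame of samples with derived `subtype` and
#'   `coarse_subtype` columns.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("read_clinical_table: file not found: ", path)
  raw <- read_tsv_meta(path)
  require_columns(raw, c("sample_id", "patient_id", "er_positive",
                         "pr_positive", "her2_positive", "ki67_fraction"),
                  "clinical table")
  dup <- unique(raw$sample_id[duplicated(raw$sample_id)])
  if (length(dup) > 0) {
    stop("read_clinical_table: duplicate sample_id(s): ",
         paste(dup, collapse = ", "))
  }
  for (col in c("er_positive", "pr_positive", "her2_positive")) {
    raw[[col]] <- as.logical(raw[[col]])
  }
  raw$ki67_fraction <- as.numeric(raw$ki67_fraction)
  for (col in c("stage", "cohort_arm", "sample_origin", "menopause")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
    raw[[col]] <- as.character(raw[[col]])
  }
  if (!"age_years" %in% names(raw)) raw$age_years <- NA_integer_
  derived <- derive_subtype(raw$er_positive, raw$pr_positive,
                            raw$her2_positive, raw$ki67_fraction)
  mism <- NULL
  if ("subtype" %in% names(raw)) {
    bad <- !is.na(raw$subtype) & raw$subtype != derived
    if (any(bad)) {
      mism <- data.frame(sample_id = raw$sample_id[bad],
                         stated_subtype = raw$subtype[bad],
                         derived_subtype = derived[bad],
                         stringsAsFactors = FALSE)
      warning(sprintf(
        "read_clinical_table: %d sample(s) with stated subtype differing from the IHC derivation; see attr(., 'subtype_mismatches')",
        nrow(mism)))
    }
  }
  raw$subtype <- derived
  raw$coarse_subtype <- coarse_subtype(derived)
  attr(raw, "subtype_mismatches") <- mism
  raw
}

#' Read gene-level copy-number calls
#'
#' TSV with columns `sample_id`, `gene_symbol`, `call` (one of
#' `"amplification"`, `"deletion"`).  Duplicate (sample, gene, call) rows
#' are collapsed to one record.
#'
#' @param path Path to the CNV TSV.
#' @return Data frame of CNV calls.
#' @export
read_cnv_table <- function(path) {
  if (!file.exists(path)) stop("read_cnv_table: file not found: ", path)
  raw <- read_tsv_meta(path)
  require_columns(raw, c("sample_id", "gene_symbol", "call"), "CNV table")
  bad <- !(raw$call %in% c("amplification", "deletion"))
  if (any(bad)) {
    stop("read_cnv_table: unknown call value(s): ",
         paste(unique(raw$call[bad]), collapse = ", "))
  }
  out <- unique(raw[, c("sample_id", "gene_symbol", "call")])
  rownames(out) <- NULL
  out
}

#' Read a panel-of-normals index
#'
#' A panel of normals (PON) catalogues variants observed in normal samples;
#' somatic call sets are screened against it to remove residual germline
#' variation and recurrent artifacts.  Input TSV columns: `chrom`, `pos`,
#' `ref`, `alt`, `n_normals`.
#'
#' @param path Path to the PON TSV.
#' @return Named integer vector: counts keyed by [variant_key()].
#' @export
read_pon_table <- function(path) {
  if (!file.exists(path)) stop("read_pon_table: file not found: ", path)
  raw <- read_tsv_meta(path)
  require_columns(raw, c("chrom", "pos", "ref", "alt", "n_normals"),
                  "PON table")
  if (any(raw$n_normals < 0)) stop("read_pon_table: negative n_normals")
  setNames(as.integer(raw$n_normals),
           variant_key(raw$chrom, raw$pos, raw$ref, raw$alt))
}

#' Screen somatic calls against a panel of normals
#'
#' A mutation is removed iff its variant key appears in the PON with a
#' count exceeding `max_pon_count`; variants absent from the index are
#' treated as count 0 and kept.  Input order is preserved in both outputs
#' and `kept` plus `removed` partition the input.
#'
#' @param mutations Somatic mutation data frame.
#' @param pon_index Named counts from [read_pon_table()].
#' @param max_pon_count Maximum tolerated number of normals (default 0:
#'   any PON occurrence removes the call).
#' @return List with data frames `kept` and `removed`.
#' @export
pon_filter <- function(mutations, pon_index, max_pon_count = 0) {
  stopifnot(max_pon_count >= 0)
  if (nrow(mutations) == 0) return(list(kept = mutations, removed = mutations))
  key <- variant_key(mutations$chrom, mutations$pos,
                     mutations$ref_allele, mutations$alt_allele)
  count <- unname(pon_index[key])
  count[is.na(count)] <- 0L
  drop <- count > max_pon_count
  list(kept = mutations[!drop, , drop = FALSE],
       removed = mutations[drop, , drop = FALSE])
}

#' Assemble a cohort object
#'
#' Bundles the clinical table with somatic, CNV and germline calls after
#' referential checks: sample ids must be unique and every somatic or CNV
#' record must point at a known sample.
#'
#' @param samples Clinical data frame (from [read_clinical_table()] or
#'   [generate_cohort()]).
#' @param somatic Somatic mutation data frame.
#' @param cnv Optional CNV call data frame.
#' @param germline Optional germline variant data frame.
#' @param cnv_evaluable Optional character vector of sample ids in which
#'   copy number could be determined; defaults to all samples.
#' @return Object of class `bc_cohort`.
#' @export
bc_cohort <- function(samples, somatic, cnv = NULL, germline = NULL,
                      cnv_evaluable = NULL) {
  dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
  if (length(dup) > 0) {
    stop("bc_cohort: duplicate sample_id(s): ", paste(dup, collapse = ", "))
  }
  orphan <- setdiff(somatic$sample_id, samples$sample_id)
  if (length(orphan) > 0) {
    stop("bc_cohort: somatic calls reference unknown sample(s): ",
         paste(utils::head(orphan, 5), collapse = ", "))
  }
  if (!is.null(cnv)) {
    orphan <- setdiff(cnv$sample_id, samples$sample_id)
    if (length(orphan) > 0) {
      stop("bc_cohort: CNV calls reference unknown sample(s): ",
           paste(utils::head(orphan, 5), collapse = ", "))
    }
  }
  if (is.null(cnv_evaluable)) cnv_evaluable <- samples$sample_id
  structure(list(samples = samples, somatic = somatic, cnv = cnv,
                 germline = germline, cnv_evaluable = cnv_evaluable),
            class = "bc_cohort")
}

#' @export
print.bc_cohort <- function(x, ...) {
  cat(sprintf("<bc_cohort> %d samples, %d somatic calls, %d CNV calls, %d germline variants\n",
              nrow(x$samples), nrow(x$somatic),
              if (is.null(x$cnv)) 0L else nrow(x$cnv),
              if (is.null(x$germline)) 0L else nrow(x$germline)))
  tab <- table(x$samples$subtype)
  cat("subtypes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Build a binary alteration matrix
#'
#' Samples-by-features 0/1 matrix.  At gene level a cell is 1 iff the
#' sample carries at least one non-silent somatic mutation in the gene
#' (silent calls are excluded, with the excluded count recorded in the
#' `n_silent_excluded` attribute) and, when `include_cnv`, a CNV call also
#' sets the cell.  Samples with no qualifying alteration are kept as
#' all-zero rows.  At pathway level the gene matrix is collapsed through
#' the catalog via [pathway_matrix()].
#'
#' @param cohort A [bc_cohort()] object.
#' @param feature_level `"gene"` or `"pathway"`.
#' @param include_cnv Count CNV calls as alterations (default `FALSE`).
#' @param catalog Pathway catalog (required for `feature_level =
#'   "pathway"`); see [load_catalog()].
#' @return Binary integer matrix with samples in rows.
#' @export
build_alteration_matrix <- function(cohort, feature_level = c("gene", "pathway"),
                                    include_cnv = FALSE, catalog = NULL) {
  feature_level <- match.arg(feature_level)
  som <- cohort$somatic
  silent <- som$variant_class == "silent"
  n_silent <- sum(silent)
  som <- som[!silent, , drop = FALSE]
  genes <- sort(unique(c(som$gene_symbol,
                         if (include_cnv && !is.null(cohort$cnv))
                           cohort$cnv$gene_symbol)))
  sids <- cohort$samples$sample_id
  mat <- matrix(0L, nrow = length(sids), ncol = length(genes),
                dimnames = list(sids, genes))
  if (nrow(som) > 0) {
    mat[cbind(match(som$sample_id, sids), match(som$gene_symbol, genes))] <- 1L
  }
  if (include_cnv && !is.null(cohort$cnv) && nrow(cohort$cnv) > 0) {
    mat[cbind(match(cohort$cnv$sample_id, sids),
              match(cohort$cnv$gene_symbol, genes))] <- 1L
  }
  attr(mat, "n_silent_excluded") <- n_silent
  if (feature_level == "pathway") {
    if (is.null(catalog)) {
      stop("build_alteration_matrix: a pathway catalog is required at pathway level")
    }
    return(pathway_matrix(mat, catalog))
  }
  mat
}

#' Write / read an alteration matrix as TSV
#'
#' The wide TSV has samples in rows and features in columns; the companion
#' long format lists one `(sample_id, feature, altered)` row per nonzero
#' cell.  `read_matrix(write_matrix(m))` is the identity.
#'
#' @param mat Binary matrix with dimnames.
#' @param path Output path.
#' @param meta Named list of metadata for the `#` header.
#' @return `write_matrix` the path, invisibly; `read_matrix` the matrix.
#' @export
write_matrix <- function(mat, path, meta = list()) {
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_meta(df, path, meta)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- read_tsv_meta(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "integer"
  m
}

#' Long-format export of an alteration matrix
#'
#' Oncoprint-ready long table: one row per altered (sample, feature) cell.
#'
#' @param mat Binary matrix.
#' @return Data frame with columns `sample_id`, `feature`.
#' @export
matrix_to_long <- function(mat) {
  idx <- which(mat != 0, arr.ind = TRUE)
  out <- data.frame(sample_id = rownames(mat)[idx[, 1]],
                    feature = colnames(mat)[idx[, 2]],
                    stringsAsFactors = FALSE)
  out[order(out$sample_id, out$feature), , drop = FALSE]
}
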