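#' Default run configuration
#'
#' Thresholds used across the pipeline, each anchored to the analysis that
#' owns it: hotspot cohort-frequency cutoff 2\%, subtype-enrichment FDR
#' 0.25, cross-cohort and pairwise-association FDR 0.05, germline
#' East-Asian allele-frequency cutoff 0.5\%, evidence-score cutoff 7
#' (strict), and panel-of-normals maximum count 0.
#'
#' @param input_dir Directory holding the input tables (the layout written
#'   by [write_cohort()]).
#' @param outdir Output directory.
#' @param seed Integer seed echoed into every output header.
#' @param overrides Named list of threshold overrides.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(input_dir, outdir, seed = 1L, overrides = list()) {
  cfg <- list(
    input_dir = input_dir, outdir = outdir, seed = as.integer(seed),
    somatic = file.path(input_dir, "somatic.maf"),
    clinical = file.path(input_dir, "clinical.tsv"),
    cnv = file.path(input_dir, "cnv.tsv"),
    germline = file.path(input_dir, "germline.tsv"),
    pon = file.path(input_dir, "pon.tsv"),
    gene_context = file.path(input_dir, "gene_context.tsv"),
    cnv_evaluable = file.path(input_dir, "cnv_evaluable.tsv"),
    hotspot_min_frequency = 0.02,
    subtype_fdr = 0.25,
    compare_fdr = 0.05,
    pairwise_fdr = 0.05,
    germline_max_eas_af = 0.005,
    charger_cutoff = 7,
    pon_max_count = 0)
  cfg <- utils::modifyList(cfg, overrides)
  valid <- cfg$hotspot_min_frequency > 0 && cfg$hotspot_min_frequency < 1 &&
    cfg$subtype_fdr > 0 && cfg$subtype_fdr < 1 &&
    cfg$compare_fdr > 0 && cfg$compare_fdr < 1 &&
    cfg$germline_max_eas_af > 0 && cfg$germline_max_eas_af <= 1 &&
    cfg$pon_max_count >= 0
  if (!valid) stop("run_config: threshold outside its valid range")
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#'
#' Flat keys mirroring [run_config()]; explicit arguments override file
#' values.
#'
#' @param path YAML file.
#' @param overrides Named list applied on top of the file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$input_dir), !is.null(y$outdir))
  run_config(y$input_dir, y$outdir, seed = y$seed %||% 1L,
             overrides = utils::modifyList(
               y[setdiff(names(y), c("input_dir", "outdir", "seed"))],
               overrides))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full interpretation pipeline
#'
#' Executes ingest, panel-of-normals filtering, mutation landscape,
#' subtype and covariate enrichment, pathway aggregation with pairwise
#' exclusivity/co-occurrence analysis, germline classification and
#' actionability tiering, writing one TSV per result next to a `config.yaml`
#' echo.  Every output carries a `#` header with the tool version, config
#' hash and seed; record counts entering and leaving each filter are
#' logged in `log.tsv`.  All inputs are checked before any stage runs, and
#' a failure inside a stage is reported with the stage name.  Outputs are
#' deterministic functions of the inputs: rerunning on identical inputs
#' reproduces byte-identical files.
#'
#' @param config A [run_config()].
#' @param catalog Pathway catalog (default: the shipped catalog).
#' @param kb Actionability knowledge base (default: the shipped KB).
#' @param reference Optional reference frequency table (`feature`,
#'   `n_altered`, `n_total`) for the pathway-level cross-cohort
#'   comparison; defaults to the built-in Western-style pathway reference.
#' @return Invisible list of the in-memory results.
#' @export
run_pipeline <- function(config, catalog = load_catalog(), kb = load_kb(),
                         reference = make_reference_cohort(
                           default_reference_pathway_freqs(), 869)) {
  stopifnot(inherits(config, "run_config"))
  for (f in c("somatic", "clinical", "cnv", "germline", "pon",
              "gene_context")) {
    if (!file.exists(config[[f]])) {
      stop(sprintf("run_pipeline: missing input file (%s): %s", f, config[[f]]))
    }
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config[!(names(config) %in% c("input_dir", "outdir"))])
  meta <- list(config = hash, seed = config$seed)
  log <- list()
  note <- function(stage_name, what, n_in, n_out) {
    log[[length(log) + 1]] <<- data.frame(stage = stage_name, what = what,
                                          n_in = n_in, n_out = n_out,
                                          stringsAsFactors = FALSE)
  }
  out <- function(df, name) write_tsv_meta(df, file.path(config$outdir, name), meta)

  ## ingest ---------------------------------------------------------------
  ingest <- stage("ingest", {
    som <- read_somatic_table(config$somatic, dialect = "maf")
    clin <- read_clinical_table(config$clinical)
    cnv <- read_cnv_table(config$cnv)
    pon <- read_pon_table(config$pon)
    germ <- read_germline_table(config$germline)
    ctx <- read_gene_context(config$gene_context)
    evaluable <- if (file.exists(config$cnv_evaluable))
      read_tsv_meta(config$cnv_evaluable)$sample_id else clin$sample_id
    list(som = som, clin = clin, cnv = cnv, pon = pon, germ = germ,
         ctx = ctx, evaluable = evaluable)
  })
  note("ingest", "somatic calls read", NA,
       nrow(ingest$som$mutations) + nrow(ingest$som$rejects))
  note("ingest", "somatic calls rejected", nrow(ingest$som$mutations) +
         nrow(ingest$som$rejects), nrow(ingest$som$rejects))
  if (nrow(ingest$som$rejects) > 0) out(ingest$som$rejects, "somatic_rejects.tsv")

  ## PON filter -----------------------------------------------------------
  filtered <- stage("pon_filter", {
    pon_filter(ingest$som$mutations, ingest$pon, config$pon_max_count)
  })
  note("pon_filter", "somatic calls", nrow(ingest$som$mutations),
       nrow(filtered$kept))
  cohort <- stage("assemble", {
    bc_cohort(ingest$clin, filtered$kept, cnv = ingest$cnv,
              germline = ingest$germ, cnv_evaluable = ingest$evaluable)
  })

  ## landscape ------------------------------------------------------------
  landscape <- stage("landscape", {
    gmat <- build_alteration_matrix(cohort, "gene")
    freq_all <- gene_frequency(cohort, "none")
    freq_sub <- gene_frequency(cohort, "subtype")
    hs <- detect_hotspots(cohort$somatic, nrow(cohort$samples),
                          config$hotspot_min_frequency)
    top <- freq_all$feature[seq_len(min(10, nrow(freq_all)))]
    vafs <- vaf_summary(cohort$somatic, top)
    load <- mutation_load(cohort)
    cnvf <- cnv_frequency(cohort, "none")
    list(gmat = gmat, freq_all = freq_all, freq_sub = freq_sub, hs = hs,
         vafs = vafs, load = load, cnvf = cnvf)
  })
  out(landscape$freq_all, "gene_frequency.tsv")
  out(landscape$freq_sub, "gene_frequency_by_subtype.tsv")
  out(landscape$hs, "hotspots.tsv")
  out(landscape$vafs$summary, "vaf_summary.tsv")
  out(landscape$load$per_sample, "mutation_load.tsv")
  out(landscape$cnvf, "cnv_frequency.tsv")
  write_matrix(landscape$gmat, file.path(config$outdir, "gene_matrix.tsv"), meta)
  out(matrix_to_long(landscape$gmat), "gene_matrix_long.tsv")

  ## enrichment -----------------------------------------------------------
  enrich <- stage("enrichment", {
    subtype_enrichment(landscape$gmat, cohort$samples, config$subtype_fdr)
  })
  out(enrich, "subtype_enrichment.tsv")

  ## pathways -------------------------------------------------------------
  pw <- stage("pathways", {
    pmat <- pathway_matrix(landscape$gmat, catalog)
    pfreq <- pathway_frequency(pmat, cohort$samples, "none")
    passoc <- pairwise_association(pmat, config$pairwise_fdr)
    gassoc_feats <- landscape$freq_all$feature[
      landscape$freq_all$frequency >= 0.03]
    if (length(gassoc_feats) < 2) {
      gassoc_feats <- landscape$freq_all$feature[
        seq_len(min(5, nrow(landscape$freq_all)))]
    }
    gassoc <- pairwise_association(
      landscape$gmat[, gassoc_feats, drop = FALSE], config$pairwise_fdr)
    adj <- cooccurrence_adjacency(pmat)
    primary_ids <- cohort$samples$sample_id[
      cohort$samples$cohort_arm %in% c("neoadjuvant", "surgical")]
    pfreq_primary <- pathway_frequency(
      pmat[rownames(pmat) %in% primary_ids, , drop = FALSE],
      cohort$samples[cohort$samples$sample_id %in% primary_ids, ], "none")
    fus <- data.frame(feature = pfreq_primary$feature,
                      n_altered = pfreq_primary$n_altered,
                      n_total = pfreq_primary$n_total,
                      stringsAsFactors = FALSE)
    comp <- cohort_compare(fus, reference, config$compare_fdr)
    list(pmat = pmat, pfreq = pfreq, passoc = passoc, gassoc = gassoc,
         adj = adj, comp = comp)
  })
  write_matrix(pw$pmat, file.path(config$outdir, "pathway_matrix.tsv"), meta)
  out(pw$pfreq, "pathway_frequency.tsv")
  out(pw$passoc, "pathway_associations.tsv")
  out(pw$gassoc, "gene_associations.tsv")
  out(pw$adj, "pathway_adjacency.tsv")
  out(pw$comp$results, "cohort_comparison.tsv")

  ## germline -------------------------------------------------------------
  germline <- stage("germline", {
    pf <- prefilter_rare(cohort$germline, config$germline_max_eas_af)
    scored <- score_evidence(pf$kept, ingest$ctx)
    classified <- classify_germline(scored, config$charger_cutoff)
    summary <- carrier_summary(classified, length(unique(cohort$samples$patient_id)))
    list(pf = pf, classified = classified, summary = summary)
  })
  note("germline_prefilter", "variants", nrow(cohort$germline),
       nrow(germline$pf$kept))
  out(germline$classified, "germline_classified.tsv")
  out(germline$summary$per_gene, "germline_per_gene.tsv")

  ## actionability --------------------------------------------------------
  act <- stage("actionability", {
    sa <- sample_actionability(cohort, kb)
    summ <- actionability_summary(sa$per_sample, cohort$samples)
    list(sa = sa, summ = summ)
  })
  out(act$sa$matches, "actionability_matches.tsv")
  out(act$sa$per_sample, "actionability_per_sample.tsv")
  out(act$summ$level_fractions, "actionability_levels_by_subtype.tsv")

  log_df <- do.call(rbind, log)
  out(log_df, "log.tsv")
  cfg_echo <- config
  class(cfg_echo) <- NULL
  # the echo omits the output directory itself so that identical analyses
  # written to different locations remain byte-identical
  cfg_echo$outdir <- NULL
  yaml::write_yaml(c(list(tool = paste0("bcpanel ", .bcpanel_version()),
                          config_hash = hash), cfg_echo),
                   file.path(config$outdir, "config.yaml"))
  invisible(list(cohort = cohort, landscape = landscape, enrichment = enrich,
                 pathways = pw, germline = germline, actionability = act,
                 log = log_df))
}

#' Generate and write a synthetic cohort in one call
#'
#' Thin wrapper over [cohort_spec()], [generate_cohort()] and
#' [write_cohort()].
#'
#' @param outdir Output directory for the cohort files.
#' @param seed Mandatory integer seed.
#' @param n_samples Cohort size, default 1134.
#' @param ... Further arguments to [cohort_spec()].
#' @return The generated cohort, invisibly.
#' @export
simulate_cohort <- function(outdir, seed, n_samples = 1134, ...) {
  if (missing(seed)) stop("simulate_cohort: seed is mandatory")
  spec <- cohort_spec(n_samples = n_samples, seed = seed, ...)
  cohort <- generate_cohort(spec)
  write_cohort(cohort, outdir)
  invisible(cohort)
}
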