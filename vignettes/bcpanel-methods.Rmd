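---
title: "Methods: cohort-level interpretation of breast cancer panel sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort-level interpretation of breast cancer panel sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcpanel)
```

## Scope and model

`bcpanel` covers the interpretive layer of targeted panel sequencing of
breast cancer at cohort scale. It deliberately begins where the upstream
bioinformatics ends: somatic mutation calls, gene-level copy-number calls
and annotated germline variants enter as tables, and the package derives
the cohort-level quantities a molecular tumour board or a descriptive
genomics paper needs — subtype composition, mutation landscape, hotspot
recurrence, enrichment statistics, pathway-level alteration structure,
germline carrier burden and clinical actionability tiers. No alignment,
variant calling, segmentation or consequence annotation happens here.

### Molecular subtyping

Subtypes follow the surrogate immunohistochemistry classification used in
clinical breast pathology. ER/PR/HER2 status are booleans; Ki67 is a
positive-cell fraction in [0, 1] with "low" defined as ≤ 0.14 (the
conventional 14% cut). The five classes are:

* luminal A — ER+ *and* PR+, HER2−, Ki67 low;
* luminal B/HER2− — ER or PR positive, HER2−, Ki67 high (this class also
  absorbs single-receptor-positive HER2− tumours with low Ki67, which fail
  the stricter luminal A definition);
* luminal B/HER2+ — hormone-receptor positive, HER2+ (Ki67 irrelevant);
* HER2+ (non-luminal) — ER−, PR−, HER2+;
* triple-negative — all three markers negative.

Ki67 only discriminates within HR+/HER2− disease; when it is required but
missing, `derive_subtype()` raises an explicit "undeterminable" error
rather than guessing. The four coarse groups (HR+/HER2−, HR+/HER2+,
HR−/HER2+, TNBC) are a deterministic collapse of the five classes.

### Landscape statistics

Per-gene mutation frequency is the fraction of samples carrying at least
one *non-silent* somatic call in the gene; synonymous calls are carried
through ingestion so they can be counted, then excluded at matrix
construction with the excluded count reported. Denominators are always
group sizes (all sequenced samples in the group), never only the mutated
subset; CNV frequencies instead use the number of samples in which copy
number could be determined, which in real capture data is slightly smaller
than the cohort.

A hotspot is a recurrent identical protein change at cohort frequency of
at least 2% (configurable), counting each sample once per (gene, protein
change). Because published hotspot lists annotate frequencies at whole
percents and include entries that only *round* to the threshold, the
effective cutoff admits frequencies within 5×10⁻⁴ of it. This
rounding-inclusive reading is a deliberate choice; the strict alternative
(`frequency ≥ threshold` exactly) can be obtained by passing a larger
threshold.

Mutation load and VAF distributions are compared across groups with the
tie-corrected Kruskal–Wallis test (chi-square approximation). A completely
tied sample carries no rank information; the package defines H = 0, p = 1
for that degenerate case instead of propagating 0/0.

### Enrichment machinery

All categorical enrichment runs through one code path: a 2×2 table, the
two-sided Fisher exact p-value (sum of all tables with the observed
margins whose point probability does not exceed the observed one, with a
10⁻⁷ relative tolerance guarding floating-point ties), the sample odds
ratio (ad)/(bc) (+∞ and 0 conventions at zero cross-products), and a Woolf
logit 95% confidence interval with the Haldane–Anscombe +0.5 correction on
zero cells so drawn intervals stay finite. p-values are adjusted by
Benjamini–Hochberg within one family per analysis — all gene × subtype
pairs form one family, all features of one cohort comparison form one
family, all feature pairs of one association matrix form one family. This
per-analysis family definition is the only reading consistent with
per-figure significance annotations in the literature this machinery
mirrors.

Subtype enrichment is one-vs-rest (each subtype against the remaining
cohort). Pairwise subtype contrasts can be obtained by subsetting the
clinical table; one-vs-rest is the primary, documented mode. Odds ratios
are oriented so that OR > 1 means enrichment in the named group (or in
cohort A for two-cohort comparisons).

The default significance thresholds differ by analysis on purpose:
FDR < 0.25 for the exploratory subtype-association screen and FDR < 0.05
for cohort comparisons and exclusivity/co-occurrence calls. Both are
configurable in `run_config()`.

### Pathways and exclusivity

Nine canonical oncogenic signalling pathways are supported: cell cycle,
Hippo, Notch, PI3K, Wnt, RTK/RAS, p53, TGF-β and Myc. Membership is
*input*, not code: the shipped `pathway_catalog.tsv` is a curated default
(the well-known pan-cancer pathway templates restricted to genes commonly
found on breast-cancer panels) and can be replaced file-for-file. A gene
may sit in several pathways (CDKN2A in both cell cycle and p53) and then
contributes to each. A pathway cell is the OR over member-gene cells, so
pathway frequency always dominates the best member gene's frequency.

Mutual exclusivity and co-occurrence are assessed per unordered feature
pair from the joint 2×2 of presence/absence, with the same Fisher/BH
machinery. `log10(OR)` is capped at ±3 so colour scales stay finite; the
cap exceeds any finite OR observable at n ≈ 1000 with all margins ≥ 1.
Significant pairs are labelled co-occurring (OR > 1) or mutually exclusive
(OR < 1) at q < 0.05 by default — the threshold is configurable because
published exclusivity figures rarely state theirs. Features altered in no
or all samples have degenerate margins and are skipped, with the skip list
reported.

### Germline classification

The classifier is an evidence-point system in the CharGer family of
ACMG-guided scorers, with the modifications appropriate for a cohort with
East-Asian ancestry and a curated cancer-specific ClinVar view:

1. **Rarity is a prefilter, not evidence.** Variants at East-Asian gnomAD
   allele frequency ≥ 0.5% are removed up front; variants absent from the
   population database are treated as rare and kept (absence implies
   rarity), with the count reported. Consequently the PM2
   (absent-from-population) evidence module is disabled by construction
   and can never appear in an evidence trail.
2. **Active modules and weights**: PVS1 (8 points) for truncating
   consequences — stop gained, frameshift, canonical splice, start lost —
   in a cancer-susceptibility gene whose mechanism is loss of function;
   PS1 (7) for the same amino-acid change as a cancer-related ClinVar
   pathogenic variant; PM4 (2) for protein-length-changing inframe events;
   PM5 (2) for a novel missense at a residue with a cancer-related
   pathogenic missense (suppressed when PS1 fires). The 8/7/2/1 weights
   are the published CharGer strengths and are exposed via
   `charger_weights()`. Supporting (PP) modules are defined in the weight
   table but off by default: the in-silico annotations they need are not
   part of the input contract, and silently half-scoring them would be
   worse than omitting them.
3. **Classification**: a variant is *pathogenic* iff it carries a
   cancer-related ClinVar pathogenic record; otherwise *likely pathogenic*
   iff its score strictly exceeds 7; otherwise *uncertain*. The strict
   inequality matters: PS1 alone (7 points) does not suffice.

"Cancer-related ClinVar pathogenic" is an input column, not a live query:
the package trusts the curated annotation it is given. The spec's single
`same_aa_known_pathogenic` flag cannot drive PS1 and PM5 simultaneously,
so the input contract carries two flags (`same_aa_change_pathogenic`,
`same_residue_pathogenic`).

Carrier summaries count patients, not variants: a patient with qualifying
variants in two genes increments both per-gene counts but counts once in
the cohort total. Cross-population comparisons use Pearson's chi-square on
the carriers × population table, falling back to Fisher's exact test when
any expected count drops below 5.

### Actionability

Evidence tiers follow the OncoKB scheme: L1 (FDA-recognised biomarker),
L2A/L2B (standard-of-care evidence in the same / another tumour type),
L3A/L3B (investigational evidence), L4 (biological evidence), ordered
L1 > L2A > L2B > L3A > L3B > L4. The knowledge base is a replaceable TSV;
the shipped table is a small curated breast-cancer set seeded from
well-established drug–gene pairs (alpelisib for activating PIK3CA, PARP
inhibitors for truncating BRCA1/2, HER2-directed agents for ERBB2
amplification, AKT inhibitors for AKT1 p.E17K, and so on). Matching
semantics: exact protein change; truncating (nonsense/frameshift/splice);
per-record allowlisted classes for "any oncogenic" (because oncogenicity
calls are knowledge-base facts, not reproducible offline logic); and CNV
amplification. Each sample receives the level of its most significant
match; group summaries include an explicit "none" bucket so level
fractions sum to 1.

## The synthetic cohort generator

The generator exists so that every stage is testable end-to-end without
any protected patient data. Its defaults describe one fixed set of study
conditions modelled on a large Chinese prospective clinical sequencing
cohort:

* 1134 samples in three arms — 419 neoadjuvant, 606 surgical, 109
  advanced — apportioned by largest remainder so the default cohort hits
  those counts exactly;
* a subtype mix dominated by HR+/HER2− disease (12/42/13/12/21% across
  luminal A, luminal B/HER2−, luminal B/HER2+, HER2+, TNBC); the
  proportions are a realistic choice for a Chinese clinical series and
  were fixed once, jointly with the per-subtype gene table, so that the
  implied marginals reproduce the headline rates below;
* per-subtype gene mutation probabilities whose mixture marginals
  reproduce headline rates: TP53 ≈ 53% overall rising to ≈ 80% in TNBC,
  PIK3CA ≈ 32% (≈ 38% in luminal B/HER2−), NF1 ≈ 10%, and pathway-level
  unions near p53 55%, PI3K 45%, RTK/RAS 32%, Notch 17%. Genes without
  published per-gene rates (most RTK/RAS and Notch members) carry modest
  1–7% frequencies chosen once to realise those pathway unions;
* hotspot shares per gene (e.g. p.H1047R takes 41% of PIK3CA carriers,
  p.E17K 85% of AKT1 carriers), with the remainder drawn from a positional
  background model; expected cohort-level hotspot frequencies land near
  13% (PIK3CA p.H1047R), 4% (AKT1 p.E17K) and 2% (KMT2C p.K2797fs, TP53
  p.R248Q);
* VAFs from per-gene Beta distributions — Beta(2, 3) by default (mode
  ≈ 0.33, plausible for clonal heterozygous events at high purity), with
  right-shifted parameters for PIK3CA and AKT1 so those genes show the
  highest VAFs; read depth per variant is Poisson(1000) truncated at 30,
  matching 1000× mean panel coverage, with the alt count binomial at the
  drawn VAF (floored at 1 — a called variant has support);
* CNV frequencies led by the 17q12 amplicon (ERBB2/MIEN1/GRB7 at 25/25/24%
  amplification), with copy number evaluable in 1114 of 1134 samples;
* injected pairwise coupling via the 2×2 joint law with given marginals
  and odds ratio (the Plackett construction, solved per subtype);
  defaults: ARID1A–PTEN at OR = 0 (full mutual exclusivity — no sample
  ever carries both) and NF1–RUNX1 at OR = 6. Infeasible requests (an OR
  incompatible with the marginals) raise an error naming the pair;
* a germline layer realising 66 carriers among 1134 patients (5.8%) with
  per-gene patient counts led by BRCA1 (22); the published per-gene counts
  sum to 72 gene-level events, so six carriers receive events in two
  genes. Events alternate between two classification routes (known
  cancer-related ClinVar pathogenic; truncating loss-of-function scoring
  PVS1 = 8 > 7), on top of a background of ~30% rare VUS and ~5% common
  benign variants that exercise the prefilter;
* gene-indicator events are always non-silent, because the configured
  per-gene frequencies are probabilities of a qualifying (non-synonymous)
  mutation; a thin independent layer of synonymous calls (~5% of cohort
  size) is added on top so the silent-exclusion bookkeeping downstream has
  real work without biasing the configured marginals;
* a handful of recurrent artifact variants catalogued in the panel of
  normals and injected into the somatic calls, so the PON filter has real
  work; consequently any frequency analysis must run *after*
  `pon_filter()`, exactly as the pipeline does.

Everything is drawn from a single seeded RNG stream in a fixed order, so
identical (spec, seed) pairs give byte-identical output files.

What the generator does **not** emulate: mutational signatures and
trinucleotide context, subclonal copy-number structure and allele-specific
VAF distortion, panel footprint differences between cohorts, linkage
between somatic and germline layers, and survival/response endpoints.
Passing tests therefore demonstrate that the statistics recover the
structure they are designed to measure — not that the generator is a
substitute for real tumour data.

## Numerical and testing choices

* Exact-test p-values are validated against exhaustive hypergeometric
  enumeration (independent `lchoose` arithmetic) for **all** 2×2 tables
  with total ≤ 40, and against `stats::fisher.test` on a random grid.
* Frequency recovery is assessed against exact binomial (Clopper–Pearson)
  99% intervals aggregated over 50 seeded 1134-sample cohorts (the
  per-gene interval has ≈ 99.3% coverage, so a single-cohort all-genes
  requirement would fail by construction ~40% of the time; the aggregate
  formulation tests the same property without that artefact).
* FDR control is checked on 20 seeded null cohorts (200 samples × 1000
  independent features at 30%), requiring the flagged fraction at q < 0.05
  to stay within 0.05 + 3·SE of seeds.
* Coupling recovery is checked at the cohort scale the analysis targets
  (n = 1000, 20 seeds, OR ∈ {0, 0.2, 5, ∞}), requiring ≥ 90% correct
  pattern labels per OR class and zero co-carriers for OR = 0 in every
  run.
* A 20-variant golden set with hand-derived evidence trails pins the
  germline classifier, including the strict score-7 boundary and the
  absence of PM2 from every trail.
* Determinism is enforced by md5 comparison of full output trees from
  repeated runs. The `config.yaml` echo omits the output directory path
  (and nothing else) so runs into different directories stay
  byte-identical.

## Limitations

* Pathway membership and the actionability knowledge base ship as small
  curated defaults; analyses at publication scale should substitute the
  user's own curated tables.
* The germline classifier implements only the evidence modules its input
  contract can support; richer ACMG implementations (segregation,
  functional data, in-silico ensembles) require annotations this package
  does not ingest.
* One-vs-rest subtype enrichment is the only built-in contrast mode.
* Cross-cohort comparisons take reference cohorts as frequency tables and
  cannot correct for panel footprint differences beyond reporting
  unshared features.
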