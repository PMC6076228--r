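---
title: "Methods: ensemble pathogenicity scoring and automated Mendelian diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble pathogenicity scoring and automated Mendelian diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mendeldx)
```

# Scope

`mendeldx` interprets variant calls from targeted Mendelian-disease gene
panels. It assumes variant calling is done: inputs are a VCF per patient,
tabular annotation databases (population allele frequencies, curated
pathogenicity classes, precomputed raw scores for 17 deleteriousness
predictors) and a phenotype term list. Everything upstream — read QC,
alignment, variant calling — and everything wet-lab is out of scope, as is
re-implementing any of the 17 predictors themselves: their raw scores are
inputs.

# The MPPS ensemble classifier

## Model

Individual deleteriousness predictors disagree, have region-dependent
reliability across the genome, and frequently emit no prediction at all
for a given variant. MPPS addresses all three problems with a weighted,
region-aware ensemble over 17 predictors: 8 functional prediction scores
(Polyphen2_HDIV, Polyphen2_HVAR, MutationTaster, SIFT, LRT, FATHMM,
MutationAssessor, M-CAP), 7 further scores (PROVEAN, VEST3, MetaSVM,
MetaLR, fathmm-MKL, CADD, DANN) and 2 conservation scores (GERP++,
phyloP100way).

Raw scores are first mapped to five ordered categories — damaging,
possibly damaging, unclassified, possibly benign, benign — worth
+10 / +5 / 0 / −5 / −10 points. The per-tool cut-offs
(`mpps_thresholds()`) follow each tool's published recommendation where
one exists (SIFT ≤ 0.05, PolyPhen-2 HDIV ≥ 0.957 / ≤ 0.452, CADD phred
≥ 20 / ≤ 10, M-CAP ≥ 0.025, PROVEAN ≤ −2.5, …); the interval between the
two cut-offs is split at its midpoint into the two "possibly"
categories. All cut-offs are configurable — the categorical scale is the
model, the cut-offs are calibration.

Fitting (`mpps()`, `fit_region_weights()`) estimates each predictor's
reliability as its fraction of correct predictions in a genomic region,
separately for the two truth classes: `w_dmg` on pathogenic variants
(a sensitivity), `w_ben` on neutral variants (a specificity). Regions are
fixed 10 Mb bins keyed by `chrom:floor((pos-1)/1e7)`; bins with fewer
than `min_n = 50` truth variants of either class fall back to a pooled
genome-wide row. Both choices are ours: 10 Mb keeps tens of truth
variants per bin even for modest truth sets, and 50 per class caps the
binomial standard error of a weight near 7 points. Weights live on the
0–1 scale; because scores are weight-normalized (below), any common
rescaling of the weights cancels.

Classification (`classify_variant()`, `predict()`) runs an iterative
trio-agreement protocol:

1. **Trio selection.** Rank the candidate predictors by `w_dmg`
   (damaging side) and by `w_ben` (benign side) in the variant's region;
   round *r* uses ranks 3(r−1)+1 … 3r on each side, i.e. the best three
   per side first, then the next best three, and so on in
   non-overlapping triples. Ties break by tool name in byte order so
   results are machine-independent.
2. **Scoring.** Each side's score is the weight-normalized point sum
   `Σ wᵢ pᵢ / Σ wᵢ` over its trio, which stays in [−10, +10] for any
   non-negative weights (an all-zero-weight trio scores 0). Absent
   predictions contribute 0 points but keep their weight in the
   denominator, so missingness pulls scores toward 0 rather than being
   silently dropped.
3. **Conservation bonus.** If both GERP++ ≥ 2.0 and phyloP100way ≥ 1.6
   the variant counts as conserved and both trio scores gain +1, clamped
   at +10. The bonus is applied after normalization to both sides
   symmetrically; an absent conservation score on either side means not
   conserved. The two conservation scores are excluded from trio
   candidacy by default (they would otherwise play a double role);
   `include_conservation = TRUE` restores them as candidates.
4. **Agreement.** A side's verdict is damaging when its score ≥ +1,
   benign when ≤ −1, indeterminate in between — scores inside (−1, +1)
   are treated as noise rather than evidence. If the two sides agree,
   that classification is reported with the round number. Otherwise the
   next round runs with the next rank-triples, up to 5 rounds (15
   candidate predictors / 3). If no round agrees the variant is flagged
   mis-classified **and still classified** by the sign of the mean of
   the two round-1 scores (an exact zero falls to benign, the
   conservative side). Every variant therefore receives a result and
   batch Prediction Coverage is 100% by construction.

## What the defaults mean

| parameter | default | meaning |
|---|---|---|
| `bin_size` | 1e7 bp | region width for weight estimation |
| `min_n` | 50 | truth variants per class for a region-specific weight |
| agreement cut | ±1 score unit | minimum evidence for a side verdict |
| `gerp_threshold` | 2.0 | GERP++ RS considered conserved |
| `phylop_threshold` | 1.6 | phyloP100way considered conserved |
| `max_rounds` | 5 | rank-triples available from 15 candidates |

# Evaluation statistics

`tool_accuracy()` reports per-class percent-correct and Prediction
Coverage — predicted variants (correctly or incorrectly) divided by all
variants evaluated. Accuracy denominators are by default the variants
*with* a prediction, keeping accuracy and coverage orthogonal; a flag
switches to all-variant denominators. `benchmark_all()` builds the
per-tool + ensemble comparison table, fitting weights on a seeded 50/50
split and evaluating on the disjoint half; resubstitution must be
requested explicitly. `genotype_concordance()` compares genotype maps as
unordered allele pairs over shared loci. All reported percentages round
half-up to 2 decimals (`round_half_up()`), matching conventional
clinical reporting, rather than R's round-half-even.

# The AADSM diagnosis pipeline

Three steps, mirroring how a clinical scientist works a case up:

1. **Filter and annotate** (`annotate()`, `filter_variants()`): drop
   common variants (allele frequency ≥ 0.01) unless a curated DM/DM?
   class rescues them; drop synonymous variants unless within 2 bp of a
   splice site; drop off-panel variants (outside exons ± 10 bp) when a
   panel manifest is supplied. Whether common variants should be removed
   or merely down-weighted is genuinely open; we remove them and expose
   the cutoff, because rescuing via the curated class already covers the
   known-pathogenic-but-common case.
2. **Score** (`score_variant()`): each surviving variant gets integer
   points for frequency (novel 4 … common −6), mutation type (whole-gene
   or multi-exon CNV 4), consequence (nonsense/frameshift/splicing 4,
   in-frame indel 3, missense 2, synonymous −4), curated class (DM 4,
   DM? 2, DP/DFP 1) and the MPPS call (damaging +2, benign −2). The
   *inputs* to this scale are the established rank drivers; the
   magnitudes are our design (chosen so a single curated hit cannot
   outrank a novel truncating variant with ensemble support) and are all
   configurable in `aadsm_config()`.
3. **Rank and report** (`phenotype_gene_list()`, `rank_diseases()`,
   `generate_report()`): genes are ranked by how many patient phenotype
   terms link to them — ranking, never exclusion, so a miscoded
   phenotype cannot hide a molecular finding. Every disease with a
   scored variant in one of its genes is ranked by
   `variant_support · (1 + phenotype_match) + 2 · inheritance_consistent`,
   where `phenotype_match` is the fraction of the disease's terms the
   patient shows, `variant_support` the best variant total in its genes,
   and autosomal-recessive consistency needs two heterozygous hits or
   one homozygous/hemizygous hit. This combination formula is ours: it
   makes variant evidence primary (a perfect phenotype match can at most
   double it) and inheritance a fixed small bonus. X-linked diseases are
   treated like dominant ones for consistency because the database
   schema does not distinguish XLD from XLR. Ties break by disease id
   for stable output; reports are capped at `max_rank = 100` diseases.
   Phenotype matching is exact term overlap — the database accepts any
   controlled vocabulary (e.g. HPO ids) but no ontology expansion is
   performed; with free-text terms, near-miss synonyms will not match.

Reports are written as a JSON document (machine-readable, round-trips
through `read_report()`) and an HTML page listing ranked diseases,
ranked variants with their score components, and provenance (package
version, configuration hash, timestamp — overridable for byte-identical
reruns).

# Synthetic data: what it emulates and what it does not

The generators (`simulate_truth_set()`, `simulate_tool_profiles()`,
`build_gene_phenotype_db()`, `simulate_patient()`) provide every input
with known ground truth. All are pure functions of (parameters, seed).

* The **genome** is 22 autosomes + X as integer intervals; positions
  only.
* **Tool profiles** draw each prediction independently per tool with
  specified per-region sensitivity/specificity, missingness and
  softening rates; raw scores are back-computed as the midpoint of the
  matching category band, so the category mapping inverts the simulation
  exactly. Benchmark conditions follow the validation experiments:
  per-tool accuracies drawn uniformly in [0.70, 0.95] and missing rates
  in [0.1, 0.3], the observed range of real predictor behaviour, with
  2,000 evaluation variants (a desk-scale stand-in for the ~48,000-variant
  curated truth sets such experiments use).
* **Databases and patients**: diseases are assigned to the 19 clinical
  categories proportionally to the built-in counts; each disease has 1–2
  genes, an inheritance mode (40% AD / 45% AR / 15% XL) and 5 phenotype
  terms from a vocabulary sized so each term is shared by ~3 diseases.
  A simulated patient carries the causal variant(s) per the inheritance
  mode, 100–200 common background variants (allele frequencies in
  [0.01, 0.5], removable by the default filter by construction) and the
  disease's terms with configurable noise. The cohort experiments use
  100 patients.

What the simulation deliberately does **not** model: correlation between
predictors (real tools share training data and features, so real
ensemble gains will be smaller than simulated ones), realistic mutation
spectra or linkage structure, ontology-structured phenotypes, incomplete
penetrance, and truth-set label noise. Passing the recovery tests
therefore shows the machinery is correct and self-consistent — not that
the defaults are clinically validated on real cohorts.

# Numerical and degenerate-input choices

* Weighted scores with an all-zero weight sum are defined as 0.
* A truth set with a single class yields uninformative 0.5 weights for
  the missing class, with a warning.
* A variant with no raw score from any tool scores 0 on both sides at
  every round, is flagged mis-classified, and classified benign by the
  zero-mean fallback.
* Empty batches, empty term lists and empty post-filter variant sets are
  legal everywhere and produce empty (but structurally complete)
  results; a report is still generated.
* Genotype concordance errors on zero shared loci rather than returning
  a vacuous 100%.
* Multi-allelic VCF lines split into one record per ALT allele; CNVs are
  symbolic `<DEL>`/`<DUP>` alleles carrying `END`, treated as whole-gene
  events when they span a gene interval.

# Problem sizes used in the shipped validation

The test-suite and acceptance experiments run at: 2,000-variant
benchmarks (1,000 per class) for coverage and ensemble-quality checks;
2,000 truth variants per class per region (two 10 Mb regions) for weight
recovery; 1,000 random instances for the score-arithmetic oracle; and
100 simulated patients for implanted-disease recovery. These sizes give
sub-percent binomial error on every recovered rate while keeping a full
run near a minute on one core.

# Known limitations

* Region weights assume truth variants are representative of the
  region; ascertainment bias in a real truth set transfers directly
  into the weights.
* The trio protocol never mixes sides within a trio; a region where one
  tool is excellent on both classes still occupies only one slot per
  side.
* The conservation bonus is binary and symmetric; it cannot rescue a
  variant across the ±1 agreement threshold by more than one unit.
* Exact-match phenotype scoring under-ranks diseases described in a
  different vocabulary than the patient's terms.
* The fixture of nine validated probands uses synthetic genomic
  coordinates (the published record is at coding-HGVS level), so it
  validates parsing and counting, not coordinate-level annotation.
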