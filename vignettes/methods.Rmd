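---
title: "Methods: tumor-normal somatic analysis and tiered reporting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-normal somatic analysis and tiered reporting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoreport)
```

# Scope and model

`oncoreport` implements the downstream computation of a paired
tumor-normal clinical sequencing workflow for pediatric cancer and
high-risk hematologic disease. Upstream steps — read alignment, base-level
variant calling, CNV segmentation by a dedicated caller, FPKM estimation
and fusion discovery — are out of scope; their outputs are this package's
inputs. The package owns everything from caller output to the molecular
tumor board report:

1. **Somatic subtraction.** Variant calls are made independently on tumor
   and normal; somatic mutations are the eligible tumor calls whose exact
   normalized key (chrom, pos, ref, alt) is absent from the eligible
   normal calls. Eligibility encodes the callers' output thresholds: at
   least 10 total reads and 3 variant reads, with a minimum variant
   allelic fraction (VAF) of 10% in tumor and 5% in normal.
2. **Germline filtering.** Normal-tissue calls pass through three layers:
   a *reference-range* filter (cancer predisposition genes, genes
   relevant to pharmacogenomics, and an explicit allow-list of variants
   relevant to patient care), a *reportable-range* filter
   (somatic-catalog identifiers and the secondary-findings gene list),
   and a *frequency* filter removing variants with population minor
   allele frequency of 1% or more.
3. **Classification and load.** Tumor variants are characterized as
   homozygous, compound heterozygous, somatic and disruptive (nonsense,
   frameshift, splice site); the mutational load counts variants with at
   least 30X tumor coverage and either caller quality ≥ 20 or VAF ≥ 25%.
4. **CNV gates and LOH.** Segment-level inputs are gated on coverage
   (normal > 95% of targets at 10X, tumor ≥ 90% at 30X) and classified
   with a loss cutoff at log2 ratio −0.2. Copy-neutral loss of
   heterozygosity is read from normal-heterozygous sites whose tumor VAF
   shifts away from 0.5.
5. **Expression outliers and fusions.** Per-gene FPKMs are normalized by
   the sample's median FPKM over a housekeeping reference set and
   compared to a panel-of-normals model (per-gene median and MAD of
   normalized expression); fusion calls are annotated against a
   known-fusion catalog with a partner-gene rule.
6. **Tiering and reporting.** Somatic findings receive a report tier
   (1–4) and, when targetable, an evidence-based actionability sub-tier
   (1–5); germline findings are categorized; reports render
   deterministically to markdown or JSON with opt-out handling and an
   audit trail.
7. **Cohort analytics.** Distinct-patient counts and predicate tallies
   over the bundled curated finding tables.

Every rule is parameterized by an external knowledge base (gene lists,
hotspot and fusion catalogs, drug-target rows with evidence annotations,
thresholds). The package ships a small curated testing knowledge base;
production deployments supply their own catalogs.

# Key parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `tumor_min_vaf` | 0.10 | fraction | tumor-side caller output threshold |
| `normal_min_vaf` | 0.05 | fraction | normal-side caller output threshold |
| `min_depth`, `min_alt_reads` | 10, 3 | reads | minimum evidence to call a variant |
| `af_threshold` | 0.01 | fraction | population-frequency filter ("< 1%") |
| load filter | 30X, Q20, 25% | reads, score, fraction | mutational-load inclusion rule |
| `loss_cutoff` | −0.2 | log2 ratio | loss call threshold, inclusive |
| `gain_cutoff` | +0.2 | log2 ratio | symmetric convention; gains are supporting evidence only |
| `min_sites`, `tumor_shift` | 10 sites, 0.25 | count, fraction | LOH support at tumor fraction 0.8, where the expected het-site shift is ≈ 0.4 |
| `z_cutoff`, `eps` | 3, 0.01 | robust z, normalized units | expression-outlier call; `eps` guards zero panel scale |
| `tumor_purity` | 0.8 | fraction | assumed tumor cell fraction |

# Design choices

Several combination rules are not forced by the workflow description and
were fixed as package design decisions:

* **Union-then-frequency.** A germline call is retained when *any*
  retention layer passes and the frequency filter does not remove it.
  Each retention layer is an independent pass-through route; the
  frequency filter can only remove, never add. Layer evaluation is
  order-independent.
* **Missing population frequency retains the variant**: a novel variant
  cannot be excluded as common.
* **Exact-key matching.** Subtraction matches caller outputs directly by
  normalized key; no fuzzy indel matching. Duplicate keys within one
  sample collapse to the deepest record. Normal evidence below the 5%
  output threshold does not veto a somatic call but is recorded as an
  annotation (`normal_vaf`) for reviewer caution.
* **Allele normalization** strips any `chr` prefix and trims the shared
  suffix then prefix of ref/alt (adjusting the position). Full
  left-alignment of repeat-region indels would require the reference
  sequence, which the package deliberately does not access (the build is
  metadata only); trimming is idempotent and sufficient for exact-key
  matching of caller output.
* **Boundary semantics.** "Greater than 95%" for the normal coverage
  gate is strict; the loss cutoff at −0.2 is inclusive ("cutoff set
  to"). Both are configurable.
* **Homozygosity rule.** The homozygous category fires on caller
  zygosity `hom`, or on VAF ≥ 0.9 at depth ≥ 30 (conventional exome
  practice; no numeric rule is prescribed by the workflow). The VAF-only
  case is additionally flagged `reduced_to_hom`, since reduction to
  homozygosity relative to germline and tumor zygosity are distinct
  readings; both flags are reported.
* **Compound heterozygosity** requires two or more distinct heterozygous
  calls in the same gene in the same sample; trans-phasing is not
  attempted (no trio phasing in scope for tumor).
* **Evidence levels are knowledge-base annotations.** The actionability
  sub-tier (clinical vs preclinical evidence × same vs different tumor
  type) is computed from drug-target catalog rows; the engine cannot
  read the literature, so the catalog curates it. When several rows
  match, the strongest (lowest) tier wins, which makes the tier monotone
  in evidence. Sub-tier 5 (board discretion) is a manual override flag
  and is never auto-assigned.
* **VOUS return** requires all three criteria: destructive consequence,
  well-validated cancer gene, and a second somatic hit in the same gene
  or reduction to homozygosity (tumor VAF ≥ 0.9) at the germline site.
* **SD convention.** Cohort load statistics use the sample (n−1)
  standard deviation, flagged in the output; a single observation
  reports SD 0 with a degeneracy flag.

# Numerical behavior and degenerate inputs

* Calls with missing depth are retained on input but ineligible for
  subtraction and load counting (with warnings).
* A caller-reported VAF wins over the allele-depth ratio; a discrepancy
  above 0.01 warns but keeps the caller value, since caller output is
  authoritative.
* Segments with no informative (normal-het) site are flagged
  `uninformative`, never LOH.
* Genes with zero scale in the expression model use `eps = 0.01`
  normalized units in the denominator, so a noiseless panel still yields
  finite, large z for planted changes and exactly zero for unperturbed
  genes.
* Under-expression flags are bounded: with per-gene location *m* and
  scale *s*, the most extreme possible z is −*m*/*s* (expression cannot
  go below zero), so loss-of-expression calls at |z| ≥ 3 are only
  attainable for genes whose panel spread is small relative to their
  location. This is a property of any scale-normalized outlier statistic
  on a non-negative measure, and is why reported loss-of-expression
  findings typically accompany a supporting deletion call.
* The bundled `simple_segmenter` merges adjacent bins whose log2 ratio
  stays within 0.1 of the running segment mean. It exists to close the
  loop in synthetic end-to-end tests; production segment calls come
  from a dedicated CNV caller and are read as input.

# The synthetic-data generator

`simulate_paired_calls()`, `simulate_ballele_track()` and
`simulate_expression_panel()` generate every input the pipeline stages
need, with planted truth, deterministically per seed.

* **Paired calls.** Positions are drawn without replacement from a
  bundled synthetic exome target map (2 chromosomes, 1000 targets), so
  planted somatic and germline keys are disjoint by construction.
  Germline variants (VAF 0.5 or 1.0) appear in both samples; somatic
  variants appear only in tumor with cellular VAFs from \[0.15, 0.5\]
  scaled by purity 0.8. Depths are Poisson around 150X (floored at 30),
  matching the intended exome depth. By default the generator plants
  read counts as `round(depth × VAF)` rather than redrawing them
  binomially: the planted VAFs are then guaranteed to respect the output
  thresholds on the realized calls, which is what "recovery of planted
  truth" should measure (binomial VAF noise at 150X would randomly push
  boundary plants below threshold and measure the generator, not the
  method). Binomial read sampling remains available via
  `vaf_noise = "binomial"`. A configurable fraction of somatic variants
  carries sub-threshold normal evidence (VAF ≈ 0.02) to exercise the
  annotate-but-don't-veto rule.
* **B-allele tracks.** One synthetic chromosome of 100 × 1 Mb bins with
  2000 heterozygous sites; normal VAFs are N(0.5, 0.02) truncated to the
  het window \[0.45, 0.55\]. Inside planted LOH bins the tumor VAF moves
  to 0.5 ± purity/2 (0.1 or 0.9 at purity 0.8, allele chosen per site)
  with binomial sampling at 100X. Planted truth intervals lie on the bin
  grid so interval-recovery scores measure detection, not grid
  quantization. Log2 ratios are 0 plus N(0, 0.05) noise, with planted
  losses at −0.5; copy-neutral LOH regions keep log2 at 0.
* **Expression panels.** Gene base abundances are log-normal; panel
  profiles (default 124, the size of the reference panel the model
  emulates) scatter around them with biological spread sdlog 0.4
  (housekeeping genes 0.05, keeping the normalizer stable), while the
  case sample follows the gene base abundances with small technical
  noise (sdlog 0.05) and multiplies planted outliers by their fold
  changes. The case's unperturbed genes therefore sit near the panel
  consensus — the regime in which a z = 3 cutoff has a negligible
  per-gene false-flag rate. A case drawn with the full cross-tissue
  spread would instead show ~0.3% false flags per gene at z = 3; calling
  outliers for such a sample requires either a tissue-matched panel
  subset (supported via the `tissue` argument of
  `build_reference_model()`) or a higher cutoff. The noiseless variant
  (`expression_noise = FALSE`) puts panel and case exactly on the base
  abundances.

What the generator does **not** emulate: mapping artifacts, strand and
position biases, sequencing error, subclonal structure, purity
estimation error, GC-dependent coverage waves, tissue-of-origin
expression heterogeneity, and fusion read evidence. Passing the
synthetic recovery checks therefore demonstrates correctness of the
decision rules under their stated assumptions, not end-to-end
performance on real specimens.

# Validation problem sizes

The test suite validates each stage against an independent brute-force
oracle and the generators' planted truth at these scales (chosen to
exercise the rules thoroughly while keeping the default test run fast):
100 seeded tumor/normal pairs of 450 planted variants for subtraction
oracle equivalence and exact planted recovery; 20 seeds × 1000 calls for
the germline cascade; 50 seeded B-allele tracks with 40%-of-chromosome
copy-neutral LOH and a 20-bin loss for LOH/loss recovery (interval
Jaccard ≥ 0.9, loss sensitivity 1.0); 50 seeded expression panels with a
planted 20-fold outlier among ~1000 null genes; and 200 randomized
findings for tier-rule re-evaluation. The `scripts/acceptance.R` script
recomputes the same quantities from scratch at comparable sizes from a
command-line seed.

# Known limitations

* Consequence annotation, pathogenicity labels and evidence levels are
  inputs; the package performs no in-silico effect prediction and no
  literature mining.
* Indel matching is exact-key; two callers describing the same repeat
  indel differently will not be matched.
* The cohort analytics operate on the bundled curated tables; per-sample
  mutational-load statistics of the original cohort are not
  recomputable from published material and are validated on synthetic
  counts only.
* The bundled knowledge base is a small testing catalog. Tier
  assignments are only as good as the catalogs supplied.
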