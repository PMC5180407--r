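# oncoreport

Downstream computation for paired tumor–normal clinical sequencing in
pediatric oncology and high-risk hematologic disease: from caller output
to a tiered molecular tumor board report.

Clinical sequencing programs for children with cancer call variants
independently on tumor and matched normal tissue, then need a
reproducible, auditable chain of decision rules to turn those calls into
a clinical report. `oncoreport` implements that chain:

* **Somatic subtraction** — somatic mutations are the eligible tumor
  calls (VAF ≥ 10%, ≥ 10 reads, ≥ 3 variant reads) whose exact
  normalized key `(chrom, pos, ref, alt)` is absent from the eligible
  normal calls (VAF ≥ 5%). Sub-threshold normal evidence annotates but
  does not veto.
* **Germline filtering** — three layers over normal-tissue calls:
  reference range (cancer predisposition + pharmacogenomics genes),
  reportable range (somatic-catalog identifiers + secondary-findings
  genes), and a population-frequency filter (minor allele frequency
  < 1%). Retained = (reference ∪ reportable) ∩ frequency-pass.
* **Variant classification** — homozygous, compound heterozygous,
  somatic, disruptive (nonsense / frameshift / splice site); mutational
  load counts calls with depth ≥ 30X and (quality ≥ 20 or VAF ≥ 25%).
* **CNV gating and copy-neutral LOH** — coverage gates (normal > 95% of
  targets at 10X, tumor ≥ 90% at 30X), loss at log2 ratio ≤ −0.2, and
  LOH from normal-heterozygous sites (VAF 45–55% in normal) whose tumor
  VAF shifts from 0.5 by ≥ 0.25.
* **Expression outliers and fusions** — per-gene FPKM normalized by the
  housekeeping-gene median, compared to a panel-of-normals model
  (per-gene median/MAD) with a robust z cutoff of 3; fusion annotation
  against a known-fusion catalog with a partner-gene rule.
* **Tiering and reporting** — somatic report tiers 1–4, evidence-based
  actionability sub-tiers 1–5 (clinical/preclinical × same/different
  tumor type; tier 5 is a manual board override), germline categories,
  the three-criterion VOUS-return rule, and deterministic markdown/JSON
  report rendering with opt-out handling and an audit trail.
* **Cohort analytics** — de-duplicated distinct-patient counts and
  tallies over bundled curated finding tables.
* **Synthetic data** — seeded generators for paired call sets, B-allele
  tracks and expression panels with planted truth, used by the test
  suite for oracle-checked end-to-end validation.

Every rule is driven by a configurable knowledge base (gene lists,
hotspots, fusions, drug-target evidence rows, thresholds); a small
curated testing catalog ships with the package.

## Worked example

```r
library(oncoreport)

# Seeded synthetic tumor/normal pair with planted truth
sim <- simulate_paired_calls(simulation_config(seed = 7))
som <- subtract_somatic(sim$tumor, sim$normal)
nrow(sim$tumor); nrow(sim$normal); nrow(som)
#> [1] 330
#> [1] 309
#> [1] 30
head(as.data.frame(som)[, c("chrom", "pos", "ref", "alt", "vaf", "gene")], 3)
#>   chrom    pos ref alt       vaf  gene
#> 1     1  13992   T   A 0.3964497 G1001
#> 2     1  54648   T   G 0.1666667 G1005
#> 3     1 110654   G   T 0.2253521 G1011
```

All 30 planted somatic variants are recovered and all 300 germline
variants subtracted (`variant_key(som)` equals
`sim$truth$somatic_keys`).

```r
# Tier a known fusion in its disease context
kb <- load_knowledge_base()
f  <- tiered_finding("fusion", "ABL1", "BCR-ABL1 fusion",
                     labels = "diagnostic", known_driver = TRUE)
assign_report_tier(f, "CML", kb)          # 1: tumor type-specific actionable
#> [1] 1
assign_actionability_tier(f, "CML", kb)   # 1: clinical evidence, same tumor type
#> [1] 1
categorize_utility(f, kb)
#> [1] "diagnostic"         "therapeutic_target"
```

```r
# Cohort analytics over the bundled curated tables
s <- cohort_summary()
sprintf("targetable: %d/%d (%.0f%%)", s$targetable$numerator,
        s$targetable$denominator, 100 * s$targetable$proportion)
#> [1] "targetable: 38/101 (38%)"
```

A thin command-line wrapper over the same functions is available at
`inst/cli/oncoreport.R` (subcommands `somatic`, `germline`, `cohort`).

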