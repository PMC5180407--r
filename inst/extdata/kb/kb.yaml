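# Knowledge-base configuration: catalog paths are resolved relative to this file.
catalogs:
  reference_range_genes: reference_range_genes.txt
  acmg_genes: acmg_genes.txt
  cosmic_ids: cosmic_ids.txt
  cancer_genes: cancer_genes.txt
  hotspots: hotspots.tsv
  known_fusions: known_fusions.tsv
  drug_targets: drug_targets.tsv
  housekeeping_genes: housekeeping_genes.txt
  patient_care_variants: patient_care_variants.tsv
thresholds:
  af_threshold: 0.01
enabled_filters:
  - reference_range
  - reportable_range
  - frequency
  - tiering
  - fusion
  - expression
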