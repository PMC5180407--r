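# Clinical sequencing report - patient 14-85546

Diagnosis: CML
Disease group: hematologic
Assay: cWES
Secondary findings: opted in

## Somatic findings - Tier 1 (tumor type-specific actionable)

No findings.

## Somatic findings - Tier 2 (targetable pathway / other tumor type / established cancer gene)

No findings.

## Somatic findings - Tier 3 (other mutations in cancer genes)

No findings.

## Somatic findings - Tier 4 (variants of uncertain significance)

No findings.

## Fusion transcripts

- ABL1 | BCR-ABL1 fusion | report tier 1 | actionability tier 1 | utility: diagnostic, therapeutic_target

## Copy number variation

No findings.

## Expression outliers

No findings.

## Germline findings - secondary findings

- BRCA1 | c.68_69delAG (p.Glu23Valfs) | acmg_pathogenic

## Germline findings - other

No findings.

## Pharmacogenomics

No findings.

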