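#' Reference-range filter
#'
#' Retains normal-tissue calls in cancer predisposition genes, genes
#' relevant to pharmacogenomics, or explicit (gene, coding-change)
#' variants relevant to patient care.
#'
#' @param vc A `variant_calls` data frame.
#' @param kb A [knowledge_base()].
#' @return Logical vector (TRUE = passes the layer).
#' @export
reference_range_filter <- function(vc, kb) {
  if (nrow(vc) == 0) return(logical())
  in_genes <- nzchar(vc$gene) & vc$gene %in% kb$reference_range_genes
  pc <- kb$patient_care_variants
  in_pc <- if (nrow(pc) > 0)
    paste(vc$gene, vc$hgvs_c) %in% paste(pc$gene, pc$hgvs_c)
  else rep(FALSE, nrow(vc))
  in_genes | in_pc
}

#' Reportable-range filter
#'
#' Retains calls whose somatic-catalog identifier is known, or that fall
#' in a gene on the secondary-findings reporting list.
#'
#' @inheritParams reference_range_filter
#' @return Logical vector.
#' @export
reportable_range_filter <- function(vc, kb) {
  if (nrow(vc) == 0) return(logical())
  (nzchar(vc$cosmic_id) & vc$cosmic_id %in% kb$cosmic_ids) |
    (nzchar(vc$gene) & vc$gene %in% kb$acmg_genes)
}

#' Population-frequency filter
#'
#' Retains calls whose population minor allele frequency is below the
#' threshold (default 1%). A call with no known population frequency is
#' retained: a novel variant cannot be excluded as common.
#'
#' @inheritParams reference_range_filter
#' @return Logical vector (TRUE = retained by the frequency layer).
#' @export
frequency_filter <- function(vc, kb) {
  if (nrow(vc) == 0) return(logical())
  is.na(vc$population_af) | vc$population_af < kb$af_threshold
}

#' Run the three-layer germline filter cascade
#'
#' Every call receives a decision: it is retained when it passes at
#' least one enabled retention layer (reference range or reportable
#' range; union semantics) and is not removed by the frequency filter.
#' Layer evaluation is order-independent.
#'
#' @inheritParams reference_range_filter
#' @return A data frame with one row per call: the call key plus logical
#'   columns `reference_range`, `reportable_range`, `frequency`,
#'   `retained` and a semicolon-separated `reasons` string.
#' @export
run_germline_pipeline <- function(vc, kb) {
  n <- nrow(vc)
  enabled <- kb$enabled_filters
  ref <- if ("reference_range" %in% enabled) reference_range_filter(vc, kb)
         else rep(FALSE, n)
  rep_ <- if ("reportable_range" %in% enabled) reportable_range_filter(vc, kb)
          else rep(FALSE, n)
  freq <- if ("frequency" %in% enabled) frequency_filter(vc, kb)
          else rep(TRUE, n)
  retained <- (ref | rep_) & freq
  reasons <- vapply(seq_len(n), function(i) {
    r <- c(if (ref[i]) "reference_range", if (rep_[i]) "reportable_range",
           if (!freq[i]) "removed_by_frequency")
    if (length(r) == 0) "no_retention_layer" else paste(r, collapse = ";")
  }, character(1))
  data.frame(key = variant_key(vc), gene = vc$gene,
             reference_range = ref, reportable_range = rep_,
             frequency = freq, retained = retained, reasons = reasons,
             stringsAsFactors = FALSE)
}
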