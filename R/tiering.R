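#' Targetability of a gene or fusion target
#'
#' A genetic alteration is considered targetable when (1) an approved or
#' experimental drug hits the target or its downstream pathway, or (2)
#' there is preclinical evidence supporting efficient targeting; and (3)
#' some age-appropriate dosing information exists.
#'
#' @param gene Gene symbol (for a fusion, the targeted partner gene).
#' @param kb A [knowledge_base()] with a `drug_targets` catalog.
#' @return A list: `targetable` flag, `criteria` (named logicals
#'   `drug_available`, `preclinical_evidence`, `pediatric_dosing`),
#'   `drugs` (matching drug names) and `reason`.
#' @export
is_targetable <- function(gene, kb) {
  rows <- kb$drug_targets[kb$drug_targets$gene == gene, , drop = FALSE]
  if (nrow(rows) == 0)
    return(list(targetable = FALSE,
                criteria = c(drug_available = FALSE,
                             preclinical_evidence = FALSE,
                             pediatric_dosing = FALSE),
                drugs = character(), reason = "no catalog entry"))
  dosed <- tolower(rows$pediatric_dosing) == "yes"
  drug_avail <- rows$approval_status %in% c("approved", "experimental")
  preclin <- rows$evidence_class == "preclinical"
  ok <- (drug_avail | preclin) & dosed
  list(targetable = any(ok),
       criteria = c(drug_available = any(drug_avail),
                    preclinical_evidence = any(preclin),
                    pediatric_dosing = any(dosed)),
       drugs = unique(rows$drug[ok]),
       reason = if (any(ok)) "" else "criteria not met")
}

#' Construct a reportable finding
#'
#' @param source One of `snv_indel`, `fusion`, `cnv`, `expression`,
#'   `germline`.
#' @param gene Gene symbol (targeted partner for a fusion).
#' @param description Human-readable alteration (e.g. `"BCR-ABL1 fusion"`,
#'   `"c.3574C>T (p.R1192C)"`).
#' @param hgvs_p Protein change, used for hotspot matching.
#' @param cosmic_id Somatic-catalog identifier or empty.
#' @param labels Character vector of catalog utility labels among
#'   `diagnostic`, `prognostic`, `other_impact`, `health_maintenance`.
#' @param known_driver TRUE when the alteration is a previously
#'   characterized driver (e.g. a catalog-known fusion from
#'   [annotate_fusions()]); SNV hotspot status is derived from
#'   `hgvs_p` automatically.
#' @param germline_category For germline findings: `acmg_pathogenic`,
#'   `non_acmg_cancer`, `pharmacogenomic`, `vous_returned` or `n/a`.
#' @param board_override TRUE when the molecular tumor board manually
#'   qualified the finding for treatment planning (actionability tier 5;
#'   never auto-assigned).
#' @param evidence Character vector of citation strings.
#' @return A `tiered_finding` list (tiers unset until assigned).
#' @export
tiered_finding <- function(source = c("snv_indel", "fusion", "cnv",
                                      "expression", "germline"),
                           gene, description = "", hgvs_p = "",
                           cosmic_id = "", labels = character(),
                           known_driver = FALSE,
                           germline_category = "n/a",
                           board_override = FALSE,
                           evidence = character()) {
  source <- match.arg(source)
  structure(list(source = source, gene = gene, description = description,
                 hgvs_p = hgvs_p, cosmic_id = cosmic_id, labels = labels,
                 known_driver = known_driver,
                 germline_category = germline_category,
                 board_override = board_override, evidence = evidence,
                 report_tier = NA_integer_, actionability_tier = NA_integer_,
                 utility = character()), class = "tiered_finding")
}

tumor_type_matches <- function(context, tumor_types) {
  terms <- trimws(strsplit(tumor_types, ";", fixed = TRUE)[[1]])
  tolower(trimws(context)) %in% tolower(terms[nzchar(terms)])
}

#' Assign the somatic report tier (1-4)
#'
#' Ordered rules; the lowest-numbered (strongest) matching tier wins:
#' \enumerate{
#'   \item known tumor type-specific actionable mutation: the alteration
#'     is a previously characterized driver (catalog hotspot by protein
#'     change, or a known-driver flag as set for catalog fusions), the
#'     gene is targetable, and a drug row carries evidence in this tumor
#'     type;
#'   \item mutation in a targetable pathway / actionable in another
#'     tumor type, or in a well-established cancer gene;
#'   \item other mutation in a cancer gene (somatic-catalog identifier
#'     known);
#'   \item somatic variant of uncertain significance (catch-all).
#' }
#'
#' @param finding A [tiered_finding()] (somatic source).
#' @param context Tumor type of the patient.
#' @param kb A [knowledge_base()].
#' @return Integer tier 1-4.
#' @export
assign_report_tier <- function(finding, context, kb) {
  g <- finding$gene
  hot <- isTRUE(finding$known_driver) ||
    (nrow(kb$hotspots) > 0 && nzchar(finding$hgvs_p) &&
       any(kb$hotspots$gene == g & kb$hotspots$hgvs_p == finding$hgvs_p))
  tg <- is_targetable(g, kb)
  rows <- kb$drug_targets[kb$drug_targets$gene == g, , drop = FALSE]
  same_type <- nrow(rows) > 0 &&
    any(vapply(rows$tumor_types, function(tt) tumor_type_matches(context, tt),
               logical(1)))
  if (hot && tg$targetable && same_type) return(1L)
  if (tg$targetable || g %in% kb$cancer_genes) return(2L)
  if (nzchar(finding$cosmic_id) && finding$cosmic_id %in% kb$cosmic_ids)
    return(3L)
  4L
}

#' Assign the actionability sub-tier (1-5)
#'
#' Evidence-level sub-tiering of targetable alterations:
#' clinical-benefit data in the same tumor type and gene gives tier 1;
#' clinical data in a different tumor type tier 2; preclinical data in
#' the same tumor type tier 3; preclinical data in a different tumor
#' type tier 4; tier 5 is reserved for a manual molecular-tumor-board
#' override and never auto-assigned. When several evidence rows match,
#' the strongest (lowest) tier wins. Adding evidence can only keep or
#' lower the tier.
#'
#' @param finding A [tiered_finding()]; must be targetable unless
#'   `board_override` is set.
#' @param context Tumor type of the patient.
#' @param kb A [knowledge_base()].
#' @return Integer sub-tier 1-5.
#' @export
assign_actionability_tier <- function(finding, context, kb) {
  if (isTRUE(finding$board_override)) return(5L)
  rows <- kb$drug_targets[kb$drug_targets$gene == finding$gene, , drop = FALSE]
  if (nrow(rows) == 0) stop("evidence required: no drug-target entry for ",
                            finding$gene)
  tiers <- vapply(seq_len(nrow(rows)), function(j) {
    same <- tumor_type_matches(context, rows$tumor_types[j])
    clinical <- rows$evidence_class[j] == "clinical"
    if (clinical && same) 1L else if (clinical) 2L
    else if (same) 3L else 4L
  }, integer(1))
  min(tiers)
}

#' Decide whether a germline VOUS is returned
#'
#' A germline variant of uncertain significance is returned to the
#' family only when all three criteria hold: (1) the variant is
#' predicted destructive (nonsense, frameshift or splice site); (2) it
#' lies in a well-validated cancer-associated gene; (3) a second somatic
#' alteration exists in the same gene, or the variant is reduced to
#' homozygosity in the tumor (tumor VAF >= 0.9 at the germline site).
#'
#' @param vous A single-row `variant_calls` data frame (the germline
#'   variant).
#' @param somatic Classification table from [classify_variants()] for
#'   the tumor (or a `variant_calls` table of somatic calls).
#' @param kb A [knowledge_base()].
#' @param tumor_vaf Tumor VAF at the germline site (NA when unknown).
#' @return A list: `return` flag and the named `criteria` record.
#' @export
vous_return_decision <- function(vous, somatic, kb, tumor_vaf = NA_real_) {
  stopifnot(nrow(vous) == 1)
  destructive <- vous$consequence %in% DISRUPTIVE_CONSEQUENCES
  cancer_gene <- nzchar(vous$gene) && vous$gene %in% kb$cancer_genes
  somatic_genes <- if (!is.null(somatic$gene)) {
    if (!is.null(somatic$somatic)) somatic$gene[somatic$somatic]
    else somatic$gene
  } else character()
  second_hit <- (nzchar(vous$gene) && vous$gene %in% somatic_genes) ||
    (!is.na(tumor_vaf) && tumor_vaf >= 0.9)
  criteria <- c(destructive = destructive, cancer_gene = cancer_gene,
                second_somatic_hit_or_reduced_to_hom = second_hit)
  list(return = all(criteria), criteria = criteria)
}

#' Clinical-utility categories of a finding
#'
#' Maps catalog labels onto the five utility categories: diagnostic,
#' prognostic, therapeutic target (iff targetable), other impact
#' (e.g. pharmacogenomic), and health maintenance / genetic counseling.
#'
#' @param finding A [tiered_finding()].
#' @param kb A [knowledge_base()].
#' @return Character vector (possibly empty) drawn from the five
#'   categories.
#' @export
categorize_utility <- function(finding, kb) {
  u <- intersect(finding$labels, c("diagnostic", "prognostic",
                                   "other_impact", "health_maintenance"))
  if ("pharmacogenomic" %in% finding$labels ||
      finding$germline_category == "pharmacogenomic")
    u <- c(u, "other_impact")
  if (is_targetable(finding$gene, kb)$targetable)
    u <- c(u, "therapeutic_target")
  sort(unique(u))
}
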