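#' Sample metadata
#'
#' @param patient_id Patient identifier.
#' @param sample_role `"tumor"` or `"normal"`.
#' @param disease_group `"solid"` or `"hematologic"` (required for tumor
#'   samples).
#' @param diagnosis Free-text diagnosis.
#' @param timepoint `"primary"` or `"relapse_refractory"`.
#' @param assay `"cWES"`, `"WES"`, `"panel"` or `"rnaseq"`.
#' @return A `sample_meta` list.
#' @export
sample_meta <- function(patient_id, sample_role = c("tumor", "normal"),
                        disease_group = NA_character_, diagnosis = "",
                        timepoint = c("primary", "relapse_refractory"),
                        assay = c("cWES", "WES", "panel", "rnaseq")) {
  sample_role <- match.arg(sample_role)
  if (!nzchar(patient_id)) stop("patient_id must be non-empty")
  if (sample_role == "tumor" && is.na(disease_group))
    stop("disease_group required for tumor samples")
  structure(list(patient_id = patient_id, sample_role = sample_role,
                 disease_group = disease_group, diagnosis = diagnosis,
                 timepoint = match.arg(timepoint), assay = match.arg(assay)),
            class = "sample_meta")
}

REPORT_SECTIONS <- c("somatic_tier_1", "somatic_tier_2", "somatic_tier_3",
                     "somatic_tier_4", "fusions", "cnv", "expression",
                     "germline_acmg", "germline_other", "pharmacogenomics")

finding_section <- function(f) {
  if (f$source == "germline") {
    if (f$germline_category == "pharmacogenomic") return("pharmacogenomics")
    if (f$germline_category == "acmg_pathogenic") return("germline_acmg")
    return("germline_other")
  }
  if (f$source == "fusion") return("fusions")
  if (f$source == "cnv") return("cnv")
  if (f$source == "expression") return("expression")
  if (!is.na(f$report_tier)) return(paste0("somatic_tier_", f$report_tier))
  "somatic_tier_4"
}

#' Assemble a clinical report
#'
#' Places each finding in exactly one report section (somatic tiers 1-4,
#' fusions, CNV, expression, germline categories, pharmacogenomics).
#' Secondary (ACMG) findings are suppressed from the rendered document
#' when the patient opted out, and recorded in the `audit` table
#' instead.
#'
#' @param patient A [sample_meta()].
#' @param findings List of [tiered_finding()] objects with tiers
#'   assigned.
#' @param secondary_findings_optin TRUE unless the patient opted out of
#'   secondary findings.
#' @return A `clinical_report` list with `sections` (ordered) and
#'   `audit` (suppressed findings).
#' @export
clinical_report <- function(patient, findings,
                            secondary_findings_optin = TRUE) {
  sections <- setNames(vector("list", length(REPORT_SECTIONS)), REPORT_SECTIONS)
  audit <- list()
  for (f in findings) {
    sec <- finding_section(f)
    if (sec == "germline_acmg" && !secondary_findings_optin) {
      audit[[length(audit) + 1L]] <- f
    } else {
      sections[[sec]] <- c(sections[[sec]], list(f))
    }
  }
  structure(list(patient = patient, sections = sections, audit = audit,
                 secondary_findings_optin = secondary_findings_optin),
            class = "clinical_report")
}

finding_line <- function(f) {
  bits <- c(f$gene,
            if (nzchar(f$description)) f$description,
            if (!is.na(f$report_tier)) paste0("report tier ", f$report_tier),
            if (!is.na(f$actionability_tier))
              paste0("actionability tier ", f$actionability_tier),
            if (length(f$utility)) paste0("utility: ",
                                          paste(f$utility, collapse = ", ")),
            if (f$germline_category != "n/a") f$germline_category)
  paste(bits, collapse = " | ")
}

section_title <- c(
  somatic_tier_1 = "Somatic findings - Tier 1 (tumor type-specific actionable)",
  somatic_tier_2 = "Somatic findings - Tier 2 (targetable pathway / other tumor type / established cancer gene)",
  somatic_tier_3 = "Somatic findings - Tier 3 (other mutations in cancer genes)",
  somatic_tier_4 = "Somatic findings - Tier 4 (variants of uncertain significance)",
  fusions = "Fusion transcripts",
  cnv = "Copy number variation",
  expression = "Expression outliers",
  germline_acmg = "Germline findings - secondary findings",
  germline_other = "Germline findings - other",
  pharmacogenomics = "Pharmacogenomics")

#' Render a clinical report
#'
#' Deterministic rendering: section order is fixed, findings appear in
#' input order within sections, and rerunning on the same report yields
#' byte-identical output.
#'
#' @param report A [clinical_report()].
#' @param format `"markdown"` or `"json"`.
#' @return A single character string (the document).
#' @export
render_report <- function(report, format = c("markdown", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    doc <- list(
      patient = unclass(report$patient),
      secondary_findings_optin = report$secondary_findings_optin,
      sections = lapply(report$sections, function(fs)
        lapply(fs, function(f) {
          x <- unclass(f)
          x$report_tier <- if (is.na(x$report_tier)) NULL else x$report_tier
          x$actionability_tier <-
            if (is.na(x$actionability_tier)) NULL else x$actionability_tier
          x
        })))
    return(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                                         digits = NA, pretty = TRUE)))
  }
  lines <- c(paste0("# Clinical sequencing report - patient ",
                    report$patient$patient_id),
             "",
             paste0("Diagnosis: ", report$patient$diagnosis),
             paste0("Disease group: ", report$patient$disease_group),
             paste0("Assay: ", report$patient$assay),
             paste0("Secondary findings: ",
                    if (report$secondary_findings_optin) "opted in" else "opted out"),
             "")
  for (sec in REPORT_SECTIONS) {
    fs <- report$sections[[sec]]
    lines <- c(lines, paste0("## ", section_title[[sec]]), "")
    if (length(fs) == 0) {
      lines <- c(lines, "No findings.", "")
    } else {
      lines <- c(lines, paste0("- ", vapply(fs, finding_line, character(1))), "")
    }
  }
  paste(lines, collapse = "\n")
}

#' Audit table of suppressed findings
#'
#' @param report A [clinical_report()].
#' @return Data frame of findings suppressed by opt-out (gene,
#'   description, category).
#' @export
report_audit <- function(report) {
  if (length(report$audit) == 0)
    return(data.frame(gene = character(), description = character(),
                      germline_category = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(report$audit, function(f)
    data.frame(gene = f$gene, description = f$description,
               germline_category = f$germline_category,
               stringsAsFactors = FALSE)))
}
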