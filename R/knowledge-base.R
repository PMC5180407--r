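#' Construct a knowledge base
#'
#' The knowledge base parameterizes every filter and tier rule: gene
#' catalogs for the reference-range and reportable-range germline
#' filters, somatic-catalog identifiers, hotspot (gene, protein-change)
#' pairs, known fusions, drug-target rows with evidence annotations,
#' housekeeping genes for expression normalization, and the population
#' allele-frequency threshold.
#'
#' @param reference_range_genes,acmg_genes,cancer_genes,housekeeping_genes
#'   Character vectors of gene symbols.
#' @param cosmic_ids Character vector of somatic-catalog identifiers.
#' @param hotspots Data frame with columns `gene`, `hgvs_p`.
#' @param known_fusions Data frame with columns `gene5`, `gene3` and
#'   optional label columns `diagnostic`, `prognostic`, `targetable`.
#' @param drug_targets Data frame with columns `gene`, `drug`,
#'   `approval_status` (`approved`/`experimental`), `pediatric_dosing`
#'   (`yes`/`no`), `evidence_class` (`clinical`/`preclinical`),
#'   `tumor_types` (semicolon-separated), `pathway`.
#' @param patient_care_variants Data frame with columns `gene`, `hgvs_c`,
#'   `label`: the explicit allow-list of variants relevant to patient
#'   care.
#' @param af_threshold Population minor-allele-frequency threshold for
#'   the germline frequency filter; variants at or above it are removed
#'   (default 0.01).
#' @param enabled_filters Character vector of enabled components; used
#'   by [load_knowledge_base()] to decide which catalogs are mandatory.
#' @return An object of class `knowledge_base`.
#' @export
knowledge_base <- function(reference_range_genes = character(),
                           acmg_genes = character(),
                           cosmic_ids = character(),
                           cancer_genes = character(),
                           hotspots = NULL,
                           known_fusions = NULL,
                           drug_targets = NULL,
                           housekeeping_genes = character(),
                           patient_care_variants = NULL,
                           af_threshold = 0.01,
                           enabled_filters = c("reference_range",
                                               "reportable_range",
                                               "frequency")) {
  if (!is.numeric(af_threshold) || af_threshold <= 0 || af_threshold >= 1)
    stop("af_threshold must lie in (0, 1)")
  empty <- function(cols) {
    df <- as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                        stringsAsFactors = FALSE)
    df
  }
  kb <- structure(list(
    reference_range_genes = sort(unique(reference_range_genes)),
    acmg_genes = sort(unique(acmg_genes)),
    cosmic_ids = sort(unique(cosmic_ids)),
    cancer_genes = sort(unique(cancer_genes)),
    hotspots = hotspots %||% empty(c("gene", "hgvs_p")),
    known_fusions = known_fusions %||% empty(c("gene5", "gene3")),
    drug_targets = drug_targets %||% empty(c("gene", "drug",
      "approval_status", "pediatric_dosing", "evidence_class",
      "tumor_types", "pathway")),
    housekeeping_genes = sort(unique(housekeeping_genes)),
    patient_care_variants = patient_care_variants %||% empty(c("gene", "hgvs_c", "label")),
    af_threshold = af_threshold,
    enabled_filters = enabled_filters), class = "knowledge_base")
  check_kb_requirements(kb)
  kb
}

kb_requirements <- list(
  reference_range = "reference_range_genes",
  reportable_range = c("cosmic_ids", "acmg_genes"),
  tiering = c("hotspots", "cancer_genes", "drug_targets"),
  fusion = "known_fusions",
  expression = "housekeeping_genes")

check_kb_requirements <- function(kb) {
  for (filt in intersect(kb$enabled_filters, names(kb_requirements))) {
    for (cat in kb_requirements[[filt]]) {
      x <- kb[[cat]]
      n <- if (is.data.frame(x)) nrow(x) else length(x)
      if (n == 0)
        stop("catalog '", cat, "' is empty but filter '", filt, "' is enabled")
    }
  }
  invisible(kb)
}

#' Load a knowledge base from a YAML configuration
#'
#' The configuration names one file per catalog (paths resolved relative
#' to the configuration file), threshold values, and the list of enabled
#' filters. Gene-list files are plain text (one symbol per line, `#`
#' comments); tabular catalogs are TSV. Duplicate symbols are
#' de-duplicated. An empty catalog required by an enabled filter is an
#' error naming that filter.
#'
#' @param config Path to a YAML configuration file. The default is the
#'   bundled testing knowledge base.
#' @return A `knowledge_base` object.
#' @export
load_knowledge_base <- function(config = system.file("extdata", "kb", "kb.yaml",
                                                     package = "oncoreport")) {
  if (!file.exists(config)) stop("no such config file: ", config)
  cfg <- yaml::read_yaml(config)
  base_dir <- dirname(normalizePath(config))
  resolve <- function(p) if (is.null(p)) NULL else
    if (file.exists(p)) p else file.path(base_dir, p)
  cat_cfg <- cfg$catalogs %||% list()
  get_list <- function(name) {
    p <- resolve(cat_cfg[[name]])
    if (is.null(p)) return(character())
    if (!file.exists(p)) stop("catalog file not found: ", p)
    read_gene_list(p)
  }
  get_tsv <- function(name) {
    p <- resolve(cat_cfg[[name]])
    if (is.null(p)) return(NULL)
    if (!file.exists(p)) stop("catalog file not found: ", p)
    df <- read_tsv_file(p)
    for (col in names(df)) if (is.character(df[[col]])) df[[col]][is.na(df[[col]])] <- ""
    unique(df)
  }
  knowledge_base(
    reference_range_genes = get_list("reference_range_genes"),
    acmg_genes = get_list("acmg_genes"),
    cosmic_ids = get_list("cosmic_ids"),
    cancer_genes = get_list("cancer_genes"),
    hotspots = get_tsv("hotspots"),
    known_fusions = get_tsv("known_fusions"),
    drug_targets = get_tsv("drug_targets"),
    housekeeping_genes = get_list("housekeeping_genes"),
    patient_care_variants = get_tsv("patient_care_variants"),
    af_threshold = cfg$thresholds$af_threshold %||% 0.01,
    enabled_filters = unlist(cfg$enabled_filters) %||%
      c("reference_range", "reportable_range", "frequency"))
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("<knowledge_base>\n")
  cat("  reference-range genes:", length(x$reference_range_genes), "\n")
  cat("  secondary-findings genes:", length(x$acmg_genes), "\n")
  cat("  somatic-catalog ids:", length(x$cosmic_ids), "\n")
  cat("  cancer genes:", length(x$cancer_genes), "\n")
  cat("  hotspots:", nrow(x$hotspots), "\n")
  cat("  known fusions:", nrow(x$known_fusions), "\n")
  cat("  drug-target rows:", nrow(x$drug_targets), "\n")
  cat("  housekeeping genes:", length(x$housekeeping_genes), "\n")
  cat("  af threshold:", x$af_threshold, "\n")
  invisible(x)
}

#' Load a bundled cohort fixture table
#'
#' The package ships curated tables of reported findings (targetable
#' somatic alterations by actionability tier; clinical-utility findings;
#' germline findings by section) used by the cohort analytics. Rows carry
#' the patient identifier, section, alteration and footnote flags
#' (`same_patient`, `therapy_received`).
#'
#' @param name One of `"table2"`/`"targetable"`, `"table3"`/`"utility"`,
#'   `"table4"`/`"germline"`.
#' @return A data frame.
#' @export
load_fixture_table <- function(name) {
  files <- c(table2 = "table2_targetable.tsv", targetable = "table2_targetable.tsv",
             table3 = "table3_utility.tsv", utility = "table3_utility.tsv",
             table4 = "table4_germline.tsv", germline = "table4_germline.tsv")
  if (!name %in% names(files)) stop("unknown fixture table: ", name)
  path <- system.file("extdata", "fixtures", files[[name]],
                      package = "oncoreport")
  df <- read_tsv_file(path, colClasses = "character")
  for (col in c("same_patient", "therapy_received", "previously_known"))
    if (!is.null(df[[col]])) df[[col]] <- toupper(df[[col]]) == "TRUE"
  for (col in names(df)) if (is.character(df[[col]])) df[[col]][is.na(df[[col]])] <- ""
  df
}

#' Load the cohort denominators
#'
#' Per-category patient counts of the study cohort (all patients, solid
#' vs hematologic, germline-tested, ...) used as denominators for cohort
#' proportions.
#'
#' @return A named integer vector.
#' @export
cohort_denominators <- function() {
  path <- system.file("extdata", "fixtures", "denominators.tsv",
                      package = "oncoreport")
  df <- read_tsv_file(path)
  setNames(as.integer(df$count), df$category)
}
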