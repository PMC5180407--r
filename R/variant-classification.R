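#' Mutational-load filter configuration
#'
#' Tumor-specific variants counted toward the mutational load require at
#' least 30X coverage in tumor and either a caller quality score >= 20
#' or a variant allelic fraction >= 25%.
#'
#' @param min_coverage Minimum tumor depth (default 30).
#' @param min_quality Minimum caller quality score (default 20).
#' @param alt_vaf Alternative VAF branch (default 0.25).
#' @return A `load_filter_config` list.
#' @export
load_filter_config <- function(min_coverage = 30, min_quality = 20,
                               alt_vaf = 0.25) {
  stopifnot(min_coverage > 0, min_quality > 0, alt_vaf > 0)
  structure(list(min_coverage = min_coverage, min_quality = min_quality,
                 alt_vaf = alt_vaf), class = "load_filter_config")
}

#' Mutational-load eligibility of tumor calls
#'
#' @param vc A `variant_calls` data frame.
#' @param cfg A [load_filter_config()].
#' @return Logical vector: `depth >= 30 & (quality >= 20 | vaf >= 0.25)`.
#'   Calls missing both quality and VAF are ineligible with a warning.
#' @export
load_filter <- function(vc, cfg = load_filter_config()) {
  if (nrow(vc) == 0) return(logical())
  both_missing <- is.na(vc$quality_score) & is.na(vc$vaf)
  if (any(both_missing))
    warning(sum(both_missing),
            " call(s) missing both quality score and VAF treated as ineligible")
  qual_ok <- !is.na(vc$quality_score) & vc$quality_score >= cfg$min_quality
  vaf_ok <- !is.na(vc$vaf) & vc$vaf >= cfg$alt_vaf
  !is.na(vc$depth) & vc$depth >= cfg$min_coverage & (qual_ok | vaf_ok)
}

DISRUPTIVE_CONSEQUENCES <- c("nonsense", "frameshift", "splice_site")

#' Characterize tumor variants
#'
#' Tags each call with every applicable category:
#' \describe{
#'   \item{homozygous}{caller zygosity `hom`, or VAF >= `hom_vaf` at
#'     depth >= `hom_min_depth` (conventional exome practice; reported
#'     separately as `reduced_to_hom` when the VAF rule alone fires)}
#'   \item{compound_het}{two or more distinct heterozygous calls share a
#'     gene in this sample (phase unknown)}
#'   \item{somatic}{the call key is in `somatic_keys`}
#'   \item{disruptive}{loss-of-function consequence: nonsense,
#'     frameshift or splice site}
#' }
#' Assignment is deterministic and independent of input order.
#'
#' @param vc A normalized `variant_calls` data frame.
#' @param somatic_keys Character vector of somatic keys (from
#'   [subtract_somatic()] output via [variant_key()]).
#' @param cfg A [load_filter_config()] used for the `load_eligible` flag.
#' @param hom_vaf,hom_min_depth Numeric rule for calling homozygosity
#'   from VAF when the caller zygosity is unknown (defaults 0.9, 30).
#' @return A data frame: call key, gene, logical category columns and
#'   `load_eligible`.
#' @export
classify_variants <- function(vc, somatic_keys = character(),
                              cfg = load_filter_config(),
                              hom_vaf = 0.9, hom_min_depth = 30) {
  key <- variant_key(vc)
  n <- nrow(vc)
  if (n == 0)
    return(data.frame(key = character(), gene = character(),
                      homozygous = logical(), reduced_to_hom = logical(),
                      compound_het = logical(), somatic = logical(),
                      disruptive = logical(), load_eligible = logical(),
                      stringsAsFactors = FALSE))
  vaf_hom <- !is.na(vc$vaf) & vc$vaf >= hom_vaf &
    !is.na(vc$depth) & vc$depth >= hom_min_depth
  homozygous <- vc$zygosity == "hom" | vaf_hom
  reduced_to_hom <- vaf_hom & vc$zygosity != "hom"
  het <- vc$zygosity == "het"
  comp <- rep(FALSE, n)
  for (g in unique(vc$gene[het & nzchar(vc$gene)])) {
    idx <- which(het & vc$gene == g)
    if (length(unique(key[idx])) >= 2) comp[idx] <- TRUE
  }
  data.frame(key = key, gene = vc$gene,
             homozygous = homozygous, reduced_to_hom = reduced_to_hom,
             compound_het = comp, somatic = key %in% somatic_keys,
             disruptive = vc$consequence %in% DISRUPTIVE_CONSEQUENCES,
             load_eligible = suppressWarnings(load_filter(vc, cfg)),
             stringsAsFactors = FALSE)
}

#' Cohort mutational-load statistics
#'
#' Summarizes per-sample mutational-load counts: mean, sample (n-1)
#' standard deviation, median and range, overall and per disease group.
#' For a single sample the SD is reported as 0 with `sd_degenerate`
#' flagged.
#'
#' @param counts Numeric vector, one load count per tumor sample.
#' @param disease_group Optional character vector parallel to `counts`
#'   (e.g. `"solid"` / `"hematologic"`).
#' @return A list with `overall` (and `by_group` when groups are given);
#'   each element holds n, mean, sd, median, min, max, sd_degenerate.
#' @export
cohort_load_stats <- function(counts, disease_group = NULL) {
  if (length(counts) == 0) stop("no counts supplied")
  if (any(is.na(counts))) stop("NA counts not allowed")
  one <- function(x) {
    degenerate <- length(x) < 2
    list(n = length(x), mean = mean(x),
         sd = if (degenerate) 0 else stats::sd(x),
         median = stats::median(x), min = min(x), max = max(x),
         sd_degenerate = degenerate, sd_convention = "sample (n-1)")
  }
  out <- list(overall = one(counts))
  if (!is.null(disease_group)) {
    stopifnot(length(disease_group) == length(counts))
    out$by_group <- lapply(split(counts, disease_group), one)
  }
  out
}
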