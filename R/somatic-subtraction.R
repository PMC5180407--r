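#' Subtraction configuration
#'
#' Output thresholds for calling a variant in each sample: a minimum
#' variant allelic fraction of 10% in tumor and 5% in normal, with at
#' least 10 total reads and 3 variant-supporting reads.
#'
#' @param tumor_min_vaf Minimum tumor VAF (default 0.10).
#' @param normal_min_vaf Minimum normal VAF (default 0.05).
#' @param min_depth Minimum total reads (default 10).
#' @param min_alt_reads Minimum variant-supporting reads (default 3).
#' @return A `subtraction_config` list.
#' @export
subtraction_config <- function(tumor_min_vaf = 0.10, normal_min_vaf = 0.05,
                               min_depth = 10, min_alt_reads = 3) {
  stopifnot(normal_min_vaf > 0, normal_min_vaf <= tumor_min_vaf,
            tumor_min_vaf < 1)
  structure(list(tumor_min_vaf = tumor_min_vaf,
                 normal_min_vaf = normal_min_vaf,
                 min_depth = min_depth, min_alt_reads = min_alt_reads),
            class = "subtraction_config")
}

#' Eligibility of calls under the output thresholds
#'
#' A call is eligible when its depth and variant-read counts meet the
#' minimum (10 total / 3 variant reads) and its VAF meets the
#' role-specific minimum (10% tumor, 5% normal). Calls with missing
#' depth are ineligible with a warning.
#'
#' @param vc A `variant_calls` data frame.
#' @param role `"tumor"` or `"normal"`.
#' @param cfg A [subtraction_config()].
#' @return Logical vector, one element per call.
#' @export
call_eligible <- function(vc, role = c("tumor", "normal"),
                          cfg = subtraction_config()) {
  role <- match.arg(role)
  if (nrow(vc) == 0) return(logical())
  min_vaf <- if (role == "tumor") cfg$tumor_min_vaf else cfg$normal_min_vaf
  missing_depth <- is.na(vc$depth) | is.na(vc$alt_depth)
  if (any(missing_depth))
    warning(sum(missing_depth), " call(s) with missing depth treated as ineligible")
  ok <- !missing_depth & !is.na(vc$vaf) &
    vc$depth >= cfg$min_depth & vc$alt_depth >= cfg$min_alt_reads &
    vc$vaf >= min_vaf
  ok
}

# Duplicate keys within one sample collapse to the deepest record.
collapse_duplicates <- function(vc) {
  if (nrow(vc) == 0) return(vc)
  key <- variant_key(vc)
  if (!anyDuplicated(key)) return(vc)
  ord <- order(key, -ifelse(is.na(vc$depth), -1L, vc$depth))
  vc2 <- as.data.frame(vc)[ord, , drop = FALSE]
  keep <- !duplicated(variant_key(vc2))
  out <- vc2[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  variant_calls(out, sample_role = attr(vc, "sample_role"))
}

#' Somatic variants by tumor-normal subtraction
#'
#' Somatic mutations are identified by subtracting all variants called
#' in normal tissue (output at VAF >= 5%) from variants called in the
#' tumor (output at VAF >= 10%). Matching is by exact normalized key
#' (chrom, pos, ref, alt). Normal evidence below the normal output
#' threshold does not veto a tumor call, but its VAF is recorded in the
#' `normal_vaf` column for reviewer caution.
#'
#' @param tumor,normal Normalized `variant_calls` tables.
#' @param cfg A [subtraction_config()].
#' @return A `variant_calls` data frame of somatic calls (sorted), with
#'   an extra `normal_vaf` column (`NA` when the normal sample shows no
#'   evidence at all).
#' @export
subtract_somatic <- function(tumor, normal, cfg = subtraction_config()) {
  tumor <- collapse_duplicates(tumor)
  normal <- collapse_duplicates(normal)
  t_ok <- call_eligible(tumor, "tumor", cfg)
  n_ok <- call_eligible(normal, "normal", cfg)
  t_keys <- variant_key(tumor)
  n_keys <- variant_key(normal)
  somatic <- as.data.frame(tumor)[t_ok & !(t_keys %in% n_keys[n_ok]), , drop = FALSE]
  # sub-threshold normal evidence annotation
  idx <- match(variant_key(variant_calls(somatic)), n_keys)
  somatic$normal_vaf <- ifelse(is.na(idx), NA_real_, normal$vaf[idx])
  somatic <- somatic[order(somatic$chrom, somatic$pos, somatic$ref, somatic$alt),
                     , drop = FALSE]
  rownames(somatic) <- NULL
  out <- variant_calls(somatic[, setdiff(names(somatic), "normal_vaf")],
                       sample_role = "tumor")
  out$normal_vaf <- somatic$normal_vaf
  out
}
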