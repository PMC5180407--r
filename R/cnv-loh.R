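#' Coverage profile of a sample
#'
#' @param sample_role `"tumor"` or `"normal"`.
#' @param fraction_targets_10x,fraction_targets_30x Fractions of targeted
#'   nucleotides covered at least 10X / 30X, in \[0, 1\].
#' @return A `coverage_profile` list.
#' @export
coverage_profile <- function(sample_role = c("tumor", "normal"),
                             fraction_targets_10x = NA_real_,
                             fraction_targets_30x = NA_real_) {
  sample_role <- match.arg(sample_role)
  for (f in c(fraction_targets_10x, fraction_targets_30x))
    if (!is.na(f) && (f < 0 || f > 1)) stop("coverage fractions must lie in [0, 1]")
  structure(list(sample_role = sample_role,
                 fraction_targets_10x = fraction_targets_10x,
                 fraction_targets_30x = fraction_targets_30x),
            class = "coverage_profile")
}

#' Copy-number coverage quality gate
#'
#' CNV analysis requires greater than 95% of targeted nucleotides at
#' 10X or more in the reference normal (strict inequality) and at least
#' 90% covered 30X in the corresponding tumor.
#'
#' @param normal,tumor [coverage_profile()] objects.
#' @param normal_min_10x,tumor_min_30x Thresholds (defaults 0.95 strict,
#'   0.90 inclusive).
#' @return TRUE when both samples pass.
#' @export
coverage_gate <- function(normal, tumor, normal_min_10x = 0.95,
                          tumor_min_30x = 0.90) {
  isTRUE(normal$fraction_targets_10x > normal_min_10x) &&
    isTRUE(tumor$fraction_targets_30x >= tumor_min_30x)
}

#' Segment call table
#'
#' @param df Data frame with columns `chrom`, `start`, `end` (1-based,
#'   closed), `log2_ratio`, and optionally `n_targets`.
#' @return A `segment_calls` data frame with `state` and `loh` columns
#'   added (NA until called).
#' @export
segment_calls <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "log2_ratio") %in% names(df)))
  if (any(df$start > df$end)) stop("segment start > end")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$n_targets)) df$n_targets <- NA_integer_
  if (is.null(df$state)) df$state <- NA_character_
  if (is.null(df$loh)) df$loh <- NA
  structure(df, class = c("segment_calls", "data.frame"))
}

#' Call segment copy-number states
#'
#' State is `loss` when the log2 ratio is at or below the loss cutoff
#' (default -0.2, inclusive), `gain` at or above the gain cutoff
#' (default +0.2), else `neutral`. Gains are supporting evidence only;
#' the gain cutoff is a configurable convention.
#'
#' @param segments A [segment_calls()] data frame.
#' @param loss_cutoff,gain_cutoff Log2-ratio cutoffs.
#' @return The segments with `state` filled; every segment gets exactly
#'   one state.
#' @export
call_segment_states <- function(segments, loss_cutoff = -0.2,
                                gain_cutoff = 0.2) {
  segments$state <- ifelse(segments$log2_ratio <= loss_cutoff, "loss",
                    ifelse(segments$log2_ratio >= gain_cutoff, "gain",
                           "neutral"))
  segments
}

#' Allelic-site table
#'
#' Heterozygous-site allelic fractions used for LOH detection. Sites are
#' classified in the normal sample: `het` when the normal VAF lies in
#' \[0.45, 0.55\], `hom` in \[0.90, 1.00\], else `other`.
#'
#' @param df Data frame with columns `chrom`, `pos`, `normal_vaf`,
#'   `tumor_vaf`.
#' @return Data frame with a `class_in_normal` column added.
#' @export
allelic_sites <- function(df) {
  stopifnot(all(c("chrom", "pos", "normal_vaf", "tumor_vaf") %in% names(df)))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$class_in_normal <- ifelse(
    df$normal_vaf >= 0.45 & df$normal_vaf <= 0.55, "het",
    ifelse(df$normal_vaf >= 0.90 & df$normal_vaf <= 1.00, "hom", "other"))
  df
}

#' Detect loss of heterozygosity from allelic fractions
#'
#' A segment is flagged LOH when at least `min_sites` sites that are
#' heterozygous in the normal show a tumor VAF shifted from 0.5 by at
#' least `tumor_shift` in either direction (allele-labeling symmetric).
#' Copy-neutral LOH is an LOH flag on a copy-neutral segment. Segments
#' containing no informative (normal-het) site are flagged
#' uninformative.
#'
#' @param sites An [allelic_sites()] data frame.
#' @param segments A [segment_calls()] data frame (states already
#'   called if copy-neutral LOH is to be read off).
#' @param min_sites Minimum shifted het sites to support LOH (default
#'   10).
#' @param tumor_shift Minimum |tumor VAF - 0.5| counting as shifted
#'   (default 0.25, chosen for tumor fraction ~0.8 where the expected
#'   het shift is ~0.4).
#' @return The segments with columns `loh`, `n_informative`,
#'   `n_shifted`, `uninformative` and `copy_neutral_loh`.
#' @export
detect_loh <- function(sites, segments, min_sites = 10, tumor_shift = 0.25) {
  n_inf <- integer(nrow(segments)); n_shift <- integer(nrow(segments))
  het <- sites$class_in_normal == "het"
  for (i in seq_len(nrow(segments))) {
    in_seg <- het & sites$chrom == segments$chrom[i] &
      sites$pos >= segments$start[i] & sites$pos <= segments$end[i]
    n_inf[i] <- sum(in_seg)
    n_shift[i] <- sum(in_seg & abs(sites$tumor_vaf - 0.5) >= tumor_shift)
  }
  segments$n_informative <- n_inf
  segments$n_shifted <- n_shift
  segments$uninformative <- n_inf == 0
  segments$loh <- n_shift >= min_sites
  segments$copy_neutral_loh <- segments$loh &
    !is.na(segments$state) & segments$state == "neutral"
  segments
}

#' Merge binned log2 ratios into segments
#'
#' A deliberately simple mean-shift segmenter used for synthetic
#' end-to-end tests (production segment calls come from an external CNV
#' caller and are read as input): adjacent bins join the current segment
#' while their log2 ratio differs from the running segment mean by less
#' than `merge_tol`.
#'
#' @param bins Data frame with `chrom`, `start`, `end`, `log2_ratio`,
#'   ordered and non-overlapping within each chromosome.
#' @param merge_tol Merge tolerance on the log2 ratio (default 0.1).
#' @return A [segment_calls()] data frame with segment mean ratios and
#'   `n_targets` = bins merged.
#' @export
simple_segmenter <- function(bins, merge_tol = 0.1) {
  stopifnot(nrow(bins) > 0)
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    if (is.unsorted(b$start, strictly = TRUE) ||
        any(b$start[-1] <= b$end[-nrow(b)]))
      stop("bins must be ordered and non-overlapping within chromosome ", ch)
  }
  segs <- list()
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    cur_start <- b$start[1]; cur_end <- b$end[1]
    cur_vals <- b$log2_ratio[1]
    flush <- function() {
      segs[[length(segs) + 1L]] <<- data.frame(
        chrom = ch, start = cur_start, end = cur_end,
        log2_ratio = mean(cur_vals), n_targets = length(cur_vals),
        stringsAsFactors = FALSE)
    }
    if (nrow(b) > 1) {
      for (i in 2:nrow(b)) {
        if (abs(b$log2_ratio[i] - mean(cur_vals)) < merge_tol) {
          cur_end <- b$end[i]; cur_vals <- c(cur_vals, b$log2_ratio[i])
        } else {
          flush()
          cur_start <- b$start[i]; cur_end <- b$end[i]
          cur_vals <- b$log2_ratio[i]
        }
      }
    }
    flush()
  }
  segment_calls(do.call(rbind, segs))
}
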