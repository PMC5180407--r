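#' Housekeeping-normalized expression profile
#'
#' Per-gene FPKM values are normalized by the sample's median FPKM over
#' a housekeeping-gene reference set, making profiles comparable across
#' samples and invariant to global scaling of the FPKM vector.
#'
#' @param sample_id Sample identifier.
#' @param fpkm Named numeric vector of FPKM values (names = gene
#'   symbols).
#' @param housekeeping Character vector of housekeeping gene symbols;
#'   those present in `fpkm` define the normalizer.
#' @return An `expression_profile` list with `fpkm`, `hk_median` and
#'   `normalized`.
#' @export
expression_profile <- function(sample_id, fpkm, housekeeping) {
  stopifnot(!is.null(names(fpkm)), all(nzchar(names(fpkm))))
  hk <- intersect(housekeeping, names(fpkm))
  if (length(hk) == 0) stop("no housekeeping genes present in sample ", sample_id)
  hk_median <- stats::median(fpkm[hk])
  if (!is.finite(hk_median) || hk_median <= 0)
    stop("housekeeping median must be positive in sample ", sample_id)
  structure(list(sample_id = sample_id, fpkm = fpkm,
                 hk_median = hk_median, normalized = fpkm / hk_median),
            class = "expression_profile")
}

#' Build a panel-of-normals expression reference model
#'
#' Computes a robust per-gene location (median) and scale (median
#' absolute deviation) of housekeeping-normalized expression across a
#' panel of normal transcriptomes. Genes absent from a profile count as
#' 0 in that profile.
#'
#' @param panel List of [expression_profile()] objects (>= 2).
#' @param tissue Optional character vector of tissue labels parallel to
#'   `panel`, stored as the panel composition.
#' @return A `reference_model` list with `genes`, `location`, `scale`,
#'   `panel_size`, `tissue_composition`.
#' @export
build_reference_model <- function(panel, tissue = NULL) {
  if (length(panel) < 2) stop("panel must contain at least 2 profiles")
  genes <- sort(unique(unlist(lapply(panel, function(p) names(p$normalized)))))
  mat <- vapply(panel, function(p) {
    v <- p$normalized[genes]
    v[is.na(v)] <- 0
    unname(v)
  }, numeric(length(genes)))
  location <- apply(mat, 1, stats::median)
  scale <- apply(mat, 1, stats::mad)
  comp <- if (!is.null(tissue)) table(tissue) else NULL
  structure(list(genes = genes, location = setNames(location, genes),
                 scale = setNames(scale, genes), panel_size = length(panel),
                 tissue_composition = comp), class = "reference_model")
}

#' Flag expression outliers against the reference model
#'
#' A gene is flagged over-expressed when its robust z score
#' `(normalized - location) / max(scale, eps)` reaches `z_cutoff`, and
#' under-expressed at `-z_cutoff`. `eps` (in normalized units) guards
#' genes with zero panel scale. The numeric cutoff is a configurable
#' convention.
#'
#' @param sample An [expression_profile()].
#' @param model A [build_reference_model()] result.
#' @param z_cutoff Robust z threshold (default 3).
#' @param eps Scale floor (default 0.01 normalized units).
#' @return Data frame with columns `gene`, `direction` (`over`/`under`)
#'   and `z`, sorted by decreasing |z|. Genes absent from the model are
#'   skipped with a warning.
#' @export
flag_outliers <- function(sample, model, z_cutoff = 3, eps = 0.01) {
  genes <- names(sample$normalized)
  unknown <- setdiff(genes, model$genes)
  if (length(unknown) > 0)
    warning(length(unknown), " gene(s) absent from the reference model skipped")
  genes <- intersect(genes, model$genes)
  z <- (sample$normalized[genes] - model$location[genes]) /
    pmax(model$scale[genes], eps)
  hit <- abs(z) >= z_cutoff
  out <- data.frame(gene = genes[hit],
                    direction = ifelse(z[hit] > 0, "over", "under"),
                    z = unname(z[hit]), stringsAsFactors = FALSE)
  out[order(-abs(out$z), out$gene), , drop = FALSE]
}

#' Read a two-column expression table
#'
#' @param path TSV with columns `gene_id` and `FPKM` (header optional
#'   names; first two columns used).
#' @return Named numeric vector of FPKMs.
#' @export
read_expression_table <- function(path) {
  df <- read_tsv_file(path)
  setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Read a fusion-call table
#'
#' @param path TSV with columns `gene5`, `gene3`, `break5`, `break3`,
#'   `supporting_reads`.
#' @return Data frame of fusion calls.
#' @export
read_fusion_table <- function(path) {
  df <- read_tsv_file(path)
  need <- c("gene5", "gene3")
  if (!all(need %in% names(df))) stop("fusion table needs gene5/gene3 columns")
  if (any(!nzchar(df$gene5))) stop("empty gene5 in fusion table")
  if (!is.null(df$supporting_reads) && any(df$supporting_reads < 1))
    stop("supporting_reads must be >= 1")
  df
}

#' Annotate fusion calls against the known-fusion catalog
#'
#' A fusion is `known` when the exact ordered (5', 3') pair is in the
#' catalog, either orientation of the pair matches, or a single partner
#' gene matches a catalog fusion (partner-gene rule: a novel fusion is
#' expected to act like a known fusion sharing one partner).
#' `match_type` distinguishes `exact` from `partner` matches; 5'/3'
#' order of the input is preserved.
#'
#' @param calls Data frame with `gene5`, `gene3` columns.
#' @param kb A [knowledge_base()] with a `known_fusions` catalog.
#' @return `calls` with columns `known`, `match_type` and `annotation`
#'   (diagnostic/prognostic/targetable labels from the catalog).
#' @export
annotate_fusions <- function(calls, kb) {
  cat <- kb$known_fusions
  n <- nrow(calls)
  known <- logical(n); mtype <- rep("none", n); ann <- character(n)
  cat_pairs <- paste(cat$gene5, cat$gene3)
  labels_of <- function(rows) {
    lab <- c()
    for (j in rows) {
      if (!is.null(cat$diagnostic) && nzchar(cat$diagnostic[j]))
        lab <- c(lab, paste0("diagnostic:", cat$diagnostic[j]))
      if (!is.null(cat$prognostic) && isTRUE(toupper(cat$prognostic[j]) == "TRUE"))
        lab <- c(lab, "prognostic")
      if (!is.null(cat$targetable) && nzchar(cat$targetable[j]))
        lab <- c(lab, paste0("targetable:", cat$targetable[j]))
    }
    paste(unique(lab), collapse = ";")
  }
  for (i in seq_len(n)) {
    g5 <- calls$gene5[i]; g3 <- calls$gene3[i]
    exact <- which(cat_pairs %in% c(paste(g5, g3), paste(g3, g5)))
    if (length(exact) > 0) {
      known[i] <- TRUE; mtype[i] <- "exact"; ann[i] <- labels_of(exact)
    } else {
      partner <- which(cat$gene5 %in% c(g5, g3) | cat$gene3 %in% c(g5, g3))
      if (length(partner) > 0) {
        known[i] <- TRUE; mtype[i] <- "partner"; ann[i] <- labels_of(partner)
      }
    }
  }
  calls$known <- known
  calls$match_type <- mtype
  calls$annotation <- ann
  calls
}

#' RNA quality-control gate
#'
#' Metadata check on user-supplied QC numbers: at least 50 million
#' uniquely mapped reads and less than 5% DNA contamination.
#'
#' @param uniquely_mapped_reads Count of uniquely mapped reads.
#' @param dna_contamination Fraction in \[0, 1\].
#' @param min_reads,max_contamination Thresholds.
#' @return TRUE when the sample passes.
#' @export
rna_qc_gate <- function(uniquely_mapped_reads, dna_contamination,
                        min_reads = 5e7, max_contamination = 0.05) {
  isTRUE(uniquely_mapped_reads >= min_reads) &&
    isTRUE(dna_contamination < max_contamination)
}
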