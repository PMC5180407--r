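#' Variant call tables
#'
#' A `variant_calls` object is a data frame with one row per normalized
#' variant observation in one sample. Columns:
#' \describe{
#'   \item{chrom}{chromosome name, `chr` prefix stripped}
#'   \item{pos}{1-based position (closed coordinates)}
#'   \item{ref, alt}{reference/alternate allele strings}
#'   \item{depth}{total read depth; `NA` when the caller omitted it}
#'   \item{alt_depth}{alternate-supporting reads}
#'   \item{vaf}{variant allelic fraction in \[0, 1\]}
#'   \item{quality_score}{caller quality (opaque, per-call)}
#'   \item{gene, consequence, hgvs_c, hgvs_p}{annotations (may be empty)}
#'   \item{population_af}{minor allele frequency in the reference
#'     population, `NA` when unknown}
#'   \item{cosmic_id}{somatic-catalog identifier or empty}
#'   \item{zygosity}{`het`, `hom` or `unknown`}
#' }
#'
#' @param df A data frame with (a subset of) the columns above; missing
#'   annotation columns are filled with defaults.
#' @param sample_role `"tumor"` or `"normal"`, stored as an attribute.
#' @return A `variant_calls` data frame.
#' @export
variant_calls <- function(df = NULL, sample_role = NA_character_) {
  template <- data.frame(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    depth = integer(), alt_depth = integer(), vaf = numeric(),
    quality_score = numeric(), gene = character(), consequence = character(),
    hgvs_c = character(), hgvs_p = character(), population_af = numeric(),
    cosmic_id = character(), zygosity = character(),
    stringsAsFactors = FALSE)
  if (is.null(df) || nrow(df) == 0) {
    out <- template
  } else {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    defaults <- list(depth = NA_integer_, alt_depth = NA_integer_,
                     vaf = NA_real_, quality_score = NA_real_, gene = "",
                     consequence = "other", hgvs_c = "", hgvs_p = "",
                     population_af = NA_real_, cosmic_id = "",
                     zygosity = "unknown")
    for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
    missing_core <- setdiff(c("chrom", "pos", "ref", "alt"), names(df))
    if (length(missing_core))
      stop("variant_calls(): missing columns: ", paste(missing_core, collapse = ", "))
    out <- df[, names(template)]
    out$chrom <- as.character(out$chrom)
    out$pos <- as.integer(out$pos)
  }
  validate_variant_calls(out)
  structure(out, class = c("variant_calls", "data.frame"),
            sample_role = sample_role)
}

validate_variant_calls <- function(vc) {
  if (nrow(vc) == 0) return(invisible(vc))
  if (any(vc$pos < 1)) stop("positions must be >= 1")
  bad_vaf <- !is.na(vc$vaf) & (vc$vaf < 0 | vc$vaf > 1)
  if (any(bad_vaf)) stop("vaf out of [0, 1]")
  ok <- !is.na(vc$depth) & !is.na(vc$alt_depth)
  if (any(ok & vc$alt_depth > vc$depth)) stop("alt_depth exceeds depth")
  bad_af <- !is.na(vc$population_af) & (vc$population_af < 0 | vc$population_af > 1)
  if (any(bad_af)) stop("population_af out of [0, 1]")
  invisible(vc)
}

#' Key that identifies a variant for exact matching
#'
#' @param vc A `variant_calls` data frame (normalized).
#' @return Character vector `chrom:pos:ref:alt`, one element per call.
#' @export
variant_key <- function(vc) {
  if (nrow(vc) == 0) return(character())
  paste(vc$chrom, vc$pos, vc$ref, vc$alt, sep = ":")
}

#' Normalize variant calls
#'
#' Strips any `chr` prefix from chromosome names, trims the shared
#' suffix/prefix of ref/alt alleles (adjusting the position for prefix
#' trimming), fills the VAF from allele depths where the caller omitted
#' it, and sorts by (chrom, pos, ref, alt). Caller-reported VAF wins over
#' the depth ratio; a discrepancy above `vaf_tol` triggers a warning.
#' Normalization is idempotent.
#'
#' @param vc A `variant_calls` data frame.
#' @param vaf_tol Tolerated absolute difference between the reported VAF
#'   and `alt_depth/depth` before warning (default 0.01).
#' @return A normalized `variant_calls` data frame.
#' @export
normalize_variant_calls <- function(vc, vaf_tol = 0.01) {
  role <- attr(vc, "sample_role")
  vc <- as.data.frame(vc, stringsAsFactors = FALSE)
  if (nrow(vc) > 0) {
    vc$chrom <- sub("^chr", "", as.character(vc$chrom))
    trimmed <- trim_alleles(vc$pos, vc$ref, vc$alt)
    vc$pos <- trimmed$pos; vc$ref <- trimmed$ref; vc$alt <- trimmed$alt
    if (any(vc$ref == vc$alt))
      stop("ref equals alt after normalization at ",
           paste(variant_key(vc)[vc$ref == vc$alt], collapse = ", "))
    ratio <- ifelse(!is.na(vc$depth) & vc$depth > 0 & !is.na(vc$alt_depth),
                    vc$alt_depth / vc$depth, NA_real_)
    fill <- is.na(vc$vaf) & !is.na(ratio)
    vc$vaf[fill] <- ratio[fill]
    disc <- !is.na(vc$vaf) & !is.na(ratio) & abs(vc$vaf - ratio) > vaf_tol
    if (any(disc))
      warning(sum(disc), " call(s) with VAF differing from alt_depth/depth by > ",
              vaf_tol, "; caller VAF retained")
    vc <- vc[order(vc$chrom, vc$pos, vc$ref, vc$alt), , drop = FALSE]
    rownames(vc) <- NULL
  }
  variant_calls(vc, sample_role = role)
}

trim_alleles <- function(pos, ref, alt) {
  n <- length(pos)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    # shared suffix
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1, nchar(r) - 1); a <- substr(a, 1, nchar(a) - 1)
    }
    # shared prefix
    while (nchar(r) > 1 && nchar(a) > 1 && substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r)); a <- substr(a, 2, nchar(a)); p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2) x[2] else "", character(1))
}

#' Read a variant-call file (VCF)
#'
#' Parses a VCF (v4.x) with per-sample depth (`DP`) and allele-depth
#' (`AD`) fields into a normalized [variant_calls()] table: multi-allelic
#' records are split into one call per alternate allele, alleles are
#' trimmed, the VAF is taken from the per-sample `VF` field when present
#' and computed from allele depths otherwise. Annotations are read from
#' the INFO fields `GENE`, `CSQ`, `HGVSC`, `HGVSP`, `POPAF` and `COSMIC`.
#'
#' @param path Path to a VCF file.
#' @param sample_role `"tumor"` or `"normal"`.
#' @param sample Sample column to use (default: the first).
#' @return A normalized `variant_calls` data frame, sorted by
#'   (chrom, pos, ref, alt).
#' @export
read_variant_file <- function(path, sample_role = c("tumor", "normal"),
                              sample = NULL) {
  sample_role <- match.arg(sample_role)
  if (!file.exists(path)) stop("no such file: ", path)
  check_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(variant_calls(sample_role = sample_role))
  gt <- v@gt
  has_sample <- !is.null(gt) && ncol(gt) >= 2
  if (has_sample) {
    scol <- if (is.null(sample)) 2L else {
      idx <- match(sample, colnames(gt))
      if (is.na(idx)) stop("sample not found: ", sample)
      idx
    }
    fmt <- strsplit(gt[, 1], ":", fixed = TRUE)
    val <- strsplit(gt[, scol], ":", fixed = TRUE)
    getf <- function(i, key) {
      j <- match(key, fmt[[i]])
      if (is.na(j) || j > length(val[[i]])) NA_character_ else val[[i]][j]
    }
  }
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    info <- fix$INFO[i] %||% ""
    dp <- NA_integer_; ad <- rep(NA_integer_, length(alts))
    vf <- rep(NA_real_, length(alts)); zyg <- "unknown"
    if (has_sample) {
      dp_s <- getf(i, "DP")
      if (!is.na(dp_s) && dp_s != ".") dp <- as.integer(dp_s)
      ad_s <- getf(i, "AD")
      if (!is.na(ad_s) && ad_s != ".") {
        parts <- as.integer(strsplit(ad_s, ",", fixed = TRUE)[[1]])
        if (length(parts) >= length(alts) + 1) ad <- parts[-1][seq_along(alts)]
      }
      vf_s <- getf(i, "VF")
      if (!is.na(vf_s) && vf_s != ".") {
        parts <- chr_num(strsplit(vf_s, ",", fixed = TRUE)[[1]])
        if (length(parts) >= length(alts)) vf <- parts[seq_along(alts)]
      }
      gt_s <- getf(i, "GT")
      if (!is.na(gt_s)) {
        al <- strsplit(gsub("\\|", "/", gt_s), "/", fixed = FALSE)[[1]]
        al <- al[al != "."]
        if (length(al) >= 2) zyg <- if (al[1] == al[2]) "hom" else "het"
      }
    }
    if (is.na(dp)) {
      dp_info <- info_field(info, "DP")
      if (nzchar(dp_info)) dp <- as.integer(dp_info)
    }
    split_info <- function(key, default = "") {
      x <- info_field(info, key)
      if (!nzchar(x)) return(rep(default, length(alts)))
      parts <- strsplit(x, ",", fixed = TRUE)[[1]]
      if (length(parts) == length(alts)) parts else rep(parts[1], length(alts))
    }
    popaf <- chr_num(split_info("POPAF", "."))
    rows[[i]] <- data.frame(
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      ref = fix$REF[i], alt = alts,
      depth = dp, alt_depth = ad, vaf = vf,
      quality_score = chr_num(fix$QUAL[i]),
      gene = split_info("GENE"), consequence = split_info("CSQ", "other"),
      hgvs_c = split_info("HGVSC"), hgvs_p = split_info("HGVSP"),
      population_af = popaf, cosmic_id = split_info("COSMIC"),
      zygosity = zyg, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (any(is.na(out$depth)))
    warning(sum(is.na(out$depth)), " call(s) with missing depth retained")
  normalize_variant_calls(variant_calls(out, sample_role = sample_role))
}

check_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#"))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8)
      stop("malformed VCF record at line ", i, ": expected >= 8 fields")
    if (is.na(suppressWarnings(as.integer(f[2]))))
      stop("malformed VCF record at line ", i, ": non-numeric POS")
  }
  invisible(TRUE)
}

#' Write variant calls as VCF
#'
#' Emits a VCF v4.2 text file carrying all `variant_calls` columns
#' (annotations in INFO, depths and exact VAF in the sample column) so
#' that [read_variant_file()] reproduces the table exactly.
#'
#' @param vc A `variant_calls` data frame.
#' @param path Output path.
#' @param sample_name Sample column header (default from the
#'   `sample_role` attribute).
#' @return `path`, invisibly.
#' @export
write_variant_file <- function(vc, path, sample_name = NULL) {
  role <- attr(vc, "sample_role")
  if (is.null(sample_name))
    sample_name <- if (!is.na(role %||% NA)) toupper(role) else "SAMPLE"
  header <- c(
    "##fileformat=VCFv4.2",
    "##reference=GRCh37",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=HGVSC,Number=1,Type=String,Description=\"Coding change\">",
    "##INFO=<ID=HGVSP,Number=1,Type=String,Description=\"Protein change\">",
    "##INFO=<ID=POPAF,Number=1,Type=Float,Description=\"Population minor allele frequency\">",
    "##INFO=<ID=COSMIC,Number=1,Type=String,Description=\"Somatic catalog id\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=VF,Number=A,Type=Float,Description=\"Variant allelic fraction\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
  body <- character(nrow(vc))
  esc <- function(x) gsub("[;=\t]", "_", x)
  for (i in seq_len(nrow(vc))) {
    info <- c(
      if (nzchar(vc$gene[i])) paste0("GENE=", esc(vc$gene[i])),
      paste0("CSQ=", esc(vc$consequence[i])),
      if (nzchar(vc$hgvs_c[i])) paste0("HGVSC=", esc(vc$hgvs_c[i])),
      if (nzchar(vc$hgvs_p[i])) paste0("HGVSP=", esc(vc$hgvs_p[i])),
      if (!is.na(vc$population_af[i])) paste0("POPAF=", num_chr(vc$population_af[i])),
      if (nzchar(vc$cosmic_id[i])) paste0("COSMIC=", esc(vc$cosmic_id[i])))
    info <- if (length(info)) paste(info, collapse = ";") else "."
    gt <- switch(vc$zygosity[i], het = "0/1", hom = "1/1", "./.")
    ad <- if (is.na(vc$depth[i]) || is.na(vc$alt_depth[i])) "." else
      paste(vc$depth[i] - vc$alt_depth[i], vc$alt_depth[i], sep = ",")
    smp <- paste(gt,
                 if (is.na(vc$depth[i])) "." else vc$depth[i],
                 ad, num_chr(vc$vaf[i]), sep = ":")
    body[i] <- paste(vc$chrom[i], vc$pos[i], ".", vc$ref[i], vc$alt[i],
                     num_chr(vc$quality_score[i]), "PASS", info,
                     "GT:DP:AD:VF", smp, sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}
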