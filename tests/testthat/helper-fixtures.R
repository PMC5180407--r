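# Shared builders for tests: compact call constructors, a miniature
# knowledge base, and random-call generators used by the oracle checks.

make_calls <- function(..., sample_role = "tumor") {
  df <- data.frame(..., stringsAsFactors = FALSE)
  variant_calls(df, sample_role = sample_role)
}

one_call <- function(chrom = "1", pos = 100L, ref = "A", alt = "T",
                     depth = 100L, alt_depth = 50L, vaf = NA_real_,
                     quality_score = 40, gene = "", consequence = "missense",
                     hgvs_c = "", hgvs_p = "", population_af = NA_real_,
                     cosmic_id = "", zygosity = "het",
                     sample_role = "tumor") {
  vc <- make_calls(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   depth = depth, alt_depth = alt_depth, vaf = vaf,
                   quality_score = quality_score, gene = gene,
                   consequence = consequence, hgvs_c = hgvs_c,
                   hgvs_p = hgvs_p, population_af = population_af,
                   cosmic_id = cosmic_id, zygosity = zygosity,
                   sample_role = sample_role)
  normalize_variant_calls(vc)
}

mini_kb <- function(...) {
  knowledge_base(
    reference_range_genes = c("BRCA1", "TP53", "UGT1A1", "APC"),
    acmg_genes = c("TP53", "BRCA1", "RYR1"),
    cosmic_ids = c("COSM100", "COSM200"),
    cancer_genes = c("TP53", "NRAS", "KRAS", "SDHC", "DICER1", "APC", "ITK"),
    hotspots = data.frame(gene = c("NRAS", "KRAS"),
                          hgvs_p = c("p.Q61K", "p.G12C"),
                          stringsAsFactors = FALSE),
    known_fusions = data.frame(gene5 = c("BCR", "EWSR1"),
                               gene3 = c("ABL1", "FLI1"),
                               diagnostic = c("CML", "Ewing sarcoma"),
                               prognostic = c("TRUE", ""),
                               targetable = c("TKI", ""),
                               stringsAsFactors = FALSE),
    drug_targets = data.frame(
      gene = c("NRAS", "ABL1"), drug = c("trametinib", "dasatinib"),
      approval_status = c("approved", "approved"),
      pediatric_dosing = c("yes", "yes"),
      evidence_class = c("preclinical", "clinical"),
      tumor_types = c("Neuroblastoma;AML", "CML"),
      pathway = c("MAPK", "ABL kinase"), stringsAsFactors = FALSE),
    housekeeping_genes = c("ACTB", "GAPDH"),
    patient_care_variants = data.frame(gene = "UGT1A1", hgvs_c = "*28",
                                       label = "irinotecan sensitivity",
                                       stringsAsFactors = FALSE),
    enabled_filters = c("reference_range", "reportable_range", "frequency"),
    ...)
}

# Random normalized calls with annotations drawn so that every germline
# filter layer fires on a controllable fraction of them.
random_annotated_calls <- function(n, seed, kb,
                                   sample_role = "normal") {
  set.seed(seed)
  genes <- c(kb$reference_range_genes, kb$acmg_genes, kb$cancer_genes,
             sprintf("OFF%03d", 1:20))
  cosmic_pool <- c(kb$cosmic_ids, sprintf("COSMX%04d", 1:20), "")
  depth <- pmax(10L, stats::rpois(n, 80))
  alt <- pmax(1L, stats::rbinom(n, depth, 0.5))
  make_calls(
    chrom = sample(c("1", "2"), n, TRUE),
    pos = sample.int(5e6, n),
    ref = sample(c("A", "C", "G", "T"), n, TRUE),
    alt = "N",
    depth = depth, alt_depth = alt, vaf = alt / depth,
    quality_score = round(stats::runif(n, 10, 60), 1),
    gene = sample(genes, n, TRUE),
    consequence = sample(c("missense", "nonsense", "frameshift",
                           "splice_site", "synonymous"), n, TRUE),
    hgvs_c = "", hgvs_p = "",
    population_af = ifelse(stats::runif(n) < 0.3, NA_real_,
                           stats::runif(n, 0, 0.05)),
    cosmic_id = sample(cosmic_pool, n, TRUE),
    zygosity = sample(c("het", "hom"), n, TRUE),
    sample_role = sample_role)
}

# Independent brute-force subtraction oracle: per-call re-evaluation and
# exhaustive key comparison, sharing no code with subtract_somatic().
oracle_subtract_keys <- function(tumor, normal, cfg = subtraction_config()) {
  elig <- function(vc, min_vaf) {
    keep <- character()
    for (i in seq_len(nrow(vc))) {
      if (!is.na(vc$depth[i]) && !is.na(vc$alt_depth[i]) &&
          !is.na(vc$vaf[i]) &&
          vc$depth[i] >= cfg$min_depth && vc$alt_depth[i] >= cfg$min_alt_reads &&
          vc$vaf[i] >= min_vaf)
        keep <- c(keep, paste(vc$chrom[i], vc$pos[i], vc$ref[i], vc$alt[i],
                              sep = ":"))
    }
    unique(keep)
  }
  t_keys <- elig(tumor, cfg$tumor_min_vaf)
  n_keys <- elig(normal, cfg$normal_min_vaf)
  sort(t_keys[!vapply(t_keys, function(k) any(n_keys == k), logical(1))])
}
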