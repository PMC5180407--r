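#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults emulate the
#' assay conditions the pipeline is designed for: ~150X mean exome
#' coverage, tumor purity 0.8, germline heterozygous/homozygous calls,
#' somatic VAFs that respect the 10% tumor output threshold after purity
#' scaling, a two-chromosome synthetic exome target map, and a
#' 124-sample panel of normal transcriptomes.
#'
#' @param seed Integer seed; the same seed yields identical outputs.
#' @param n_germline,n_somatic Numbers of planted germline/somatic
#'   variants.
#' @param somatic_vaf_range Interval of planted somatic cellular VAFs
#'   before purity scaling (default c(0.15, 0.5)).
#' @param germline_hom_weight Probability that a planted germline
#'   variant is homozygous (VAF 1.0) rather than heterozygous (0.5).
#' @param coverage_mean Mean read depth (default 150).
#' @param tumor_purity Tumor cell fraction (default 0.8).
#' @param contam_fraction Fraction of somatic variants given
#'   sub-threshold normal-sample evidence (default 0.2).
#' @param vaf_noise `"rounded"` plants `alt_depth = round(depth * vaf)`
#'   so realized VAFs respect the planted values; `"binomial"` draws
#'   alt_depth binomially.
#' @param n_bins,bin_size B-allele/log2 track geometry (default 100 bins
#'   of 1 Mb on one synthetic chromosome).
#' @param n_sites Heterozygous sites on the track (default 2000).
#' @param site_depth Read depth at allelic sites (default 100).
#' @param loh_bins Integer bin indices carrying planted copy-neutral
#'   LOH (default bins 31-70, 40% of the chromosome).
#' @param loss_bins Integer bin indices carrying a planted copy-number
#'   loss (default none).
#' @param loss_log2 Planted log2 ratio in loss bins (default -0.5).
#' @param log2_noise SD of Gaussian bin-level log2 noise (default 0.05).
#' @param n_genes,n_housekeeping Expression-panel gene counts (defaults
#'   1000 + 100 housekeeping).
#' @param panel_size Number of normal transcriptomes (default 124).
#' @param panel_sdlog Biological log-scale spread across the panel
#'   (default 0.4).
#' @param case_sdlog Technical log-scale noise of the case sample
#'   (default 0.05); the case's unperturbed genes track the panel
#'   consensus.
#' @param outlier_genes Named numeric vector of planted fold-changes
#'   (default one 20-fold over-expressed gene).
#' @param expression_noise FALSE generates the noiseless variant (panel
#'   profiles exactly at the gene means).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_germline = 300, n_somatic = 30,
                              somatic_vaf_range = c(0.15, 0.5),
                              germline_hom_weight = 0.3,
                              coverage_mean = 150, tumor_purity = 0.8,
                              contam_fraction = 0.2,
                              vaf_noise = c("rounded", "binomial"),
                              n_bins = 100, bin_size = 1e6, n_sites = 2000,
                              site_depth = 100,
                              loh_bins = 31:70, loss_bins = integer(),
                              loss_log2 = -0.5, log2_noise = 0.05,
                              n_genes = 1000, n_housekeeping = 100,
                              panel_size = 124, panel_sdlog = 0.4,
                              case_sdlog = 0.05,
                              outlier_genes = c(G0001 = 20),
                              expression_noise = TRUE) {
  stopifnot(n_germline >= 0, n_somatic >= 0,
            somatic_vaf_range[1] > 0, somatic_vaf_range[2] < 1,
            somatic_vaf_range[1] <= somatic_vaf_range[2],
            tumor_purity > 0, tumor_purity <= 1,
            panel_size >= 2, n_genes >= n_housekeeping)
  if (any(outlier_genes <= 0)) stop("fold-changes must be positive")
  structure(list(seed = as.integer(seed), n_germline = n_germline,
                 n_somatic = n_somatic, somatic_vaf_range = somatic_vaf_range,
                 germline_hom_weight = germline_hom_weight,
                 coverage_mean = coverage_mean, tumor_purity = tumor_purity,
                 contam_fraction = contam_fraction,
                 vaf_noise = match.arg(vaf_noise),
                 n_bins = n_bins, bin_size = bin_size, n_sites = n_sites,
                 site_depth = site_depth, loh_bins = loh_bins,
                 loss_bins = loss_bins, loss_log2 = loss_log2,
                 log2_noise = log2_noise, n_genes = n_genes,
                 n_housekeeping = n_housekeeping, panel_size = panel_size,
                 panel_sdlog = panel_sdlog, case_sdlog = case_sdlog,
                 outlier_genes = outlier_genes,
                 expression_noise = expression_noise),
            class = "simulation_config")
}

#' Synthetic exome target map
#'
#' @return Data frame of the bundled two-chromosome, 1000-target
#'   synthetic exome map (chrom, start, end, target_id, gene).
#' @export
synthetic_targets <- function() {
  read_tsv_file(system.file("extdata", "synthetic_targets.tsv",
                            package = "oncoreport"))
}

BASES <- c("A", "C", "G", "T")

#' Simulate a paired tumor/normal call set with planted truth
#'
#' Germline variants (VAF 0.5 or 1.0) appear in both samples; somatic
#' variants appear only in the tumor at cellular VAFs drawn from
#' `somatic_vaf_range` scaled by tumor purity. Positions are drawn
#' without replacement from the synthetic exome target map, so planted
#' somatic and germline keys are disjoint by construction. A fraction
#' of somatic variants carries sub-threshold normal evidence. Output is
#' deterministic per seed.
#'
#' @param cfg A [simulation_config()].
#' @return A list: `tumor` and `normal` (`variant_calls`), and `truth`
#'   (somatic_keys, germline_keys, expected_counts).
#' @export
simulate_paired_calls <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  tmap <- synthetic_targets()
  n_total <- cfg$n_germline + cfg$n_somatic
  if (n_total > nrow(tmap))
    stop("more variants requested than targets available")
  idx <- sample.int(nrow(tmap), n_total)
  pos <- tmap$start[idx] + sample.int(150, n_total, replace = TRUE) - 1L
  ref <- sample(BASES, n_total, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1))
  gene <- tmap$gene[idx]
  chrom <- as.character(tmap$chrom[idx])
  consequence <- sample(c("missense", "synonymous", "nonsense", "frameshift",
                          "splice_site", "inframe_indel", "other"),
                        n_total, replace = TRUE,
                        prob = c(0.5, 0.2, 0.08, 0.08, 0.06, 0.04, 0.04))
  depth_of <- function(n) pmax(30L, stats::rpois(n, cfg$coverage_mean))
  plant <- function(depth, vaf) {
    alt_d <- if (cfg$vaf_noise == "rounded") pmin(depth, round(depth * vaf))
             else stats::rbinom(length(depth), depth, vaf)
    list(depth = as.integer(depth), alt = as.integer(alt_d),
         vaf = alt_d / depth)
  }
  is_som <- c(rep(FALSE, cfg$n_germline), rep(TRUE, cfg$n_somatic))
  g_hom <- stats::runif(cfg$n_germline) < cfg$germline_hom_weight
  g_vaf <- ifelse(g_hom, 1.0, 0.5)
  s_vaf <- stats::runif(cfg$n_somatic, cfg$somatic_vaf_range[1],
                        cfg$somatic_vaf_range[2]) * cfg$tumor_purity
  contam <- stats::runif(cfg$n_somatic) < cfg$contam_fraction

  base_cols <- function(i) data.frame(
    chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alt[i],
    gene = gene[i], consequence = consequence[i],
    quality_score = round(stats::runif(length(i), 20, 60), 1),
    stringsAsFactors = FALSE)

  # normal sample: all germline + contaminating somatic evidence
  gi <- which(!is_som); si <- which(is_som)
  n_g <- plant(depth_of(cfg$n_germline), g_vaf)
  normal <- base_cols(gi)
  normal$depth <- n_g$depth; normal$alt_depth <- n_g$alt; normal$vaf <- n_g$vaf
  normal$zygosity <- ifelse(g_hom, "hom", "het")
  if (any(contam)) {
    ci <- si[contam]
    n_c <- plant(depth_of(length(ci)), 0.02)
    cn <- base_cols(ci)
    cn$depth <- n_c$depth; cn$alt_depth <- n_c$alt; cn$vaf <- n_c$vaf
    cn$zygosity <- rep("het", nrow(cn))
    normal <- rbind(normal, cn)
  }
  # tumor sample: germline (redrawn depths) + somatic
  t_g <- plant(depth_of(cfg$n_germline), g_vaf)
  tumor_g <- base_cols(gi)
  tumor_g$depth <- t_g$depth; tumor_g$alt_depth <- t_g$alt; tumor_g$vaf <- t_g$vaf
  tumor_g$zygosity <- ifelse(g_hom, "hom", "het")
  t_s <- plant(depth_of(cfg$n_somatic), s_vaf)
  tumor_s <- base_cols(si)
  tumor_s$depth <- t_s$depth; tumor_s$alt_depth <- t_s$alt; tumor_s$vaf <- t_s$vaf
  tumor_s$zygosity <- rep("het", nrow(tumor_s))
  tumor <- rbind(tumor_g, tumor_s)

  tumor <- normalize_variant_calls(variant_calls(tumor, sample_role = "tumor"))
  normal <- normalize_variant_calls(variant_calls(normal, sample_role = "normal"))
  key_of <- function(i) paste(chrom[i], pos[i], ref[i], alt[i], sep = ":")
  scfg <- subtraction_config()
  truth <- list(
    somatic_keys = sort(key_of(si)),
    germline_keys = sort(key_of(gi)),
    expected_counts = list(
      n_tumor_calls = nrow(tumor), n_normal_calls = nrow(normal),
      n_tumor_eligible = sum(call_eligible(tumor, "tumor", scfg)),
      n_normal_eligible = sum(call_eligible(normal, "normal", scfg)),
      n_somatic = cfg$n_somatic))
  list(tumor = tumor, normal = normal, truth = truth)
}

bin_table <- function(cfg) {
  start <- (seq_len(cfg$n_bins) - 1) * cfg$bin_size + 1
  data.frame(chrom = "1", start = start, end = start + cfg$bin_size - 1,
             stringsAsFactors = FALSE)
}

bins_to_interval <- function(bins_df, which_bins) {
  if (length(which_bins) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  r <- range(which_bins)
  data.frame(chrom = "1", start = bins_df$start[r[1]], end = bins_df$end[r[2]],
             stringsAsFactors = FALSE)
}

#' Simulate a B-allele-fraction track with planted LOH and losses
#'
#' Heterozygous sites get normal VAFs ~ N(0.5, 0.02) truncated to
#' \[0.45, 0.55\]. Inside planted LOH bins the tumor VAF shifts to
#' `0.5 +/- purity/2` (allele chosen at random per site) with binomial
#' read sampling at `site_depth`; elsewhere it stays centered at the
#' normal VAF. Bin-level log2 ratios are 0 plus Gaussian noise, with
#' `loss_log2` added in planted loss bins; copy-neutral LOH bins keep
#' log2 at 0. Planted truth intervals lie on the bin grid.
#'
#' @param cfg A [simulation_config()].
#' @return A list: `sites` ([allelic_sites()]), `bins` (per-bin
#'   [segment_calls()]), `truth` (loh_intervals, loss_intervals).
#' @export
simulate_ballele_track <- function(cfg = simulation_config()) {
  set.seed(cfg$seed + 1L)
  bins <- bin_table(cfg)
  chrom_len <- cfg$n_bins * cfg$bin_size
  pos <- sort(sample.int(chrom_len, cfg$n_sites))
  bin_of <- pmin(cfg$n_bins, (pos - 1) %/% cfg$bin_size + 1)
  nv <- stats::rnorm(cfg$n_sites, 0.5, 0.02)
  nv <- pmin(0.55, pmax(0.45, nv))
  in_loh <- bin_of %in% cfg$loh_bins
  hi_allele <- stats::runif(cfg$n_sites) < 0.5
  p_tumor <- ifelse(in_loh,
                    0.5 + ifelse(hi_allele, 1, -1) * cfg$tumor_purity / 2,
                    nv)
  tv <- stats::rbinom(cfg$n_sites, cfg$site_depth, p_tumor) / cfg$site_depth
  sites <- allelic_sites(data.frame(chrom = "1", pos = pos, normal_vaf = nv,
                                    tumor_vaf = tv, stringsAsFactors = FALSE))
  log2 <- stats::rnorm(cfg$n_bins, 0, cfg$log2_noise)
  log2[cfg$loss_bins] <- log2[cfg$loss_bins] + cfg$loss_log2
  bins$log2_ratio <- log2
  truth <- list(loh_intervals = bins_to_interval(bins, cfg$loh_bins),
                loss_intervals = bins_to_interval(bins, cfg$loss_bins))
  list(sites = sites, bins = segment_calls(bins), truth = truth)
}

#' Simulate a panel of normal transcriptomes and a case profile
#'
#' Gene base abundances are log-normal; panel profiles scatter around
#' them with biological log-scale spread (`panel_sdlog`), housekeeping
#' genes with a tight spread so the housekeeping median is stable. The
#' case profile follows the gene base abundances with technical noise
#' (`case_sdlog`) and multiplies planted outlier genes by their
#' fold-changes. With `expression_noise = FALSE` the panel and case sit
#' exactly on the base abundances (noiseless variant).
#'
#' @param cfg A [simulation_config()].
#' @return A list: `panel` (list of [expression_profile()]), `case`
#'   (an [expression_profile()]), `housekeeping` (gene symbols), and
#'   `truth` (outlier_genes).
#' @export
simulate_expression_panel <- function(cfg = simulation_config()) {
  set.seed(cfg$seed + 2L)
  if (any(cfg$outlier_genes <= 0)) stop("fold-changes must be positive")
  n_reg <- cfg$n_genes - cfg$n_housekeeping
  genes <- sprintf("G%04d", seq_len(n_reg))
  hk <- sprintf("HK%03d", seq_len(cfg$n_housekeeping))
  base <- c(stats::rlnorm(n_reg, meanlog = 3, sdlog = 1.5),
            stats::rlnorm(cfg$n_housekeeping, meanlog = 5, sdlog = 0.5))
  names(base) <- c(genes, hk)
  unknown <- setdiff(names(cfg$outlier_genes), names(base))
  if (length(unknown) > 0) stop("outlier genes not simulated: ",
                                paste(unknown, collapse = ", "))
  jitter_prof <- function(sdlog_reg, sdlog_hk) {
    if (!cfg$expression_noise) return(base)
    f <- exp(c(stats::rnorm(n_reg, 0, sdlog_reg),
               stats::rnorm(cfg$n_housekeeping, 0, sdlog_hk)))
    base * f
  }
  panel <- lapply(seq_len(cfg$panel_size), function(i)
    expression_profile(sprintf("normal_%03d", i),
                       jitter_prof(cfg$panel_sdlog, 0.05), hk))
  case_fpkm <- jitter_prof(cfg$case_sdlog, 0.02)
  fold <- setNames(rep(1, cfg$n_genes), names(base))
  fold[names(cfg$outlier_genes)] <- cfg$outlier_genes
  case <- expression_profile("case", case_fpkm * fold, hk)
  list(panel = panel, case = case, housekeeping = hk,
       truth = list(outlier_genes = cfg$outlier_genes))
}
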