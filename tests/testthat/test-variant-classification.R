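test_that("loss-of-function consequences are disruptive", {
  nonsense <- one_call(gene = "KMT2C", consequence = "nonsense",
                       hgvs_p = "p.E704X")
  fs <- one_call(gene = "ATRX", consequence = "frameshift",
                 hgvs_p = "p.T1747fs", pos = 200L)
  mis <- one_call(gene = "TP53", consequence = "missense", pos = 300L)
  cl <- classify_variants(rbind(as.data.frame(nonsense), as.data.frame(fs),
                                as.data.frame(mis)) |> variant_calls())
  expect_equal(cl$disruptive, c(TRUE, TRUE, FALSE))
})

test_that("two distinct het calls in one gene are compound heterozygous", {
  df <- rbind(
    as.data.frame(one_call(gene = "MLL2", pos = 100L, hgvs_c = "c.11640delG",
                           consequence = "frameshift")),
    as.data.frame(one_call(gene = "MLL2", pos = 900L, hgvs_c = "c.15631G>A",
                           consequence = "missense")),
    as.data.frame(one_call(gene = "OTHER", pos = 500L)))
  cl <- classify_variants(variant_calls(df))
  expect_equal(cl$compound_het[cl$gene == "MLL2"], c(TRUE, TRUE))
  expect_false(any(cl$compound_het[cl$gene == "OTHER"]))
  # a single gene with only hom calls never qualifies
  hom <- one_call(gene = "MLL2", zygosity = "hom")
  expect_false(classify_variants(hom)$compound_het)
})

test_that("homozygosity comes from caller zygosity or a high-VAF rule", {
  hom <- one_call(zygosity = "hom")
  cl <- classify_variants(hom)
  expect_true(cl$homozygous)
  expect_false(cl$reduced_to_hom)
  high_vaf <- one_call(depth = 100L, alt_depth = 95L, zygosity = "het")
  cl2 <- classify_variants(high_vaf)
  expect_true(cl2$homozygous)
  expect_true(cl2$reduced_to_hom)
  low_depth <- one_call(depth = 20L, alt_depth = 19L, zygosity = "het")
  expect_false(classify_variants(low_depth)$homozygous)
})

test_that("classification is independent of input order", {
  kb <- mini_kb()
  calls <- random_annotated_calls(100, 31, kb, sample_role = "tumor")
  cl1 <- classify_variants(calls)
  perm <- sample(nrow(calls))
  cl2 <- classify_variants(variant_calls(as.data.frame(calls)[perm, ],
                                         sample_role = "tumor"))
  expect_equal(cl2[order(cl2$key), ], cl1[order(cl1$key), ],
               ignore_attr = TRUE)
})

test_that("mutational-load filter applies the coverage and quality-or-VAF rule", {
  cfg <- load_filter_config()
  boundary <- suppressWarnings(one_call(depth = 30L, alt_depth = 8L,
                                        vaf = 0.25, quality_score = 19))
  expect_true(load_filter(boundary, cfg))
  expect_false(load_filter(one_call(depth = 29L, alt_depth = 26L,
                                    quality_score = 99), cfg))
  expect_true(load_filter(one_call(depth = 30L, alt_depth = 3L,
                                   quality_score = 20), cfg))
  expect_warning(
    res <- load_filter(one_call(depth = 50L, alt_depth = NA_integer_,
                                vaf = NA_real_, quality_score = NA_real_), cfg),
    "missing both")
  expect_false(res)
  # brute-force re-evaluation on random calls
  kb <- mini_kb()
  calls <- random_annotated_calls(500, 13, kb, sample_role = "tumor")
  got <- load_filter(calls, cfg)
  oracle <- vapply(seq_len(nrow(calls)), function(i)
    !is.na(calls$depth[i]) && calls$depth[i] >= 30 &&
      ((!is.na(calls$quality_score[i]) && calls$quality_score[i] >= 20) ||
         (!is.na(calls$vaf[i]) && calls$vaf[i] >= 0.25)), logical(1))
  expect_equal(got, oracle)
})

test_that("load filter is monotone in depth, quality and VAF", {
  base <- suppressWarnings(
    one_call(depth = 30L, alt_depth = 8L, vaf = 0.25, quality_score = 20))
  expect_true(load_filter(base))
  for (delta in list(c(10, 0, 0), c(0, 10, 0), c(0, 0, 0.2))) {
    up <- suppressWarnings(
      one_call(depth = base$depth + as.integer(delta[1]),
               alt_depth = base$alt_depth,
               vaf = min(1, base$vaf + delta[3]),
               quality_score = base$quality_score + delta[2]))
    expect_true(load_filter(up))
  }
})

test_that("cohort load statistics match an independent computation", {
  expect_error(cohort_load_stats(numeric()), "no counts")
  s <- cohort_load_stats(c(10, 20, 30))
  expect_equal(s$overall$mean, 20)
  expect_equal(s$overall$median, 20)
  expect_equal(c(s$overall$min, s$overall$max), c(10, 30))
  s1 <- cohort_load_stats(5)
  expect_equal(s1$overall$sd, 0)
  expect_true(s1$overall$sd_degenerate)
  # second implementation from first principles
  set.seed(8)
  x <- rpois(100, 60)
  grp <- rep(c("solid", "hematologic"), 50)
  s2 <- cohort_load_stats(x, grp)
  man_mean <- sum(x) / length(x)
  man_sd <- sqrt(sum((x - man_mean)^2) / (length(x) - 1))
  xs <- sort(x)
  man_median <- (xs[50] + xs[51]) / 2
  expect_equal(s2$overall$mean, man_mean)
  expect_equal(s2$overall$sd, man_sd)
  expect_equal(s2$overall$median, man_median)
  xh <- x[grp == "hematologic"]
  expect_equal(s2$by_group$hematologic$mean, sum(xh) / length(xh))
})
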