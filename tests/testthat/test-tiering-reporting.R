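kb_full <- load_knowledge_base()

test_that("targetability needs a drug (or preclinical evidence) plus pediatric dosing", {
  kit <- is_targetable("KIT", kb_full)
  expect_true(kit$targetable)
  expect_true(kit$criteria[["pediatric_dosing"]])
  # catalog entry without dosing information fails criterion 3
  nodose <- is_targetable("ERBB2", kb_full)
  expect_false(nodose$targetable)
  expect_true(nodose$criteria[["drug_available"]])
  none <- is_targetable("ZZZ9", kb_full)
  expect_false(none$targetable)
  expect_equal(none$reason, "no catalog entry")
})

test_that("report tiers follow the ordered rules with tier 4 as catch-all", {
  hot <- tiered_finding("snv_indel", "NRAS", hgvs_p = "p.Q61K")
  expect_equal(assign_report_tier(hot, "Neuroblastoma", kb_full), 1L)
  # same alteration, tumor type without catalog evidence: not tier 1
  expect_equal(assign_report_tier(hot, "Melanoma", kb_full), 2L)
  # a catalog-known fusion in its disease context is tier 1
  fus <- tiered_finding("fusion", "ABL1", "BCR-ABL1 fusion",
                        known_driver = TRUE)
  expect_equal(assign_report_tier(fus, "CML", kb_full), 1L)
  # cancer gene, no drug, no hotspot
  cg <- tiered_finding("snv_indel", "CEBPA")
  expect_equal(assign_report_tier(cg, "AML", kb_full), 2L)
  # not a cancer gene, but a known somatic-catalog id
  cos <- tiered_finding("snv_indel", "ZZGENE", cosmic_id = "COSM476")
  expect_equal(assign_report_tier(cos, "AML", kb_full), 3L)
  vous <- tiered_finding("snv_indel", "ZZGENE")
  expect_equal(assign_report_tier(vous, "AML", kb_full), 4L)
})

test_that("report tiers match an independent rule re-evaluation on random findings", {
  set.seed(99)
  genes <- c(kb_full$cancer_genes, kb_full$drug_targets$gene,
             sprintf("RND%02d", 1:20))
  for (i in 1:200) {
    g <- sample(genes, 1)
    hp <- if (runif(1) < 0.3 && nrow(kb_full$hotspots) > 0)
      sample(kb_full$hotspots$hgvs_p, 1) else ""
    cid <- if (runif(1) < 0.3) sample(c(kb_full$cosmic_ids, "COSMXX"), 1) else ""
    ctx <- sample(c("AML", "Neuroblastoma", "Melanoma"), 1)
    f <- tiered_finding("snv_indel", g, hgvs_p = hp, cosmic_id = cid)
    got <- assign_report_tier(f, ctx, kb_full)
    # independent re-evaluation
    rows <- kb_full$drug_targets[kb_full$drug_targets$gene == g, , drop = FALSE]
    tg <- nrow(rows) > 0 && any(
      (rows$approval_status %in% c("approved", "experimental") |
         rows$evidence_class == "preclinical") &
        tolower(rows$pediatric_dosing) == "yes")
    hot <- nzchar(hp) && any(kb_full$hotspots$gene == g &
                               kb_full$hotspots$hgvs_p == hp)
    same <- nrow(rows) > 0 && any(vapply(
      strsplit(rows$tumor_types, ";"), function(tt)
        tolower(ctx) %in% tolower(trimws(tt)), logical(1)))
    want <- if (hot && tg && same) 1L
            else if (tg || g %in% kb_full$cancer_genes) 2L
            else if (nzchar(cid) && cid %in% kb_full$cosmic_ids) 3L else 4L
    expect_equal(got, want)
  }
})

test_that("actionability sub-tiers follow the evidence level and tumor-type match", {
  expect_equal(assign_actionability_tier(
    tiered_finding("fusion", "ABL1", "BCR-ABL1 fusion"), "CML", kb_full), 1L)
  expect_equal(assign_actionability_tier(
    tiered_finding("snv_indel", "SMARCA4", hgvs_p = "p.R1192C"),
    "Hepatic rhabdoid tumor", kb_full), 2L)
  expect_equal(assign_actionability_tier(
    tiered_finding("snv_indel", "NRAS", hgvs_p = "p.Q61K"),
    "Neuroblastoma", kb_full), 3L)
  expect_equal(assign_actionability_tier(
    tiered_finding("snv_indel", "ALK", hgvs_p = "p.Q1146K"),
    "Adrenocortical carcinoma", kb_full), 4L)
  expect_equal(assign_actionability_tier(
    tiered_finding("expression", "CUL4A", board_override = TRUE),
    "Osteosarcoma", kb_full), 5L)
  expect_error(assign_actionability_tier(
    tiered_finding("snv_indel", "NOGENE"), "AML", kb_full),
    "evidence required")
})

test_that("adding evidence rows can only keep or lower the actionability tier", {
  kb2 <- kb_full
  f <- tiered_finding("snv_indel", "ALK")
  t_before <- assign_actionability_tier(f, "Adrenocortical carcinoma", kb2)
  kb2$drug_targets <- rbind(kb2$drug_targets, data.frame(
    gene = "ALK", drug = "lorlatinib", approval_status = "approved",
    pediatric_dosing = "yes", evidence_class = "clinical",
    tumor_types = "Adrenocortical carcinoma", pathway = "ALK kinase"))
  expect_lte(assign_actionability_tier(f, "Adrenocortical carcinoma", kb2),
             t_before)
})

test_that("a VOUS is returned only when destructive, in a cancer gene, with a second hit", {
  kb <- mini_kb()
  vous <- one_call(gene = "SDHC", consequence = "nonsense")
  som_hit <- classify_variants(one_call(gene = "SDHC", pos = 999L),
                               somatic_keys = variant_key(one_call(gene = "SDHC",
                                                                   pos = 999L)))
  d1 <- vous_return_decision(vous, som_hit, kb)
  expect_true(d1$return)
  # non-destructive fails criterion 1
  mis <- one_call(gene = "SDHC", consequence = "missense")
  expect_false(vous_return_decision(mis, som_hit, kb)$return)
  # no second hit, but reduced to homozygosity in tumor
  no_hit <- classify_variants(variant_calls())
  expect_false(vous_return_decision(vous, no_hit, kb)$return)
  expect_true(vous_return_decision(vous, no_hit, kb, tumor_vaf = 0.95)$return)
  # gene outside the validated cancer-gene catalog fails criterion 2
  odd <- one_call(gene = "OFF001", consequence = "frameshift")
  expect_false(vous_return_decision(odd, som_hit, kb, tumor_vaf = 0.95)$return)
})

test_that("utility categories derive from labels and targetability", {
  nt5 <- tiered_finding("snv_indel", "NT5C2", labels = "pharmacogenomic")
  expect_true("other_impact" %in% categorize_utility(nt5, kb_full))
  pax <- tiered_finding("fusion", "FOXO1", "PAX7-FOXO1 fusion",
                        labels = c("diagnostic", "prognostic"))
  expect_setequal(categorize_utility(pax, kb_full),
                  c("diagnostic", "prognostic"))
  kitf <- tiered_finding("snv_indel", "KIT", hgvs_p = "p.Asn655Lys")
  expect_true("therapeutic_target" %in% categorize_utility(kitf, kb_full))
  blank <- tiered_finding("snv_indel", "ZZGENE")
  expect_equal(categorize_utility(blank, kb_full), character())
})

demo_report <- function(optin = TRUE) {
  pat <- sample_meta("14-85546", "tumor", disease_group = "hematologic",
                     diagnosis = "CML", assay = "cWES")
  f1 <- tiered_finding("fusion", "ABL1", "BCR-ABL1 fusion",
                       labels = "diagnostic")
  f1$report_tier <- 1L
  f1$actionability_tier <- assign_actionability_tier(f1, "CML", kb_full)
  f1$utility <- categorize_utility(f1, kb_full)
  f2 <- tiered_finding("germline", "BRCA1", "c.68_69delAG (p.Glu23Valfs)",
                       germline_category = "acmg_pathogenic",
                       labels = "health_maintenance")
  clinical_report(pat, list(f1, f2), secondary_findings_optin = optin)
}

test_that("report rendering is deterministic and populates fixed-order sections", {
  r <- demo_report()
  md1 <- render_report(r, "markdown")
  md2 <- render_report(demo_report(), "markdown")
  expect_identical(md1, md2)
  js1 <- render_report(r, "json")
  expect_identical(js1, render_report(demo_report(), "json"))
  # fusion section precedes germline sections; both populated
  expect_lt(regexpr("BCR-ABL1", md1), regexpr("BRCA1", md1))
  expect_match(md1, "actionability tier 1")
  # empty findings still render all sections
  empty <- clinical_report(r$patient, list())
  expect_match(render_report(empty, "markdown"), "No findings.")
})

test_that("rendered output matches the golden report", {
  md <- render_report(demo_report(), "markdown")
  golden <- paste(readLines(test_path("golden_report.md"), warn = FALSE),
                  collapse = "\n")
  expect_identical(md, golden)
})

test_that("opt-out suppresses secondary findings from the document but keeps an audit record", {
  r <- demo_report(optin = FALSE)
  md <- render_report(r, "markdown")
  expect_false(grepl("BRCA1", md))
  audit <- report_audit(r)
  expect_equal(audit$gene, "BRCA1")
  # every retained finding appears exactly once
  md_in <- render_report(demo_report(TRUE), "markdown")
  expect_equal(lengths(regmatches(md_in, gregexpr("BCR-ABL1 fusion", md_in))), 1L)
})
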