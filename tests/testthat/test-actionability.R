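kb <- default_gene_kb()

phenos <- function(msi = "MSS", hrd = 0.01, sbs4 = 0, id3 = 0, score = 0) {
  tibble::tibble(
    tmb = 1, wgd = FALSE, hrd_probability = hrd, hrd_positive = hrd >= 0.7,
    msisensor_like_score = score, msi_signature_proportion = 0,
    msi_call = msi, sbs4_fraction = sbs4, id3_fraction = id3
  )
}

no_germline <- function() oncointerpret:::GERMLINE_PROTO()

driver_row <- function(gene, descriptor = NA, type = "point",
                       class = "oncogene_point", evidence = "e", cn = NA_real_) {
  tibble::tibble(
    gene = gene, alteration_type = type, descriptor = descriptor,
    driver_class = class, evidence = evidence, cn = cn
  )
}

test_that("phenotype and driver rules map to I-1 with correct precedence", {
  # MSI-H gastrointestinal tumor: checkpoint-inhibitor match
  a <- assign_category(
    oncointerpret:::empty_driver_table(), phenos(msi = "MSI-H"), no_germline(),
    kb, "stomach", "actionability"
  )
  expect_equal(a$category, "I-1")
  expect_match(a$evidence, "pembrolizumab")

  # approved point match beats a trial match
  drv <- dplyr::bind_rows(
    driver_row("EGFR", "L858R"),
    driver_row("AKT1", "E17K")
  )
  a2 <- assign_category(drv, phenos(), no_germline(), kb,
                        "lung_adenocarcinoma", "actionability")
  expect_equal(a2$category, "I-1")
  expect_match(a2$evidence, "erlotinib")

  # HRD-positive prostate: approved PARP inhibitor
  a3 <- assign_category(oncointerpret:::empty_driver_table(), phenos(hrd = 0.95),
                        no_germline(), kb, "prostate", "actionability")
  expect_equal(a3$category, "I-1")
  expect_match(a3$evidence, "olaparib")
  # ... but only a trial in a non-approved indication
  a4 <- assign_category(oncointerpret:::empty_driver_table(), phenos(hrd = 0.95),
                        no_germline(), kb, "stomach", "actionability")
  expect_equal(a4$category, "I-2")
  expect_match(a4$evidence, "NCT04171700")
})

test_that("resistance rules give I-3 only when nothing better matches", {
  kras <- driver_row("KRAS", "G12V")
  a <- assign_category(kras, phenos(), no_germline(), kb, "colorectal",
                       "actionability")
  expect_equal(a$category, "I-3")
  expect_match(a$evidence, "cetuximab")

  # G12C in colorectal has an approved inhibitor instead
  a2 <- assign_category(driver_row("KRAS", "G12C"), phenos(), no_germline(),
                        kb, "colorectal", "actionability")
  expect_equal(a2$category, "I-1")

  # nothing matches anywhere: none
  a3 <- assign_category(oncointerpret:::empty_driver_table(), phenos(),
                        no_germline(), kb, "colorectal", "actionability")
  expect_equal(a3$category, "none")
})

test_that("clarity categories: mechanism, origin, familial - in that order", {
  wt <- driver_row("EGFR", type = "amplification", class = "hyperamplification",
                   evidence = "cn_80;wt_allele_amplification", cn = 80)
  a <- assign_category(wt, phenos(), no_germline(), kb, "lung_adenocarcinoma",
                       "clarity")
  expect_equal(a$category, "II-1")

  # tobacco etiology (the unknown-primary pattern): SBS4 36.4%, ID3 38.7%
  a2 <- assign_category(oncointerpret:::empty_driver_table(),
                        phenos(sbs4 = 0.364, id3 = 0.387), no_germline(),
                        kb, "other", "clarity")
  expect_equal(a2$category, "II-2")
  expect_true(a2$type_agnostic)

  # germline finding concludes the familial question
  g <- tibble::tibble(
    gene = "APC", hgvs_p = "p.T1556fs", population_af = 1e-4,
    clinvar_class = "pathogenic", predisposition_gene = TRUE,
    second_hit_mechanisms = "loh"
  )
  a3 <- assign_category(oncointerpret:::empty_driver_table(), phenos(),
                        g, kb, "colorectal", "clarity")
  expect_equal(a3$category, "II-3")
  expect_match(a3$evidence, "APC")

  # confidently negative: no germline finding and low HRD
  a4 <- assign_category(oncointerpret:::empty_driver_table(), phenos(hrd = 0.01),
                        no_germline(), kb, "breast", "clarity")
  expect_equal(a4$category, "II-3")
  expect_match(a4$evidence, "unsupported")

  # precedence: mechanism wins over origin and familial evidence
  a5 <- assign_category(wt, phenos(sbs4 = 0.4, id3 = 0.4), g, kb,
                        "lung_adenocarcinoma", "clarity")
  expect_equal(a5$category, "II-1")
})

test_that("assignment is invariant to driver row order", {
  drv <- dplyr::bind_rows(
    driver_row("AKT1", "E17K"),
    driver_row("EGFR", "L858R"),
    driver_row("KRAS", "G12V")
  )
  a <- assign_category(drv, phenos(), no_germline(), kb,
                       "lung_adenocarcinoma", "actionability")
  b <- assign_category(drv[c(3, 1, 2), ], phenos(), no_germline(), kb,
                       "lung_adenocarcinoma", "actionability")
  expect_equal(a$category, b$category)
})

test_that("cohort summaries conserve counts and recompute percentages", {
  assignments <- dplyr::bind_rows(
    tibble::tibble(primary_question = "actionability",
                   category = rep(c("I-1", "I-2", "I-3", "none"), c(28, 22, 5, 24))),
    tibble::tibble(primary_question = "clarity",
                   category = rep(c("II-1", "II-2", "II-3", "none"), c(3, 7, 3, 3)))
  )
  s <- summarize_cohort(assignments, n_enrolled = 120)
  get <- function(arm, cat, col) s[[col]][s$arm == arm & s$category == cat]
  expect_equal(get("actionability", "I-1", "pct_1dp"), 35.4)
  expect_equal(get("actionability", "I-2", "pct_1dp"), 27.8)
  expect_equal(get("actionability", "I-3", "pct_1dp"), 6.3)
  expect_equal(get("clarity", "supportive", "pct_0dp"), 81)
  expect_equal(get("overall", "supportive", "pct_0dp"), 72)
  expect_equal(get("cohort", "reported", "pct_0dp"), 79)
  # conservation per arm
  act <- s[s$arm == "actionability" & !s$category %in% "supportive", ]
  expect_equal(sum(act$n), 79)
  expect_true(all(act$pct == 100 * act$n / act$denominator))
  # zero-count category prints 0.0
  z <- summarize_cohort(tibble::tibble(primary_question = "actionability",
                                       category = rep("none", 5)))
  expect_equal(z$pct_1dp[z$arm == "actionability" & z$category == "supportive"], 0.0)
})

test_that("half-up rounding matches the printed-percentage convention", {
  expect_equal(round_half_up(81.25, 1), 81.3)
  expect_equal(round_half_up(81.25, 0), 81)
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(-0.05, 1), -0.1)
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(round_half_up(100 * 1452 / 7232, 1), 20.1)
})

test_that("low-TCF samples are noninterpretable with sections suppressed", {
  cfg <- simulation_config(seed = 61, n_sbs = 100, n_indel = 20, n_sv = 10,
                           purity = 0.10, n_microsat = 20)
  res <- suppressMessages(interpret_simulated(cfg))
  expect_false(res$report$interpretable)
  expect_equal(nrow(res$report$drivers), 0)
  expect_equal(nrow(res$report$phenotypes), 0)

  # TCF exactly 0.15 is interpretable (the cutoff is strictly below 15%)
  cfg2 <- simulation_config(seed = 62, n_sbs = 100, n_indel = 20, n_sv = 10,
                            purity = 0.15, n_microsat = 20)
  res2 <- suppressMessages(interpret_simulated(cfg2))
  expect_true(res2$report$interpretable)
})

test_that("run_pipeline writes artifacts, logs decisions, and names failing stages", {
  out <- withr::local_tempdir()
  cfg <- simulation_config(seed = 63, n_sbs = 200, n_indel = 40, n_sv = 20,
                           n_microsat = 20)
  rpt <- suppressMessages(run_pipeline(cfg, out))
  expect_s3_class(rpt, "interpretation_report")
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "report.md")))
  expect_true(file.exists(file.path(out, "filtered_variants.tsv")))
  expect_true(file.exists(file.path(out, "ground_truth_manifest.tsv")))
  log <- readLines(file.path(out, "run_log.txt"))
  expect_true(any(grepl("vaf_ceiling_applies_to", log)))
  back <- read_report(file.path(out, "report.json"))
  expect_equal(back$category, rpt$category)

  # a missing segments input fails with a stage-named diagnostic
  expect_error(
    run_pipeline(list(variants = "x.tsv"), withr::local_tempdir()),
    "segments"
  )
})
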