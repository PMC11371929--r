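kb <- default_gene_kb()

test_that("oncogene point drivers need a hotspot or drug link; TSGs need damage", {
  egfr <- make_variant(gene = "EGFR", descriptor = "L858R",
                       variant_class = "missense")
  call <- classify_point_driver(egfr, kb_entry(kb, "EGFR"))
  expect_equal(call$driver_class, "oncogene_point")
  expect_match(call$evidence, "cosmic_recurrent_hotspot")
  expect_match(call$evidence, "actionable_drug")

  # TSG missense with no deleterious prediction and no ClinVar entry
  apc_mis <- make_variant(gene = "APC", descriptor = "A99T",
                          variant_class = "missense")
  expect_null(classify_point_driver(apc_mis, kb_entry(kb, "APC")))

  # synonymous variant at a hotspot position is still excluded by class
  syn <- make_variant(gene = "EGFR", descriptor = "L858R",
                      variant_class = "synonymous")
  expect_null(classify_point_driver(syn, kb_entry(kb, "EGFR")))

  # TSG truncating and predicted-deleterious missense both qualify
  apc_fs <- make_indel(gene = "APC", variant_class = "frameshift")
  expect_equal(
    classify_point_driver(apc_fs, kb_entry(kb, "APC"))$driver_class,
    "tsg_inactivating"
  )
  pten <- make_variant(gene = "PTEN", descriptor = "R130G",
                       variant_class = "missense")
  call2 <- classify_point_driver(pten, kb_entry(kb, "PTEN"))
  expect_match(call2$evidence, "sift_deleterious")

  # TERT promoter alterations use the oncogene branch
  tert <- make_variant(gene = "TERT", descriptor = "C228T",
                       variant_class = "promoter")
  expect_equal(
    classify_point_driver(tert, kb_entry(kb, "TERT"))$driver_class,
    "oncogene_point"
  )

  # gene absent from the knowledgebase: no call, with a notice
  expect_message(
    out <- classify_point_driver(make_variant(gene = "NOPE"), NULL),
    "knowledgebase"
  )
  expect_null(out)
})

test_that("amplification thresholds are ploidy-relative and inclusive", {
  nras <- kb_entry(kb, "NRAS") # no drug links: cutoff ploidy + 5
  below <- carved_profile(nras$chrom, nras$start - 2e5, nras$end + 2e5,
                          total_cn = 6.9, minor_cn = 1)
  expect_null(call_amplification("NRAS", below, nras))
  at <- carved_profile(nras$chrom, nras$start - 2e5, nras$end + 2e5,
                       total_cn = 7.0, minor_cn = 1)
  expect_equal(call_amplification("NRAS", at, nras)$driver_class, "amplification")

  ccnd1 <- kb_entry(kb, "CCND1") # drugged: cutoff ploidy + 1
  p3 <- carved_profile(ccnd1$chrom, ccnd1$start - 2e5, ccnd1$end + 2e5,
                       total_cn = 3.0, minor_cn = 1)
  expect_equal(call_amplification("CCND1", p3, ccnd1)$driver_class, "amplification")
  p29 <- carved_profile(ccnd1$chrom, ccnd1$start - 2e5, ccnd1$end + 2e5,
                        total_cn = 2.9, minor_cn = 1)
  expect_null(call_amplification("CCND1", p29, ccnd1))

  # ecDNA-scale copy numbers are annotated hyperamplified
  fgfr2 <- kb_entry(kb, "FGFR2")
  p185 <- carved_profile(fgfr2$chrom, fgfr2$start - 2e5, fgfr2$end + 2e5,
                         total_cn = 185, minor_cn = 1)
  hyper <- call_amplification("FGFR2", p185, fgfr2)
  expect_equal(hyper$driver_class, "hyperamplification")
  expect_match(hyper$evidence, "hyperamplification_cn_ge_50")

  # monotonicity: raising CN never removes the call
  for (cn in c(7, 20, 80, 200)) {
    p <- carved_profile(nras$chrom, nras$start - 2e5, nras$end + 2e5,
                        total_cn = cn, minor_cn = 1)
    expect_false(is.null(call_amplification("NRAS", p, nras)))
  }
})

test_that("gene copy number is the length-weighted mean over overlapping segments", {
  pten <- kb_entry(kb, "PTEN")
  mid <- (pten$start + pten$end) / 2
  segs <- flat_profile()$segments
  segs <- segs[segs$chrom != pten$chrom, ]
  segs <- dplyr::bind_rows(segs, tibble::tibble(
    chrom = pten$chrom,
    start = c(1, mid + 1),
    end = c(mid, oncointerpret:::CHROM_LENGTHS[[pten$chrom]]),
    total_cn = c(2, 4), minor_cn = c(1, 1)
  ))
  prof <- tumor_profile("t", 0.6, 2, segs)
  expect_equal(gene_copy_number(prof, pten), 3, tolerance = 0.01)
  expect_equal(gene_copy_number(prof, pten, method = "max_segment") %in% c(2, 4), TRUE)
})

test_that("biallelic deletion uses both stated criteria, inclusively", {
  pten <- kb_entry(kb, "PTEN")
  half <- carved_profile(pten$chrom, pten$start - 2e5, pten$end + 2e5,
                         total_cn = 0.5, minor_cn = 0)
  expect_equal(
    call_biallelic_deletion("PTEN", half, pten)$driver_class,
    "biallelic_deletion"
  )
  # CN 0.9 spanning a zero-total segment qualifies via the second branch
  L <- oncointerpret:::CHROM_LENGTHS[[pten$chrom]]
  third <- (pten$end - pten$start) / 10
  segs <- flat_profile()$segments
  segs <- segs[segs$chrom != pten$chrom, ]
  segs <- dplyr::bind_rows(segs, tibble::tibble(
    chrom = pten$chrom,
    start = c(1, pten$start + 9 * third + 1),
    end = c(pten$start + 9 * third, L),
    total_cn = c(1, 0), minor_cn = c(0, 0)
  ))
  prof <- tumor_profile("t", 0.6, 2, segs)
  cn <- gene_copy_number(prof, pten)
  expect_lt(cn, 1)
  expect_gt(cn, 0.5)
  expect_match(call_biallelic_deletion("PTEN", prof, pten)$evidence, "zero_segment")

  none <- carved_profile(pten$chrom, pten$start - 2e5, pten$end + 2e5,
                         total_cn = 0.9, minor_cn = 0)
  expect_null(call_biallelic_deletion("PTEN", none, pten))
})

test_that("fusion detection requires containment, allowlist and orientation", {
  eml4 <- kb_entry(kb, "EML4")
  alk <- kb_entry(kb, "ALK")
  good <- make_sv(
    chrom1 = alk$chrom, pos1 = alk$start + 1e4, strand1 = "+",
    chrom2 = eml4$chrom, pos2 = eml4$start + 1e4, strand2 = "+",
    sv_type = "INV"
  )
  expect_equal(detect_gene_fusions(good, kb)$descriptor, "EML4-ALK")

  # incompatible orientation: no call
  bad <- good
  bad$strand1 <- "-"
  bad$strand2 <- "-"
  expect_equal(nrow(detect_gene_fusions(bad, kb)), 0)

  # both breakpoints intergenic: no call
  interg <- make_sv(chrom1 = "2", pos1 = 1e6, chrom2 = "2", pos2 = 2e6)
  expect_equal(nrow(detect_gene_fusions(interg, kb)), 0)

  # non-allowlisted pair with no fusion-driver partner: no call
  kras <- kb_entry(kb, "KRAS")
  egfr <- kb_entry(kb, "EGFR")
  pair <- make_sv(
    chrom1 = kras$chrom, pos1 = kras$start + 100, strand1 = "+",
    chrom2 = egfr$chrom, pos2 = egfr$start + 100, strand2 = "-",
    sv_type = "TRA"
  )
  expect_equal(nrow(detect_gene_fusions(pair, kb)), 0)
})

test_that("germline screening keeps only rare P/LP variants in predisposition genes", {
  g <- tibble::tibble(
    gene = c("BRCA1", "BRCA2", "BRCA2", "MUC16"),
    hgvs_p = c("p.L1780P", "p.C717*", "p.N991D", "p.A1T"),
    population_af = c(0.0001, 0.005, 0.0001, 0.0001),
    clinvar_class = c("pathogenic", "pathogenic", "vus", "pathogenic"),
    predisposition_gene = c(TRUE, TRUE, TRUE, FALSE)
  )
  kept <- screen_germline(g, kb)
  expect_equal(kept$gene, "BRCA1") # 0.005 fails the strict <0.5% bound; VUS excluded
})

test_that("second hits are found via LOH, somatic truncation, or disruptive SV", {
  brca1 <- kb_entry(kb, "BRCA1")
  hit <- tibble::tibble(
    gene = "BRCA1", hgvs_p = "p.L1780P", population_af = 1e-4,
    clinvar_class = "pathogenic", predisposition_gene = TRUE
  )
  loh <- carved_profile(brca1$chrom, brca1$start - 1e6, brca1$end + 1e6,
                        total_cn = 1, minor_cn = 0)
  expect_true("loh" %in% detect_second_hit(hit, oncointerpret:::empty_variant_table(), loh, kb = kb))

  flat <- flat_profile()
  expect_length(
    detect_second_hit(hit, oncointerpret:::empty_variant_table(), flat, kb = kb), 0
  )
  trunc <- make_variant(gene = "BRCA1", variant_class = "nonsense")
  expect_true("somatic_truncating" %in%
    detect_second_hit(hit, trunc, flat, kb = kb))

  # BRIP1 disrupted by an intragenic deletion plus LOH, with no germline hit:
  # reported as somatic biallelic inactivation instead
  brip1 <- kb_entry(kb, "BRIP1")
  sv <- make_sv(
    chrom1 = brip1$chrom, pos1 = brip1$start + 1e4,
    chrom2 = brip1$chrom, pos2 = brip1$start + 1e4 + 21100L
  )
  prof <- carved_profile(brip1$chrom, brip1$start - 1e6, brip1$end + 1e6,
                         total_cn = 1, minor_cn = 0)
  bi <- detect_somatic_biallelic(oncointerpret:::empty_variant_table(), sv, prof, kb)
  expect_equal(bi$gene, "BRIP1")
  expect_equal(bi$driver_class, "tsg_inactivating")
  expect_match(bi$evidence, "disruptive_sv;loh")
})

test_that("driver calling is deterministic and quiet on a driver-free sample", {
  cfg <- simulation_config(seed = 55, n_sbs = 500, n_indel = 100, n_sv = 60,
                           n_microsat = 10)
  sim <- simulate_callset(cfg)
  fv <- suppressMessages(filter_snv_indel(sim$variants))
  fs <- filter_sv(sim$svs)
  d1 <- call_drivers(fv, fs, sim$profile, kb)
  expect_equal(nrow(d1), 0) # no injected driver, no spurious call
  # permuting the input order changes nothing
  d2 <- call_drivers(fv[sample(nrow(fv)), ], fs[sample(nrow(fs)), ], sim$profile, kb)
  expect_identical(d1, d2)
})

test_that("injected drivers are recovered across a simulated sweep", {
  specs <- list(
    list(type = "point", gene = "EGFR", descriptor = "L858R",
         variant_class = "missense"),
    list(type = "amplification", gene = "MET", cn = 10),
    list(type = "deletion", gene = "PTEN"),
    list(type = "fusion", gene = "ALK", partner_5p = "EML4")
  )
  for (s in seq_along(specs)) {
    cfg <- simulation_config(seed = 70 + s, n_sbs = 200, n_indel = 40, n_sv = 30,
                             n_microsat = 10, drivers = specs[s])
    sim <- simulate_callset(cfg)
    fv <- suppressMessages(filter_snv_indel(sim$variants))
    fs <- filter_sv(sim$svs)
    d <- call_drivers(fv, fs, sim$profile, kb)
    expect_true(specs[[s]]$gene %in% d$gene, label = specs[[s]]$gene)
  }
})
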