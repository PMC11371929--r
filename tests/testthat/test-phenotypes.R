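test_that("TMB is count over callable megabases and scales linearly", {
  expect_equal(compute_tmb(2800, 2800), 1.0)
  expect_equal(compute_tmb(0), 0)
  expect_equal(round_half_up(compute_tmb(43509), 2), 15.54)
  expect_equal(compute_tmb(2 * 43509), 2 * compute_tmb(43509))
  expect_error(compute_tmb(10, 0), "positive")
})

test_that("whole-genome duplication is strict at ploidy 3.5", {
  expect_false(call_wgd(3.5))
  expect_true(call_wgd(3.51))
  expect_false(call_wgd(2.0))
  expect_error(call_wgd(0), "positive")
})

test_that("HRD features collect signature fractions, MH deletions and LOH", {
  ref <- default_signature_references()
  sbs <- fit_exposures_nnls(
    noiseless_catalog(ref$SBS96, c(SBS3 = 0.2, SBS8 = 0.1, SBS1 = 0.7), 1000),
    ref$SBS96, c("SBS1", "SBS3", "SBS8")
  )
  idcat <- noiseless_catalog(ref$ID83, c(ID6 = 0.4, ID1 = 0.6), 500)
  idfit <- fit_exposures_nnls(idcat, ref$ID83, c("ID1", "ID6"))
  sv <- fit_exposures_nnls(
    noiseless_catalog(ref$SV32, c(RS3 = 0.2, RS5 = 0.13, RS1 = 0.67), 300),
    ref$SV32, c("RS1", "RS3", "RS5")
  )
  prof <- carved_profile("3", 50e6, 70e6, total_cn = 1, minor_cn = 0)
  f <- extract_hrd_features(sbs, idfit, sv, idcat, prof)
  expect_equal(f$sbs3_fraction, 0.2, tolerance = 1e-6)
  expect_equal(f$sbs8_fraction, 0.1, tolerance = 1e-6)
  expect_equal(f$id6_fraction, 0.4, tolerance = 1e-6)
  expect_equal(f$rs_fraction, 0.33, tolerance = 1e-6)
  expect_equal(f$loh_segment_count, 1) # the 20-Mb minor_cn=0 carve counts
  counts <- oncointerpret:::catalog_counts(idcat)
  mh <- sum(counts[grepl("^DEL\\.MH", names(counts))])
  dels <- sum(counts[grepl("^DEL", names(counts))])
  expect_equal(f$mh_del_proportion, mh / dels)
})

test_that("LOH feature excludes short and whole-chromosome LOH segments", {
  ref <- default_signature_references()
  zero <- mutational_catalog(integer(0), "ID83")
  sbs0 <- fit_exposures_nnls(mutational_catalog(integer(0), "SBS96"), ref$SBS96, "SBS1")
  id0 <- fit_exposures_nnls(zero, ref$ID83, "ID1")
  sv0 <- fit_exposures_nnls(mutational_catalog(integer(0), "SV32"), ref$SV32, "RS1")
  short <- carved_profile("3", 50e6, 55e6, total_cn = 1, minor_cn = 0) # 5 Mb
  f1 <- extract_hrd_features(sbs0, id0, sv0, zero, short)
  expect_equal(f1$loh_segment_count, 0)
  expect_true(f1$degenerate_indels)
  expect_equal(f1$mh_del_proportion, 0) # no deletions at all

  # a chromosome whose entire extent is one LOH segment is excluded
  segs <- flat_profile()$segments
  segs$minor_cn[segs$chrom == "5"] <- 0
  segs$total_cn[segs$chrom == "5"] <- 1
  whole <- tumor_profile("w", 0.6, 2, segs)
  f2 <- extract_hrd_features(sbs0, id0, sv0, zero, whole)
  expect_equal(f2$loh_segment_count, 0)
})

test_that("HRD probability is the standardized logistic and inclusive at 0.7", {
  co <- default_hrd_coefficients()
  at_center <- tibble::tibble(
    sbs3_fraction = 0.05, sbs8_fraction = 0.05, id6_fraction = 0.05,
    rs_fraction = 0.10, mh_del_proportion = 0.10, loh_segment_count = 3
  )
  expect_equal(hrd_probability(at_center, co), stats::plogis(-3), tolerance = 1e-12)

  # intercept at qlogis(0.7) with centered features: exactly at the cutoff,
  # and the positive call is inclusive
  co70 <- co
  co70$intercept <- stats::qlogis(0.7)
  p <- hrd_probability(at_center, co70)
  expect_equal(p, 0.7, tolerance = 1e-12)
  expect_true(p >= co$positive_cutoff)

  # monotone non-decreasing in every positively weighted feature
  for (feat in co$features$name) {
    up <- at_center
    up[[feat]] <- up[[feat]] + 0.2
    expect_gte(hrd_probability(up, co), hrd_probability(at_center, co))
  }
  expect_error(hrd_probability(at_center[, -1], co), "missing")
})

test_that("microsatellite score is 0 for concordant and 100 for shifted sites", {
  concordant <- dplyr::bind_rows(lapply(1:20, function(i) {
    tibble::tibble(
      locus_id = sprintf("m%02d", i), repeat_unit = "A",
      sample = rep(c("tumor", "normal"), each = 2),
      length = c(10L, 11L, 10L, 11L), count = c(40L, 10L, 40L, 10L)
    )
  }))
  expect_equal(msisensor_like_score(concordant), 0)

  shifted <- dplyr::bind_rows(lapply(1:20, function(i) {
    tibble::tibble(
      locus_id = sprintf("m%02d", i), repeat_unit = "A",
      sample = rep(c("tumor", "normal"), each = 2),
      length = c(12L, 13L, 10L, 11L), count = c(40L, 10L, 40L, 10L)
    )
  }))
  expect_equal(msisensor_like_score(shifted), 100)

  # low-coverage loci are not evaluable
  thin <- dplyr::mutate(concordant, count = 2L)
  expect_error(msisensor_like_score(thin), "evaluable")
})

test_that("generator instability fraction is recovered by the score", {
  scores <- vapply(1:3, function(s) {
    cfg <- simulation_config(seed = 600 + s, n_sbs = 0, n_indel = 0, n_sv = 0,
                             artifact_fraction = 0, n_microsat = 200,
                             instability_fraction = 0.30)
    sim <- simulate_callset(cfg)
    msisensor_like_score(sim$microsatellites)
  }, numeric(1))
  expect_true(all(abs(scores - 30) <= 7))
})

test_that("the MSI call is an inclusive OR over its two evidence sources", {
  expect_equal(msi_call(0.5, 0.01), "MSS")
  expect_equal(msi_call(20, 0.6), "MSI-H")
  expect_equal(msi_call(3.5, 0), "MSI-H")
  expect_equal(msi_call(0, 0.20), "MSI-H")
  # lowering a threshold never flips MSI-H to MSS
  expect_equal(msi_call(4, 0.1, score_threshold = 2), "MSI-H")
})
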