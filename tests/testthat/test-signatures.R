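test_that("NNLS recovers a noiseless two-signature mixture exactly", {
  ref <- toy_sbs_reference()
  catalog <- noiseless_catalog(ref, c(SBS1 = 0.7, SBS5 = 0.3), 1000)
  fit <- fit_exposures_nnls(catalog, ref, c("SBS1", "SBS5"))
  expect_equal(unname(fit$exposures["SBS1"]), 700, tolerance = 1e-6)
  expect_equal(unname(fit$exposures["SBS5"]), 300, tolerance = 1e-6)
  expect_gt(fit$cosine, 1 - 1e-9)
})

test_that("degenerate inputs: zero catalogs and single-signature catalogs", {
  ref <- toy_sbs_reference()
  zero <- mutational_catalog(integer(0), "SBS96")
  fit <- fit_exposures_nnls(zero, ref, c("SBS1", "SBS5"))
  expect_true(fit$degenerate)
  expect_equal(unname(fit$exposures), c(0, 0))
  expect_equal(fit$cosine, 1.0)

  solo <- noiseless_catalog(ref, c(SBS4 = 1), 500)
  fit2 <- fit_exposures_nnls(solo, ref, "SBS4")
  expect_equal(unname(fit2$exposures), 500, tolerance = 1e-6)
  expect_equal(sum(fit2$exposures) / fit2$total, 1)
})

test_that("active-set and class mismatches are rejected", {
  ref <- toy_sbs_reference()
  catalog <- noiseless_catalog(ref, c(SBS1 = 1), 100)
  expect_error(fit_exposures_nnls(catalog, ref, character(0)), "non-empty")
  expect_error(fit_exposures_nnls(catalog, ref, "SBS999"), "absent")
  idref <- synthetic_signature_reference("ID83")
  expect_error(fit_exposures_nnls(catalog, idref, "ID1"), "class")
})

test_that("NNLS matches an exhaustive active-set oracle on small instances", {
  ref <- toy_sbs_reference()
  sigs <- c("SBS1", "SBS4", "SBS13", "SBS18")
  m <- ref$matrix[1:8, sigs]
  m <- sweep(m, 2, colSums(m), "/") # renormalize the 8-channel slice
  set.seed(42)
  for (i in 1:10) {
    y <- as.numeric(m %*% runif(4, 0, 100)) + runif(8, 0, 5)
    x_pkg <- pracma::lsqnonneg(m, y)$x
    x_orc <- nnls_oracle(m, y)
    expect_equal(x_pkg, x_orc, tolerance = 1e-4)
  }
})

test_that("exposures sum to the catalog total after rescaling", {
  ref <- toy_sbs_reference()
  cfg <- simulation_config(seed = 23, n_sbs = 1200, n_indel = 0, n_sv = 0,
                           artifact_fraction = 0, n_microsat = 10)
  sim <- simulate_callset(cfg)
  catalog <- build_sbs96_catalog(sim$variants)
  fit <- fit_exposures_nnls(catalog, ref)
  expect_equal(sum(fit$exposures), sum(catalog$count), tolerance = 1e-9)
  expect_true(all(fit$exposures >= 0))
})

test_that("multinomial mixture recovery stays within 3 percentage points", {
  ref <- toy_sbs_reference()
  truth <- c(SBS1 = 0.3, SBS4 = 0.4, SBS5 = 0.3)
  errs <- vapply(1:3, function(s) {
    catalog <- withr::with_seed(1000 + s, mutational_catalog(
      stats::setNames(
        as.integer(rmultinom(1, 5000, as.numeric(ref$matrix[, names(truth)] %*% truth))),
        rownames(ref$matrix)
      ), "SBS96"
    ))
    fit <- fit_exposures_nnls(catalog, ref, names(truth))
    max(abs(fit$exposures / fit$total - truth))
  }, numeric(1))
  expect_true(all(errs < 0.03))
})

test_that("refinement leaves a well-explained catalog alone and records a trace", {
  ref <- toy_sbs_reference()
  cfg <- simulation_config(seed = 29, n_sbs = 2000, n_indel = 0, n_sv = 0,
                           sbs_mixture = c(SBS1 = 0.5, SBS5 = 0.5),
                           artifact_fraction = 0, n_microsat = 10)
  sim <- simulate_callset(cfg)
  catalog <- build_sbs96_catalog(sim$variants)
  fit <- refine_signature_set(catalog, ref, c("SBS1", "SBS5"))
  expect_false(fit$refined)
  expect_gte(fit$cosine, 0.90)
  expect_equal(fit$trace$action, "initial")
})

test_that("refinement adds a withheld signature carrying 40% of the mass", {
  ref <- toy_sbs_reference()
  cfg <- simulation_config(seed = 37, n_sbs = 2000, n_indel = 0, n_sv = 0,
                           sbs_mixture = c(SBS1 = 0.3, SBS4 = 0.4, SBS5 = 0.3),
                           artifact_fraction = 0, n_microsat = 10)
  sim <- simulate_callset(cfg)
  catalog <- build_sbs96_catalog(sim$variants)
  # oracle for the trigger: the initial set alone cannot reach the target
  init <- fit_exposures_nnls(catalog, ref, c("SBS1", "SBS5"))
  expect_lt(init$cosine, 0.90)
  fit <- refine_signature_set(catalog, ref, c("SBS1", "SBS5"))
  expect_true("SBS4" %in% names(fit$exposures))
  expect_true("SBS4" %in% fit$trace$signature[fit$trace$action == "add"])
  expect_gte(fit$cosine, 0.90)
  # forward additions never decrease the cosine
  adds <- fit$trace$cosine
  expect_true(all(diff(adds[seq_len(sum(fit$trace$action != "remove"))]) > -1e-12))
})

test_that("a fit exactly at the trigger is not refined (strictly-below rule)", {
  ref <- toy_sbs_reference()
  cfg <- simulation_config(seed = 41, n_sbs = 1500, n_indel = 0, n_sv = 0,
                           sbs_mixture = c(SBS1 = 0.6, SBS4 = 0.4),
                           artifact_fraction = 0, n_microsat = 10)
  sim <- simulate_callset(cfg)
  catalog <- build_sbs96_catalog(sim$variants)
  c0 <- fit_exposures_nnls(catalog, ref, c("SBS1", "SBS5"))$cosine
  fit <- refine_signature_set(catalog, ref, c("SBS1", "SBS5"), cosine_target = c0)
  expect_false(fit$refined)
  expect_equal(nrow(fit$trace), 1)
})

test_that("MSI signature proportion is the exposure mass on the seven signatures", {
  expect_equal(
    exposure_fractions(c(SBS6 = 500, SBS1 = 500))$fraction[1], 0.5
  )
  ref <- toy_sbs_reference()
  catalog <- noiseless_catalog(ref, c(SBS6 = 0.3, SBS15 = 0.3, SBS1 = 0.4), 1000)
  fit <- fit_exposures_nnls(catalog, ref, c("SBS6", "SBS15", "SBS1"))
  expect_equal(msi_signature_proportion(fit), 0.6, tolerance = 1e-6)
  no_msi <- fit_exposures_nnls(
    noiseless_catalog(ref, c(SBS1 = 1), 100), ref, c("SBS1", "SBS5")
  )
  expect_equal(msi_signature_proportion(no_msi), 0)
  zero <- fit_exposures_nnls(mutational_catalog(integer(0), "SBS96"), ref, "SBS6")
  expect_equal(msi_signature_proportion(zero), 0)
})

test_that("tidy/glance expose fractions and fit metadata", {
  ref <- toy_sbs_reference()
  fit <- fit_exposures_nnls(noiseless_catalog(ref, c(SBS1 = 1), 100), ref, "SBS1")
  td <- generics::tidy(fit)
  expect_named(td, c("signature", "count", "fraction", "pct"))
  gl <- generics::glance(fit)
  expect_equal(gl$cosine, 1, tolerance = 1e-9)
  expect_false(gl$best_effort)
})
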