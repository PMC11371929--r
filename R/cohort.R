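# A simulated study cohort: twenty samples whose configurations carry a
# known intended category, spanning approved-therapy matches (point
# drivers, fusion, MSI-H, HRD), trial matches (point, amplification,
# hyperamplification, HRD in a non-approved indication), resistance-rule
# exclusions, and the three clarity outcomes (wild-type-allele
# hyperamplification, tobacco-etiology origin, familial evaluation).

#' Simulation configurations for a 20-sample cohort with known categories
#'
#' Each configuration's `intended_category` records the category the rule
#' engine is expected to assign; the mix covers I-1 through I-3 and II-1
#' through II-3.
#'
#' @param seed Base seed; sample `i` uses `seed * 100 + i`.
#' @return List of [simulation_config()] objects.
#' @export
cohort_scenarios <- function(seed = 1) {
  point <- function(gene, descriptor, variant_class = "missense") {
    list(list(type = "point", gene = gene, descriptor = descriptor,
              variant_class = variant_class))
  }
  amp <- function(gene, cn) list(list(type = "amplification", gene = gene, cn = cn))
  scen <- list(
    list(cancer_type = "lung_adenocarcinoma", question = "actionability",
         drivers = point("EGFR", "L858R"), intended = "I-1"),
    list(cancer_type = "colorectal", question = "actionability",
         drivers = point("BRAF", "V600E"), intended = "I-1"),
    list(cancer_type = "breast", question = "actionability",
         drivers = point("PIK3CA", "H1047R"), intended = "I-1"),
    list(cancer_type = "urothelial", question = "actionability",
         drivers = point("FGFR3", "S249C"), intended = "I-1"),
    list(cancer_type = "lung_adenocarcinoma", question = "actionability",
         drivers = list(list(type = "fusion", gene = "ALK", partner_5p = "EML4")),
         intended = "I-1"),
    list(cancer_type = "stomach", question = "actionability",
         msi_status = "MSI-H", intended = "I-1"),
    list(cancer_type = "prostate", question = "actionability",
         hrd_status = TRUE, intended = "I-1"),
    list(cancer_type = "lung_adenocarcinoma", question = "actionability",
         drivers = point("KRAS", "G12D"), intended = "I-2"),
    list(cancer_type = "other", question = "actionability",
         drivers = point("HRAS", "Q61R"), intended = "I-2"),
    list(cancer_type = "breast", question = "actionability",
         drivers = point("AKT1", "E17K"), intended = "I-2"),
    list(cancer_type = "stomach", question = "actionability",
         hrd_status = TRUE, intended = "I-2"),
    list(cancer_type = "other", question = "actionability",
         drivers = amp("CCND1", 12), intended = "I-2"),
    list(cancer_type = "other", question = "actionability",
         drivers = amp("MET", 10), intended = "I-2"),
    list(cancer_type = "cholangiocarcinoma", question = "actionability",
         drivers = amp("FGFR2", 185), intended = "I-2"),
    list(cancer_type = "colorectal", question = "actionability",
         drivers = point("KRAS", "G12V"), intended = "I-3"),
    list(cancer_type = "colorectal", question = "actionability",
         drivers = point("NRAS", "Q61K"), intended = "I-3"),
    list(cancer_type = "lung_adenocarcinoma", question = "clarity",
         drivers = c(point("EGFR", "L858R"), amp("EGFR", 80)), intended = "II-1"),
    list(cancer_type = "other", question = "clarity",
         sbs_mixture = c(SBS1 = 0.24, SBS4 = 0.36, SBS5 = 0.40),
         id_mixture = c(ID1 = 0.31, ID2 = 0.30, ID3 = 0.39),
         intended = "II-2"),
    list(cancer_type = "colorectal", question = "clarity",
         germline_payload = tibble(
           gene = "APC", hgvs_p = "p.T1556fs", population_af = 1e-4,
           clinvar_class = "pathogenic", predisposition_gene = TRUE,
           second_hit = "loh"
         ),
         intended = "II-3"),
    list(cancer_type = "breast", question = "clarity", intended = "II-3")
  )
  imap(scen, function(s, i) {
    simulation_config(
      seed = seed * 100 + i,
      sample_id = sprintf("cohort_%02d", i),
      cancer_type = s$cancer_type, question = s$question,
      drivers = s$drivers %||% list(),
      sbs_mixture = s$sbs_mixture, id_mixture = s$id_mixture,
      msi_status = s$msi_status %||% "MSS",
      hrd_status = isTRUE(s$hrd_status),
      germline_payload = s$germline_payload,
      intended_category = s$intended
    )
  })
}

#' Simulate a call set and interpret it
#'
#' Convenience wrapper: [simulate_callset()] followed by
#' [interpret_sample()].
#'
#' @param config A [simulation_config()].
#' @param kb,references,thresholds Passed through.
#' @return List with `report` and `ground_truth`.
#' @export
interpret_simulated <- function(config, kb = default_gene_kb(),
                                references = default_signature_references(),
                                thresholds = filter_thresholds()) {
  sim <- simulate_callset(config, references, kb)
  report <- interpret_sample(
    sim$variants, sim$svs, sim$profile, sim$germline, sim$microsatellites,
    cancer_type = config$cancer_type, question = config$question,
    kb = kb, references = references, thresholds = thresholds
  )
  list(report = report, ground_truth = sim$ground_truth)
}
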