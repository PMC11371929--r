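# Sample-level genome phenotypes: tumor mutational burden, whole-genome
# duplication, homologous recombination deficiency probability, and the
# microsatellite instability call.

#' Tumor mutational burden
#'
#' @param filtered_variant_count Number of high-confidence somatic mutations.
#' @param callable_mb Callable genome size in Mb (default 2800).
#' @return Mutations per Mb.
#' @export
compute_tmb <- function(filtered_variant_count, callable_mb = 2800) {
  if (callable_mb <= 0) stop_validate("callable_mb must be positive")
  filtered_variant_count / callable_mb
}

#' Whole-genome duplication call
#'
#' @param ploidy Tumor genome ploidy (> 0).
#' @return `TRUE` iff ploidy strictly exceeds 3.5.
#' @export
call_wgd <- function(ploidy) {
  if (any(ploidy <= 0)) stop_validate("ploidy must be positive")
  ploidy > 3.5
}

#' Extract the HRD feature vector for one sample
#'
#' Collects the six features scored by the HRD model: the exposure fractions
#' of SBS3 and SBS8 (substitutions), ID6 (indels) and RS3+RS5
#' (rearrangements), the proportion of deletions carrying microhomology
#' (microhomology-channel deletions over all deletion-class indels, 0 with a
#' degenerate flag when the sample has no deletions), and the number of long
#' LOH segments (minor copy number 0, length >= `loh_min_len`, excluding
#' chromosomes whose entire segmented extent is one LOH segment).
#'
#' @param sbs_exposure An SBS96 `signature_exposure`.
#' @param id_exposure An ID83 `signature_exposure`.
#' @param sv_exposure An SV32 `signature_exposure`.
#' @param id_catalog The ID83 `mutational_catalog` (for the microhomology
#'   tally).
#' @param profile A `tumor_profile`.
#' @param loh_min_len Minimum LOH segment length in bp (default 15 Mb).
#' @return An `hrd_features` tibble (one row).
#' @export
extract_hrd_features <- function(sbs_exposure, id_exposure, sv_exposure,
                                 id_catalog, profile, loh_min_len = 15e6) {
  if (sbs_exposure$class != "SBS96" || id_exposure$class != "ID83" ||
    sv_exposure$class != "SV32" || !identical(catalog_class(id_catalog), "ID83")) {
    stop_validate("exposure/catalog classes do not match their expected roles")
  }
  expo_frac <- function(exposure, sigs) {
    if (exposure$total == 0) return(0)
    sum(exposure$exposures[intersect(names(exposure$exposures), sigs)]) / exposure$total
  }
  id_counts <- catalog_counts(id_catalog)
  del <- grepl("^DEL", names(id_counts))
  mh <- grepl("^DEL\\.MH", names(id_counts))
  n_del <- sum(id_counts[del])
  mh_prop <- if (n_del > 0) sum(id_counts[mh]) / n_del else 0
  segs <- profile$segments
  loh_count <- 0L
  if (nrow(segs) > 0) {
    segs <- mutate(segs, len = .data$end - .data$start + 1, loh = .data$minor_cn == 0)
    whole_chrom_loh <- segs |>
      group_by(.data$chrom) |>
      summarise(whole = n() == 1 && all(.data$loh), .groups = "drop")
    segs <- left_join(segs, whole_chrom_loh, by = "chrom")
    loh_count <- sum(segs$loh & segs$len >= loh_min_len & !segs$whole)
  }
  out <- tibble(
    sbs3_fraction = expo_frac(sbs_exposure, "SBS3"),
    sbs8_fraction = expo_frac(sbs_exposure, "SBS8"),
    id6_fraction = expo_frac(id_exposure, "ID6"),
    rs_fraction = expo_frac(sv_exposure, c("RS3", "RS5")),
    mh_del_proportion = mh_prop,
    loh_segment_count = as.numeric(loh_count),
    degenerate_indels = n_del == 0
  )
  structure(out, class = c("hrd_features", class(out)))
}

#' Default HRD model coefficients
#'
#' Reads the bundled editable JSON: per-feature center/scale
#' standardization, logistic weights and intercept, plus the positive-call
#' cutoff (0.7, inclusive).
#'
#' @param path JSON file (defaults to the bundled fixture).
#' @return A list with `intercept`, `positive_cutoff` and a `features`
#'   tibble.
#' @export
default_hrd_coefficients <- function(path = system.file("extdata", "hrd_coefficients.json",
                                       package = "oncointerpret")) {
  raw <- jsonlite::read_json(path)
  list(
    intercept = raw$intercept,
    positive_cutoff = raw$positive_cutoff %||% 0.7,
    features = purrr::map_dfr(raw$features, as_tibble)
  )
}

#' HRD probability score
#'
#' Logistic combination of the standardized feature vector:
#' `plogis(intercept + sum(w_i * (x_i - center_i) / scale_i))`. A sample is
#' called HRD positive when the probability is greater than or equal to the
#' cutoff (0.7 by default, inclusive).
#'
#' @param features An `hrd_features` row (or any list providing the named
#'   features).
#' @param coefficients Coefficient set from [default_hrd_coefficients()].
#' @return Probability in `(0, 1)`.
#' @export
hrd_probability <- function(features, coefficients = default_hrd_coefficients()) {
  co <- coefficients$features
  missing_feat <- setdiff(co$name, names(features))
  if (length(missing_feat) > 0) {
    stop_validate(paste0("missing HRD feature(s): ", paste(missing_feat, collapse = ", ")))
  }
  vals <- map_dbl(co$name, ~ as.numeric(features[[.x]][1]))
  z <- coefficients$intercept + sum(co$weight * (vals - co$center) / co$scale)
  stats::plogis(z)
}

#' MSIsensor-like microsatellite instability score
#'
#' Percentage of evaluable microsatellite loci whose tumor and normal
#' repeat-length histograms differ. A locus is evaluable when both
#' histograms carry at least `min_reads` reads. A locus counts as unstable
#' when (a) a chi-square test on the two histograms gives p < `p_cutoff`
#' and (b) at least `min_novel_reads` tumor reads fall on repeat lengths
#' unobserved in the normal. Clause (b) is the minimum-count guard: a bare
#' two-sample chi-square at the 5% level flags ~5% of perfectly stable loci
#' by construction, which would put stable samples above the default
#' MSI-score threshold; requiring novel-length support keeps the
#' stable-locus false-positive rate near zero without affecting genuinely
#' shifted loci.
#'
#' @param sites A validated microsatellite tibble
#'   (see [read_microsatellite_table()]).
#' @param p_cutoff Chi-square significance level (default 0.05).
#' @param min_reads Minimum reads per histogram for a locus to be evaluable
#'   (default 20).
#' @param min_novel_reads Minimum tumor reads at lengths absent from the
#'   normal histogram (default 5).
#' @return Score in `[0, 100]`.
#' @export
msisensor_like_score <- function(sites, p_cutoff = 0.05, min_reads = 20,
                                 min_novel_reads = 5) {
  sites <- validate_microsatellites(sites)
  per_locus <- sites |>
    tidyr::pivot_wider(
      id_cols = c("locus_id", "length"), names_from = "sample",
      values_from = "count", values_fill = 0L, values_fn = sum
    )
  eval_one <- function(df) {
    tum <- df$tumor
    nor <- df$normal
    if (sum(tum) < min_reads || sum(nor) < min_reads) return(NA)
    novel <- sum(tum[nor == 0])
    tab <- rbind(tum, nor)
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2) return(FALSE)
    p <- suppressWarnings(chisq.test(tab)$p.value)
    isTRUE(p < p_cutoff) && novel >= min_novel_reads
  }
  verdicts <- per_locus |>
    group_by(.data$locus_id) |>
    tidyr::nest() |>
    ungroup() |>
    mutate(unstable = map(.data$data, eval_one)) |>
    pull("unstable") |>
    unlist()
  verdicts <- verdicts[!is.na(verdicts)]
  if (length(verdicts) == 0) stop_validate("no evaluable microsatellite sites")
  100 * sum(verdicts) / length(verdicts)
}

#' Microsatellite instability call
#'
#' MSI-H when either evidence source crosses its threshold: the site-level
#' instability score or the MSI-associated signature proportion. Both
#' thresholds are inclusive and configurable.
#'
#' @param score [msisensor_like_score()] result (percentage).
#' @param msi_sig_proportion [msi_signature_proportion()] result.
#' @param score_threshold Default 3.5.
#' @param proportion_threshold Default 0.20.
#' @return `"MSI-H"` or `"MSS"`.
#' @export
msi_call <- function(score, msi_sig_proportion, score_threshold = 3.5,
                     proportion_threshold = 0.20) {
  if (score >= score_threshold || msi_sig_proportion >= proportion_threshold) {
    "MSI-H"
  } else {
    "MSS"
  }
}

#' Compute the full phenotype report for one sample
#'
#' @param n_mutations High-confidence somatic mutation count for TMB.
#' @param sbs_exposure,id_exposure,sv_exposure Fitted `signature_exposure`s.
#' @param id_catalog The ID83 catalog.
#' @param profile A `tumor_profile`.
#' @param msites Microsatellite site tibble.
#' @param callable_mb Callable genome size for TMB (default 2800).
#' @param hrd_coefficients HRD model coefficients.
#' @param msi_score_threshold,msi_proportion_threshold MSI thresholds.
#' @return A one-row `phenotype_report` tibble: `tmb`, `wgd`,
#'   `hrd_probability`, `hrd_positive`, `msisensor_like_score`,
#'   `msi_signature_proportion`, `msi_call`.
#' @export
compute_phenotypes <- function(n_mutations, sbs_exposure, id_exposure,
                               sv_exposure, id_catalog, profile, msites,
                               callable_mb = 2800,
                               hrd_coefficients = default_hrd_coefficients(),
                               msi_score_threshold = 3.5,
                               msi_proportion_threshold = 0.20) {
  feats <- extract_hrd_features(sbs_exposure, id_exposure, sv_exposure, id_catalog, profile)
  hrd_p <- hrd_probability(feats, hrd_coefficients)
  score <- msisensor_like_score(msites)
  prop <- msi_signature_proportion(sbs_exposure)
  sig_frac <- function(exposure, sig) {
    if (exposure$total == 0 || !sig %in% names(exposure$exposures)) return(0)
    unname(exposure$exposures[sig]) / exposure$total
  }
  out <- tibble(
    tmb = compute_tmb(n_mutations, callable_mb),
    wgd = call_wgd(profile$ploidy),
    hrd_probability = hrd_p,
    hrd_positive = hrd_p >= hrd_coefficients$positive_cutoff,
    msisensor_like_score = score,
    msi_signature_proportion = prop,
    msi_call = msi_call(score, prop, msi_score_threshold, msi_proportion_threshold),
    # etiologic fractions used by tumor-origin inference (tobacco exposure)
    sbs4_fraction = sig_frac(sbs_exposure, "SBS4"),
    id3_fraction = sig_frac(id_exposure, "ID3")
  )
  structure(out, class = c("phenotype_report", class(out)))
}
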