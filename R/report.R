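# End-to-end sample interpretation and patient reports.

PHENOTYPE_PROTO <- function() {
  tibble(
    tmb = numeric(), wgd = logical(), hrd_probability = numeric(),
    hrd_positive = logical(), msisensor_like_score = numeric(),
    msi_signature_proportion = numeric(), msi_call = character(),
    sbs4_fraction = numeric(), id3_fraction = numeric()
  )
}

GERMLINE_PROTO <- function() {
  tibble(
    gene = character(), hgvs_p = character(), population_af = numeric(),
    clinvar_class = character(), predisposition_gene = logical(),
    second_hit_mechanisms = character()
  )
}

CATEGORY_PROTO <- function() {
  tibble(
    primary_question = character(), category = character(),
    evidence = character(), type_agnostic = logical()
  )
}

new_interpretation_report <- function(...) {
  structure(list(...), class = "interpretation_report")
}

#' @export
print.interpretation_report <- function(x, ...) {
  cat(sprintf(
    "<interpretation_report> %s (%s, %s)\n", x$sample_id, x$cancer_type, x$question
  ))
  if (!x$interpretable) {
    cat(sprintf("  noninterpretable: TCF %.2f < 0.15\n", x$tcf))
    return(invisible(x))
  }
  cat(sprintf(
    "  category %s; %d driver(s); TMB %.2f/Mb; HRD %.3f; MSI %s\n",
    x$category$category, nrow(x$drivers), x$phenotypes$tmb,
    x$phenotypes$hrd_probability, x$phenotypes$msi_call
  ))
  invisible(x)
}

#' Interpret one tumor/normal call set end to end
#'
#' Runs the full post-calling pipeline for one sample: somatic filtering,
#' catalog construction, signature refitting with cancer-type default sets,
#' genome phenotyping, driver interpretation, germline screening with
#' second-hit detection, and category assignment. Samples with tumor cell
#' fraction below 0.15 (strict) are reported noninterpretable with all
#' downstream sections suppressed.
#'
#' @param variants Somatic SNV/indel tibble (unfiltered).
#' @param svs Somatic SV tibble (unfiltered).
#' @param profile A `tumor_profile`.
#' @param germline Germline variant tibble.
#' @param msites Microsatellite site tibble.
#' @param cancer_type,question Sample metadata (see [assign_category()]).
#' @param kb A `gene_kb`.
#' @param references Signature references (list with `SBS96`, `ID83`,
#'   `SV32`).
#' @param thresholds [filter_thresholds()].
#' @param callable_mb Callable genome size for TMB.
#' @param hrd_coefficients HRD model coefficients.
#' @return An `interpretation_report`.
#' @export
interpret_sample <- function(variants, svs, profile, germline, msites,
                             cancer_type, question = "actionability",
                             kb = default_gene_kb(),
                             references = default_signature_references(),
                             thresholds = filter_thresholds(),
                             callable_mb = 2800,
                             hrd_coefficients = default_hrd_coefficients()) {
  provenance <- list(
    thresholds = unclass(thresholds), callable_mb = callable_mb,
    cosine_target = 0.90, hrd_cutoff = hrd_coefficients$positive_cutoff,
    tcf_interpretability_cutoff = 0.15, kb_version = kb$version
  )
  if (profile$tcf < 0.15) {
    return(new_interpretation_report(
      sample_id = profile$sample_id, cancer_type = cancer_type,
      question = question, interpretable = FALSE,
      tcf = profile$tcf, ploidy = profile$ploidy,
      drivers = empty_driver_table(), phenotypes = PHENOTYPE_PROTO(),
      signatures = list(), germline_findings = GERMLINE_PROTO(),
      category = CATEGORY_PROTO(), provenance = provenance
    ))
  }
  fv <- filter_snv_indel(variants, thresholds)
  fs <- filter_sv(svs, thresholds)
  pass_v <- filter(fv, .data$pass)
  pass_s <- filter(fs, .data$pass)
  catalogs <- list(
    SBS96 = build_sbs96_catalog(pass_v),
    ID83 = build_id83_catalog(pass_v),
    SV32 = build_sv32_catalog(pass_s)
  )
  exposures <- imap(catalogs, function(cat, cl) {
    refine_signature_set(cat, references[[cl]], default_signature_set(cancer_type, cl))
  })
  phenotypes <- compute_phenotypes(
    n_mutations = nrow(pass_v),
    sbs_exposure = exposures$SBS96, id_exposure = exposures$ID83,
    sv_exposure = exposures$SV32, id_catalog = catalogs$ID83,
    profile = profile, msites = msites, callable_mb = callable_mb,
    hrd_coefficients = hrd_coefficients
  )
  drivers <- call_drivers(pass_v, pass_s, profile, kb)
  findings <- screen_germline(germline, kb)
  if (nrow(findings) > 0) {
    findings$second_hit_mechanisms <- map_chr(seq_len(nrow(findings)), function(i) {
      paste(detect_second_hit(findings[i, ], pass_v, profile, pass_s, kb), collapse = ";")
    })
  } else {
    findings <- GERMLINE_PROTO()
  }
  category <- tibble::as_tibble(as.data.frame(
    assign_category(drivers, phenotypes, findings, kb, cancer_type, question)
  ))
  sig_block <- imap(exposures, function(e, cl) {
    list(
      fractions = exposure_fractions(e), cosine = e$cosine,
      active_set = e$active_set, refined = e$refined,
      best_effort = e$best_effort
    )
  })
  new_interpretation_report(
    sample_id = profile$sample_id, cancer_type = cancer_type,
    question = question, interpretable = TRUE,
    tcf = profile$tcf, ploidy = profile$ploidy,
    drivers = drivers,
    phenotypes = tibble::as_tibble(as.data.frame(phenotypes)),
    signatures = sig_block,
    germline_findings = as_tibble(findings), category = as_tibble(category),
    provenance = provenance
  )
}

coerce_tbl <- function(df, proto) {
  if (is.null(df) || (is.data.frame(df) && nrow(df) == 0) || length(df) == 0) {
    return(proto)
  }
  df <- as_tibble(df)
  for (col in names(proto)) {
    if (!col %in% names(df)) {
      df[[col]] <- vector(class(proto[[col]])[1], nrow(df))
    }
    df[[col]] <- switch(class(proto[[col]])[1],
      integer = as.integer(df[[col]]),
      numeric = as.numeric(df[[col]]),
      logical = as.logical(df[[col]]),
      as.character(df[[col]])
    )
  }
  df[, names(proto)]
}

#' Write an interpretation report
#'
#' JSON reports round-trip losslessly through [read_report()]; Markdown
#' reports render the category, drivers, phenotype scores and germline
#' findings for human review.
#'
#' @param report An `interpretation_report`.
#' @param path Output file.
#' @param format `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "markdown")) {
  format <- arg_match(format)
  stopifnot(inherits(report, "interpretation_report"))
  if (format == "json") {
    jsonlite::write_json(
      unclass(report), path,
      auto_unbox = TRUE, digits = NA, na = "null", null = "null", pretty = TRUE
    )
  } else {
    writeLines(render_markdown_report(report), path)
  }
  invisible(path)
}

#' Read a JSON interpretation report
#'
#' @param path JSON file written by [write_report()].
#' @return An `interpretation_report`.
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sig <- raw$signatures
  if (length(sig) > 0) {
    sig <- imap(sig, function(s, cl) {
      list(
        fractions = coerce_tbl(s$fractions, tibble(
          signature = character(), count = numeric(), fraction = numeric(),
          pct = numeric()
        )),
        cosine = as.numeric(s$cosine), active_set = as.character(s$active_set),
        refined = as.logical(s$refined), best_effort = as.logical(s$best_effort)
      )
    })
  } else {
    sig <- list()
  }
  new_interpretation_report(
    sample_id = raw$sample_id, cancer_type = raw$cancer_type,
    question = raw$question, interpretable = as.logical(raw$interpretable),
    tcf = as.numeric(raw$tcf), ploidy = as.numeric(raw$ploidy),
    drivers = coerce_tbl(raw$drivers, empty_driver_table()),
    phenotypes = coerce_tbl(raw$phenotypes, PHENOTYPE_PROTO()),
    signatures = sig,
    germline_findings = coerce_tbl(raw$germline_findings, GERMLINE_PROTO()),
    category = coerce_tbl(raw$category, CATEGORY_PROTO()),
    provenance = raw$provenance
  )
}

render_markdown_report <- function(report) {
  lines <- c(
    sprintf("# Genome interpretation report: %s", report$sample_id),
    "",
    sprintf("- Cancer type: %s", report$cancer_type),
    sprintf("- Question: %s", report$question),
    sprintf("- Tumor cell fraction: %.3f; ploidy: %.2f", report$tcf, report$ploidy)
  )
  if (!report$interpretable) {
    return(c(lines, "", "**Noninterpretable**: tumor cell fraction below 15%."))
  }
  ph <- report$phenotypes
  lines <- c(
    lines, "",
    sprintf("## Category: %s", report$category$category),
    if (nzchar(report$category$evidence)) paste0("Evidence: ", report$category$evidence),
    "",
    "## Phenotypes",
    sprintf("- TMB: %.2f mutations/Mb", ph$tmb),
    sprintf("- Whole-genome duplication: %s", ph$wgd),
    sprintf("- HRD probability: %.3f (%s)", ph$hrd_probability,
      ifelse(ph$hrd_positive, "positive", "negative")),
    sprintf("- MSI: %s (score %.1f, signature proportion %.3f)",
      ph$msi_call, ph$msisensor_like_score, ph$msi_signature_proportion),
    "",
    "## Drivers"
  )
  if (nrow(report$drivers) == 0) {
    lines <- c(lines, "(none)")
  } else {
    lines <- c(lines, sprintf(
      "- %s %s [%s] (%s)", report$drivers$gene,
      dplyr::coalesce(report$drivers$descriptor, report$drivers$alteration_type),
      report$drivers$driver_class, report$drivers$evidence
    ))
  }
  lines <- c(lines, "", "## Germline findings")
  if (nrow(report$germline_findings) == 0) {
    lines <- c(lines, "(none)")
  } else {
    lines <- c(lines, sprintf(
      "- %s %s (%s)%s", report$germline_findings$gene,
      report$germline_findings$hgvs_p, report$germline_findings$clinvar_class,
      ifelse(nzchar(report$germline_findings$second_hit_mechanisms),
        paste0("; second hit: ", report$germline_findings$second_hit_mechanisms), ""
      )
    ))
  }
  lines
}

#' Run the pipeline from a configuration
#'
#' Accepts either a [simulation_config()] (the call set is generated) or a
#' list of input file paths (`variants`, `svs`, `segments`, `germline`,
#' `microsatellites`, plus `sample_id`, `tcf`, `ploidy`, `cancer_type`,
#' `question`). Writes the filtered tables, exposures and the JSON +
#' Markdown reports under `output_dir`; a structured run log records every
#' threshold actually applied. Stage failures raise an error naming the
#' stage.
#'
#' @param config Configuration (see above).
#' @param output_dir Output directory (created if needed).
#' @param kb,references,thresholds See [interpret_sample()].
#' @return The `interpretation_report`, invisibly.
#' @export
run_pipeline <- function(config, output_dir, kb = default_gene_kb(),
                         references = default_signature_references(),
                         thresholds = filter_thresholds()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  if (inherits(config, "simulation_config")) {
    sim <- stage("simulate", simulate_callset(config, references, kb))
    variants <- sim$variants
    svs <- sim$svs
    profile <- sim$profile
    germline <- sim$germline
    msites <- sim$microsatellites
    cancer_type <- config$cancer_type
    question <- config$question
    stage("simulate", readr::write_tsv(
      ground_truth_manifest(sim$ground_truth),
      file.path(output_dir, "ground_truth_manifest.tsv"), progress = FALSE
    ))
  } else {
    for (need in c("variants", "segments")) {
      if (is.null(config[[need]])) {
        abort(sprintf(
          "pipeline stage 'inputs' failed: missing '%s' input (required by the %s stage)",
          need, if (need == "segments") "phenotypes/drivers" else "filter"
        ))
      }
    }
    variants <- stage("inputs", read_variant_table(config$variants, config$dialect %||% "tsv"))
    svs <- if (!is.null(config$svs)) stage("inputs", read_sv_table(config$svs)) else empty_sv_table()
    segments <- stage("inputs", read_segments(config$segments))
    profile <- stage("inputs", tumor_profile(
      config$sample_id %||% "sample", config$tcf, config$ploidy, segments,
      sample_type = config$sample_type %||% "fresh",
      acquisition = config$acquisition %||% "surgery"
    ))
    germline <- if (!is.null(config$germline)) {
      stage("inputs", validate_germline(readr::read_tsv(
        config$germline, col_types = "ccdcl", progress = FALSE, show_col_types = FALSE
      )))
    } else {
      GERMLINE_PROTO()[, 1:5]
    }
    msites <- stage("inputs", read_microsatellite_table(config$microsatellites))
    cancer_type <- config$cancer_type %||% "other"
    question <- config$question %||% "actionability"
  }
  fv <- stage("filter", filter_snv_indel(variants, thresholds))
  fs <- stage("filter", filter_sv(svs, thresholds))
  write_variant_table(
    select(filter(fv, .data$pass), -dplyr::any_of(c("pass", "fail_reasons", "id"))),
    file.path(output_dir, "filtered_variants.tsv")
  )
  write_sv_table(
    select(filter(fs, .data$pass), -dplyr::any_of(c("pass", "fail_reasons", "id"))),
    file.path(output_dir, "filtered_svs.bedpe")
  )
  report <- stage("interpret", interpret_sample(
    variants, svs, profile, germline, msites, cancer_type, question,
    kb = kb, references = references, thresholds = thresholds
  ))
  write_report(report, file.path(output_dir, "report.json"), "json")
  write_report(report, file.path(output_dir, "report.md"), "markdown")
  log_lines <- c(
    sprintf("sample: %s", profile$sample_id),
    sprintf("thresholds: %s", jsonlite::toJSON(unclass(thresholds), auto_unbox = TRUE)),
    sprintf("vaf_ceiling_applies_to: %s", thresholds$vaf_ceiling_applies_to),
    sprintf("records_in: %d variants, %d svs", nrow(variants), nrow(svs)),
    sprintf("records_pass: %d variants, %d svs", sum(fv$pass), sum(fs$pass)),
    sprintf("category: %s", if (nrow(report$category) > 0) report$category$category else "noninterpretable")
  )
  writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  invisible(report)
}
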