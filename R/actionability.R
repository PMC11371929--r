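# Actionability and clarity categorization.
#
# Actionability arm (precedence I-1 > I-2 > I-3 > none):
#   I-1  approved therapy matched to a driver or phenotype (MSI-H -> immune
#        checkpoint therapy; HRD-positive in approved indications -> PARP
#        inhibitor),
#   I-2  clinical-trial match,
#   I-3  a resistance rule fires with no I-1/I-2 match (elimination of
#        ineffective options).
# Clarity arm (precedence II-1 > II-2 > II-3):
#   II-1 resistance/response mechanism (wild-type-allele hyperamplification
#        of the targeted gene),
#   II-2 tumor-origin evidence (tobacco etiology: SBS4 fraction >= 0.20 AND
#        ID3 fraction >= 0.20),
#   II-3 familial evaluation concluded (germline finding, or confidently
#        negative with low HRD).

KNOWN_CANCER_TYPES <- c(
  "lung_adenocarcinoma", "colorectal", "stomach", "breast", "prostate",
  "cholangiocarcinoma", "urothelial", "melanoma", "pancreatic", "ovarian"
)

match_driver_drugs <- function(drivers, kb, cancer_type, level) {
  hits <- list()
  for (i in seq_len(nrow(drivers))) {
    d <- drivers[i, ]
    entry <- kb_entry(kb, d$gene)
    if (is.null(entry)) next
    alteration <- switch(d$alteration_type,
      point = "point", amplification = "amplification", fusion = "fusion",
      NULL
    )
    if (is.null(alteration)) next
    desc <- if (alteration == "point") d$descriptor else NULL
    matches <- kb_drug_matches(entry, alteration, desc, cancer_type)
    matches <- keep(matches, ~ identical(.x$evidence, level))
    for (m in matches) {
      hits[[length(hits) + 1]] <- sprintf(
        "%s %s -> %s%s", d$gene,
        if (alteration == "point") d$descriptor else alteration,
        m$drug, if (!is.null(m$trial_id)) paste0(" (", m$trial_id, ")") else ""
      )
    }
  }
  unlist(hits) %||% character()
}

match_phenotype_rules <- function(phenotypes, kb, cancer_type, level) {
  hits <- character()
  for (r in kb$phenotype_rules) {
    if (!identical(r$evidence, level)) next
    fires <- switch(r$phenotype,
      msi_h = identical(phenotypes$msi_call, "MSI-H"),
      hrd = isTRUE(phenotypes$hrd_positive),
      FALSE
    )
    if (!fires) next
    types <- r$cancer_types
    if (!(identical(types, "any") || cancer_type %in% unlist(types))) next
    hits <- c(hits, sprintf(
      "%s -> %s%s", toupper(r$phenotype), r$drug,
      if (!is.null(r$trial_id)) paste0(" (", r$trial_id, ")") else ""
    ))
  }
  hits
}

match_resistance_rules <- function(drivers, kb, cancer_type) {
  hits <- character()
  point <- filter(drivers, .data$alteration_type == "point")
  for (i in seq_len(nrow(point))) {
    d <- point[i, ]
    entry <- kb_entry(kb, d$gene)
    if (is.null(entry)) next
    hotspot_descs <- map_chr(entry$hotspots, "descriptor")
    for (r in entry$resistance_rules) {
      if (!cancer_type %in% unlist(r$cancer_types)) next
      descs <- if (identical(r$descriptors, "any_hotspot")) hotspot_descs else unlist(r$descriptors)
      descs <- setdiff(descs, unlist(r$except_descriptors))
      if (!is.na(d$descriptor) && d$descriptor %in% descs) {
        hits <- c(hits, sprintf(
          "%s %s -> avoid %s", d$gene, d$descriptor, r$excluded_therapy
        ))
      }
    }
  }
  hits
}

#' Assign the actionability or clarity category for one sample
#'
#' @param drivers Driver tibble from [call_drivers()].
#' @param phenotypes One-row `phenotype_report` from [compute_phenotypes()].
#' @param germline_findings Rows retained by [screen_germline()].
#' @param kb A `gene_kb`.
#' @param cancer_type Tumor type label; unknown types are evaluated with
#'   type-agnostic rules only and flagged.
#' @param question `"actionability"` or `"clarity"` (the reason the sample
#'   was referred).
#' @return One-row `category_assignment` tibble: `primary_question`,
#'   `category` (`I-1`, `I-2`, `I-3`, `II-1`, `II-2`, `II-3` or `none`),
#'   `evidence` (semicolon-joined matches), `type_agnostic`.
#' @export
assign_category <- function(drivers, phenotypes, germline_findings, kb,
                            cancer_type, question = c("actionability", "clarity")) {
  question <- arg_match(question)
  type_agnostic <- !cancer_type %in% KNOWN_CANCER_TYPES
  category <- "none"
  evidence <- character()
  if (question == "actionability") {
    approved <- c(
      match_driver_drugs(drivers, kb, cancer_type, "approved"),
      match_phenotype_rules(phenotypes, kb, cancer_type, "approved")
    )
    trial <- c(
      match_driver_drugs(drivers, kb, cancer_type, "trial"),
      match_phenotype_rules(phenotypes, kb, cancer_type, "trial")
    )
    resist <- match_resistance_rules(drivers, kb, cancer_type)
    if (length(approved) > 0) {
      category <- "I-1"; evidence <- approved
    } else if (length(trial) > 0) {
      category <- "I-2"; evidence <- trial
    } else if (length(resist) > 0) {
      category <- "I-3"; evidence <- resist
    }
  } else {
    wt_amp <- filter(drivers, grepl("wt_allele_amplification", .data$evidence))
    origin <- phenotypes$sbs4_fraction >= 0.20 && phenotypes$id3_fraction >= 0.20
    if (nrow(wt_amp) > 0) {
      category <- "II-1"
      evidence <- sprintf("%s wild-type allele hyperamplification", wt_amp$gene)
    } else if (origin) {
      category <- "II-2"
      evidence <- sprintf(
        "tobacco etiology: SBS4 %.1f%%, ID3 %.1f%% -> lung origin",
        100 * phenotypes$sbs4_fraction, 100 * phenotypes$id3_fraction
      )
    } else if (nrow(germline_findings) > 0) {
      category <- "II-3"
      evidence <- sprintf(
        "germline %s %s (%s)", germline_findings$gene, germline_findings$hgvs_p,
        germline_findings$clinvar_class
      )
    } else if (phenotypes$hrd_probability < 0.2) {
      category <- "II-3"
      evidence <- sprintf(
        "no germline finding; HRD %.3f -> familial cancer confidently unsupported",
        phenotypes$hrd_probability
      )
    }
  }
  structure(
    tibble(
      primary_question = question, category = category,
      evidence = paste(evidence, collapse = ";"), type_agnostic = type_agnostic
    ),
    class = c("category_assignment", class(tibble())))
}

#' Summarize category assignments over a cohort
#'
#' Per-arm category counts with percentages under half-up rounding
#' (raw, one-decimal and zero-decimal forms), per-arm supportive rates
#' (category other than `none`), the overall supportive rate, and - when
#' `n_enrolled` is given - the reported-over-enrolled success rate.
#'
#' @param assignments Tibble of `category_assignment` rows (one per
#'   reported sample).
#' @param n_enrolled Optional total enrolled count (reported samples are
#'   `nrow(assignments)`).
#' @return A `cohort_summary` tibble: `arm`, `category`, `n`,
#'   `denominator`, `pct`, `pct_1dp`, `pct_0dp`.
#' @export
summarize_cohort <- function(assignments, n_enrolled = NULL) {
  stopifnot(nrow(assignments) >= 1)
  mk <- function(arm, category, n, denom) {
    p <- 100 * n / denom
    tibble(
      arm = arm, category = category, n = as.integer(n),
      denominator = as.integer(denom),
      pct = p, pct_1dp = round_half_up(p, 1), pct_0dp = round_half_up(p, 0)
    )
  }
  rows <- list()
  for (arm in unique(assignments$primary_question)) {
    sub <- filter(assignments, .data$primary_question == arm)
    denom <- nrow(sub)
    for (cat in sort(unique(sub$category))) {
      rows <- c(rows, list(mk(arm, cat, sum(sub$category == cat), denom)))
    }
    rows <- c(rows, list(mk(arm, "supportive", sum(sub$category != "none"), denom)))
  }
  rows <- c(rows, list(mk(
    "overall", "supportive", sum(assignments$category != "none"), nrow(assignments)
  )))
  if (!is.null(n_enrolled)) {
    rows <- c(rows, list(mk("cohort", "reported", nrow(assignments), n_enrolled)))
  }
  out <- bind_rows(rows)
  structure(out, class = c("cohort_summary", class(out)))
}
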