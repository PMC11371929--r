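# Driver interpretation: oncogene/TSG point-driver rules, copy-number
# drivers relative to ploidy, gene fusions from SV breakpoints, germline
# screening and somatic second hits.
#
# Point-driver criteria:
#   oncogene - missense / in-frame indel / promoter alterations that are
#   either recurrent (COSMIC-style hotspot count >= the recurrence
#   threshold) or linked to an actionable drug;
#   TSG - truncating alterations (frameshift, nonsense, splice), or
#   missense predicted deleterious by SIFT/PolyPhen or pathogenic in
#   ClinVar.
# Copy-number criteria (gene CN = length-weighted mean of overlapping
# segments' total copy number):
#   amplification at CN >= ploidy + 5 (inclusive), relaxed to ploidy + 1
#   when any targeted drug is linked to the gene; hyperamplification is
#   additionally annotated at CN >= 50 (ecDNA-scale flag);
#   biallelic deletion at CN <= 0.5, or CN < 1 with an overlapping
#   zero-total-copy segment.

ONCOGENE_CLASSES <- c("missense", "inframe_indel", "promoter")
TSG_TRUNCATING <- c("frameshift", "nonsense", "splice")

empty_driver_table <- function() {
  tibble(
    gene = character(), alteration_type = character(), descriptor = character(),
    driver_class = character(), evidence = character(), cn = numeric()
  )
}

#' Classify one somatic variant under the oncogene/TSG driver rules
#'
#' @param variant A one-row variant tibble (must have passed somatic
#'   filtering).
#' @param kb_entry The gene's knowledgebase entry ([kb_entry()]).
#' @param cosmic_min Hotspot recurrence threshold (default: the
#'   knowledgebase's, normally 10).
#' @return A one-row driver tibble, or `NULL` when the variant does not
#'   qualify (including gene absent from the knowledgebase, with a note).
#' @export
classify_point_driver <- function(variant, kb_entry,
                                  cosmic_min = NULL) {
  if (is.null(kb_entry)) {
    note(paste0("gene not in knowledgebase: ", variant$gene))
    return(NULL)
  }
  cosmic_min <- cosmic_min %||% 10
  vc <- variant$variant_class
  desc <- variant$descriptor
  evidence <- character()
  driver_class <- NULL
  role <- kb_entry$role
  if (role %in% c("oncogene", "both") && vc %in% ONCOGENE_CLASSES) {
    hs <- keep(kb_entry$hotspots, ~ identical(.x$descriptor, desc))
    recurrent <- length(hs) > 0 && any(map_dbl(hs, "cosmic_count") >= cosmic_min)
    drugged <- !is.na(desc) && kb_has_drug(kb_entry, "point", desc)
    if (recurrent) evidence <- c(evidence, "cosmic_recurrent_hotspot")
    if (drugged) evidence <- c(evidence, "actionable_drug")
    if (recurrent || drugged) {
      evidence <- c(paste0("oncogene_alteration_", vc), evidence)
      driver_class <- "oncogene_point"
    }
  }
  if (is.null(driver_class) && role %in% c("tsg", "both")) {
    if (vc %in% TSG_TRUNCATING) {
      evidence <- c(paste0("tsg_truncating_", vc))
      driver_class <- "tsg_inactivating"
    } else if (vc == "missense" && !is.na(desc)) {
      pred <- kb_entry$deleterious[[desc]]
      hits <- c(
        if (isTRUE(pred$sift)) "sift_deleterious",
        if (isTRUE(pred$polyphen)) "polyphen_deleterious",
        if (isTRUE(pred$clinvar)) "clinvar_pathogenic"
      )
      if (length(hits) > 0) {
        evidence <- c("tsg_missense", hits)
        driver_class <- "tsg_inactivating"
      }
    }
  }
  if (is.null(driver_class)) return(NULL)
  tibble(
    gene = variant$gene, alteration_type = "point", descriptor = desc,
    driver_class = driver_class, evidence = paste(evidence, collapse = ";"),
    cn = NA_real_
  )
}

#' Classify all passing variants against the knowledgebase
#'
#' @param variants Filtered variant tibble (rows with `pass == TRUE` are
#'   used if a `pass` column is present).
#' @param kb A `gene_kb`.
#' @param cosmic_min Hotspot recurrence threshold.
#' @return Driver tibble (zero or more rows).
#' @export
classify_point_drivers <- function(variants, kb = default_gene_kb(),
                                   cosmic_min = NULL) {
  cosmic_min <- cosmic_min %||% kb$cosmic_recurrence_threshold
  if ("pass" %in% names(variants)) variants <- filter(variants, .data$pass)
  cand <- filter(variants, .data$gene %in% names(kb$genes))
  if (nrow(cand) == 0) return(empty_driver_table())
  calls <- map(seq_len(nrow(cand)), function(i) {
    classify_point_driver(cand[i, ], kb_entry(kb, cand$gene[i]), cosmic_min)
  })
  out <- bind_rows(calls)
  if (nrow(out) == 0) empty_driver_table() else distinct(out)
}

#' Length-weighted gene copy number
#'
#' Gene CN is the mean of overlapping segments' total copy number weighted
#' by overlap length (a max-segment rule is available via `method`).
#'
#' @param profile A `tumor_profile`.
#' @param kb_entry Gene knowledgebase entry (provides the interval).
#' @param method `"weighted_mean"` (default) or `"max_segment"`.
#' @return Gene copy number, or `NA` when no segment overlaps the gene.
#' @export
gene_copy_number <- function(profile, kb_entry, method = c("weighted_mean", "max_segment")) {
  method <- arg_match(method)
  segs <- filter(
    profile$segments,
    .data$chrom == kb_entry$chrom,
    .data$start <= kb_entry$end, .data$end >= kb_entry$start
  )
  if (nrow(segs) == 0) return(NA_real_)
  ov <- pmin(segs$end, kb_entry$end) - pmax(segs$start, kb_entry$start) + 1
  if (method == "weighted_mean") {
    sum(segs$total_cn * ov) / sum(ov)
  } else {
    segs$total_cn[which.max(ov)]
  }
}

#' Call an oncogenic amplification for one gene
#'
#' Amplification when gene CN >= ploidy + 5 (inclusive), or >= ploidy + 1
#' when a targeted drug is linked to the gene. CN >= `hyper_cn` (default
#' 50) is additionally annotated as hyperamplification - an ecDNA-scale
#' flag that does not change amplification status.
#'
#' @param gene Gene symbol.
#' @param profile A `tumor_profile`.
#' @param kb_entry The gene's knowledgebase entry.
#' @param hyper_cn Hyperamplification annotation threshold.
#' @return One-row driver tibble or `NULL`.
#' @export
call_amplification <- function(gene, profile, kb_entry, hyper_cn = 50) {
  cn <- gene_copy_number(profile, kb_entry)
  if (is.na(cn)) {
    note(paste0("no segment overlaps ", gene))
    return(NULL)
  }
  drugged <- length(kb_entry$drugs) > 0
  cutoff <- profile$ploidy + if (drugged) 1 else 5
  if (cn < cutoff) return(NULL)
  evidence <- sprintf(
    "cn_%.1f_ge_ploidy_plus_%d", cn, if (drugged) 1L else 5L
  )
  hyper <- cn >= hyper_cn
  if (hyper) evidence <- paste(evidence, "hyperamplification_cn_ge_50", sep = ";")
  tibble(
    gene = gene, alteration_type = "amplification", descriptor = NA_character_,
    driver_class = if (hyper) "hyperamplification" else "amplification",
    evidence = evidence, cn = cn
  )
}

#' Call a TSG biallelic deletion for one gene
#'
#' Deletion when gene CN <= 0.5 (inclusive), or gene CN < 1 with an
#' overlapping segment of total copy number 0.
#'
#' @inheritParams call_amplification
#' @return One-row driver tibble or `NULL`.
#' @export
call_biallelic_deletion <- function(gene, profile, kb_entry) {
  cn <- gene_copy_number(profile, kb_entry)
  if (is.na(cn)) {
    note(paste0("no segment overlaps ", gene))
    return(NULL)
  }
  segs <- filter(
    profile$segments,
    .data$chrom == kb_entry$chrom,
    .data$start <= kb_entry$end, .data$end >= kb_entry$start
  )
  zero_seg <- any(segs$total_cn == 0)
  if (cn <= 0.5) {
    evidence <- sprintf("gene_cn_%.2f_le_0.5", cn)
  } else if (cn < 1 && zero_seg) {
    evidence <- sprintf("gene_cn_%.2f_lt_1_with_zero_segment", cn)
  } else {
    return(NULL)
  }
  tibble(
    gene = gene, alteration_type = "deletion", descriptor = NA_character_,
    driver_class = "biallelic_deletion", evidence = evidence, cn = cn
  )
}

#' Copy-number driver calls across the knowledgebase
#'
#' Evaluates amplification for oncogenes and biallelic deletion for tumor
#' suppressors over every knowledgebase gene with segment coverage.
#'
#' @param profile A `tumor_profile`.
#' @param kb A `gene_kb`.
#' @return Driver tibble.
#' @export
call_cn_drivers <- function(profile, kb = default_gene_kb()) {
  calls <- map(kb$genes, function(entry) {
    out <- list()
    if (entry$role %in% c("oncogene", "both")) {
      out <- c(out, list(call_amplification(entry$gene, profile, entry)))
    }
    if (entry$role %in% c("tsg", "both")) {
      out <- c(out, list(call_biallelic_deletion(entry$gene, profile, entry)))
    }
    bind_rows(out)
  })
  out <- bind_rows(calls)
  if (nrow(out) == 0) empty_driver_table() else out
}

gene_at_breakpoint <- function(kb, chrom, pos) {
  hit <- filter(
    kb$gene_table,
    .data$chrom == !!chrom, .data$start <= !!pos, .data$end >= !!pos
  )
  if (nrow(hit) == 0) NULL else hit[1, ]
}

#' Detect gene fusions from structural-variant breakpoints
#'
#' A fusion is reported when one breakpoint falls inside gene A and the
#' other inside gene B (A != B), the pair is on the curated allowlist or
#' one partner is a known fusion driver (which then acts as the 3'
#' partner), and the breakend orientations are compatible with a
#' head-to-tail transcript. Orientation convention: a `+` breakend retains
#' the segment left of the breakpoint on the derivative chromosome, so a
#' 5' partner on the forward strand requires `+` and a 3' partner on the
#' forward strand requires `-` (swapped for reverse-strand genes).
#'
#' @param svs Filtered SV tibble (rows with `pass == TRUE` are used if a
#'   `pass` column is present).
#' @param kb A `gene_kb`.
#' @return Driver tibble; fusion rows carry the 3' driver partner in
#'   `gene` and `"5p-3p"` in `descriptor`.
#' @export
detect_gene_fusions <- function(svs, kb = default_gene_kb()) {
  if ("pass" %in% names(svs)) svs <- filter(svs, .data$pass)
  if (nrow(svs) == 0) return(empty_driver_table())
  allow <- map_chr(kb$fusion_pairs, ~ paste(.x, collapse = ">"))
  calls <- list()
  for (i in seq_len(nrow(svs))) {
    ga <- gene_at_breakpoint(kb, svs$chrom1[i], svs$pos1[i])
    gb <- gene_at_breakpoint(kb, svs$chrom2[i], svs$pos2[i])
    if (is.null(ga) || is.null(gb) || ga$gene == gb$gene) next
    # candidate 5'/3' assignments with their breakend strands
    cands <- list(
      list(five = ga, three = gb, s5 = svs$strand1[i], s3 = svs$strand2[i]),
      list(five = gb, three = ga, s5 = svs$strand2[i], s3 = svs$strand1[i])
    )
    for (cd in cands) {
      allowed <- paste(cd$five$gene, cd$three$gene, sep = ">") %in% allow ||
        cd$three$fusion_driver
      if (!allowed) next
      ok <- identical(cd$s5, fusion_orientation(cd$five$strand, TRUE)) &&
        identical(cd$s3, fusion_orientation(cd$three$strand, FALSE))
      if (!ok) next
      calls[[length(calls) + 1]] <- tibble(
        gene = cd$three$gene, alteration_type = "fusion",
        descriptor = paste0(cd$five$gene, "-", cd$three$gene),
        driver_class = "fusion",
        evidence = sprintf(
          "breakpoints_in_%s_and_%s;orientation_compatible",
          cd$five$gene, cd$three$gene
        ),
        cn = NA_real_
      )
      break
    }
  }
  out <- bind_rows(calls)
  if (nrow(out) == 0) empty_driver_table() else distinct(out)
}

#' Screen germline variants for reportable findings
#'
#' Keeps variants that are rare (population allele frequency < 0.5%,
#' strict), pathogenic or likely pathogenic in ClinVar, and in a cancer
#' predisposition gene.
#'
#' @param germline_variants Germline tibble (see [validate_germline()]).
#' @param kb A `gene_kb` (provides the predisposition list), or a character
#'   vector of predisposition genes.
#' @return The retained rows.
#' @export
screen_germline <- function(germline_variants, kb = default_gene_kb()) {
  germline_variants <- validate_germline(germline_variants)
  predisposition <- if (inherits(kb, "gene_kb")) kb$predisposition_genes else kb
  filter(
    germline_variants,
    .data$population_af < 0.005,
    .data$clinvar_class %in% c("pathogenic", "likely_pathogenic"),
    .data$gene %in% predisposition
  )
}

#' Detect a somatic second hit for one germline finding
#'
#' Evidence for biallelic inactivation: (a) LOH at the locus (an
#' overlapping segment with minor copy number 0), or (b) a passing somatic
#' truncating variant, biallelic deletion, or gene-disrupting SV in the
#' same gene. Returns the mechanisms found, by name.
#'
#' @param germline_hit One row retained by [screen_germline()].
#' @param somatic_variants Filtered variant tibble.
#' @param profile A `tumor_profile`.
#' @param svs Optional filtered SV tibble.
#' @param kb A `gene_kb`.
#' @return Character vector of mechanisms (empty when none).
#' @export
detect_second_hit <- function(germline_hit, somatic_variants, profile,
                              svs = NULL, kb = default_gene_kb()) {
  entry <- kb_entry(kb, germline_hit$gene)
  if (is.null(entry)) return(character())
  mechanisms <- character()
  segs <- filter(
    profile$segments,
    .data$chrom == entry$chrom, .data$start <= entry$end, .data$end >= entry$start
  )
  if (nrow(segs) > 0 && any(segs$minor_cn == 0)) {
    mechanisms <- c(mechanisms, "loh")
  }
  if ("pass" %in% names(somatic_variants)) {
    somatic_variants <- filter(somatic_variants, .data$pass)
  }
  trunc <- filter(
    somatic_variants,
    .data$gene == entry$gene, .data$variant_class %in% TSG_TRUNCATING
  )
  if (nrow(trunc) > 0) mechanisms <- c(mechanisms, "somatic_truncating")
  del <- call_biallelic_deletion(entry$gene, profile, entry)
  if (!is.null(del)) mechanisms <- c(mechanisms, "biallelic_deletion")
  if (!is.null(svs) && nrow(svs) > 0) {
    if ("pass" %in% names(svs)) svs <- filter(svs, .data$pass)
    inside <- function(chrom, pos) {
      chrom == entry$chrom & pos >= entry$start & pos <= entry$end
    }
    disrupt <- inside(svs$chrom1, svs$pos1) | inside(svs$chrom2, svs$pos2)
    if (any(disrupt)) mechanisms <- c(mechanisms, "disruptive_sv")
  }
  mechanisms
}

#' Somatic biallelic TSG inactivation without a germline hit
#'
#' Flags tumor suppressors disrupted by a passing somatic truncating
#' variant or gene-disrupting SV combined with LOH at the locus (the
#' two-somatic-hit pattern).
#'
#' @param variants Filtered variant tibble.
#' @param svs Filtered SV tibble.
#' @param profile A `tumor_profile`.
#' @param kb A `gene_kb`.
#' @return Driver tibble.
#' @export
detect_somatic_biallelic <- function(variants, svs, profile, kb = default_gene_kb()) {
  if ("pass" %in% names(variants)) variants <- filter(variants, .data$pass)
  if ("pass" %in% names(svs)) svs <- filter(svs, .data$pass)
  tsgs <- filter(kb$gene_table, .data$role %in% c("tsg", "both"))
  calls <- list()
  for (i in seq_len(nrow(tsgs))) {
    entry <- kb_entry(kb, tsgs$gene[i])
    segs <- filter(
      profile$segments,
      .data$chrom == entry$chrom, .data$start <= entry$end, .data$end >= entry$start
    )
    loh <- nrow(segs) > 0 && any(segs$minor_cn == 0)
    if (!loh) next
    trunc <- nrow(filter(
      variants, .data$gene == entry$gene, .data$variant_class %in% TSG_TRUNCATING
    )) > 0
    disrupt <- FALSE
    if (nrow(svs) > 0) {
      inside <- function(chrom, pos) {
        chrom == entry$chrom & pos >= entry$start & pos <= entry$end
      }
      disrupt <- any(inside(svs$chrom1, svs$pos1) | inside(svs$chrom2, svs$pos2))
    }
    if (trunc || disrupt) {
      mech <- c(if (trunc) "somatic_truncating", if (disrupt) "disruptive_sv")
      calls[[length(calls) + 1]] <- tibble(
        gene = entry$gene, alteration_type = "biallelic_inactivation",
        descriptor = NA_character_, driver_class = "tsg_inactivating",
        evidence = paste(c(mech, "loh"), collapse = ";"), cn = NA_real_
      )
    }
  }
  out <- bind_rows(calls)
  if (nrow(out) == 0) empty_driver_table() else out
}

#' All driver calls for one sample
#'
#' Combines point drivers, copy-number drivers, fusions, and somatic
#' biallelic TSG inactivation; annotates hyperamplified genes whose
#' observed mutant allele fraction is under half the allele-balanced
#' expectation with `wt_allele_amplification` evidence (the
#' resistance-mechanism pattern). Output is canonicalized by gene and
#' class, so input order never changes the result.
#'
#' @param variants Filtered variant tibble.
#' @param svs Filtered SV tibble.
#' @param profile A `tumor_profile`.
#' @param kb A `gene_kb`.
#' @return Driver tibble.
#' @export
call_drivers <- function(variants, svs, profile, kb = default_gene_kb()) {
  drivers <- bind_rows(
    classify_point_drivers(variants, kb),
    call_cn_drivers(profile, kb),
    detect_gene_fusions(svs, kb),
    detect_somatic_biallelic(variants, svs, profile, kb)
  )
  if (nrow(drivers) == 0) return(empty_driver_table())
  # wild-type-allele hyperamplification: targeted point mutation at far
  # lower VAF than an allele-balanced amplification would give
  hyper <- filter(drivers, .data$driver_class == "hyperamplification")
  if (nrow(hyper) > 0 && nrow(variants) > 0) {
    pv <- if ("pass" %in% names(variants)) filter(variants, .data$pass) else variants
    for (g in hyper$gene) {
      muts <- filter(pv, .data$gene == g, .data$variant_type == "snv")
      if (nrow(muts) == 0) next
      cn <- hyper$cn[hyper$gene == g][1]
      expected <- expected_vaf(profile$tcf, cn, mult = cn / 2)
      observed <- muts$tumor_alt / pmax(muts$tumor_depth, 1)
      if (any(observed < 0.5 * expected)) {
        idx <- drivers$gene == g & drivers$driver_class == "hyperamplification"
        drivers$evidence[idx] <- paste(
          drivers$evidence[idx], "wt_allele_amplification", sep = ";"
        )
      }
    }
  }
  drivers |>
    arrange(.data$gene, .data$driver_class, .data$descriptor) |>
    distinct()
}
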