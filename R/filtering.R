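# High-confidence somatic filtering for SNV/indel and SV calls.
#
# A point call passes when: tumor variant reads >= 2, normal variant reads
# <= 1, mapping quality >= 15, normal-sample VAF <= 5%, and panel-of-normals
# allele frequency <= 1%. All boundaries are inclusive on the passing side.
# The 5% VAF ceiling is applied to the NORMAL sample by default (a tumor
# ceiling of 5% would discard nearly all true somatic calls; a normal
# ceiling is a standard contamination guard); the alternative tumor reading
# is available via `vaf_ceiling_applies_to`.
#
# An SV passes when: tumor support >= 2, normal support <= 1, mapping
# quality >= 15, and panel-of-normals frequency <= 5% (strictly greater is
# excluded).

#' Somatic filter thresholds
#'
#' @param min_tumor_alt Minimum tumor variant reads (default 2).
#' @param max_normal_alt Maximum normal variant reads (default 1).
#' @param min_mapping_quality Minimum mapping quality (default 15).
#' @param max_normal_vaf Maximum variant allele frequency in the sample
#'   named by `vaf_ceiling_applies_to` (default 0.05).
#' @param max_pon_af Maximum panel-of-normals allele frequency for
#'   SNVs/indels (default 0.01).
#' @param sv_min_tumor_support,sv_max_normal_support,sv_min_mq,sv_max_pon_freq
#'   The SV criteria (defaults 2, 1, 15, 0.05).
#' @param vaf_ceiling_applies_to `"normal"` (default) or `"tumor"`; which
#'   sample the VAF ceiling is applied to.
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_tumor_alt = 2, max_normal_alt = 1,
                              min_mapping_quality = 15, max_normal_vaf = 0.05,
                              max_pon_af = 0.01, sv_min_tumor_support = 2,
                              sv_max_normal_support = 1, sv_min_mq = 15,
                              sv_max_pon_freq = 0.05,
                              vaf_ceiling_applies_to = c("normal", "tumor")) {
  vaf_ceiling_applies_to <- arg_match(vaf_ceiling_applies_to)
  th <- list(
    min_tumor_alt = min_tumor_alt, max_normal_alt = max_normal_alt,
    min_mapping_quality = min_mapping_quality, max_normal_vaf = max_normal_vaf,
    max_pon_af = max_pon_af, sv_min_tumor_support = sv_min_tumor_support,
    sv_max_normal_support = sv_max_normal_support, sv_min_mq = sv_min_mq,
    sv_max_pon_freq = sv_max_pon_freq,
    vaf_ceiling_applies_to = vaf_ceiling_applies_to
  )
  nums <- unlist(th[1:9])
  if (any(nums < 0)) stop_validate("thresholds must be non-negative")
  if (th$max_normal_vaf > 1 || th$max_pon_af > 1 || th$sv_max_pon_freq > 1) {
    stop_validate("fractional thresholds must be <= 1")
  }
  structure(th, class = "filter_thresholds")
}

join_reasons <- function(mat) {
  apply(mat, 1, function(fails) paste(colnames(mat)[fails], collapse = ";"))
}

#' Filter somatic SNV/indel calls
#'
#' Applies the high-confidence criteria and returns the input annotated with
#' a `pass` flag and a `fail_reasons` column naming every violated criterion
#' (semicolon-separated, empty for passing records). Records with zero
#' normal depth are treated as normal VAF 0 with a note rather than a
#' division error.
#'
#' @param variants A validated variant tibble.
#' @param thresholds A [filter_thresholds()] object.
#' @return The annotated tibble; `dplyr::filter(out, pass)` gives the
#'   high-confidence set.
#' @export
filter_snv_indel <- function(variants, thresholds = filter_thresholds()) {
  variants <- validate_variants(variants)
  if (nrow(variants) == 0) {
    return(mutate(variants, pass = logical(0), fail_reasons = character(0)))
  }
  zero_nd <- variants$normal_depth == 0
  if (any(zero_nd)) {
    note(sprintf(
      "%d record(s) with zero normal depth; normal VAF treated as 0", sum(zero_nd)
    ))
  }
  normal_vaf <- ifelse(zero_nd, 0, variants$normal_alt / pmax(variants$normal_depth, 1))
  tumor_vaf <- ifelse(variants$tumor_depth == 0, 0,
    variants$tumor_alt / pmax(variants$tumor_depth, 1)
  )
  vaf <- if (thresholds$vaf_ceiling_applies_to == "normal") normal_vaf else tumor_vaf
  vaf_name <- paste0("max_", thresholds$vaf_ceiling_applies_to, "_vaf")
  fails <- cbind(
    min_tumor_alt = variants$tumor_alt < thresholds$min_tumor_alt,
    max_normal_alt = variants$normal_alt > thresholds$max_normal_alt,
    min_mapping_quality = variants$mapping_quality < thresholds$min_mapping_quality,
    vaf = vaf > thresholds$max_normal_vaf,
    max_pon_af = variants$pon_af > thresholds$max_pon_af
  )
  colnames(fails)[4] <- vaf_name
  mutate(variants, pass = rowSums(fails) == 0, fail_reasons = join_reasons(fails))
}

#' Filter somatic structural variants
#'
#' @param svs A validated SV tibble.
#' @param thresholds A [filter_thresholds()] object.
#' @return The annotated tibble with `pass` and `fail_reasons` columns.
#' @export
filter_sv <- function(svs, thresholds = filter_thresholds()) {
  svs <- validate_svs(svs)
  if (nrow(svs) == 0) {
    return(mutate(svs, pass = logical(0), fail_reasons = character(0)))
  }
  fails <- cbind(
    sv_min_tumor_support = svs$tumor_support < thresholds$sv_min_tumor_support,
    sv_max_normal_support = svs$normal_support > thresholds$sv_max_normal_support,
    sv_min_mq = svs$mapping_quality < thresholds$sv_min_mq,
    sv_max_pon_freq = svs$pon_freq > thresholds$sv_max_pon_freq
  )
  mutate(svs, pass = rowSums(fails) == 0, fail_reasons = join_reasons(fails))
}
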