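# Readers and writers for the external representations: variant tables
# (TSV or a tumor/normal VCF subset), SV tables (BEDPE), copy-number
# segments (SEG-style TSV), signature matrices (TSV, channels x signatures),
# microsatellite site tables (long TSV), and interpretation reports
# (JSON / Markdown).
#
# Coordinates are 1-based inclusive everywhere in memory (VCF convention).
# BEDPE emission converts to 0-based half-open at the boundary and back
# losslessly.

VARIANT_CLASSES <- c(
  "missense", "nonsense", "frameshift", "inframe_indel", "splice",
  "synonymous", "promoter", "other"
)

VARIANT_COLS <- c(
  "chrom", "pos", "ref", "alt", "variant_class", "gene", "descriptor",
  "tumor_depth", "tumor_alt", "normal_depth", "normal_alt",
  "mapping_quality", "pon_af", "trinucleotide_context",
  "rep_unit_size", "rep_count", "mh_len"
)

SV_COLS <- c(
  "chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2", "sv_type",
  "size", "tumor_support", "normal_support", "mapping_quality", "pon_freq",
  "homology_len"
)

#' Validate a somatic variant table
#'
#' Checks the record invariants: read-count consistency (`tumor_alt <=
#' tumor_depth`, `normal_alt <= normal_depth`), 1-based positions,
#' panel-of-normals allele frequency in `[0, 1]`, and that SNVs carry a
#' trinucleotide context while indels carry repeat/microhomology features.
#'
#' @param variants A variant tibble (see [read_variant_table()] for columns).
#' @return The validated tibble, with a `variant_type` column (`"snv"` /
#'   `"indel"`) added if absent.
#' @export
validate_variants <- function(variants) {
  variants <- as_tibble(variants)
  if (!"descriptor" %in% names(variants)) {
    variants$descriptor <- rep(NA_character_, nrow(variants))
  }
  missing_cols <- setdiff(VARIANT_COLS, names(variants))
  if (length(missing_cols) > 0) {
    stop_validate(paste0("missing variant columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!"variant_type" %in% names(variants)) {
    variants <- mutate(variants,
      variant_type = ifelse(nchar(.data$ref) == 1 & nchar(.data$alt) == 1, "snv", "indel")
    )
  }
  if (nrow(variants) == 0) return(variants)
  with(variants, {
    if (any(pos < 1)) stop_validate("positions must be >= 1")
    if (any(tumor_alt > tumor_depth)) stop_validate("tumor_alt exceeds tumor_depth")
    if (any(normal_alt > normal_depth)) stop_validate("normal_alt exceeds normal_depth")
    if (any(tumor_alt < 0 | normal_alt < 0 | tumor_depth < 0 | normal_depth < 0)) {
      stop_validate("read counts must be non-negative")
    }
    if (any(pon_af < 0 | pon_af > 1)) stop_validate("pon_af must lie in [0, 1]")
    if (any(mapping_quality < 0)) stop_validate("mapping_quality must be non-negative")
  })
  snv <- variants$variant_type == "snv"
  if (any(snv & is.na(variants$trinucleotide_context))) {
    stop_validate("SNV records must carry a trinucleotide_context")
  }
  if (any(!snv & (is.na(variants$rep_unit_size) | is.na(variants$rep_count) |
    is.na(variants$mh_len)))) {
    stop_validate("indel records must carry repeat/microhomology features")
  }
  if (any(snv & !is.na(variants$rep_unit_size))) {
    stop_validate("SNV records must not carry indel features")
  }
  variants
}

variant_col_types <- function() {
  readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    variant_class = readr::col_character(), gene = readr::col_character(),
    descriptor = readr::col_character(),
    tumor_depth = readr::col_integer(), tumor_alt = readr::col_integer(),
    normal_depth = readr::col_integer(), normal_alt = readr::col_integer(),
    mapping_quality = readr::col_double(), pon_af = readr::col_double(),
    trinucleotide_context = readr::col_character(),
    rep_unit_size = readr::col_integer(), rep_count = readr::col_integer(),
    mh_len = readr::col_integer(), .default = readr::col_character()
  )
}

#' Read a somatic SNV/indel table
#'
#' Reads tumor/normal somatic calls from either a TSV with the package's
#' column layout or a minimal tumor/normal VCF v4.2 subset (INFO keys `MQ`,
#' `PON_AF`, `GENE`, `VC`, `TNC`, `RUS`, `RC`, `MH`; per-sample `FORMAT`
#' fields `AD` and `DP` for the TUMOR and NORMAL columns). Unknown TSV
#' columns are ignored with a note. Records are validated on the way in.
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return A validated variant tibble.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- arg_match(dialect)
  if (!file.exists(path)) stop_validate(paste0("no such file: ", path))
  if (dialect == "tsv") {
    df <- readr::read_tsv(path,
      col_types = variant_col_types(), progress = FALSE,
      na = c("", "NA"), show_col_types = FALSE
    )
    probs <- readr::problems(df)
    if (nrow(probs) > 0) {
      stop_parse(paste0("malformed variant row: ", probs$expected[1]),
        line = probs$row[1] + 1L
      )
    }
    extra <- setdiff(names(df), c(VARIANT_COLS, "variant_type"))
    if (length(extra) > 0) {
      note(paste0("ignoring unknown variant columns: ", paste(extra, collapse = ", ")))
      df <- select(df, -dplyr::all_of(extra))
    }
    if ("gene" %in% names(df)) df$gene <- dplyr::coalesce(df$gene, "")
    validate_variants(df)
  } else {
    read_variant_vcf(path)
  }
}

#' Write a somatic SNV/indel table
#'
#' @param variants A validated variant tibble.
#' @param path Output file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path, dialect = c("tsv", "vcf")) {
  dialect <- arg_match(dialect)
  variants <- validate_variants(variants)
  if (dialect == "tsv") {
    readr::write_tsv(variants[, c(VARIANT_COLS, "variant_type")], path, progress = FALSE)
  } else {
    write_variant_vcf(variants, path)
  }
  invisible(path)
}

vcf_info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
}

read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(validate_variants(empty_variant_table()))
  }
  gt <- v@gt
  parse_sample <- function(col) {
    fmt <- strsplit(gt[, "FORMAT"], ":")
    val <- strsplit(gt[, col], ":")
    ad <- mapply(function(f, x) x[match("AD", f)], fmt, val)
    dp <- mapply(function(f, x) x[match("DP", f)], fmt, val)
    alt <- as.integer(vapply(strsplit(ad, ","), function(x) x[2], character(1)))
    list(depth = as.integer(dp), alt = alt)
  }
  tum <- parse_sample("TUMOR")
  nor <- parse_sample("NORMAL")
  info <- fix$INFO
  int_or_na <- function(x) suppressWarnings(as.integer(x))
  df <- tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    variant_class = vcf_info_field(info, "VC"),
    gene = dplyr::coalesce(vcf_info_field(info, "GENE"), ""),
    descriptor = vcf_info_field(info, "PCHG"),
    tumor_depth = tum$depth, tumor_alt = tum$alt,
    normal_depth = nor$depth, normal_alt = nor$alt,
    mapping_quality = as.numeric(vcf_info_field(info, "MQ")),
    pon_af = as.numeric(vcf_info_field(info, "PON_AF")),
    trinucleotide_context = vcf_info_field(info, "TNC"),
    rep_unit_size = int_or_na(vcf_info_field(info, "RUS")),
    rep_count = int_or_na(vcf_info_field(info, "RC")),
    mh_len = int_or_na(vcf_info_field(info, "MH"))
  )
  validate_variants(df)
}

write_variant_vcf <- function(variants, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=PON_AF,Number=1,Type=Float,Description=\"Panel-of-normals allele frequency\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=PCHG,Number=1,Type=String,Description=\"Protein change descriptor\">",
    "##INFO=<ID=VC,Number=1,Type=String,Description=\"Variant class\">",
    "##INFO=<ID=TNC,Number=1,Type=String,Description=\"Trinucleotide context\">",
    "##INFO=<ID=RUS,Number=1,Type=Integer,Description=\"Repeat unit size\">",
    "##INFO=<ID=RC,Number=1,Type=Integer,Description=\"Repeat count in reference\">",
    "##INFO=<ID=MH,Number=1,Type=Integer,Description=\"Microhomology length\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR\tNORMAL"
  )
  fmt_info <- function(key, val) ifelse(is.na(val), NA_character_, paste0(key, "=", val))
  rows <- variants |>
    mutate(
      info = purrr::pmap_chr(
        list(
          fmt_info("MQ", .data$mapping_quality), fmt_info("PON_AF", .data$pon_af),
          ifelse(.data$gene == "", NA_character_, paste0("GENE=", .data$gene)),
          ifelse(is.na(.data$descriptor), NA_character_, paste0("PCHG=", .data$descriptor)),
          fmt_info("VC", .data$variant_class), fmt_info("TNC", .data$trinucleotide_context),
          fmt_info("RUS", .data$rep_unit_size), fmt_info("RC", .data$rep_count),
          fmt_info("MH", .data$mh_len)
        ),
        function(...) paste(stats::na.omit(c(...)), collapse = ";")
      ),
      line = sprintf(
        "%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tAD:DP\t%d,%d:%d\t%d,%d:%d",
        .data$chrom, .data$pos, .data$ref, .data$alt, .data$info,
        .data$tumor_depth - .data$tumor_alt, .data$tumor_alt, .data$tumor_depth,
        .data$normal_depth - .data$normal_alt, .data$normal_alt, .data$normal_depth
      )
    ) |>
    pull("line")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

empty_variant_table <- function() {
  tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    variant_class = character(), gene = character(), descriptor = character(),
    tumor_depth = integer(), tumor_alt = integer(),
    normal_depth = integer(), normal_alt = integer(),
    mapping_quality = numeric(), pon_af = numeric(),
    trinucleotide_context = character(),
    rep_unit_size = integer(), rep_count = integer(), mh_len = integer(),
    variant_type = character()
  )
}

#' Validate a structural-variant table
#'
#' Enforces breakpoint ordering for intra-chromosomal events
#' (`pos1 <= pos2`), `size == pos2 - pos1` for non-translocations,
#' non-negative read support and `pon_freq` in `[0, 1]`.
#'
#' @param svs An SV tibble (see [read_sv_table()] for columns).
#' @return The validated tibble.
#' @export
validate_svs <- function(svs) {
  svs <- as_tibble(svs)
  missing_cols <- setdiff(SV_COLS, names(svs))
  if (length(missing_cols) > 0) {
    stop_validate(paste0("missing SV columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(svs) == 0) return(svs)
  bad_type <- !svs$sv_type %in% c("DEL", "DUP", "INV", "TRA")
  if (any(bad_type)) stop_validate("sv_type must be one of DEL, DUP, INV, TRA")
  intra <- svs$sv_type != "TRA"
  if (any(intra & svs$chrom1 != svs$chrom2)) {
    stop_validate("non-TRA events must be intra-chromosomal")
  }
  if (any(intra & svs$pos1 > svs$pos2)) {
    stop_validate("intra-chromosomal events require pos1 <= pos2")
  }
  if (any(intra & svs$size != svs$pos2 - svs$pos1)) {
    stop_validate("size must equal pos2 - pos1 for non-TRA events")
  }
  if (any(svs$tumor_support < 0 | svs$normal_support < 0)) {
    stop_validate("SV read support must be non-negative")
  }
  if (any(svs$pon_freq < 0 | svs$pon_freq > 1)) stop_validate("pon_freq must lie in [0, 1]")
  svs
}

empty_sv_table <- function() {
  tibble(
    chrom1 = character(), pos1 = integer(), strand1 = character(),
    chrom2 = character(), pos2 = integer(), strand2 = character(),
    sv_type = character(), size = integer(),
    tumor_support = integer(), normal_support = integer(),
    mapping_quality = numeric(), pon_freq = numeric(), homology_len = integer()
  )
}

#' Read a structural-variant table (BEDPE)
#'
#' Ten standard BEDPE columns (0-based half-open breakpoint intervals,
#' converted to 1-based in memory) followed by `sv_type`, `tumor_support`,
#' `normal_support`, `mapping_quality`, `pon_freq`, `homology_len`.
#'
#' @param path Input BEDPE file.
#' @return A validated SV tibble with 1-based `pos1`/`pos2`.
#' @export
read_sv_table <- function(path) {
  if (!file.exists(path)) stop_validate(paste0("no such file: ", path))
  df <- readr::read_tsv(path,
    col_names = c(
      "chrom1", "start1", "end1", "chrom2", "start2", "end2", "name", "score",
      "strand1", "strand2", "sv_type", "tumor_support", "normal_support",
      "mapping_quality", "pon_freq", "homology_len"
    ),
    col_types = "ciiciiccccciiddi", comment = "#", progress = FALSE,
    show_col_types = FALSE
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop_parse(paste0("malformed BEDPE row: ", probs$expected[1]), line = probs$row[1])
  }
  df |>
    mutate(
      pos1 = .data$start1 + 1L, pos2 = .data$start2 + 1L,
      tumor_support = as.integer(.data$tumor_support),
      normal_support = as.integer(.data$normal_support),
      size = ifelse(.data$sv_type == "TRA", NA_integer_, .data$pos2 - .data$pos1)
    ) |>
    select(dplyr::all_of(SV_COLS)) |>
    validate_svs()
}

#' Write a structural-variant table (BEDPE)
#'
#' @param svs A validated SV tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sv_table <- function(svs, path) {
  svs <- validate_svs(svs)
  out <- svs |>
    mutate(
      start1 = .data$pos1 - 1L, end1 = .data$pos1,
      start2 = .data$pos2 - 1L, end2 = .data$pos2,
      name = paste0("sv", row_number()), score = "."
    ) |>
    select(
      "chrom1", "start1", "end1", "chrom2", "start2", "end2", "name", "score",
      "strand1", "strand2", "sv_type", "tumor_support", "normal_support",
      "mapping_quality", "pon_freq", "homology_len"
    )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Validate copy-number segments
#'
#' Segments are 1-based inclusive, must satisfy `start <= end`,
#' `0 <= minor_cn <= total_cn`, and may not overlap within a chromosome.
#'
#' @param segments Tibble with `chrom`, `start`, `end`, `total_cn`, `minor_cn`.
#' @return The validated tibble, sorted canonically.
#' @export
validate_segments <- function(segments) {
  segments <- as_tibble(segments)
  needed <- c("chrom", "start", "end", "total_cn", "minor_cn")
  missing_cols <- setdiff(needed, names(segments))
  if (length(missing_cols) > 0) {
    stop_validate(paste0("missing segment columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(segments) == 0) return(segments)
  if (any(segments$start > segments$end)) stop_validate("segment start exceeds end")
  if (any(segments$minor_cn < 0)) stop_validate("minor_cn must be non-negative")
  if (any(segments$minor_cn > segments$total_cn + 1e-9)) {
    stop_validate("minor_cn exceeds total_cn")
  }
  segments <- arrange_genome(segments)
  overlap <- segments |>
    group_by(.data$chrom) |>
    summarise(bad = any(.data$start[-1] <= .data$end[-n()]), .groups = "drop")
  if (any(overlap$bad, na.rm = TRUE)) {
    stop_validate(paste0(
      "overlapping segments on chromosome ",
      paste(overlap$chrom[which(overlap$bad)], collapse = ", ")
    ))
  }
  segments
}

#' Read copy-number segments (SEG-style TSV)
#'
#' @param path TSV with columns `chrom`, `start`, `end`, `total_cn`,
#'   `minor_cn` (1-based inclusive coordinates).
#' @return A validated, canonically sorted segment tibble.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop_validate(paste0("no such file: ", path))
  df <- readr::read_tsv(path,
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), total_cn = readr::col_double(),
      minor_cn = readr::col_double()
    ), progress = FALSE, show_col_types = FALSE
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop_parse(paste0("malformed segment row: ", probs$expected[1]), line = probs$row[1] + 1L)
  }
  validate_segments(df)
}

#' Write copy-number segments
#'
#' @param segments A validated segment tibble.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  readr::write_tsv(validate_segments(segments), path, progress = FALSE)
  invisible(path)
}

#' Construct a tumor profile
#'
#' Bundles sample-level tumor state: tumor cell fraction (purity), ploidy,
#' the segmented allele-specific copy-number profile, and specimen metadata.
#'
#' @param sample_id Sample identifier.
#' @param tcf Tumor cell fraction in `[0, 1]`.
#' @param ploidy Genome-wide average copy number (> 0).
#' @param segments Segment tibble (see [validate_segments()]).
#' @param sample_type `"fresh"` or `"FFPE"`.
#' @param acquisition `"surgery"` or `"biopsy"`.
#' @return A `tumor_profile` object.
#' @export
tumor_profile <- function(sample_id, tcf, ploidy, segments,
                          sample_type = c("fresh", "FFPE"),
                          acquisition = c("surgery", "biopsy")) {
  sample_type <- arg_match(sample_type)
  acquisition <- arg_match(acquisition)
  if (tcf < 0 || tcf > 1) stop_validate("tcf must lie in [0, 1]")
  if (ploidy <= 0) stop_validate("ploidy must be positive")
  structure(
    list(
      sample_id = sample_id, tcf = tcf, ploidy = ploidy,
      segments = validate_segments(segments),
      sample_type = sample_type, acquisition = acquisition
    ),
    class = "tumor_profile"
  )
}

#' @export
print.tumor_profile <- function(x, ...) {
  cat(sprintf(
    "<tumor_profile> %s: TCF %.2f, ploidy %.2f, %d segments (%s, %s)\n",
    x$sample_id, x$tcf, x$ploidy, nrow(x$segments), x$sample_type, x$acquisition
  ))
  invisible(x)
}

#' Validate a germline variant table
#'
#' @param germline Tibble with `gene`, `hgvs_p`, `population_af`,
#'   `clinvar_class`, `predisposition_gene`.
#' @return The validated tibble.
#' @export
validate_germline <- function(germline) {
  germline <- as_tibble(germline)
  needed <- c("gene", "hgvs_p", "population_af", "clinvar_class", "predisposition_gene")
  missing_cols <- setdiff(needed, names(germline))
  if (length(missing_cols) > 0) {
    stop_validate(paste0("missing germline columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(germline) == 0) return(germline)
  if (any(germline$population_af < 0 | germline$population_af > 1)) {
    stop_validate("population_af must lie in [0, 1]")
  }
  ok <- germline$clinvar_class %in% c(
    "pathogenic", "likely_pathogenic", "vus", "benign", "none"
  )
  if (!all(ok)) stop_validate("unknown clinvar_class value")
  germline
}

#' Read a microsatellite site table
#'
#' Long TSV with one row per (locus, sample, repeat length): columns
#' `locus_id`, `repeat_unit`, `sample` (`"tumor"` / `"normal"`), `length`,
#' `count`.
#'
#' @param path Input TSV.
#' @return A validated microsatellite tibble.
#' @export
read_microsatellite_table <- function(path) {
  if (!file.exists(path)) stop_validate(paste0("no such file: ", path))
  df <- readr::read_tsv(path, col_types = "cccii", progress = FALSE, show_col_types = FALSE)
  validate_microsatellites(df)
}

#' Write a microsatellite site table
#'
#' @param sites A validated microsatellite tibble.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_microsatellite_table <- function(sites, path) {
  readr::write_tsv(validate_microsatellites(sites), path, progress = FALSE)
  invisible(path)
}

#' Validate a microsatellite site table
#'
#' Each locus must carry non-empty tumor and normal repeat-length histograms
#' with non-negative counts.
#'
#' @param sites Long microsatellite tibble (see [read_microsatellite_table()]).
#' @return The validated tibble.
#' @export
validate_microsatellites <- function(sites) {
  sites <- as_tibble(sites)
  needed <- c("locus_id", "repeat_unit", "sample", "length", "count")
  missing_cols <- setdiff(needed, names(sites))
  if (length(missing_cols) > 0) {
    stop_validate(paste0("missing microsatellite columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(sites) == 0) return(sites)
  if (any(sites$count < 0)) stop_validate("histogram counts must be non-negative")
  if (!all(sites$sample %in% c("tumor", "normal"))) {
    stop_validate("sample must be 'tumor' or 'normal'")
  }
  both <- sites |>
    distinct(.data$locus_id, .data$sample) |>
    count(.data$locus_id)
  if (any(both$n < 2)) {
    stop_validate("every locus needs both a tumor and a normal histogram")
  }
  sites
}

#' Read a signature reference matrix (TSV)
#'
#' COSMIC-layout TSV: first column channel names, remaining columns one
#' signature each. Channel order is canonicalized; columns summing to 1
#' within 1e-6 are accepted as-is, columns within 1e-3 are renormalized with
#' a note, anything further off is an error. A row count that does not match
#' the declared class is a format error.
#'
#' @param path Input TSV.
#' @param class Catalog class: `"SBS96"`, `"ID83"` or `"SV32"`.
#' @return A `signature_reference`.
#' @export
read_signature_reference <- function(path, class) {
  class <- arg_match0(class, c("SBS96", "ID83", "SV32"))
  if (!file.exists(path)) stop_validate(paste0("no such file: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    channel = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE, show_col_types = FALSE)
  channels <- catalog_channels(class)
  if (nrow(df) != length(channels)) {
    stop_parse(sprintf(
      "%s reference requires %d channel rows, found %d", class, length(channels), nrow(df)
    ))
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$channel
  sums <- colSums(mat)
  off <- abs(sums - 1)
  # the 1e-3 renormalization band is inclusive (guard against binary
  # representation of an exactly-0.001 deficit)
  if (any(off > 1e-3 + 1e-9)) {
    stop_validate(paste0(
      "signature columns far from the probability simplex: ",
      paste(colnames(mat)[off > 1e-3], collapse = ", ")
    ))
  }
  if (any(off > 1e-6)) {
    note(paste0(
      "renormalizing signature columns: ",
      paste(colnames(mat)[off > 1e-6], collapse = ", ")
    ))
    mat <- sweep(mat, 2, sums, "/")
  }
  new_signature_reference(mat, class)
}

#' Write a signature reference matrix (TSV)
#'
#' @param reference A `signature_reference`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_signature_reference <- function(reference, path) {
  df <- as_tibble(reference$matrix)
  df <- dplyr::bind_cols(tibble(channel = rownames(reference$matrix)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
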