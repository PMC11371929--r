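# Mutational catalog construction: SBS96 (pyrimidine-strand trinucleotide
# substitutions), ID83 (COSMIC-style indel channels) and SV32 (clustered /
# non-clustered rearrangements by type and size). Every builder preserves
# the input mutation count.

#' Construct a mutational catalog
#'
#' @param counts Named numeric vector of channel counts, or a tibble with
#'   `channel` and `count` columns. Missing channels are zero-filled;
#'   channels outside the class canon are an error.
#' @param class Catalog class: `"SBS96"`, `"ID83"` or `"SV32"`.
#' @return A `mutational_catalog`: a tibble with `channel` and `count` in
#'   canonical channel order, with the class stored as an attribute.
#' @export
mutational_catalog <- function(counts, class) {
  class <- arg_match0(class, c("SBS96", "ID83", "SV32"))
  channels <- catalog_channels(class)
  if (is.data.frame(counts)) counts <- setNames(counts$count, counts$channel)
  unknown <- setdiff(names(counts), channels)
  if (length(unknown) > 0) {
    stop_validate(paste0("unknown ", class, " channel(s): ", paste(head(unknown, 5), collapse = ", ")))
  }
  if (any(counts < 0)) stop_validate("catalog counts must be non-negative")
  full <- setNames(rep(0, length(channels)), channels)
  full[names(counts)] <- as.numeric(counts)
  out <- tibble(channel = channels, count = unname(full))
  structure(out, class = c("mutational_catalog", class(out)), catalog_class = class)
}

#' Catalog class of a `mutational_catalog`
#' @param catalog A `mutational_catalog`.
#' @return `"SBS96"`, `"ID83"` or `"SV32"`.
#' @export
catalog_class <- function(catalog) attr(catalog, "catalog_class")

catalog_counts <- function(catalog) setNames(catalog$count, catalog$channel)

#' @export
print.mutational_catalog <- function(x, ...) {
  cat(sprintf(
    "<mutational_catalog> %s: %d mutations over %d channels\n",
    catalog_class(x), sum(x$count), nrow(x)
  ))
  NextMethod()
}

#' Build the SBS96 catalog from SNV records
#'
#' Each single-base substitution is mapped to its pyrimidine-strand
#' substitution-by-context channel; records whose reference base is a purine
#' are reverse-complemented first. The context must be a 3-mer centered on
#' the reference base.
#'
#' @param variants A variant tibble; only `variant_type == "snv"` rows are
#'   used.
#' @return A `mutational_catalog` of class SBS96 whose total equals the
#'   number of SNV records.
#' @export
build_sbs96_catalog <- function(variants) {
  variants <- validate_variants(variants)
  snvs <- filter(variants, .data$variant_type == "snv")
  if (nrow(snvs) == 0) return(mutational_catalog(integer(0), "SBS96"))
  ctx <- snvs$trinucleotide_context
  if (any(nchar(ctx) != 3)) stop_validate("trinucleotide context must be a 3-mer")
  center <- substr(ctx, 2, 2)
  if (any(center != snvs$ref)) {
    stop_validate("trinucleotide context center must equal the reference base")
  }
  ref <- snvs$ref
  alt <- snvs$alt
  purine <- ref %in% c("A", "G")
  ctx[purine] <- revcomp(ctx[purine])
  ref[purine] <- unname(DNA_COMPLEMENT[ref[purine]])
  alt[purine] <- unname(DNA_COMPLEMENT[alt[purine]])
  channel <- paste0(
    substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3)
  )
  bad <- !channel %in% sbs96_channels()
  if (any(bad)) {
    stop_validate(paste0("unmappable SNV record(s), e.g. ", channel[which(bad)[1]]))
  }
  mutational_catalog(table(channel), "SBS96")
}

clamp_bin <- function(x, top, top_label) {
  ifelse(x >= top, top_label, as.character(x))
}

classify_indel <- function(ref, alt, rep_count, mh_len) {
  is_del <- nchar(ref) > nchar(alt)
  len <- abs(nchar(ref) - nchar(alt))
  seq <- if (is_del) substr(ref, 2, 1 + len) else substr(alt, 2, 1 + len)
  if (len == 1) {
    base <- if (seq %in% c("A", "G")) unname(DNA_COMPLEMENT[seq]) else seq
    if (is_del) {
      # bin = homopolymer length in the reference (includes the deleted base)
      bin <- clamp_bin(max(rep_count, 1), 6, "6+")
      paste("DEL", base, "1", bin, sep = ".")
    } else {
      bin <- clamp_bin(rep_count, 5, "5+")
      paste("INS", base, "1", bin, sep = ".")
    }
  } else if (is_del && mh_len >= 1 && rep_count <= 1) {
    size <- clamp_bin(len, 5, "5+")
    max_mh <- min(mh_len, len - 1)
    allowed <- ID_MH_BINS[[size]]
    bin <- clamp_bin(max_mh, 5, "5+")
    if (!bin %in% allowed) bin <- allowed[length(allowed)]
    paste("DEL", "MH", size, bin, sep = ".")
  } else {
    unit <- clamp_bin(len, 5, "5+")
    if (is_del) {
      bin <- clamp_bin(max(rep_count, 1), 6, "6+")
      paste("DEL", "rep", unit, bin, sep = ".")
    } else {
      bin <- clamp_bin(rep_count, 5, "5+")
      paste("INS", "rep", unit, bin, sep = ".")
    }
  }
}

#' Build the ID83 catalog from indel records
#'
#' COSMIC-style classification: 1-bp indels by pyrimidine-normalized base
#' and reference homopolymer length; longer indels at repeats by repeat-unit
#' size and reference repeat count; deletions with microhomology (not in a
#' repeat) by deletion size and homology length.
#'
#' @param variants A variant tibble; only `variant_type == "indel"` rows are
#'   used. Indel rows must carry `rep_unit_size`, `rep_count` and `mh_len`.
#' @return A `mutational_catalog` of class ID83 whose total equals the
#'   number of indel records.
#' @export
build_id83_catalog <- function(variants) {
  variants <- validate_variants(variants)
  indels <- filter(variants, .data$variant_type == "indel")
  if (nrow(indels) == 0) return(mutational_catalog(integer(0), "ID83"))
  channel <- purrr::pmap_chr(
    list(indels$ref, indels$alt, indels$rep_count, indels$mh_len),
    classify_indel
  )
  mutational_catalog(table(channel), "ID83")
}

# Flag clustered breakpoints: a breakpoint is clustered when some window of
# `window` bp starting at one of the breakpoints contains >= `min_breakpoints`
# breakpoints and includes it.
flag_clustered_breakpoints <- function(bp) {
  split_idx <- split(seq_len(nrow(bp)), bp$chrom)
  clustered <- logical(nrow(bp))
  for (idx in split_idx) {
    p <- bp$pos[idx]
    o <- order(p)
    ps <- p[o]
    upper <- findInterval(ps + bp$window[1], ps)
    flag <- logical(length(ps))
    for (k in seq_along(ps)) {
      if (upper[k] - k + 1 >= bp$min_bp[1]) flag[k:upper[k]] <- TRUE
    }
    clustered[idx[o]] <- flag
  }
  clustered
}

#' Build the SV32 catalog from structural variants
#'
#' Channels cross clustering status with event type: deletions, duplications
#' and inversions in five size bins (<10kb, 10-100kb, 100kb-1Mb, 1-10Mb,
#' >10Mb) plus translocations. An SV counts as clustered when either of its
#' breakpoints lies in a breakpoint-dense region: at least
#' `min_breakpoints` breakpoints within some `window`-bp interval. This
#' simple density rule replaces the piecewise-constant-fit convention used
#' in the rearrangement-signature literature; it is deterministic and
#' directly checkable against a brute-force density computation.
#'
#' @param svs A validated SV tibble (typically the filtered set).
#' @param window Clustering window in bp (default 1e6).
#' @param min_breakpoints Minimum breakpoints per window (default 8).
#' @return A `mutational_catalog` of class SV32 whose total equals the
#'   number of SV records.
#' @export
build_sv32_catalog <- function(svs, window = 1e6, min_breakpoints = 8) {
  svs <- validate_svs(svs)
  if (nrow(svs) == 0) return(mutational_catalog(integer(0), "SV32"))
  bp <- tibble(
    sv = rep(seq_len(nrow(svs)), 2),
    chrom = c(svs$chrom1, svs$chrom2),
    pos = c(svs$pos1, svs$pos2),
    window = window, min_bp = min_breakpoints
  )
  bp$clustered <- flag_clustered_breakpoints(bp)
  sv_clustered <- tapply(bp$clustered, bp$sv, any)
  status <- ifelse(sv_clustered[as.character(seq_len(nrow(svs)))], "clustered", "non_clustered")
  channel <- ifelse(
    svs$sv_type == "TRA",
    paste(status, "TRA", sep = ":"),
    paste(status, svs$sv_type, sv_size_bin(svs$size), sep = ":")
  )
  mutational_catalog(table(channel), "SV32")
}
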