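# Shared fixtures built in code.

make_variant <- function(chrom = "1", pos = 1000L, ref = "C", alt = "T",
                         variant_class = "missense", gene = "",
                         descriptor = NA_character_,
                         tumor_depth = 40L, tumor_alt = 10L,
                         normal_depth = 20L, normal_alt = 0L,
                         mapping_quality = 60, pon_af = 0,
                         trinucleotide_context = "ACA",
                         rep_unit_size = NA_integer_, rep_count = NA_integer_,
                         mh_len = NA_integer_) {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    variant_class = variant_class, gene = gene, descriptor = descriptor,
    tumor_depth = as.integer(tumor_depth), tumor_alt = as.integer(tumor_alt),
    normal_depth = as.integer(normal_depth), normal_alt = as.integer(normal_alt),
    mapping_quality = mapping_quality, pon_af = pon_af,
    trinucleotide_context = trinucleotide_context,
    rep_unit_size = as.integer(rep_unit_size), rep_count = as.integer(rep_count),
    mh_len = as.integer(mh_len)
  )
}

make_indel <- function(ref = "AT", alt = "A", rep_count = 1L, mh_len = 0L,
                       rep_unit_size = NULL, variant_class = "other", ...) {
  len <- abs(nchar(ref) - nchar(alt))
  if (is.null(rep_unit_size)) rep_unit_size <- len
  make_variant(
    ref = ref, alt = alt, trinucleotide_context = NA_character_,
    rep_unit_size = rep_unit_size, rep_count = rep_count,
    mh_len = mh_len, variant_class = variant_class, ...
  )
}

make_sv <- function(chrom1 = "1", pos1 = 1e6, strand1 = "+",
                    chrom2 = "1", pos2 = 2e6, strand2 = "-",
                    sv_type = "DEL", tumor_support = 10L, normal_support = 0L,
                    mapping_quality = 60, pon_freq = 0, homology_len = 0L) {
  tibble::tibble(
    chrom1 = chrom1, pos1 = as.integer(pos1), strand1 = strand1,
    chrom2 = chrom2, pos2 = as.integer(pos2), strand2 = strand2,
    sv_type = sv_type,
    size = ifelse(sv_type == "TRA", NA_integer_, as.integer(pos2 - pos1)),
    tumor_support = as.integer(tumor_support),
    normal_support = as.integer(normal_support),
    mapping_quality = mapping_quality, pon_freq = pon_freq,
    homology_len = as.integer(homology_len)
  )
}

make_segments <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      chrom = r[["chrom"]], start = as.numeric(r[["start"]]),
      end = as.numeric(r[["end"]]), total_cn = as.numeric(r[["total_cn"]]),
      minor_cn = as.numeric(r[["minor_cn"]])
    )
  }))
}

flat_profile <- function(tcf = 0.6, ploidy = 2, total_cn = 2, minor_cn = 1,
                         sample_id = "t1") {
  segs <- dplyr::bind_rows(lapply(
    names(oncointerpret:::CHROM_LENGTHS),
    function(ch) {
      tibble::tibble(
        chrom = ch, start = 1,
        end = oncointerpret:::CHROM_LENGTHS[[ch]],
        total_cn = total_cn, minor_cn = minor_cn
      )
    }
  ))
  tumor_profile(sample_id, tcf, ploidy, segs)
}

# profile with one carved segment (e.g. a gene amplification or LOH)
carved_profile <- function(carve_chrom, carve_start, carve_end, total_cn, minor_cn,
                           tcf = 0.6, ploidy = 2) {
  L <- oncointerpret:::CHROM_LENGTHS[[carve_chrom]]
  segs <- dplyr::bind_rows(
    lapply(setdiff(names(oncointerpret:::CHROM_LENGTHS), carve_chrom), function(ch) {
      tibble::tibble(
        chrom = ch, start = 1, end = oncointerpret:::CHROM_LENGTHS[[ch]],
        total_cn = 2, minor_cn = 1
      )
    }),
    tibble::tibble(
      chrom = carve_chrom,
      start = c(1, carve_start, carve_end + 1),
      end = c(carve_start - 1, carve_end, L),
      total_cn = c(2, total_cn, 2), minor_cn = c(1, minor_cn, 1)
    )
  )
  tumor_profile("carved", tcf, ploidy, segs)
}

# tiny 2-signature reference on a reduced channel space is not possible
# (references are class-locked), so toy fits use the synthetic reference
toy_sbs_reference <- function() synthetic_signature_reference("SBS96")

# deterministic noiseless catalog from a mixture over reference columns
noiseless_catalog <- function(reference, weights, n) {
  probs <- as.numeric(reference$matrix[, names(weights), drop = FALSE] %*% weights)
  mutational_catalog(
    stats::setNames(n * probs, rownames(reference$matrix)),
    reference$class
  )
}

# independent exact NNLS oracle: enumerate active sets, solve the normal
# equations, keep feasible solutions, return the best objective
nnls_oracle <- function(m, y) {
  p <- ncol(m)
  best <- list(obj = sum(y^2), x = rep(0, p))
  subsets <- unlist(lapply(seq_len(p), function(k) {
    utils::combn(p, k, simplify = FALSE)
  }), recursive = FALSE)
  for (s in subsets) {
    ms <- m[, s, drop = FALSE]
    xs <- tryCatch(solve(crossprod(ms), crossprod(ms, y)), error = function(e) NULL)
    if (is.null(xs) || any(xs < -1e-12)) next
    x <- rep(0, p)
    x[s] <- pmax(xs, 0)
    obj <- sum((y - m %*% x)^2)
    if (obj < best$obj - 1e-12) best <- list(obj = obj, x = x)
  }
  best$x
}
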