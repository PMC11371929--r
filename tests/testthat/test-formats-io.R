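test_that("variant TSV round-trips, including an empty table", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  empty <- oncointerpret:::empty_variant_table()
  write_variant_table(empty, tmp)
  expect_equal(nrow(read_variant_table(tmp)), 0)

  v <- dplyr::bind_rows(
    make_variant(tumor_alt = 5L, tumor_depth = 40L),
    make_variant(pos = 2000L, ref = "G", alt = "A", trinucleotide_context = "CGT"),
    make_indel(pos = 3000L, gene = "KRAS")
  )
  write_variant_table(v, tmp)
  back <- read_variant_table(tmp)
  expect_equal(as.data.frame(back[names(v)]), as.data.frame(v))
  # read support feeds a VAF of 5/40 downstream
  expect_equal(back$tumor_alt[1] / back$tumor_depth[1], 0.125)
})

test_that("variant validation rejects impossible records", {
  expect_error(validate_variants(make_variant(pon_af = 1.2)), "pon_af")
  expect_error(validate_variants(make_variant(tumor_alt = 50L)), "tumor_alt")
  expect_error(validate_variants(make_variant(pos = 0L)), "positions")
  expect_error(
    validate_variants(make_variant(trinucleotide_context = NA_character_)),
    "context"
  )
  # unknown columns are dropped with a note
  v <- make_variant()
  v$mystery <- 1
  tmp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(v, tmp)
  expect_message(out <- read_variant_table(tmp), "mystery")
  expect_false("mystery" %in% names(out))
})

test_that("VCF dialect round-trips tumor/normal evidence and annotations", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  v <- dplyr::bind_rows(
    make_variant(gene = "EGFR", descriptor = "L858R", tumor_alt = 12L),
    make_indel(pos = 5000L, rep_count = 6L)
  )
  write_variant_table(v, tmp, dialect = "vcf")
  back <- read_variant_table(tmp, dialect = "vcf")
  expect_equal(as.data.frame(back[names(v)]), as.data.frame(v))
})

test_that("segment reader enforces sorting, overlap and CN invariants", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  ok <- make_segments(
    list(chrom = "1", start = 101, end = 200, total_cn = 2, minor_cn = 1),
    list(chrom = "1", start = 1, end = 100, total_cn = 2, minor_cn = 1)
  )
  write_segments(ok, tmp)
  segs <- read_segments(tmp)
  expect_equal(segs$start, c(1, 101)) # sorted on the way in

  bad <- make_segments(
    list(chrom = "1", start = 1, end = 150, total_cn = 2, minor_cn = 1),
    list(chrom = "1", start = 100, end = 200, total_cn = 2, minor_cn = 1)
  )
  expect_error(validate_segments(bad), "overlap")
  expect_error(
    validate_segments(make_segments(
      list(chrom = "1", start = 1, end = 10, total_cn = 1, minor_cn = 2)
    )),
    "minor_cn"
  )
})

test_that("BEDPE conversion is lossless and 0-based on disk", {
  tmp <- withr::local_tempfile(fileext = ".bedpe")
  svs <- dplyr::bind_rows(
    make_sv(),
    make_sv(chrom1 = "2", pos1 = 5e6, chrom2 = "7", pos2 = 9e6, sv_type = "TRA",
            strand2 = "+")
  )
  write_sv_table(svs, tmp)
  raw <- readr::read_tsv(tmp, col_names = FALSE, show_col_types = FALSE)
  expect_equal(raw$X2, svs$pos1 - 1) # 0-based half-open start
  expect_equal(raw$X3, svs$pos1)
  back <- read_sv_table(tmp)
  expect_equal(as.data.frame(back[names(svs)]), as.data.frame(svs))
})

test_that("SV validation enforces breakpoint ordering and size", {
  expect_error(validate_svs(make_sv(pos1 = 2e6, pos2 = 1e6)), "pos1 <= pos2")
  bad <- make_sv()
  bad$size <- 5L
  expect_error(validate_svs(bad), "size")
  expect_error(validate_svs(make_sv(pon_freq = 1.5)), "pon_freq")
})

test_that("signature reference TSV honours the simplex tolerance rules", {
  ref <- synthetic_signature_reference("SBS96", c("SBS1", "SBS5"))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_signature_reference(ref, tmp)
  back <- read_signature_reference(tmp, "SBS96")
  expect_equal(back$matrix, ref$matrix, tolerance = 1e-12)
  expect_equal(unname(colSums(back$matrix)), c(1, 1), tolerance = 1e-9)

  # column at 0.999: renormalized with a note
  off <- ref
  off$matrix[, 1] <- off$matrix[, 1] * 0.999
  df <- tibble::as_tibble(off$matrix)
  df <- dplyr::bind_cols(tibble::tibble(channel = rownames(off$matrix)), df)
  readr::write_tsv(df, tmp)
  expect_message(back2 <- read_signature_reference(tmp, "SBS96"), "renormalizing")
  expect_equal(unname(colSums(back2$matrix)), c(1, 1), tolerance = 1e-9)

  # wrong channel count for the declared class
  readr::write_tsv(df[1:95, ], tmp)
  expect_error(read_signature_reference(tmp, "SBS96"), "96")
})

test_that("microsatellite tables validate and round-trip", {
  sites <- tibble::tibble(
    locus_id = rep("ms_1", 4), repeat_unit = "A",
    sample = c("tumor", "tumor", "normal", "normal"),
    length = c(10L, 11L, 10L, 11L), count = c(30L, 5L, 28L, 6L)
  )
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_microsatellite_table(sites, tmp)
  expect_equal(as.data.frame(read_microsatellite_table(tmp)), as.data.frame(sites))
  expect_error(
    validate_microsatellites(dplyr::filter(sites, sample == "tumor")),
    "both"
  )
})

test_that("JSON reports round-trip losslessly, including unicode genes", {
  cfg <- simulation_config(seed = 3, n_sbs = 300, n_indel = 60, n_sv = 30,
                           n_microsat = 40)
  res <- suppressMessages(interpret_simulated(cfg))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_report(res$report, tmp, "json")
  back <- read_report(tmp)
  expect_equal(back$drivers, res$report$drivers)
  expect_equal(back$phenotypes, res$report$phenotypes)
  expect_equal(back$category, res$report$category)
  expect_equal(back$tcf, res$report$tcf)
  expect_equal(
    back$signatures$SBS96$fractions, res$report$signatures$SBS96$fractions
  )

  # a driver row with a non-ASCII gene label survives byte-exact
  rpt <- res$report
  rpt$drivers <- tibble::tibble(
    gene = "GENÉ1", alteration_type = "point", descriptor = "p.ΔE746",
    driver_class = "oncogene_point", evidence = "e", cn = NA_real_
  )
  write_report(rpt, tmp, "json")
  expect_identical(read_report(tmp)$drivers$gene, "GENÉ1")
  expect_identical(read_report(tmp)$drivers$descriptor, "p.ΔE746")

  # markdown rendering covers category, drivers, phenotypes, germline
  md <- withr::local_tempfile(fileext = ".md")
  write_report(res$report, md, "markdown")
  txt <- readLines(md)
  expect_true(any(grepl("## Category", txt)))
  expect_true(any(grepl("## Phenotypes", txt)))
  expect_true(any(grepl("## Germline", txt)))
})
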