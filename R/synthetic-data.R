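# Synthetic tumor/normal call-set generator. Emits the exact tables the
# interpretation pipeline consumes - somatic SNV/indel calls, SVs,
# a segmented tumor profile, germline variants and microsatellite site
# histograms - together with a ground-truth manifest, so every stage has a
# deterministic, no-download test surface.
#
# The generator models caller *outputs*, not reads: channels are drawn
# multinomially from the signature mixture, read support is binomial given
# the expected VAF under purity and local copy number
# (VAF = purity x mutated_copies / (purity x total_cn + 2(1 - purity))),
# and depths are Poisson with means 40x (tumor) and 20x (normal), the
# assay's nominal coverages, with tumor depth scaled by local copy number.
# Injected artifact records each violate exactly one named filter
# criterion. No error model for caller artifacts beyond this scheme is
# attempted.

CHROM_LENGTHS <- c(
  "1" = 248.9e6, "2" = 242.2e6, "3" = 198.3e6, "4" = 190.2e6, "5" = 181.5e6,
  "6" = 170.8e6, "7" = 159.3e6, "8" = 145.1e6, "9" = 138.4e6, "10" = 133.8e6,
  "11" = 135.1e6, "12" = 133.3e6, "13" = 114.4e6, "14" = 107.0e6,
  "15" = 102.0e6, "16" = 90.3e6, "17" = 83.3e6, "18" = 80.4e6, "19" = 58.6e6,
  "20" = 64.4e6, "21" = 46.7e6, "22" = 50.8e6, "X" = 156.0e6
)

DEFAULT_MIXTURES <- list(
  base = list(
    SBS96 = c(SBS1 = 0.4, SBS5 = 0.6),
    ID83 = c(ID1 = 0.5, ID2 = 0.5),
    SV32 = c(RS1 = 0.4, RS2 = 0.35, RS6 = 0.25)
  ),
  hrd = list(
    SBS96 = c(SBS1 = 0.25, SBS3 = 0.30, SBS5 = 0.35, SBS8 = 0.10),
    ID83 = c(ID1 = 0.35, ID2 = 0.25, ID6 = 0.40),
    SV32 = c(RS1 = 0.35, RS2 = 0.20, RS3 = 0.30, RS5 = 0.15)
  ),
  msi = list(
    SBS96 = c(
      SBS1 = 0.15, SBS5 = 0.25, SBS6 = 0.25, SBS15 = 0.10, SBS20 = 0.05,
      SBS21 = 0.05, SBS26 = 0.05, SBS44 = 0.10
    ),
    ID83 = c(ID1 = 0.6, ID2 = 0.4),
    SV32 = c(RS1 = 0.4, RS2 = 0.35, RS6 = 0.25)
  )
)

#' Configure a synthetic tumor/normal call set
#'
#' Defaults describe a routine tumor: purity 0.6, diploid, 4,000
#' substitutions, 600 indels, 120 SVs, 200 microsatellite loci, 10%
#' injected artifact records, clock-like signature mixtures. `hrd_status`
#' switches to an HRD mixture (SBS3/SBS8, ID6, RS3/RS5, 12 long LOH
#' segments); `msi_status = "MSI-H"` switches to an MSI mixture (60% mass
#' on the MSI signatures) and shifts `instability_fraction` of the
#' microsatellite loci.
#'
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param sample_id,cancer_type,question Sample metadata.
#' @param n_sbs,n_indel,n_sv Clean passenger record counts per class.
#' @param sbs_mixture,id_mixture,sv_mixture Named non-negative weights
#'   summing to 1 (defaults depend on `hrd_status` / `msi_status`).
#' @param purity Tumor cell fraction in `[0, 1]`.
#' @param ploidy Genome-average copy number.
#' @param msi_status `"MSS"` or `"MSI-H"`.
#' @param hrd_status Logical.
#' @param n_loh_segments Long LOH segments carved when `hrd_status` is TRUE.
#' @param drivers List of driver instructions; each a list with `type`
#'   (`"point"`, `"amplification"`, `"deletion"`, `"fusion"`), `gene`, and
#'   type-specifics (`descriptor` + `variant_class` for point; `cn` for
#'   amplification; `partner_5p` for fusion, the named `gene` being the 3'
#'   driver partner).
#' @param germline_payload Germline variant tibble, optionally with a
#'   `second_hit` column (`"loh"`, `"somatic_truncating"`, `"none"`).
#' @param artifact_fraction Fraction of extra records injected that each
#'   violate exactly one filter criterion.
#' @param n_microsat Microsatellite locus count.
#' @param instability_fraction Fraction of loci given a shifted tumor
#'   length distribution (defaults to 0.30 for MSI-H, 0 otherwise).
#' @param sample_type,acquisition Specimen metadata.
#' @param intended_category Optional ground-truth category label carried in
#'   the manifest.
#' @return A `simulation_config`.
#' @export
simulation_config <- function(seed, sample_id = sprintf("sim_%06d", seed),
                              cancer_type = "other",
                              question = c("actionability", "clarity"),
                              n_sbs = 4000, n_indel = 600, n_sv = 120,
                              sbs_mixture = NULL, id_mixture = NULL,
                              sv_mixture = NULL, purity = 0.6, ploidy = 2.0,
                              msi_status = c("MSS", "MSI-H"),
                              hrd_status = FALSE, n_loh_segments = 12,
                              drivers = list(), germline_payload = NULL,
                              artifact_fraction = 0.1, n_microsat = 200,
                              instability_fraction = NULL,
                              sample_type = "fresh", acquisition = "surgery",
                              intended_category = NA_character_) {
  question <- arg_match(question)
  msi_status <- arg_match(msi_status)
  base <- if (hrd_status) {
    DEFAULT_MIXTURES$hrd
  } else if (msi_status == "MSI-H") {
    DEFAULT_MIXTURES$msi
  } else {
    DEFAULT_MIXTURES$base
  }
  cfg <- list(
    seed = as.integer(seed), sample_id = sample_id, cancer_type = cancer_type,
    question = question, n_sbs = n_sbs, n_indel = n_indel, n_sv = n_sv,
    mixtures = list(
      SBS96 = sbs_mixture %||% base$SBS96,
      ID83 = id_mixture %||% base$ID83,
      SV32 = sv_mixture %||% base$SV32
    ),
    purity = purity, ploidy = ploidy, msi_status = msi_status,
    hrd_status = hrd_status, n_loh_segments = n_loh_segments,
    drivers = drivers,
    germline_payload = germline_payload %||% tibble(
      gene = character(), hgvs_p = character(), population_af = numeric(),
      clinvar_class = character(), predisposition_gene = logical(),
      second_hit = character()
    ),
    artifact_fraction = artifact_fraction, n_microsat = n_microsat,
    instability_fraction = instability_fraction %||%
      if (msi_status == "MSI-H") 0.30 else 0,
    sample_type = sample_type, acquisition = acquisition,
    intended_category = intended_category
  )
  if (any(c(cfg$n_sbs, cfg$n_indel, cfg$n_sv, cfg$n_microsat) < 0)) {
    stop_validate("record counts must be non-negative")
  }
  if (purity < 0 || purity > 1) stop_validate("purity must lie in [0, 1]")
  if (ploidy <= 0) stop_validate("ploidy must be positive")
  for (cl in names(cfg$mixtures)) {
    w <- cfg$mixtures[[cl]]
    if (any(w < 0)) stop_validate("mixture weights must be non-negative")
    if (length(w) > 0 && abs(sum(w) - 1) > 1e-9) {
      stop_validate(paste0(cl, " mixture weights must sum to 1"))
    }
  }
  if (!"second_hit" %in% names(cfg$germline_payload)) {
    cfg$germline_payload$second_hit <- rep("none", nrow(cfg$germline_payload))
  }
  structure(cfg, class = "simulation_config")
}

sample_positions <- function(n) {
  chrom <- sample(names(CHROM_LENGTHS), n, replace = TRUE,
    prob = CHROM_LENGTHS / sum(CHROM_LENGTHS)
  )
  pos <- floor(runif(n, 1, CHROM_LENGTHS[chrom] - 1e4)) + 1
  tibble(chrom = chrom, pos = as.integer(pos))
}

segment_total_cn <- function(segments, chrom, pos, default_cn) {
  hit <- segments$chrom == chrom & segments$start <= pos & segments$end >= pos
  if (any(hit)) segments$total_cn[which(hit)[1]] else default_cn
}

expected_vaf <- function(purity, total_cn, mult = 1) {
  purity * mult / (purity * total_cn + 2 * (1 - purity))
}

bin_val <- function(bin) {
  switch(bin, "6+" = 6L, "5+" = 5L, as.integer(bin))
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Build segments: per-chromosome baseline at round(ploidy), with LOH
# carve-outs (HRD / second hits) and driver amplification / deletion
# segments around gene intervals.
build_profile_segments <- function(cfg, kb) {
  base_cn <- max(1, round(cfg$ploidy))
  base_minor <- floor(base_cn / 2)
  carves <- list()
  if (cfg$hrd_status && cfg$n_loh_segments > 0) {
    chroms <- sample(names(CHROM_LENGTHS), cfg$n_loh_segments, replace = FALSE)
    for (ch in chroms) {
      len <- floor(runif(1, 20e6, 40e6))
      start <- floor(runif(1, 1e6, CHROM_LENGTHS[ch] - len - 1e6))
      carves <- c(carves, list(list(
        chrom = ch, start = start, end = start + len - 1,
        total_cn = max(1, base_cn - base_minor), minor_cn = 0
      )))
    }
  }
  for (d in cfg$drivers) {
    entry <- kb_entry(kb, d$gene)
    if (is.null(entry)) next
    pad <- 2e5
    if (identical(d$type, "amplification")) {
      carves <- c(carves, list(list(
        chrom = entry$chrom, start = entry$start - pad, end = entry$end + pad,
        total_cn = d$cn, minor_cn = 1
      )))
    } else if (identical(d$type, "deletion")) {
      carves <- c(carves, list(list(
        chrom = entry$chrom, start = entry$start - pad, end = entry$end + pad,
        total_cn = 0, minor_cn = 0
      )))
    }
  }
  gp <- cfg$germline_payload
  if (nrow(gp) > 0) {
    for (i in seq_len(nrow(gp))) {
      if (identical(gp$second_hit[i], "loh")) {
        entry <- kb_entry(kb, gp$gene[i])
        if (is.null(entry)) next
        len <- 20e6
        start <- max(1, entry$start - 2e6)
        carves <- c(carves, list(list(
          chrom = entry$chrom, start = start,
          end = min(start + len - 1, CHROM_LENGTHS[entry$chrom]),
          total_cn = max(1, base_cn - base_minor), minor_cn = 0
        )))
      }
    }
  }
  segs <- purrr::map_dfr(names(CHROM_LENGTHS), function(ch) {
    ch_carves <- keep(carves, ~ .x$chrom == ch)
    L <- CHROM_LENGTHS[[ch]]
    if (length(ch_carves) == 0) {
      return(tibble(
        chrom = ch, start = 1, end = L, total_cn = base_cn, minor_cn = base_minor
      ))
    }
    ch_carves <- ch_carves[order(map_dbl(ch_carves, "start"))]
    rows <- list()
    cursor <- 1
    for (cv in ch_carves) {
      s <- max(cv$start, cursor)
      e <- min(cv$end, L)
      if (s > e) next # overlapping carves: keep the first
      if (s > cursor) {
        rows <- c(rows, list(tibble(
          chrom = ch, start = cursor, end = s - 1,
          total_cn = base_cn, minor_cn = base_minor
        )))
      }
      rows <- c(rows, list(tibble(
        chrom = ch, start = s, end = e, total_cn = cv$total_cn, minor_cn = cv$minor_cn
      )))
      cursor <- e + 1
    }
    if (cursor <= L) {
      rows <- c(rows, list(tibble(
        chrom = ch, start = cursor, end = L, total_cn = base_cn, minor_cn = base_minor
      )))
    }
    bind_rows(rows)
  })
  validate_segments(segs)
}

# Read evidence for one somatic record; clean records are clamped to pass
# the filter (tumor_alt >= 2, normal_alt <= 1) so manifest labels stay true.
draw_reads <- function(n, purity, ploidy, cn, mult = 1) {
  factor <- (purity * cn + 2 * (1 - purity)) / (purity * ploidy + 2 * (1 - purity))
  td <- pmax(rpois(n, 40 * factor), 8L)
  ta <- rbinom(n, td, pmin(1, expected_vaf(purity, cn, mult)))
  ta <- pmin(pmax(ta, 2L), td)
  nd <- pmax(rpois(n, 20), 5L)
  na <- pmin(rbinom(n, nd, 0.002), 1L)
  # a clean record with one stray normal read must stay under the 5% normal
  # VAF ceiling, so give it at least 20x normal coverage
  nd <- ifelse(na >= 1L, pmax(nd, 20L), nd)
  list(tumor_depth = as.integer(td), tumor_alt = as.integer(ta),
       normal_depth = as.integer(nd), normal_alt = as.integer(na))
}

sbs_channel_to_fields <- function(channel) {
  f5 <- substr(channel, 1, 1)
  ref <- substr(channel, 3, 3)
  alt <- substr(channel, 5, 5)
  f3 <- substr(channel, 7, 7)
  ctx <- paste0(f5, ref, f3)
  flip <- runif(length(channel)) < 0.5
  list(
    ref = ifelse(flip, unname(DNA_COMPLEMENT[ref]), ref),
    alt = ifelse(flip, unname(DNA_COMPLEMENT[alt]), alt),
    context = ifelse(flip, revcomp(ctx), ctx)
  )
}

id_channel_to_fields <- function(channel) {
  p <- strsplit(channel, ".", fixed = TRUE)[[1]]
  type <- p[1]; fam <- p[2]; size <- p[3]; bin <- p[4]
  if (fam %in% c("C", "T")) {
    seq <- fam
    rep_count <- if (type == "DEL") max(bin_val(bin), 1L) else bin_val(bin)
    mh <- 0L
  } else if (fam == "rep") {
    seq <- random_seq(bin_val(size))
    rep_count <- if (type == "DEL") max(bin_val(bin), 1L) else bin_val(bin)
    mh <- 0L
  } else { # MH
    len <- if (bin == "5+") 6L else bin_val(size)
    seq <- random_seq(len)
    rep_count <- 1L
    mh <- bin_val(bin)
  }
  if (type == "DEL") {
    list(ref = paste0("A", seq), alt = "A", rep_unit_size = nchar(seq),
         rep_count = rep_count, mh_len = mh)
  } else {
    list(ref = "A", alt = paste0("A", seq), rep_unit_size = nchar(seq),
         rep_count = rep_count, mh_len = mh)
  }
}

sv_channel_sizes <- list(
  "<10kb" = c(1e3, 1e4), "10-100kb" = c(1e4, 1e5), "100kb-1Mb" = c(1e5, 1e6),
  "1-10Mb" = c(1e6, 1e7), ">10Mb" = c(1e7, 2e7)
)

sv_orientations <- function(type, n = 1) {
  switch(type,
    DEL = list(s1 = rep("+", n), s2 = rep("-", n)),
    DUP = list(s1 = rep("-", n), s2 = rep("+", n)),
    INV = {
      s <- sample(c("+", "-"), n, replace = TRUE)
      list(s1 = s, s2 = s)
    },
    TRA = list(
      s1 = sample(c("+", "-"), n, replace = TRUE),
      s2 = sample(c("+", "-"), n, replace = TRUE)
    )
  )
}

# Required breakend orientation for a fusion partner under the convention
# that "+" retains the segment left of the breakpoint on the derivative.
fusion_orientation <- function(strand, is_5prime) {
  if (is_5prime) {
    if (strand == "+") "+" else "-"
  } else {
    if (strand == "+") "-" else "+"
  }
}

#' Simulate a tumor/normal call set with ground truth
#'
#' Draws passenger mutation channels multinomially from the configured
#' signature mixtures, synthesizes per-record caller evidence, injects the
#' configured drivers, artifact records (each violating exactly one filter
#' criterion), germline payload with optional second hits, and
#' microsatellite site histograms. Identical configs give byte-identical
#' output.
#'
#' @param config A [simulation_config()].
#' @param references Signature references
#'   (default [default_signature_references()]).
#' @param kb Gene knowledgebase (default bundled fixture).
#' @return A list: `variants`, `svs` (tibbles with an `id` column),
#'   `profile` (a `tumor_profile`), `germline`, `microsatellites`, and
#'   `ground_truth` (manifest + phenotype labels + channel tallies).
#' @export
simulate_callset <- function(config, references = default_signature_references(),
                             kb = default_gene_kb()) {
  stopifnot(inherits(config, "simulation_config"))
  for (cl in names(config$mixtures)) {
    miss <- setdiff(names(config$mixtures[[cl]]), references[[cl]]$names)
    if (length(miss) > 0) {
      stop_validate(paste0(
        "mixture references signatures absent from the ", cl, " reference: ",
        paste(miss, collapse = ", ")
      ))
    }
  }
  withr::with_seed(config$seed, simulate_callset_impl(config, references, kb))
}

simulate_callset_impl <- function(config, references, kb) {
  segments <- build_profile_segments(config, kb)
  profile <- tumor_profile(
    config$sample_id, config$purity, config$ploidy, segments,
    sample_type = config$sample_type, acquisition = config$acquisition
  )
  tallies <- list()
  make_variants <- function(class, n) {
    weights <- config$mixtures[[class]]
    ref <- references[[class]]
    if (n == 0 || length(weights) == 0) {
      tallies[[class]] <<- setNames(integer(length(ref$names)), ref$names)[0]
      return(empty_variant_table() |> mutate(id = character(0)))
    }
    probs <- as.numeric(ref$matrix[, names(weights), drop = FALSE] %*% weights)
    counts <- as.integer(rmultinom(1, n, probs))
    channels <- rep(rownames(ref$matrix), counts)
    tallies[[class]] <<- setNames(counts, rownames(ref$matrix))
    channels <- sample(channels) # shuffle genome placement order
    locs <- sample_positions(length(channels))
    cn <- map_dbl(seq_len(nrow(locs)), function(i) {
      segment_total_cn(segments, locs$chrom[i], locs$pos[i], max(1, round(config$ploidy)))
    })
    reads <- draw_reads(length(channels), config$purity, config$ploidy, cn)
    base <- tibble(
      chrom = locs$chrom, pos = locs$pos,
      variant_class = sample(c("missense", "synonymous", "other"),
        length(channels), replace = TRUE, prob = c(0.25, 0.3, 0.45)
      ),
      gene = "",
      tumor_depth = reads$tumor_depth, tumor_alt = reads$tumor_alt,
      normal_depth = reads$normal_depth, normal_alt = reads$normal_alt,
      mapping_quality = 60, pon_af = 0
    )
    if (class == "SBS96") {
      fields <- sbs_channel_to_fields(channels)
      base <- mutate(base,
        ref = fields$ref, alt = fields$alt,
        trinucleotide_context = fields$context,
        rep_unit_size = NA_integer_, rep_count = NA_integer_, mh_len = NA_integer_,
        variant_type = "snv"
      )
    } else {
      fields <- map(channels, id_channel_to_fields)
      base <- mutate(base,
        ref = map_chr(fields, "ref"), alt = map_chr(fields, "alt"),
        trinucleotide_context = NA_character_,
        rep_unit_size = map_int(fields, ~ as.integer(.x$rep_unit_size)),
        rep_count = map_int(fields, ~ as.integer(.x$rep_count)),
        mh_len = map_int(fields, ~ as.integer(.x$mh_len)),
        variant_type = "indel"
      )
    }
    base |>
      mutate(
        descriptor = NA_character_,
        id = sprintf("%s_%05d", tolower(substr(class, 1, 2)), row_number())
      ) |>
      select(dplyr::all_of(c(VARIANT_COLS, "descriptor", "variant_type", "id")))
  }

  sbs <- make_variants("SBS96", config$n_sbs)
  indels <- make_variants("ID83", config$n_indel)

  manifest <- list()
  add_manifest <- function(ids, kind, role, intended_pass, fail_criterion = NA_character_,
                           gene = NA_character_, driver_class = NA_character_,
                           descriptor = NA_character_) {
    manifest[[length(manifest) + 1]] <<- tibble(
      id = ids, kind = kind, role = role, intended_pass = intended_pass,
      fail_criterion = fail_criterion, gene = gene,
      driver_class = driver_class, descriptor = descriptor
    )
  }
  add_manifest(sbs$id, "snv", "passenger", TRUE)
  add_manifest(indels$id, "indel", "passenger", TRUE)

  # --- driver point mutations and germline second hits -----------------
  driver_rows <- list()
  extra_svs <- list()
  mk_point <- function(gene, descriptor, variant_class, id, mult = 1) {
    entry <- kb_entry(kb, gene)
    if (is.null(entry)) stop_validate(paste0("driver gene absent from KB: ", gene))
    pos <- as.integer(floor(runif(1, entry$start, entry$end)))
    cn <- segment_total_cn(segments, entry$chrom, pos, max(1, round(config$ploidy)))
    reads <- draw_reads(1, config$purity, config$ploidy, cn, mult = mult)
    is_indel <- variant_class %in% c("frameshift", "inframe_indel")
    tibble(
      chrom = entry$chrom, pos = pos,
      ref = if (is_indel) "AT" else "C",
      alt = if (is_indel) "A" else "T",
      variant_class = variant_class, gene = gene,
      tumor_depth = reads$tumor_depth, tumor_alt = reads$tumor_alt,
      normal_depth = reads$normal_depth, normal_alt = reads$normal_alt,
      mapping_quality = 60, pon_af = 0,
      trinucleotide_context = if (is_indel) NA_character_ else "ACA",
      rep_unit_size = if (is_indel) 1L else NA_integer_,
      rep_count = if (is_indel) 1L else NA_integer_,
      mh_len = if (is_indel) 0L else NA_integer_,
      descriptor = descriptor,
      variant_type = if (is_indel) "indel" else "snv",
      id = id
    )
  }
  di <- 0
  for (d in config$drivers) {
    di <- di + 1
    if (identical(d$type, "point")) {
      id <- sprintf("drv_%03d", di)
      row <- mk_point(d$gene, d$descriptor, d$variant_class, id,
        mult = d$mult %||% 1
      )
      driver_rows <- c(driver_rows, list(row))
      role_class <- if ((kb_entry(kb, d$gene)$role) == "tsg") "tsg_inactivating" else "oncogene_point"
      add_manifest(id, row$variant_type, "driver", TRUE,
        gene = d$gene, driver_class = role_class, descriptor = d$descriptor
      )
    } else if (identical(d$type, "amplification")) {
      cls <- if (d$cn >= 50) "hyperamplification" else "amplification"
      add_manifest(sprintf("amp_%03d", di), "cna", "driver", TRUE,
        gene = d$gene, driver_class = cls
      )
    } else if (identical(d$type, "deletion")) {
      add_manifest(sprintf("del_%03d", di), "cna", "driver", TRUE,
        gene = d$gene, driver_class = "biallelic_deletion"
      )
    } else if (identical(d$type, "fusion")) {
      g5 <- kb_entry(kb, d$partner_5p)
      g3 <- kb_entry(kb, d$gene)
      if (is.null(g5) || is.null(g3)) stop_validate("fusion partner absent from KB")
      p5 <- as.integer(floor(runif(1, g5$start, g5$end)))
      p3 <- as.integer(floor(runif(1, g3$start, g3$end)))
      o5 <- fusion_orientation(g5$strand, TRUE)
      o3 <- fusion_orientation(g3$strand, FALSE)
      if (g5$chrom == g3$chrom) {
        if (p5 <= p3) {
          bp <- list(c1 = g5$chrom, x1 = p5, s1 = o5, c2 = g3$chrom, x2 = p3, s2 = o3)
        } else {
          bp <- list(c1 = g3$chrom, x1 = p3, s1 = o3, c2 = g5$chrom, x2 = p5, s2 = o5)
        }
        type <- if (bp$s1 == bp$s2) "INV" else if (bp$s1 == "+") "DEL" else "DUP"
        size <- bp$x2 - bp$x1
      } else {
        bp <- list(c1 = g5$chrom, x1 = p5, s1 = o5, c2 = g3$chrom, x2 = p3, s2 = o3)
        type <- "TRA"
        size <- NA_integer_
      }
      id <- sprintf("fus_%03d", di)
      extra_svs <- c(extra_svs, list(tibble(
        chrom1 = bp$c1, pos1 = bp$x1, strand1 = bp$s1,
        chrom2 = bp$c2, pos2 = bp$x2, strand2 = bp$s2,
        sv_type = type, size = as.integer(size),
        tumor_support = 12L, normal_support = 0L,
        mapping_quality = 60, pon_freq = 0, homology_len = 2L, id = id
      )))
      add_manifest(id, "sv", "driver", TRUE,
        gene = paste0(d$partner_5p, "-", d$gene), driver_class = "fusion"
      )
    }
  }
  gp <- config$germline_payload
  if (nrow(gp) > 0) {
    for (i in seq_len(nrow(gp))) {
      if (identical(gp$second_hit[i], "somatic_truncating")) {
        id <- sprintf("gsh_%03d", i)
        row <- mk_point(gp$gene[i], NA_character_, "nonsense", id)
        driver_rows <- c(driver_rows, list(row))
        add_manifest(id, "snv", "driver", TRUE,
          gene = gp$gene[i], driver_class = "germline_with_second_hit"
        )
      }
    }
  }

  # --- artifact records: each fails exactly one criterion --------------
  snv_criteria <- c("min_tumor_alt", "max_normal_alt", "min_mapping_quality",
                    "max_normal_vaf", "max_pon_af")
  n_art <- round(config$artifact_fraction * config$n_sbs)
  artifacts <- NULL
  if (n_art > 0) {
    crit <- rep_len(snv_criteria, n_art)
    locs <- sample_positions(n_art)
    channels <- sample(sbs96_channels(), n_art, replace = TRUE)
    fields <- sbs_channel_to_fields(channels)
    artifacts <- tibble(
      chrom = locs$chrom, pos = locs$pos, ref = fields$ref, alt = fields$alt,
      variant_class = "other", gene = "",
      tumor_depth = 40L,
      tumor_alt = ifelse(crit == "min_tumor_alt", 1L, 10L),
      normal_depth = ifelse(crit == "max_normal_alt", 60L,
        ifelse(crit == "max_normal_vaf", 10L, 20L)
      ),
      normal_alt = ifelse(crit == "max_normal_alt", 2L,
        ifelse(crit == "max_normal_vaf", 1L, 0L)
      ),
      mapping_quality = ifelse(crit == "min_mapping_quality", 10, 60),
      pon_af = ifelse(crit == "max_pon_af", 0.05, 0),
      trinucleotide_context = fields$context,
      rep_unit_size = NA_integer_, rep_count = NA_integer_, mh_len = NA_integer_,
      descriptor = NA_character_, variant_type = "snv",
      id = sprintf("art_%05d", seq_len(n_art))
    )
    add_manifest(artifacts$id, "snv", "artifact", FALSE, fail_criterion = crit)
  }

  variants <- bind_rows(sbs, indels, bind_rows(driver_rows), artifacts)

  # --- structural variants ---------------------------------------------
  svs <- simulate_svs(config, references, tallies)
  tallies <- svs$tallies
  sv_tbl <- svs$svs
  add_manifest(sv_tbl$id, "sv", "passenger", TRUE)
  sv_criteria <- c("sv_min_tumor_support", "sv_max_normal_support", "sv_min_mq",
                   "sv_max_pon_freq")
  n_sv_art <- round(config$artifact_fraction * config$n_sv)
  if (n_sv_art > 0) {
    crit <- rep_len(sv_criteria, n_sv_art)
    locs <- sample_positions(n_sv_art)
    art_sv <- tibble(
      chrom1 = locs$chrom, pos1 = locs$pos, strand1 = "+",
      chrom2 = locs$chrom, pos2 = locs$pos + 5000L, strand2 = "-",
      sv_type = "DEL", size = 5000L,
      tumor_support = ifelse(crit == "sv_min_tumor_support", 1L, 8L),
      normal_support = ifelse(crit == "sv_max_normal_support", 2L, 0L),
      mapping_quality = ifelse(crit == "sv_min_mq", 10, 60),
      pon_freq = ifelse(crit == "sv_max_pon_freq", 0.10, 0),
      homology_len = 0L,
      id = sprintf("sva_%04d", seq_len(n_sv_art))
    )
    sv_tbl <- bind_rows(sv_tbl, art_sv)
    add_manifest(art_sv$id, "sv", "artifact", FALSE, fail_criterion = crit)
  }
  sv_tbl <- bind_rows(sv_tbl, bind_rows(extra_svs))

  # --- germline variants -----------------------------------------------
  germline <- bind_rows(
    select(gp, -"second_hit"),
    tibble(
      gene = c("OR2T1", "MUC16"), hgvs_p = c("p.A123T", "p.S45F"),
      population_af = c(0.12, 0.34),
      clinvar_class = c("benign", "none"), predisposition_gene = FALSE
    )
  )
  if (nrow(gp) > 0) {
    add_manifest(sprintf("grm_%03d", seq_len(nrow(gp))), "germline", "germline_payload",
      TRUE, gene = gp$gene, driver_class = ifelse(
        gp$second_hit == "none", NA_character_, "germline_with_second_hit"
      )
    )
  }

  msites <- simulate_microsatellites(config)

  phenotype <- tibble(
    sample_id = config$sample_id,
    hrd = config$hrd_status, msi_status = config$msi_status,
    wgd = config$ploidy > 3.5,
    intended_category = config$intended_category
  )

  ground_truth <- structure(
    list(
      manifest = bind_rows(manifest),
      phenotype = phenotype,
      mixtures = config$mixtures,
      channel_tallies = tallies,
      config = config
    ),
    class = "ground_truth"
  )

  list(
    variants = validate_variants(variants),
    svs = validate_svs(sv_tbl),
    profile = profile,
    germline = validate_germline(germline),
    microsatellites = msites,
    ground_truth = ground_truth
  )
}

simulate_svs <- function(config, references, tallies) {
  ref <- references$SV32
  weights <- config$mixtures$SV32
  if (config$n_sv == 0 || length(weights) == 0) {
    tallies$SV32 <- setNames(integer(0), character(0))
    return(list(svs = empty_sv_table() |> mutate(id = character(0)), tallies = tallies))
  }
  probs <- as.numeric(ref$matrix[, names(weights), drop = FALSE] %*% weights)
  counts <- as.integer(rmultinom(1, config$n_sv, probs))
  tallies$SV32 <- setNames(counts, rownames(ref$matrix))
  channels <- rep(rownames(ref$matrix), counts)
  parse_ch <- strsplit(channels, ":", fixed = TRUE)
  status <- map_chr(parse_ch, 1)
  type <- map_chr(parse_ch, 2)
  sizebin <- map_chr(parse_ch, ~ if (length(.x) == 3) .x[3] else NA_character_)

  # non-clustered placement: widely spaced slots so no 1-Mb window ever
  # collects 8 breakpoints by accident
  rows <- list()
  slot_chrom <- sample(names(CHROM_LENGTHS), 4000, replace = TRUE,
    prob = CHROM_LENGTHS / sum(CHROM_LENGTHS)
  )
  slot_pos <- floor(runif(4000, 1, CHROM_LENGTHS[slot_chrom] - 2.5e7)) + 1
  slot_i <- 0
  next_slot <- function() {
    slot_i <<- slot_i + 1
    list(chrom = slot_chrom[slot_i], pos = as.integer(slot_pos[slot_i]))
  }
  nc_idx <- which(status == "non_clustered")
  for (i in nc_idx) {
    s <- next_slot()
    if (type[i] == "TRA") {
      s2 <- next_slot()
      while (s2$chrom == s$chrom) s2 <- next_slot()
      o <- sv_orientations("TRA")
      rows[[length(rows) + 1]] <- tibble(
        chrom1 = s$chrom, pos1 = s$pos, strand1 = o$s1,
        chrom2 = s2$chrom, pos2 = s2$pos, strand2 = o$s2,
        sv_type = "TRA", size = NA_integer_
      )
    } else {
      rng <- sv_channel_sizes[[sizebin[i]]]
      size <- as.integer(floor(exp(runif(1, log(rng[1]), log(rng[2] - 1)))))
      o <- sv_orientations(type[i])
      rows[[length(rows) + 1]] <- tibble(
        chrom1 = s$chrom, pos1 = s$pos, strand1 = o$s1,
        chrom2 = s$chrom, pos2 = s$pos + size, strand2 = o$s2,
        sv_type = type[i], size = size
      )
    }
  }
  # clustered placement: groups of 8 share a 0.5-Mb start window, so every
  # member has >= 8 breakpoints within 1 Mb
  cl_idx <- which(status == "clustered")
  if (length(cl_idx) > 0) {
    groups <- split(cl_idx, ceiling(seq_along(cl_idx) / 8))
    for (g in groups) {
      anchor <- next_slot()
      offs <- as.integer(sort(floor(runif(length(g), 0, 5e5))))
      for (k in seq_along(g)) {
        i <- g[k]
        p1 <- anchor$pos + offs[k]
        if (type[i] == "TRA") {
          s2 <- next_slot()
          while (s2$chrom == anchor$chrom) s2 <- next_slot()
          o <- sv_orientations("TRA")
          rows[[length(rows) + 1]] <- tibble(
            chrom1 = anchor$chrom, pos1 = p1, strand1 = o$s1,
            chrom2 = s2$chrom, pos2 = s2$pos, strand2 = o$s2,
            sv_type = "TRA", size = NA_integer_
          )
        } else {
          rng <- sv_channel_sizes[[sizebin[i]]]
          size <- as.integer(floor(exp(runif(1, log(rng[1]), log(rng[2] - 1)))))
          o <- sv_orientations(type[i])
          rows[[length(rows) + 1]] <- tibble(
            chrom1 = anchor$chrom, pos1 = p1, strand1 = o$s1,
            chrom2 = anchor$chrom, pos2 = p1 + size, strand2 = o$s2,
            sv_type = type[i], size = size
          )
        }
      }
    }
  }
  svs <- bind_rows(rows)
  # emission order: non-clustered first, then clusters (already so)
  svs <- mutate(svs,
    tumor_support = pmax(2L, rpois(n(), 8)),
    normal_support = 0L, mapping_quality = 60, pon_freq = 0,
    homology_len = as.integer(rpois(n(), 1)),
    id = sprintf("sv_%05d", row_number())
  )
  list(svs = svs, tallies = tallies)
}

simulate_microsatellites <- function(config) {
  n <- config$n_microsat
  if (n == 0) {
    return(tibble(
      locus_id = character(), repeat_unit = character(), sample = character(),
      length = integer(), count = integer()
    ))
  }
  n_unstable <- round(config$instability_fraction * n)
  unstable <- seq_len(n) <= n_unstable # first block; ids carry no order info
  units <- sample(c("A", "T", "CA", "AT"), n, replace = TRUE)
  reflen <- sample(10:20, n, replace = TRUE)
  depth <- 100L
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    L <- reflen[i]
    support <- c(L - 1, L, L + 1)
    p_norm <- c(0.1, 0.8, 0.1)
    norm <- as.integer(rmultinom(1, depth, p_norm))
    if (unstable[i]) {
      # contraction by 2 units in the tumor fraction of reads
      sup_t <- c(L - 3, L - 2, L - 1, L, L + 1)
      p_shift <- c(0.1, 0.8, 0.1, 0, 0)
      p_tum <- config$purity * p_shift + (1 - config$purity) * c(0, 0, p_norm)
      tum <- as.integer(rmultinom(1, depth, p_tum))
      lens_t <- sup_t
    } else {
      tum <- as.integer(rmultinom(1, depth, p_norm))
      lens_t <- support
    }
    bind_rows(
      tibble(
        locus_id = sprintf("ms_%04d", i), repeat_unit = units[i],
        sample = "normal", length = as.integer(support), count = norm
      ),
      tibble(
        locus_id = sprintf("ms_%04d", i), repeat_unit = units[i],
        sample = "tumor", length = as.integer(lens_t), count = tum
      )
    )
  })
  validate_microsatellites(rows)
}

#' Tabulate the ground truth of a simulated call set
#'
#' One row per injected element (passenger, artifact, driver, germline
#' payload) with its intended downstream handling, plus the sample-level
#' phenotype labels.
#'
#' @param ground_truth The `ground_truth` component of [simulate_callset()].
#' @return A tibble with columns `id`, `kind`, `role`, `intended_pass`,
#'   `fail_criterion`, `gene`, `driver_class`, `descriptor`.
#' @export
ground_truth_manifest <- function(ground_truth) {
  stopifnot(inherits(ground_truth, "ground_truth"))
  ground_truth$manifest
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %s: %d records (%s)\n",
    x$config$sample_id, nrow(x$manifest),
    paste(sprintf("%s=%d", names(table(x$manifest$role)), table(x$manifest$role)),
      collapse = ", "
    )
  ))
  invisible(x)
}
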