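# Channel definitions for the three mutational catalog classes.
#
# SBS96: pyrimidine-centric trinucleotide substitution channels in
# substitution-major, then 5' flank, then 3' flank lexicographic order.
#
# ID83: COSMIC-style indel channels; naming is
#   <DEL|INS>.<C|T|rep|MH>.<size>.<bin>
# where 1-bp indels use the pyrimidine-normalized base with the reference
# homopolymer length as bin, longer indels in repeats use unit size (2,3,4,5+)
# by reference repeat count, and deletions with microhomology use deletion
# size by homology length.
#
# SV32: {non_clustered, clustered} x {DEL, DUP, INV} x 5 size bins plus TRA,
# in the fixed order below.

SBS_SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
SBS_BASES <- c("A", "C", "G", "T")

#' SBS96 channel names in canonical order
#'
#' Substitution-major (C>A, C>G, C>T, T>A, T>C, T>G), then 5' flank, then 3'
#' flank, each A, C, G, T. Channel labels look like `"A[C>T]G"`.
#'
#' @return Character vector of length 96.
#' @export
sbs96_channels <- function() {
  unlist(lapply(SBS_SUBSTITUTIONS, function(s) {
    unlist(lapply(SBS_BASES, function(f5) {
      paste0(f5, "[", s, "]", SBS_BASES)
    }))
  }))
}

ID_DEL_HP_BINS <- c("1", "2", "3", "4", "5", "6+")
ID_INS_HP_BINS <- c("0", "1", "2", "3", "4", "5+")
ID_UNIT_BINS <- c("2", "3", "4", "5+")
ID_MH_BINS <- list(`2` = "1", `3` = c("1", "2"), `4` = c("1", "2", "3"),
                   `5+` = c("1", "2", "3", "4", "5+"))

#' ID83 channel names in canonical order
#'
#' 1-bp deletions (C, T by homopolymer length), 1-bp insertions (C, T),
#' longer deletions and insertions at repeats (unit size by repeat count),
#' then deletions with microhomology (size by homology length). 83 channels.
#'
#' @return Character vector of length 83.
#' @export
id83_channels <- function() {
  c(
    paste("DEL", "C", "1", ID_DEL_HP_BINS, sep = "."),
    paste("DEL", "T", "1", ID_DEL_HP_BINS, sep = "."),
    paste("INS", "C", "1", ID_INS_HP_BINS, sep = "."),
    paste("INS", "T", "1", ID_INS_HP_BINS, sep = "."),
    unlist(lapply(ID_UNIT_BINS, function(u) paste("DEL", "rep", u, ID_DEL_HP_BINS, sep = "."))),
    unlist(lapply(ID_UNIT_BINS, function(u) paste("INS", "rep", u, ID_INS_HP_BINS, sep = "."))),
    unlist(lapply(names(ID_MH_BINS), function(s) paste("DEL", "MH", s, ID_MH_BINS[[s]], sep = ".")))
  )
}

SV_SIZE_BINS <- c("<10kb", "10-100kb", "100kb-1Mb", "1-10Mb", ">10Mb")
SV_TYPES_SIZED <- c("DEL", "DUP", "INV")

#' SV32 channel names in canonical order
#'
#' `{non_clustered, clustered}` crossed with DEL/DUP/INV in five size bins
#' (<10kb, 10-100kb, 100kb-1Mb, 1-10Mb, >10Mb) plus translocations (TRA).
#'
#' @return Character vector of length 32.
#' @export
sv32_channels <- function() {
  unlist(lapply(c("non_clustered", "clustered"), function(cl) {
    c(unlist(lapply(SV_TYPES_SIZED, function(ty) paste(cl, ty, SV_SIZE_BINS, sep = ":"))),
      paste(cl, "TRA", sep = ":"))
  }))
}

#' Channel names for a catalog class
#'
#' @param class One of `"SBS96"`, `"ID83"`, `"SV32"`.
#' @return Character vector of channel names in canonical order.
#' @export
catalog_channels <- function(class) {
  switch(arg_match0(class, c("SBS96", "ID83", "SV32")),
    SBS96 = sbs96_channels(),
    ID83 = id83_channels(),
    SV32 = sv32_channels()
  )
}

sv_size_bin <- function(size) {
  cut(size,
    breaks = c(-Inf, 1e4, 1e5, 1e6, 1e7, Inf),
    labels = SV_SIZE_BINS, right = FALSE
  ) |> as.character()
}
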