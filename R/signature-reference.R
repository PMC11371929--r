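# Signature reference objects and the built-in synthetic reference.
#
# A signature_reference holds a channels x signatures probability matrix
# (each column on the simplex) for one catalog class. Real COSMIC matrices
# can be read from TSV with read_signature_reference(); the package also
# builds a fully synthetic, deterministic reference so that simulation and
# refitting are testable with no external downloads. The synthetic profiles
# only mimic the qualitative character of the eponymous COSMIC signatures
# (e.g. SBS1 concentrated on N[C>T]G, ID6 on microhomology deletions); they
# are stand-ins, not the published spectra.

new_signature_reference <- function(mat, class) {
  class <- arg_match0(class, c("SBS96", "ID83", "SV32"))
  channels <- catalog_channels(class)
  if (nrow(mat) != length(channels)) {
    stop_validate(sprintf(
      "%s reference must have %d channel rows, got %d",
      class, length(channels), nrow(mat)
    ))
  }
  if (is.null(rownames(mat))) rownames(mat) <- channels
  if (!identical(rownames(mat), channels)) {
    if (!setequal(rownames(mat), channels)) {
      stop_validate(sprintf("channel names do not match the %s canon", class))
    }
    mat <- mat[channels, , drop = FALSE]
  }
  sums <- colSums(mat)
  if (any(abs(sums - 1) > 1e-6)) {
    stop_validate("signature columns must sum to 1 within 1e-6")
  }
  structure(
    list(class = class, names = colnames(mat), matrix = mat),
    class = "signature_reference"
  )
}

#' @export
print.signature_reference <- function(x, ...) {
  cat(sprintf(
    "<signature_reference> %s: %d channels x %d signatures (%s)\n",
    x$class, nrow(x$matrix), length(x$names),
    paste(head(x$names, 8), collapse = ", ")
  ))
  invisible(x)
}

DEFAULT_SIGNATURE_NAMES <- list(
  SBS96 = c(
    "SBS1", "SBS2", "SBS3", "SBS4", "SBS5", "SBS6", "SBS8", "SBS13",
    "SBS15", "SBS18", "SBS20", "SBS21", "SBS26", "SBS30", "SBS44"
  ),
  ID83 = c("ID1", "ID2", "ID3", "ID6", "ID8"),
  SV32 = c("RS1", "RS2", "RS3", "RS4", "RS5", "RS6")
)

#' MSI-associated SBS signatures
#'
#' The seven single-base-substitution signatures whose combined exposure
#' fraction is used as signature-level evidence for microsatellite
#' instability.
#'
#' @return Character vector of signature names.
#' @export
msi_signatures <- function() {
  c("SBS6", "SBS15", "SBS20", "SBS21", "SBS26", "SBS30", "SBS44")
}

# Qualitative channel emphasis per synthetic signature: regex over channel
# names plus the share of probability mass placed (uniformly) on the matches.
SIGNATURE_EMPHASIS <- list(
  SBS1  = list(pattern = "\\[C>T\\]G", weight = 0.85),
  SBS2  = list(pattern = "T\\[C>T\\]", weight = 0.85),
  SBS3  = list(pattern = ".", weight = 0.88), # flat, HRD-like
  SBS4  = list(pattern = "\\[C>A\\]", weight = 0.80),
  SBS5  = list(pattern = "\\[T>C\\]", weight = 0.70),
  SBS6  = list(pattern = "G\\[C>T\\]", weight = 0.80),
  SBS8  = list(pattern = "\\[C>A\\][CT]", weight = 0.45),
  SBS13 = list(pattern = "T\\[C>G\\]", weight = 0.85),
  SBS15 = list(pattern = "C\\[C>T\\]", weight = 0.80),
  SBS18 = list(pattern = "\\[C>A\\]A", weight = 0.70),
  ID1   = list(pattern = "^INS\\.T\\.1\\.(4|5\\+)", weight = 0.85),
  ID2   = list(pattern = "^DEL\\.T\\.1\\.(5|6\\+)", weight = 0.85),
  ID3   = list(pattern = "^DEL\\.C\\.1\\.(1|2)", weight = 0.85),
  ID6   = list(pattern = "^DEL\\.MH", weight = 0.88),
  ID8   = list(pattern = "^DEL\\.rep", weight = 0.70),
  RS1   = list(pattern = "^non_clustered:DUP:(100kb-1Mb|1-10Mb)", weight = 0.85),
  RS2   = list(pattern = "^non_clustered:TRA", weight = 0.80),
  RS3   = list(pattern = "^non_clustered:DUP:(<10kb|10-100kb)", weight = 0.85),
  RS4   = list(pattern = "^clustered:", weight = 0.85),
  RS5   = list(pattern = "^non_clustered:DEL:(<10kb|10-100kb)", weight = 0.85),
  RS6   = list(pattern = "^non_clustered:INV", weight = 0.80)
)

synthetic_profile <- function(name, channels) {
  # deterministic sparse base unique to the signature name
  seed <- (sum(utf8ToInt(name)) * 7919 + length(channels)) %% .Machine$integer.max
  base <- withr::with_seed(seed, stats::rgamma(length(channels), shape = 0.25))
  base <- base / sum(base)
  emph <- SIGNATURE_EMPHASIS[[name]]
  if (is.null(emph)) {
    prof <- base
  } else {
    hit <- grepl(emph$pattern, channels)
    focus <- withr::with_seed(seed + 1, stats::rgamma(sum(hit), shape = 1.5))
    focus <- focus / sum(focus)
    prof <- (1 - emph$weight) * base
    prof[hit] <- prof[hit] + emph$weight * focus
  }
  prof / sum(prof)
}

#' Build the synthetic signature reference for one catalog class
#'
#' Constructs a deterministic, fully synthetic channels-by-signatures
#' probability matrix. Profiles are sparse pseudo-random spectra with
#' hand-coded emphases that echo the qualitative character of the named
#' signatures (see source); they are not the COSMIC spectra and are intended
#' for simulation, testing and self-contained analyses.
#'
#' @param class Catalog class: `"SBS96"`, `"ID83"` or `"SV32"`.
#' @param signatures Signature names to include (defaults to the built-in
#'   set for the class).
#' @return A `signature_reference`.
#' @examples
#' ref <- synthetic_signature_reference("SBS96")
#' colSums(ref$matrix)[1:3]
#' @export
synthetic_signature_reference <- function(class,
                                          signatures = DEFAULT_SIGNATURE_NAMES[[class]]) {
  class <- arg_match0(class, c("SBS96", "ID83", "SV32"))
  channels <- catalog_channels(class)
  mat <- vapply(signatures, synthetic_profile, numeric(length(channels)),
    channels = channels
  )
  rownames(mat) <- channels
  colnames(mat) <- signatures
  new_signature_reference(mat, class)
}

#' Synthetic signature references for all three catalog classes
#'
#' @return Named list with elements `SBS96`, `ID83`, `SV32`, each a
#'   [synthetic_signature_reference()].
#' @export
default_signature_references <- function() {
  list(
    SBS96 = synthetic_signature_reference("SBS96"),
    ID83 = synthetic_signature_reference("ID83"),
    SV32 = synthetic_signature_reference("SV32")
  )
}

# Cancer-type default signature sets used to seed refitting; fully
# overridable. Types not listed fall back to "other".
DEFAULT_SIGNATURE_SETS <- list(
  lung_adenocarcinoma = list(
    SBS96 = c("SBS1", "SBS2", "SBS4", "SBS5", "SBS13"),
    ID83 = c("ID1", "ID2", "ID3"), SV32 = c("RS1", "RS2", "RS6")
  ),
  colorectal = list(
    SBS96 = c("SBS1", "SBS5", "SBS18"),
    ID83 = c("ID1", "ID2"), SV32 = c("RS1", "RS2", "RS6")
  ),
  stomach = list(
    SBS96 = c("SBS1", "SBS5", "SBS18"),
    ID83 = c("ID1", "ID2"), SV32 = c("RS1", "RS2", "RS6")
  ),
  breast = list(
    SBS96 = c("SBS1", "SBS2", "SBS3", "SBS5", "SBS13"),
    ID83 = c("ID1", "ID2", "ID6"), SV32 = c("RS1", "RS3", "RS5", "RS6")
  ),
  prostate = list(
    SBS96 = c("SBS1", "SBS3", "SBS5", "SBS8"),
    ID83 = c("ID1", "ID2", "ID6"), SV32 = c("RS1", "RS3", "RS5", "RS6")
  ),
  cholangiocarcinoma = list(
    SBS96 = c("SBS1", "SBS5"),
    ID83 = c("ID1", "ID2"), SV32 = c("RS1", "RS2", "RS6")
  ),
  urothelial = list(
    SBS96 = c("SBS1", "SBS2", "SBS5", "SBS13"),
    ID83 = c("ID1", "ID2"), SV32 = c("RS1", "RS2", "RS6")
  ),
  other = list(
    SBS96 = c("SBS1", "SBS5"),
    ID83 = c("ID1", "ID2"), SV32 = c("RS1", "RS2", "RS6")
  )
)

#' Default signature set for a cancer type and catalog class
#'
#' Refitting starts from a per-tumor-type default signature set and only
#' widens it when the reconstruction cosine similarity falls below the
#' refinement trigger. The built-in table covers the tumor types used by the
#' simulator; unknown types fall back to a minimal clock-like set.
#'
#' @param cancer_type Tumor type label (e.g. `"lung_adenocarcinoma"`).
#' @param class Catalog class.
#' @return Character vector of signature names.
#' @export
default_signature_set <- function(cancer_type, class) {
  class <- arg_match0(class, c("SBS96", "ID83", "SV32"))
  sets <- DEFAULT_SIGNATURE_SETS[[cancer_type]] %||% DEFAULT_SIGNATURE_SETS$other
  sets[[class]]
}
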