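#' Round half away from zero
#'
#' Rounds `x` to `digits` decimal places with ties going half-up (0.5 rounds
#' away from zero), the convention used for all printed percentages in
#' cohort summaries. Base R's `round()` rounds half-to-even, which would
#' print 81.25% as 81.2% rather than 81.3%.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(81.25, 1) # 81.3
#' round_half_up(100 * 28 / 79, 1) # 35.4
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # small eps guards against binary representation of exact .5 ties
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Cosine similarity between two non-negative vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return Similarity in `[0, 1]`; `NA` if either vector has zero norm.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  min(1, sum(a * b) / (na * nb))
}

# Canonical chromosome ordering: 1..22, X, Y first, anything else after,
# alphabetically. Unknown contigs are accepted verbatim.
chrom_rank <- function(chrom) {
  canon <- c(as.character(1:22), "X", "Y")
  stripped <- sub("^chr", "", chrom)
  idx <- match(stripped, canon)
  ifelse(is.na(idx), length(canon) + as.numeric(factor(stripped)), idx)
}

#' Order a table of genomic records canonically
#'
#' Sorts by chromosome (1..22, X, Y, then other contigs) and position.
#'
#' @param df A data frame with `chrom` and `pos` (or `start`) columns.
#' @return The sorted tibble.
#' @export
arrange_genome <- function(df) {
  poscol <- if ("pos" %in% names(df)) "pos" else "start"
  df |>
    mutate(.rk = chrom_rank(.data$chrom)) |>
    arrange(.data$.rk, .data[[poscol]]) |>
    select(-".rk")
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  vapply(strsplit(x, ""), function(b) {
    paste(rev(unname(DNA_COMPLEMENT[b])), collapse = "")
  }, character(1))
}

stop_parse <- function(msg, line = NULL) {
  if (!is.null(line)) msg <- sprintf("%s (line %d)", msg, line)
  abort(msg, class = "oncointerpret_parse_error")
}

stop_validate <- function(msg) {
  abort(msg, class = "oncointerpret_validation_error")
}

note <- function(msg) {
  inform(msg, class = "oncointerpret_note")
}
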