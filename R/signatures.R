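# Signature refitting: non-negative least squares over a reference
# signature matrix restricted to an active set, with cosine-similarity
# driven refinement of the set (greedy forward addition, backward pruning).

new_signature_exposure <- function(class, exposures, cosine, total,
                                   degenerate = FALSE, refined = FALSE,
                                   best_effort = FALSE, trace = NULL) {
  structure(
    list(
      class = class, exposures = exposures, active_set = names(exposures),
      cosine = cosine, total = total, degenerate = degenerate,
      refined = refined, best_effort = best_effort,
      trace = trace %||% tibble(action = character(), signature = character(), cosine = numeric())
    ),
    class = "signature_exposure"
  )
}

#' @export
print.signature_exposure <- function(x, ...) {
  cat(sprintf(
    "<signature_exposure> %s: %d mutations, cosine %.3f%s\n",
    x$class, round(x$total), x$cosine,
    if (x$best_effort) " (best-effort)" else ""
  ))
  top <- sort(x$exposures, decreasing = TRUE)
  top <- top[top > 0]
  if (length(top) > 0) {
    cat(paste0(
      "  ", names(top), ": ", round(top, 1), collapse = "\n"
    ), "\n")
  }
  invisible(x)
}

#' Fit signature exposures by non-negative least squares
#'
#' Solves `min ||M x - c||_2` over `x >= 0` with `M` restricted to the
#' active signature columns (Lawson-Hanson NNLS), then rescales `x` so the
#' attributed counts sum to the catalog total whenever the solution is
#' non-degenerate. The reconstruction quality is reported as the cosine
#' similarity between the observed catalog and `M x`. An all-zero catalog
#' yields zero exposures with cosine reported as 1.0 and a degenerate-input
#' flag (this avoids NaN propagation while preserving the information).
#'
#' @param catalog A `mutational_catalog`.
#' @param reference A `signature_reference` of the same class.
#' @param active_set Signature names to fit (non-empty subset of the
#'   reference; defaults to all).
#' @return A `signature_exposure`.
#' @export
fit_exposures_nnls <- function(catalog, reference, active_set = reference$names) {
  if (!identical(catalog_class(catalog), reference$class)) {
    stop_validate(sprintf(
      "catalog class %s does not match reference class %s",
      catalog_class(catalog), reference$class
    ))
  }
  if (length(active_set) == 0) stop_validate("active_set must be non-empty")
  missing_sigs <- setdiff(active_set, reference$names)
  if (length(missing_sigs) > 0) {
    stop_validate(paste0(
      "signatures absent from the reference: ", paste(missing_sigs, collapse = ", ")
    ))
  }
  counts <- catalog_counts(catalog)
  total <- sum(counts)
  if (total == 0) {
    return(new_signature_exposure(
      reference$class, setNames(rep(0, length(active_set)), active_set),
      cosine = 1.0, total = 0, degenerate = TRUE
    ))
  }
  m <- reference$matrix[, active_set, drop = FALSE]
  x <- pracma::lsqnonneg(m, unname(counts))$x
  recon <- as.numeric(m %*% x)
  cosine <- cosine_similarity(unname(counts), recon)
  if (is.na(cosine)) cosine <- 0
  if (sum(x) > 0) x <- x * (total / sum(x))
  new_signature_exposure(
    reference$class, setNames(x, active_set),
    cosine = cosine, total = total
  )
}

#' Refine the active signature set to explain a catalog
#'
#' Starts from the given (typically cancer-type default) signature set. If
#' the NNLS reconstruction reaches cosine similarity >= `cosine_target`
#' (default 0.90; the trigger is strictly-below, so exactly 0.90 does not
#' refine), the fit is returned unchanged. Otherwise candidate signatures
#' from the full reference are added greedily - each step adds the candidate
#' with the largest cosine gain - until the target is reached or no
#' candidate improves the cosine by more than `gain_min`. Signatures
#' attributing less than `prune_frac` of the mutations are then pruned
#' backward when removal costs less than `gain_min` cosine. If the target is
#' still unreached the result carries a best-effort flag (the automated
#' stand-in for manual review). Every addition and removal is recorded in
#' the trace.
#'
#' @param catalog A `mutational_catalog`.
#' @param reference A `signature_reference` of the same class.
#' @param initial_set Starting signature names (e.g.
#'   [default_signature_set()]).
#' @param cosine_target Refinement trigger and goal (default 0.90).
#' @param gain_min Minimum cosine gain to accept a forward step, and the
#'   maximum cosine loss tolerated by a pruning step (default 0.005).
#' @param prune_frac Attribution fraction below which a signature is a
#'   pruning candidate (default 0.01).
#' @return A `signature_exposure` with `refined`, `best_effort` and `trace`
#'   populated.
#' @export
refine_signature_set <- function(catalog, reference, initial_set,
                                 cosine_target = 0.90, gain_min = 0.005,
                                 prune_frac = 0.01) {
  fit <- fit_exposures_nnls(catalog, reference, initial_set)
  trace <- tibble(action = "initial", signature = NA_character_, cosine = fit$cosine)
  if (fit$degenerate || fit$cosine >= cosine_target) {
    fit$trace <- trace
    return(fit)
  }
  active <- initial_set
  current <- fit
  refined <- FALSE
  repeat {
    if (current$cosine >= cosine_target) break
    candidates <- setdiff(reference$names, active)
    if (length(candidates) == 0) break
    trials <- map(candidates, function(s) fit_exposures_nnls(catalog, reference, c(active, s)))
    gains <- map_dbl(trials, "cosine") - current$cosine
    best <- which.max(gains)
    if (gains[best] <= gain_min) break
    active <- c(active, candidates[best])
    current <- trials[[best]]
    refined <- TRUE
    trace <- bind_rows(trace, tibble(
      action = "add", signature = candidates[best], cosine = current$cosine
    ))
  }
  repeat {
    frac <- current$exposures / max(current$total, 1)
    prunable <- names(frac)[frac < prune_frac]
    if (length(prunable) == 0 || length(active) <= 1) break
    removed <- FALSE
    for (s in prunable) {
      if (length(active) <= 1) break
      trial <- fit_exposures_nnls(catalog, reference, setdiff(active, s))
      if (current$cosine - trial$cosine < gain_min) {
        active <- setdiff(active, s)
        current <- trial
        refined <- TRUE
        trace <- bind_rows(trace, tibble(
          action = "remove", signature = s, cosine = current$cosine
        ))
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  current$refined <- refined
  current$best_effort <- current$cosine < cosine_target
  current$trace <- trace
  current
}

#' Exposure fractions and printed percentages
#'
#' One row per active signature with the attributed count, the fraction of
#' the catalog total, and the percentage rounded half-up to one decimal (the
#' reporting convention; e.g. 1,452 of 7,232 substitutions prints as 20.1).
#'
#' @param exposure A `signature_exposure`, or a named numeric vector of
#'   attributed counts.
#' @return Tibble with `signature`, `count`, `fraction`, `pct`.
#' @export
exposure_fractions <- function(exposure) {
  if (is.numeric(exposure)) {
    exposure <- list(exposures = exposure, total = sum(exposure))
  }
  total <- exposure$total
  frac <- if (total > 0) exposure$exposures / total else rep(0, length(exposure$exposures))
  tibble(
    signature = names(exposure$exposures),
    count = unname(exposure$exposures),
    fraction = unname(frac),
    pct = round_half_up(100 * unname(frac), 1)
  )
}

#' Proportion of MSI-associated signature exposure
#'
#' Sum of the fitted exposures over the seven MSI-related substitution
#' signatures (SBS6, SBS15, SBS20, SBS21, SBS26, SBS30, SBS44) divided by
#' the catalog total; 0 for an empty catalog.
#'
#' @param exposure An SBS96 `signature_exposure`.
#' @return Fraction in `[0, 1]`.
#' @export
msi_signature_proportion <- function(exposure) {
  if (exposure$total == 0) return(0)
  hit <- intersect(names(exposure$exposures), msi_signatures())
  sum(exposure$exposures[hit]) / exposure$total
}

#' @export
tidy.signature_exposure <- function(x, ...) exposure_fractions(x)

#' @export
glance.signature_exposure <- function(x, ...) {
  tibble(
    class = x$class, total = x$total, cosine = x$cosine,
    n_active = length(x$active_set), n_nonzero = sum(x$exposures > 0),
    refined = x$refined, best_effort = x$best_effort, degenerate = x$degenerate
  )
}
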