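# ggplot2 methods for the package's result objects.

#' Plot a mutational catalog
#'
#' Bar chart over the class's channels in canonical order, colored by
#' channel group (substitution type, indel family, or SV type).
#'
#' @param object A `mutational_catalog`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mutational_catalog <- function(object, ...) {
  cl <- catalog_class(object)
  group <- switch(cl,
    SBS96 = stringr::str_extract(object$channel, "\\[.*\\]"),
    ID83 = stringr::str_extract(object$channel, "^[A-Z]+\\.[A-Za-z]+"),
    SV32 = stringr::str_extract(object$channel, "^[a-z_]+:[A-Z]+")
  )
  df <- mutate(as_tibble(object),
    channel = factor(.data$channel, levels = .data$channel), group = group
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$count, fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Mutations", title = paste(cl, "catalog")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, size = 4, vjust = 0.5),
      legend.position = "none"
    )
}

#' Plot fitted signature exposures
#'
#' @param object A `signature_exposure`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.signature_exposure <- function(object, ...) {
  df <- filter(exposure_fractions(object), .data$count > 0)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$signature, -.data$count), y = .data$count
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "Attributed mutations",
      title = sprintf("%s exposures (cosine %.3f)", object$class, object$cosine)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cohort category summary
#'
#' @param object A `cohort_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cohort_summary <- function(object, ...) {
  df <- filter(object, !.data$category %in% c("supportive", "reported"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n, fill = .data$arm)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$arm), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Patients") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
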