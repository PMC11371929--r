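# Gene knowledgebase: roles, hotspot recurrence, drug/trial links,
# resistance rules, deleteriousness predictions and (fictitious) genomic
# intervals for fusion and copy-number mapping. Shipped as a versioned JSON
# fixture; no live database access.

#' Read a gene knowledgebase from JSON
#'
#' The knowledgebase is a versioned JSON document with per-gene entries
#' (role, interval, hotspots with COSMIC-style recurrence counts, drug and
#' trial links, resistance rules, SIFT/PolyPhen/ClinVar predictions) plus
#' top-level phenotype rules (MSI-H, HRD), a fusion-pair allowlist and the
#' predisposition-gene list. The bundled fixture is synthetic: intervals are
#' fictitious fixture coordinates and links cover only the genes the rule
#' engine exercises.
#'
#' @param path JSON file (defaults to the bundled fixture).
#' @return A `gene_kb` object.
#' @export
read_gene_kb <- function(path = system.file("extdata", "gene_kb.json",
                           package = "oncointerpret")) {
  if (!file.exists(path)) stop_validate(paste0("no such file: ", path))
  raw <- jsonlite::read_json(path)
  genes <- raw$genes
  names(genes) <- map_chr(genes, "gene")
  bad <- keep(genes, ~ !(.x$role %in% c("oncogene", "tsg", "both")))
  if (length(bad) > 0) {
    stop_validate(paste0("unknown gene role for: ", paste(names(bad), collapse = ", ")))
  }
  for (g in genes) {
    if (g$start > g$end) stop_validate(paste0("malformed interval for ", g$gene))
    for (h in g$hotspots) {
      if (h$cosmic_count < 0) stop_validate(paste0("negative cosmic_count in ", g$gene))
    }
  }
  gene_table <- purrr::map_dfr(genes, function(g) {
    tibble(
      gene = g$gene, role = g$role, chrom = as.character(g$chrom),
      start = as.integer(g$start), end = as.integer(g$end),
      strand = g$strand, n_exons = as.integer(g$n_exons),
      fusion_driver = isTRUE(g$fusion_driver)
    )
  })
  structure(
    list(
      version = raw$version,
      synthetic = isTRUE(raw$synthetic),
      cosmic_recurrence_threshold = raw$cosmic_recurrence_threshold %||% 10,
      predisposition_genes = unlist(raw$predisposition_genes),
      fusion_pairs = map(raw$fusion_pairs, unlist),
      phenotype_rules = raw$phenotype_rules,
      genes = genes,
      gene_table = gene_table
    ),
    class = "gene_kb"
  )
}

#' The bundled synthetic gene knowledgebase
#'
#' @return A `gene_kb` object (cached per session).
#' @export
default_gene_kb <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_gene_kb()
    cache
  }
})

#' @export
print.gene_kb <- function(x, ...) {
  cat(sprintf(
    "<gene_kb> version %s%s: %d genes, %d phenotype rules\n",
    x$version, if (x$synthetic) " (synthetic)" else "",
    length(x$genes), length(x$phenotype_rules)
  ))
  invisible(x)
}

#' Look up one gene's knowledgebase entry
#'
#' @param kb A `gene_kb`.
#' @param gene Gene symbol.
#' @return The entry (a list), or `NULL` if absent.
#' @export
kb_entry <- function(kb, gene) {
  kb$genes[[gene]]
}

# Does the entry carry any drug link for the given alteration kind?
kb_has_drug <- function(entry, alteration, descriptor = NULL) {
  any(map_lgl(entry$drugs, function(d) {
    if (d$alteration != alteration) return(FALSE)
    if (!is.null(descriptor) && !is.null(d$descriptors)) {
      return(descriptor %in% unlist(d$descriptors))
    }
    TRUE
  }))
}

kb_drug_matches <- function(entry, alteration, descriptor, cancer_type) {
  keep(entry$drugs, function(d) {
    if (d$alteration != alteration) return(FALSE)
    if (!is.null(d$descriptors) && !is.null(descriptor) &&
      !(descriptor %in% unlist(d$descriptors))) {
      return(FALSE)
    }
    types <- d$cancer_types
    identical(types, "any") || identical(types, list("any")) ||
      cancer_type %in% unlist(types)
  })
}
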