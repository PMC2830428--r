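# Gene-list parsing and per-gene boolean annotation flags.

#' Read a plain-text gene list
#'
#' One gene id per line; `#` comment lines allowed; surrounding whitespace
#' stripped; duplicates removed; case preserved.
#'
#' @param path Path to a text file, or a character vector of lines.
#' @return Character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  lines <- .read_input_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    warning("gene list is empty")
    return(character())
  }
  unique(lines)
}

#' Non-redundant union of gene sets
#'
#' @param ... Two or more character vectors of gene ids.
#' @return The deduplicated union.
#' @export
merge_nonredundant <- function(...) {
  sets <- list(...)
  if (length(sets) < 2L) stop("supply at least two sets")
  unique(unlist(sets, use.names = FALSE))
}

#' Per-gene annotation flag table
#'
#' Builds one row per universe gene with boolean membership flags for the
#' disease, cancer-driver, duplicate and singleton sets.  Duplicability is
#' tri-state: a gene in neither the duplicate nor the singleton list has
#' both flags FALSE (unknown duplicability) and is excluded from
#' duplicability denominators downstream.  A gene present in both lists is
#' an input inconsistency and raises an error.
#'
#' @param universe Character vector of gene ids (the profiled genes).
#' @param disease,driver,duplicate,singleton Character vectors of gene ids
#'   (any may be empty).
#' @return A data.frame with columns `gene_id`, `is_disease`,
#'   `is_cancer_driver`, `is_duplicate`, `is_singleton`.
#' @export
build_flags <- function(universe, disease = character(), driver = character(),
                        duplicate = character(), singleton = character()) {
  if (length(universe) == 0L) stop("'universe' must be non-empty")
  universe <- unique(universe)
  both <- intersect(duplicate, singleton)
  if (length(both) > 0L) {
    stop("gene(s) listed as both duplicate and singleton: ",
         paste(utils::head(sort(both), 10L), collapse = ", "))
  }
  data.frame(gene_id = universe,
             is_disease = universe %in% disease,
             is_cancer_driver = universe %in% driver,
             is_duplicate = universe %in% duplicate,
             is_singleton = universe %in% singleton,
             stringsAsFactors = FALSE)
}
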