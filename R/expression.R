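# Tri-state differential-expression call matrix and the per-gene DER.

#' Read a tri-state differential-expression call matrix
#'
#' Expects a TSV with a header row of dataset ids and one row per gene:
#' the gene id followed by one value per dataset, `1` (differentially
#' expressed), `0` (measured, not differentially expressed) or `NA` (not
#' measured in that dataset).
#'
#' @param path Path to the TSV, or a character vector of lines.
#' @return An integer matrix (values 1, 0 or NA) with gene ids as row
#'   names and dataset ids as column names.
#' @export
read_de_matrix <- function(path) {
  lines <- .read_input_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("DE matrix needs a header row and at least one gene row")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  datasets <- header[-1L]
  if (length(datasets) == 0L) stop("DE matrix header has no dataset columns")
  if (anyDuplicated(datasets)) stop("duplicate dataset id in header: ",
                                    datasets[duplicated(datasets)][1L])
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != length(datasets) + 1L)) {
    bad <- which(nf != length(datasets) + 1L)[1L]
    stop("ragged DE matrix: line ", bad + 1L, " has ", nf[bad],
         " fields, expected ", length(datasets) + 1L)
  }
  gene_ids <- vapply(rows, `[[`, "", 1L)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id in DE matrix: ", gene_ids[duplicated(gene_ids)][1L])
  }
  vals <- unlist(lapply(rows, `[`, -1L), use.names = FALSE)
  ok <- vals %in% c("0", "1", "NA")
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop("unknown token '", vals[bad], "' at line ",
         (bad - 1L) %/% length(datasets) + 2L, " of DE matrix (expected 1, 0 or NA)")
  }
  m <- matrix(suppressWarnings(as.integer(vals)), nrow = length(gene_ids),
              byrow = TRUE, dimnames = list(gene_ids, datasets))
  m
}

#' Genes measured in at least a minimum fraction of datasets
#'
#' A gene is retained iff the number of datasets in which it was measured
#' (call is 1 or 0, not NA) is at least `ceiling(min_fraction * n_datasets)`
#' ("at least" semantics; with 476 datasets and the default 5% the
#' threshold is 24).  An absolute count can be given instead via
#' `min_count`, which overrides `min_fraction`.
#'
#' @param de An integer matrix as returned by [read_de_matrix()].
#' @param min_fraction Minimum measured fraction in (0, 1]; default 0.05.
#' @param min_count Optional absolute minimum measured-dataset count.
#' @return Character vector of retained gene ids (in matrix row order).
#' @export
filter_measured <- function(de, min_fraction = 0.05, min_count = NULL) {
  if (!is.matrix(de) || nrow(de) == 0L || ncol(de) == 0L) {
    stop("'de' must be a non-empty gene x dataset matrix")
  }
  if (is.null(min_count)) {
    if (min_fraction <= 0 || min_fraction > 1) {
      stop("'min_fraction' must be in (0, 1]")
    }
    min_count <- ceiling(min_fraction * ncol(de))
  }
  n_measured <- rowSums(!is.na(de))
  rownames(de)[n_measured >= min_count]
}

#' Per-gene differential expression ratio (DER)
#'
#' For each gene, DER = (number of datasets in which it was called
#' differentially expressed) / (number of datasets in which it was
#' measured).  Genes measured in no dataset are dropped with a warning.
#'
#' @param de An integer matrix as returned by [read_de_matrix()].
#' @return A data.frame with columns `gene_id`, `n_measured`, `n_de`,
#'   `der` (in [0, 1]).
#' @export
compute_der <- function(de) {
  if (!is.matrix(de) || nrow(de) == 0L) stop("'de' must be a non-empty matrix")
  n_measured <- rowSums(!is.na(de))
  n_de <- rowSums(de == 1L, na.rm = TRUE)
  if (any(n_measured == 0L)) {
    warning(sum(n_measured == 0L),
            " gene(s) measured in no dataset dropped from DER table")
  }
  keep <- n_measured > 0L
  data.frame(gene_id = rownames(de)[keep],
             n_measured = as.integer(n_measured[keep]),
             n_de = as.integer(n_de[keep]),
             der = unname(n_de[keep] / n_measured[keep]),
             stringsAsFactors = FALSE)
}

#' Write a DER table to TSV
#'
#' @param der_table Output of [compute_der()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_der_table <- function(der_table, path) {
  out <- der_table
  out$der <- sprintf("%.3f", out$der)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
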