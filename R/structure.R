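# BED12 gene models -> per-gene structure metrics (lengths, exon counts).

#' Read gene models from a BED12 file
#'
#' Decodes each BED12 line into a transcript model: transcript span,
#' coding span (thickStart/thickEnd; equal values mean non-coding) and
#' exon intervals reconstructed from blockSizes/blockStarts.  Gene
#' grouping uses the name field, interpreted as `gene|transcript` when it
#' contains a `|`; otherwise a `tx2gene` mapping (transcript id ->
#' gene id) must be supplied, failing which each transcript is its own
#' gene.
#'
#' @param path Path to a BED12 file, or a character vector of lines.
#' @param tx2gene Optional two-column data.frame (`transcript_id`,
#'   `gene_id`) or named character vector mapping transcript to gene ids.
#' @return A data.frame with one row per transcript: `tx_id`, `gene_id`,
#'   `chrom`, `strand`, `tx_start`, `tx_end`, `cds_start`, `cds_end`, and
#'   list columns `exon_starts`, `exon_ends` (0-based half-open).
#' @export
read_bed12 <- function(path, tx2gene = NULL) {
  lines <- .read_input_lines(path)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stop("no gene models found in input")
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    bad <- idx[which(nf < 12L)[1L]]
    stop("malformed BED12 line ", bad, ": fewer than 12 fields")
  }
  get <- function(k) vapply(fields, `[[`, "", k)
  chrom <- get(1L)
  tx_start <- as.integer(get(2L)); tx_end <- as.integer(get(3L))
  name <- get(4L)
  strand <- get(6L)
  cds_start <- as.integer(get(7L)); cds_end <- as.integer(get(8L))
  block_count <- as.integer(get(10L))
  block_sizes <- strsplit(sub(",$", "", get(11L)), ",", fixed = TRUE)
  block_starts <- strsplit(sub(",$", "", get(12L)), ",", fixed = TRUE)
  exon_starts <- vector("list", length(idx))
  exon_ends <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    sizes <- as.integer(block_sizes[[i]])
    starts <- as.integer(block_starts[[i]])
    line_no <- idx[i]
    if (length(sizes) != block_count[i] || length(starts) != block_count[i]) {
      stop("BED12 line ", line_no, ": blockCount does not match block lists")
    }
    es <- tx_start[i] + starts
    ee <- es + sizes
    if (starts[1L] != 0L || ee[block_count[i]] != tx_end[i]) {
      stop("BED12 line ", line_no,
           ": blocks must start at chromStart and end at chromEnd")
    }
    if (block_count[i] > 1L && any(es[-1L] < ee[-block_count[i]])) {
      stop("BED12 line ", line_no, ": blocks overlap or are unsorted")
    }
    if (cds_start[i] < tx_start[i] || cds_end[i] > tx_end[i] ||
        cds_start[i] > cds_end[i]) {
      stop("BED12 line ", line_no, ": thick (CDS) interval outside transcript span")
    }
    exon_starts[[i]] <- es
    exon_ends[[i]] <- ee
  }
  if (!all(strand %in% c("+", "-"))) {
    bad <- idx[which(!strand %in% c("+", "-"))[1L]]
    stop("BED12 line ", bad, ": strand must be '+' or '-'")
  }
  gene_id <- .map_tx_to_gene(name, tx2gene)
  out <- data.frame(tx_id = name, gene_id = gene_id, chrom = chrom,
                    strand = strand, tx_start = tx_start, tx_end = tx_end,
                    cds_start = cds_start, cds_end = cds_end,
                    stringsAsFactors = FALSE)
  out$exon_starts <- exon_starts
  out$exon_ends <- exon_ends
  out
}

.map_tx_to_gene <- function(name, tx2gene) {
  if (is.null(tx2gene)) {
    ifelse(grepl("|", name, fixed = TRUE),
           sub("\\|.*$", "", name), name)
  } else {
    if (is.data.frame(tx2gene)) {
      map <- stats::setNames(as.character(tx2gene[[2L]]),
                             as.character(tx2gene[[1L]]))
    } else {
      map <- tx2gene
    }
    hit <- map[name]
    if (anyNA(hit)) {
      stop("transcript id(s) missing from tx2gene mapping: ",
           paste(utils::head(name[is.na(hit)], 5L), collapse = ", "))
    }
    unname(hit)
  }
}

#' Select one representative transcript per gene
#'
#' Picks the longest transcript of each gene.  `longest = "spliced"` (the
#' default) maximises the mature-transcript length (sum of exon lengths);
#' `"span"` maximises the genomic span.  Ties are broken by the larger
#' genomic span, then the lexicographically smallest transcript id, so
#' selection is deterministic.
#'
#' @param models A transcript data.frame from [read_bed12()].
#' @param longest `"spliced"` (default) or `"span"`.
#' @return A data.frame of the same shape with one row per gene.
#' @export
select_representative <- function(models, longest = c("spliced", "span")) {
  longest <- match.arg(longest)
  if (nrow(models) == 0L) stop("no transcripts supplied")
  spliced <- vapply(seq_len(nrow(models)), function(i) {
    sum(models$exon_ends[[i]] - models$exon_starts[[i]])
  }, numeric(1))
  span <- models$tx_end - models$tx_start
  primary <- if (longest == "spliced") spliced else span
  ord <- order(models$gene_id, -primary, -span, models$tx_id)
  m <- models[ord, , drop = FALSE]
  m <- m[!duplicated(m$gene_id), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Gene-structure metrics of transcript models
#'
#' For each transcript: genomic length (span), spliced CDS length, 5'/3'
#' UTR lengths, total exon length, total intron length, and exon/intron
#' counts.  UTR lengths follow the genomic-coordinate convention by
#' default: on the plus strand the 5' UTR is `cds_start - tx_start` and
#' the 3' UTR is `tx_end - cds_end` (swapped on the minus strand).  With
#' `utr_mode = "spliced"` only exonic bases are counted in each UTR.
#' Non-coding transcripts (`cds_start == cds_end`) get `NA` for CDS and
#' UTR fields.
#'
#' @param models A transcript data.frame from [read_bed12()], typically
#'   after [select_representative()].
#' @param utr_mode `"genomic"` (default) or `"spliced"`.
#' @return A data.frame with columns `gene_id`, `genomic_len`, `cds_len`,
#'   `utr5_len`, `utr3_len`, `exon_total_len`, `intron_total_len`,
#'   `n_exon`, `n_intron`.
#' @export
structure_metrics <- function(models, utr_mode = c("genomic", "spliced")) {
  utr_mode <- match.arg(utr_mode)
  if (nrow(models) == 0L) stop("no transcripts supplied")
  n <- nrow(models)
  genomic_len <- models$tx_end - models$tx_start
  exon_total <- vapply(seq_len(n), function(i) {
    sum(models$exon_ends[[i]] - models$exon_starts[[i]])
  }, numeric(1))
  n_exon <- vapply(models$exon_starts, length, integer(1))
  coding <- models$cds_start < models$cds_end
  exonic_overlap <- function(i, lo, hi) {
    # total exonic bases of transcript i inside [lo, hi)
    s <- pmax(models$exon_starts[[i]], lo)
    e <- pmin(models$exon_ends[[i]], hi)
    sum(pmax(e - s, 0L))
  }
  cds_len <- utr5 <- utr3 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!coding[i]) next
    cds_len[i] <- exonic_overlap(i, models$cds_start[i], models$cds_end[i])
    if (utr_mode == "genomic") {
      up <- models$cds_start[i] - models$tx_start[i]
      down <- models$tx_end[i] - models$cds_end[i]
    } else {
      up <- exonic_overlap(i, models$tx_start[i], models$cds_start[i])
      down <- exonic_overlap(i, models$cds_end[i], models$tx_end[i])
    }
    if (models$strand[i] == "+") {
      utr5[i] <- up; utr3[i] <- down
    } else {
      utr5[i] <- down; utr3[i] <- up
    }
  }
  data.frame(gene_id = models$gene_id,
             genomic_len = as.numeric(genomic_len),
             cds_len = cds_len,
             utr5_len = utr5,
             utr3_len = utr3,
             exon_total_len = exon_total,
             intron_total_len = as.numeric(genomic_len) - exon_total,
             n_exon = n_exon,
             n_intron = n_exon - 1L,
             stringsAsFactors = FALSE)
}

#' The eight structure metric column names, in report order
#' @return Character vector of metric names.
#' @export
structure_metric_names <- function() {
  c("genomic_len", "cds_len", "utr5_len", "utr3_len",
    "exon_total_len", "intron_total_len", "n_exon", "n_intron")
}
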