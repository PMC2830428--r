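# TSS evidence -> per-gene promoter count and promoter class.

#' Read TSS evidence from a BED6 file
#'
#' Each line must be a 1-bp interval (a single transcription start base):
#' chrom, start, end, name (gene id), score (clone/tag support), strand.
#' Lines starting with `#` (and UCSC `track`/`browser` lines) are skipped.
#'
#' @param path Path to a BED6 file, or a character vector of BED lines.
#' @return A data.frame with columns `chrom`, `pos` (0-based start),
#'   `strand`, `gene_id`, `support`.
#' @examples
#' tss <- read_tss_bed(c("chr1\t99\t100\tG1\t5\t+",
#'                       "chr1\t700\t701\tG1\t2\t+"))
#' promoter_profile(tss)
#' @export
read_tss_bed <- function(path) {
  lines <- .read_input_lines(path)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stop("no TSS records found in input")
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    bad <- idx[which(nf < 6L)[1L]]
    stop("malformed BED6 line ", bad, ": fewer than 6 tab-separated fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  name <- vapply(fields, `[[`, "", 4L)
  score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  strand <- vapply(fields, `[[`, "", 6L)
  if (anyNA(start) || anyNA(end)) {
    bad <- idx[which(is.na(start) | is.na(end))[1L]]
    stop("malformed BED6 line ", bad, ": non-numeric coordinate")
  }
  if (any(end - start != 1L)) {
    bad <- idx[which(end - start != 1L)[1L]]
    stop("BED6 line ", bad, ": interval width must be 1 (a single TSS base)")
  }
  if (any(start < 0L)) {
    bad <- idx[which(start < 0L)[1L]]
    stop("BED6 line ", bad, ": negative coordinate")
  }
  if (!all(strand %in% c("+", "-"))) {
    bad <- idx[which(!strand %in% c("+", "-"))[1L]]
    stop("BED6 line ", bad, ": strand must be '+' or '-'")
  }
  if (any(!nzchar(name))) {
    bad <- idx[which(!nzchar(name))[1L]]
    stop("BED6 line ", bad, ": empty gene id in name field")
  }
  score[is.na(score)] <- 1
  data.frame(chrom = chrom, pos = start, strand = strand, gene_id = name,
             support = score, stringsAsFactors = FALSE)
}

#' Cluster TSS positions by a maximum gap
#'
#' Groups genomic positions into promoter clusters.  In `"linkage"` mode
#' (the default) two adjacent sorted positions fall in the same cluster iff
#' their distance is at most `gap` (single-linkage chaining: a run of
#' 500-bp steps stays one cluster).  In `"window"` mode a new cluster opens
#' whenever a position lies more than `gap` downstream of the current
#' cluster's first position.
#'
#' @param positions Integer vector of TSS coordinates (any order).
#' @param gap Maximum joining distance in bases (default 500).
#' @param mode `"linkage"` (default) or `"window"`.
#' @return A list of increasing integer vectors, one per cluster, in
#'   ascending genomic order.
#' @examples
#' cluster_tss(c(100, 600, 1101))   # 600-100 = 500 joins, 1101-600 splits
#' @export
cluster_tss <- function(positions, gap = 500L, mode = c("linkage", "window")) {
  mode <- match.arg(mode)
  if (length(positions) == 0L) {
    stop("cannot cluster an empty set of TSS positions")
  }
  if (!is.numeric(gap) || length(gap) != 1L || gap <= 0) {
    stop("'gap' must be a single positive number")
  }
  p <- sort(as.numeric(positions))
  if (mode == "linkage") {
    new_cluster <- c(TRUE, diff(p) > gap)
  } else {
    new_cluster <- logical(length(p))
    anchor <- -Inf
    for (i in seq_along(p)) {
      if (p[i] - anchor > gap) {
        new_cluster[i] <- TRUE
        anchor <- p[i]
      }
    }
  }
  unname(split(p, cumsum(new_cluster)))
}

#' Promoter-count class of a gene
#'
#' Bins a promoter count into the four-way classification used throughout
#' the package: `SP` (single promoter), `AP2` (two), `AP3_4` (three or
#' four), `AP5plus` (five or more).
#'
#' @param n_promoters Vector of positive integer promoter counts.
#' @return A factor with levels `SP`, `AP2`, `AP3_4`, `AP5plus`.
#' @export
assign_class <- function(n_promoters) {
  if (length(n_promoters) == 0L) return(factor(character(), levels = promoter_classes()))
  if (anyNA(n_promoters) || any(n_promoters < 1)) {
    stop("promoter counts must be >= 1")
  }
  cls <- ifelse(n_promoters >= 5, "AP5plus",
         ifelse(n_promoters >= 3, "AP3_4",
         ifelse(n_promoters == 2, "AP2", "SP")))
  factor(cls, levels = promoter_classes())
}

#' The four promoter class labels, in ladder order
#' @return `c("SP", "AP2", "AP3_4", "AP5plus")`
#' @export
promoter_classes <- function() c("SP", "AP2", "AP3_4", "AP5plus")

#' Per-gene promoter profile from TSS records
#'
#' Clusters each gene's TSS positions (per strand and chromosome) and
#' reports the number of promoters and the promoter class.  Duplicate
#' positions within a group are collapsed before clustering (clone
#' redundancy does not change architecture).  A gene with TSS evidence on
#' both strands or on two chromosomes triggers a warning; its groups are
#' clustered separately and the cluster counts summed.
#'
#' @param tss A data.frame as returned by [read_tss_bed()].
#' @inheritParams cluster_tss
#' @return A data.frame with columns `gene_id`, `n_promoters`,
#'   `promoter_class`, ordered by `gene_id`; independent of input row order.
#' @export
promoter_profile <- function(tss, gap = 500L, mode = c("linkage", "window")) {
  mode <- match.arg(mode)
  if (!is.data.frame(tss) || nrow(tss) == 0L) {
    stop("'tss' must be a non-empty data.frame of TSS records")
  }
  need <- c("chrom", "pos", "strand", "gene_id")
  if (!all(need %in% names(tss))) {
    stop("'tss' must have columns ", paste(need, collapse = ", "))
  }
  grp <- interaction(tss$gene_id, tss$chrom, tss$strand, drop = TRUE)
  n_groups_per_gene <- tapply(as.character(grp), tss$gene_id,
                              function(g) length(unique(g)))
  multi <- names(n_groups_per_gene)[n_groups_per_gene > 1L]
  if (length(multi) > 0L) {
    warning("gene(s) with TSS evidence on multiple strands/chromosomes, ",
            "cluster counts summed per gene: ",
            paste(sort(multi), collapse = ", "))
  }
  counts_by_group <- tapply(tss$pos, grp, function(p) {
    length(cluster_tss(unique(p), gap = gap, mode = mode))
  })
  gene_of_group <- tapply(tss$gene_id, grp, `[[`, 1L)
  n_prom <- tapply(as.vector(counts_by_group), as.vector(gene_of_group), sum)
  out <- data.frame(gene_id = names(n_prom),
                    n_promoters = as.integer(n_prom),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out$promoter_class <- assign_class(out$n_promoters)
  out
}

# Accept either a file path or a character vector of raw lines.
.read_input_lines <- function(path) {
  if (length(path) == 1L && !grepl("[\t\n]", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE), use.names = FALSE)
  }
}
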