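# Seeded synthetic cohort generator with planted promoter-class effects.
#
# Emulates the five input kinds the pipeline consumes (TSS BED6, tri-state
# DE matrix, BED12 gene models, gene lists, interaction edge list) with
# class-dependent effects so every stage is testable without external data.

#' Synthetic cohort configuration
#'
#' Defaults plant the class-dependent effects of the reference human
#' cohort: class sizes (7291, 3772, 2941, 1176) for SP / AP2 / AP3_4 /
#' AP5plus; DER class medians (0.50, 0.52, 0.54, 0.56); cancer-driver
#' fractions (2.9, 4.3, 6.2, 9.7)%; disease fractions (16.4, 19.9, 21.7,
#' 26.6)%; duplicate fractions (67, 74, 78, 85)%; network degree means
#' rising from 6.5 (SP) to 10.5 (AP5plus), intermediates interpolated;
#' and total-intron length medians (14370, 25162, 43650, 87204) bases.
#' 476 expression datasets with per-cell measurement probability 0.6.
#'
#' @param seed Master seed (integer; per-component substreams are derived
#'   from it, so adding a component never perturbs the others).
#' @param class_sizes Four positive integers (SP, AP2, AP3_4, AP5plus).
#' @param n_datasets Number of expression datasets.
#' @param der_medians Four target DER medians in (0, 1).
#' @param der_concentration Beta concentration (alpha + beta) of the
#'   per-gene DE-rate law; larger is tighter around the class median.
#' @param disease_fracs,driver_fracs,duplicate_fracs Four per-class
#'   membership probabilities each.
#' @param degree_means Four per-class mean degrees.
#' @param degree_dispersion Negative-binomial dispersion (var = mu +
#'   dispersion * mu^2).
#' @param intron_medians Four per-class target total-intron medians
#'   (bases); the derived `length_scale_factors` are their ratios to the
#'   SP median.
#' @param measured_prob Probability a gene is measured in a dataset.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 17L,
                             class_sizes = c(7291L, 3772L, 2941L, 1176L),
                             n_datasets = 476L,
                             der_medians = c(0.50, 0.52, 0.54, 0.56),
                             der_concentration = 20,
                             disease_fracs = c(0.164, 0.199, 0.217, 0.266),
                             driver_fracs = c(0.029, 0.043, 0.062, 0.097),
                             duplicate_fracs = c(0.67, 0.74, 0.78, 0.85),
                             degree_means = c(6.5, 8.0, 9.0, 10.5),
                             degree_dispersion = 1.0,
                             intron_medians = c(14370, 25162, 43650, 87204),
                             measured_prob = 0.6) {
  stopifnot(length(class_sizes) == 4L, all(class_sizes >= 1L),
            length(der_medians) == 4L, all(der_medians > 0 & der_medians < 1),
            der_concentration > 0,
            length(disease_fracs) == 4L, length(driver_fracs) == 4L,
            length(duplicate_fracs) == 4L,
            all(c(disease_fracs, driver_fracs, duplicate_fracs) >= 0),
            all(c(disease_fracs, driver_fracs, duplicate_fracs) <= 1),
            length(degree_means) == 4L, all(degree_means > 0),
            degree_dispersion > 0,
            length(intron_medians) == 4L, all(intron_medians > 0),
            measured_prob > 0, measured_prob <= 1,
            n_datasets >= 1L)
  structure(list(
    seed = as.integer(seed),
    class_sizes = as.integer(class_sizes),
    n_datasets = as.integer(n_datasets),
    der_medians = der_medians,
    der_concentration = der_concentration,
    disease_fracs = disease_fracs,
    driver_fracs = driver_fracs,
    duplicate_fracs = duplicate_fracs,
    degree_means = degree_means,
    degree_dispersion = degree_dispersion,
    intron_medians = intron_medians,
    length_scale_factors = intron_medians / intron_medians[1L],
    measured_prob = measured_prob), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic_config: ", sum(x$class_sizes), " genes (",
      paste(x$class_sizes, collapse = "/"), " per class), ",
      x$n_datasets, " datasets, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Beta shape parameters with a given median and concentration
#'
#' Finds `alpha` (by root-finding on the Beta quantile function) such
#' that `qbeta(0.5, alpha, concentration - alpha)` equals the target
#' median, with `alpha + beta = concentration` fixed.
#'
#' @param median Target median in (0, 1).
#' @param concentration Total `alpha + beta` (> 0).
#' @return Named numeric vector `c(alpha =, beta =)`.
#' @export
beta_shapes_for_median <- function(median, concentration) {
  stopifnot(median > 0, median < 1, concentration > 0)
  # qbeta warns at the extreme-shape bracket endpoints; the root is interior
  f <- function(a) suppressWarnings(stats::qbeta(0.5, a, concentration - a)) - median
  eps <- concentration * 1e-9
  a <- stats::uniroot(f, c(eps, concentration - eps), tol = 1e-12)$root
  c(alpha = a, beta = concentration - a)
}

# Substream seeds: fixed labeled offsets from the master seed so that the
# random stream of one output file never depends on the others.
.substream <- function(config, label) {
  offsets <- c(genes = 1L, tss = 2L, der = 3L, flags = 4L,
               models = 5L, network = 6L)
  set.seed((config$seed + offsets[[label]]) %% .Machine$integer.max)
}

#' Gene table of a synthetic cohort
#'
#' Assigns gene ids, promoter classes (in configured sizes) and intended
#' promoter counts (AP3_4 genes draw 3 or 4, AP5plus genes 5 to 10).
#'
#' @param config A [synthetic_config()].
#' @return A data.frame with `gene_id`, `class`, `n_promoters`.
#' @export
gen_gene_table <- function(config) {
  .substream(config, "genes")
  n <- sum(config$class_sizes)
  cls <- factor(rep(promoter_classes(), times = config$class_sizes),
                levels = promoter_classes())
  n_prom <- integer(n)
  n_prom[cls == "SP"] <- 1L
  n_prom[cls == "AP2"] <- 2L
  n_prom[cls == "AP3_4"] <- sample(3:4, sum(cls == "AP3_4"), replace = TRUE)
  n_prom[cls == "AP5plus"] <- sample(5:10, sum(cls == "AP5plus"), replace = TRUE)
  data.frame(gene_id = sprintf("G%05d", seq_len(n)), class = cls,
             n_promoters = n_prom, stringsAsFactors = FALSE)
}

#' TSS evidence realizing the intended promoter counts
#'
#' Emits 1 to 3 TSS bases per promoter cluster, with within-cluster
#' scatter at most 300 bases and cluster anchors 2000 bases apart, so
#' gap-500 clustering recovers the intended promoter count exactly.
#'
#' @param genes Output of [gen_gene_table()].
#' @param config A [synthetic_config()].
#' @return A data.frame of TSS records (see [read_tss_bed()]).
#' @export
gen_tss <- function(genes, config) {
  .substream(config, "tss")
  n <- nrow(genes)
  chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  base <- sample(10000:5000000, n, replace = TRUE)
  per_gene <- lapply(seq_len(n), function(i) {
    k <- genes$n_promoters[i]
    anchors <- base[i] + (seq_len(k) - 1L) * 2000L
    pos <- unlist(lapply(anchors, function(a) {
      m <- sample(1:3, 1L)
      a + sort(sample(0:300, m))
    }), use.names = FALSE)
    data.frame(chrom = chrom[i], pos = pos, strand = strand[i],
               gene_id = genes$gene_id[i],
               support = sample(1:20, length(pos), replace = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_gene)
  rownames(out) <- NULL
  out
}

#' Per-gene differential-expression rates with planted class medians
#'
#' Draws each gene's latent DE rate from a Beta law whose median is the
#' gene's class target (see [beta_shapes_for_median()]) and whose
#' concentration is shared.
#'
#' @inheritParams gen_tss
#' @return Numeric vector of rates aligned with `genes`.
#' @export
gen_der_rates <- function(genes, config) {
  .substream(config, "der")
  rates <- numeric(nrow(genes))
  for (k in seq_along(promoter_classes())) {
    idx <- genes$class == promoter_classes()[k]
    sh <- beta_shapes_for_median(config$der_medians[k], config$der_concentration)
    rates[idx] <- stats::rbeta(sum(idx), sh["alpha"], sh["beta"])
  }
  rates
}

#' Tri-state DE-call matrix from latent rates
#'
#' Each gene x dataset cell is measured with probability
#' `measured_prob`; a measured cell is a DE call (1) with the gene's
#' latent rate, else 0; unmeasured cells are NA.  Uses the same random
#' substream as [gen_der_rates()]; call that first.
#'
#' @param genes Output of [gen_gene_table()].
#' @param rates Output of [gen_der_rates()].
#' @param config A [synthetic_config()].
#' @return Integer matrix, genes x datasets.
#' @export
gen_de_matrix <- function(genes, rates, config) {
  n <- nrow(genes); d <- config$n_datasets
  measured <- matrix(stats::runif(n * d) < config$measured_prob, n, d)
  calls <- matrix(stats::rbinom(n * d, 1L, rep(rates, times = d)), n, d)
  calls[!measured] <- NA_integer_
  dimnames(calls) <- list(genes$gene_id, sprintf("D%03d", seq_len(d)))
  calls
}

#' Planted annotation memberships
#'
#' Disease and cancer-driver membership are independent Bernoulli draws
#' with class-specific probabilities; duplicability is duplicate-vs-
#' singleton with the class-specific duplicate probability (every
#' synthetic gene has known duplicability).
#'
#' @inheritParams gen_tss
#' @return A list of character vectors `disease`, `driver`, `duplicate`,
#'   `singleton`.
#' @export
gen_flags <- function(genes, config) {
  .substream(config, "flags")
  k <- as.integer(genes$class)
  n <- nrow(genes)
  is_disease <- stats::runif(n) < config$disease_fracs[k]
  is_driver <- stats::runif(n) < config$driver_fracs[k]
  is_dup <- stats::runif(n) < config$duplicate_fracs[k]
  list(disease = genes$gene_id[is_disease],
       driver = genes$gene_id[is_driver],
       duplicate = genes$gene_id[is_dup],
       singleton = genes$gene_id[!is_dup])
}

#' Synthetic BED12 gene models with class-scaled lengths
#'
#' One transcript per gene.  Exon count is 1 + Poisson with class means
#' (5, 8, 11, 16); total intron length is lognormal with the class target
#' median; exon lengths are lognormal around 250 bases; the CDS covers
#' the spliced interior leaving lognormal 5'/3' UTR allocations.
#'
#' @inheritParams gen_tss
#' @return A transcript data.frame in the shape of [read_bed12()].
#' @export
gen_gene_models <- function(genes, config) {
  .substream(config, "models")
  n <- nrow(genes)
  k <- as.integer(genes$class)
  exon_lambda <- c(5, 8, 11, 16)
  n_exon <- 1L + stats::rpois(n, exon_lambda[k])
  intron_total <- round(stats::rlnorm(n, log(config$intron_medians[k]), 1.0))
  chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tx_start <- sample(10000:5000000, n, replace = TRUE)
  utr5_target <- round(stats::rlnorm(n, log(c(139, 172, 188, 207)[k]), 0.8))
  utr3_target <- round(stats::rlnorm(n, log(c(599, 881, 1178, 1325)[k]), 0.8))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ne <- n_exon[i]
    exon_sizes <- pmax(30L, round(stats::rlnorm(ne, log(250), 0.6)))
    if (ne > 1L) {
      w <- stats::runif(ne - 1L)
      intron_sizes <- pmax(60L, round(intron_total[i] * w / sum(w)))
    } else {
      intron_sizes <- integer(0)
    }
    es <- tx_start[i] + cumsum(c(0L, utils::head(exon_sizes, -1L) + intron_sizes))
    ee <- es + exon_sizes
    spliced <- sum(exon_sizes)
    u5 <- min(utr5_target[i], max(0L, (spliced - 3L) %/% 3L))
    u3 <- min(utr3_target[i], max(0L, spliced - u5 - 3L))
    # spliced CDS interval [u_left, spliced - u_right) in 5'->3' order;
    # on the minus strand the 5' UTR sits at the genomic right end
    if (strand[i] == "+") { left <- u5; right <- u3 } else { left <- u3; right <- u5 }
    cds_start <- .spliced_to_genomic(es, ee, left)
    cds_end <- .spliced_to_genomic(es, ee, spliced - right)
    rows[[i]] <- list(tx_id = paste0(genes$gene_id[i], "|", genes$gene_id[i], ".t1"),
                      gene_id = genes$gene_id[i], chrom = chrom[i],
                      strand = strand[i], tx_start = es[1L], tx_end = ee[ne],
                      cds_start = cds_start, cds_end = cds_end,
                      exon_starts = es, exon_ends = ee)
  }
  out <- data.frame(
    tx_id = vapply(rows, `[[`, "", "tx_id"),
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    tx_start = vapply(rows, function(r) as.integer(r$tx_start), integer(1)),
    tx_end = vapply(rows, function(r) as.integer(r$tx_end), integer(1)),
    cds_start = vapply(rows, function(r) as.integer(r$cds_start), integer(1)),
    cds_end = vapply(rows, function(r) as.integer(r$cds_end), integer(1)),
    stringsAsFactors = FALSE)
  out$exon_starts <- lapply(rows, function(r) as.integer(r$exon_starts))
  out$exon_ends <- lapply(rows, function(r) as.integer(r$exon_ends))
  out
}

# Genomic coordinate of a spliced offset (0-based; offset may equal the
# spliced length, mapping to the last exon end).
.spliced_to_genomic <- function(es, ee, offset) {
  sizes <- ee - es
  cum <- cumsum(sizes)
  i <- which(offset <= cum)[1L]
  prev <- if (i == 1L) 0L else cum[i - 1L]
  es[i] + (offset - prev)
}

#' Interaction edge list realizing class-dependent degrees
#'
#' Draws a negative-binomial degree per gene (class-specific means) and
#' realizes it by configuration-model stub matching.  An odd stub total
#' is repaired by one extra stub (reported via a message).  The raw edge
#' list may contain self-pairs and multi-edges; cleaning is the
#' pipeline's job.
#'
#' @inheritParams gen_tss
#' @return A data.frame with `from`, `to`.
#' @export
gen_edges <- function(genes, config) {
  .substream(config, "network")
  k <- as.integer(genes$class)
  size <- 1 / config$degree_dispersion
  deg <- stats::rnbinom(nrow(genes), mu = config$degree_means[k], size = size)
  if (sum(deg) %% 2L == 1L) {
    message("odd degree total repaired by one extra stub")
    deg[which.max(deg)] <- deg[which.max(deg)] + 1L
  }
  stubs <- rep(genes$gene_id, times = deg)
  stubs <- sample(stubs)
  half <- length(stubs) %/% 2L
  data.frame(from = stubs[seq_len(half)],
             to = stubs[half + seq_len(half)],
             stringsAsFactors = FALSE)
}

#' Generate and write a complete synthetic cohort
#'
#' Writes the five pipeline inputs plus a manifest of the true planted
#' parameters into `dir`: `tss.bed` (BED6), `de_matrix.tsv`,
#' `gene_models.bed` (BED12), `disease_genes.txt`, `driver_genes.txt`,
#' `duplicate_genes.txt`, `singleton_genes.txt`, `edges.tsv` and
#' `manifest.json`.  The same config and seed yield byte-identical files.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if missing).
#' @return Named list of file paths, with the true gene table attached as
#'   attribute `truth`.
#' @export
generate_cohort <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- gen_gene_table(config)
  tss <- gen_tss(genes, config)
  rates <- gen_der_rates(genes, config)
  de <- gen_de_matrix(genes, rates, config)
  flags <- gen_flags(genes, config)
  models <- gen_gene_models(genes, config)
  edges <- gen_edges(genes, config)

  paths <- list(tss = file.path(dir, "tss.bed"),
                de_matrix = file.path(dir, "de_matrix.tsv"),
                gene_models = file.path(dir, "gene_models.bed"),
                disease = file.path(dir, "disease_genes.txt"),
                driver = file.path(dir, "driver_genes.txt"),
                duplicate = file.path(dir, "duplicate_genes.txt"),
                singleton = file.path(dir, "singleton_genes.txt"),
                edges = file.path(dir, "edges.tsv"),
                manifest = file.path(dir, "manifest.json"))

  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", tss$chrom, tss$pos,
                     tss$pos + 1L, tss$gene_id, tss$support, tss$strand),
             paths$tss)
  .write_de_matrix(de, paths$de_matrix)
  writeLines(.bed12_lines(models), paths$gene_models)
  writeLines(flags$disease, paths$disease)
  writeLines(flags$driver, paths$driver)
  writeLines(flags$duplicate, paths$duplicate)
  writeLines(flags$singleton, paths$singleton)
  writeLines(sprintf("%s\t%s", edges$from, edges$to), paths$edges)
  manifest <- list(config = unclass(config),
                   files = lapply(paths[names(paths) != "manifest"], basename),
                   n_genes = nrow(genes),
                   class_counts = as.list(table(genes$class)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  attr(paths, "truth") <- genes
  paths
}

.write_de_matrix <- function(de, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(de)), collapse = "\t"), con)
  body <- apply(de, 1L, function(r) paste(ifelse(is.na(r), "NA", r), collapse = "\t"))
  writeLines(paste(rownames(de), body, sep = "\t"), con)
}

.bed12_lines <- function(models) {
  vapply(seq_len(nrow(models)), function(i) {
    es <- models$exon_starts[[i]]; ee <- models$exon_ends[[i]]
    sizes <- ee - es
    starts <- es - models$tx_start[i]
    paste(models$chrom[i], models$tx_start[i], models$tx_end[i],
          models$tx_id[i], 0L, models$strand[i],
          models$cds_start[i], models$cds_end[i], "0,0,0", length(es),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(starts, collapse = ","), ","),
          sep = "\t")
  }, character(1))
}
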