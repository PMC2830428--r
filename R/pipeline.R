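# Orchestration: run every analysis stage over the input files and
# collect a report object in the shape of the reference study's results
# (class sizes, DER ladder, disease/driver/duplicate ladders, structure
# median matrix, degree ladder).

#' Run the full alternative-promoter association analysis
#'
#' Profiles promoters from TSS evidence, then — for whichever optional
#' inputs are supplied — computes the DER ladder, the disease /
#' cancer-driver / duplicability enrichment ladders, the 8-metric
#' gene-structure median matrix with per-metric ladders, and the
#' interaction-degree ladder.  Stages whose input is missing are skipped
#' and recorded in the report.
#'
#' @param tss Path to (or lines of) a BED6 TSS evidence file (required).
#' @param de_matrix Optional tri-state DE-call matrix TSV.
#' @param gene_models Optional BED12 gene-model file.
#' @param disease,driver,duplicate,singleton Optional plain gene lists.
#' @param edges Optional interaction edge list (TSV or SIF).
#' @param gap TSS clustering gap in bases (default 500).
#' @param cluster_mode `"linkage"` (default) or `"window"`; see
#'   [cluster_tss()].
#' @param measured_min_frac Minimum measured fraction for the DER filter
#'   (default 0.05).
#' @param measured_min_count Optional absolute override of the DER
#'   filter threshold.
#' @param alternative Test sidedness for all ladders (default
#'   `"two_sided"`).
#' @param utr_mode `"genomic"` (default) or `"spliced"`; see
#'   [structure_metrics()].
#' @param longest `"spliced"` (default) or `"span"`; see
#'   [select_representative()].
#' @param absent_degree `"missing"` (default: genes absent from the
#'   network are excluded from degree comparisons) or `"zero"`.
#' @param min_overlap Minimum fraction of profiled genes that each
#'   optional input must share with the profile universe (default 0.5);
#'   below it the run stops, advising an id-mapping problem.
#' @param tx2gene Optional transcript-to-gene mapping for the BED12
#'   input.
#' @return An object of class `ap_report`.
#' @examples
#' cfg <- synthetic_config(class_sizes = c(40, 30, 20, 10), n_datasets = 30)
#' paths <- generate_cohort(cfg, tempfile("cohort"))
#' rep <- ap_analyze(tss = paths$tss, de_matrix = paths$de_matrix)
#' rep$class_sizes
#' @export
ap_analyze <- function(tss, de_matrix = NULL, gene_models = NULL,
                       disease = NULL, driver = NULL,
                       duplicate = NULL, singleton = NULL, edges = NULL,
                       gap = 500L, cluster_mode = "linkage",
                       measured_min_frac = 0.05, measured_min_count = NULL,
                       alternative = "two_sided",
                       utr_mode = "genomic", longest = "spliced",
                       absent_degree = c("missing", "zero"),
                       min_overlap = 0.5, tx2gene = NULL) {
  absent_degree <- match.arg(absent_degree)
  skipped <- character()

  tss_records <- read_tss_bed(tss)
  profile <- promoter_profile(tss_records, gap = gap, mode = cluster_mode)
  universe <- profile$gene_id
  classes <- profile$promoter_class
  names(classes) <- universe
  class_sizes <- table(classes)
  message("profiled ", length(universe), " genes from ",
          nrow(tss_records), " TSS records")

  check_overlap <- function(ids, what) {
    ov <- mean(ids %in% universe)
    if (length(ids) > 0L && ov < min_overlap) {
      stop(what, ": only ", round(100 * ov, 1), "% of ids overlap the ",
           "profiled genes; check that all inputs share one gene-id namespace")
    }
  }

  report <- list(class_sizes = class_sizes,
                 n_genes = length(universe),
                 profile = profile,
                 options = list(gap = gap, cluster_mode = cluster_mode,
                                measured_min_frac = measured_min_frac,
                                alternative = alternative,
                                utr_mode = utr_mode, longest = longest,
                                absent_degree = absent_degree))

  # --- DER -----------------------------------------------------------
  if (!is.null(de_matrix)) {
    de <- read_de_matrix(de_matrix)
    check_overlap(rownames(de), "DE matrix")
    kept <- filter_measured(de, min_fraction = measured_min_frac,
                            min_count = measured_min_count)
    message("DER filter: ", nrow(de), " genes in matrix -> ", length(kept),
            " measured in enough datasets (rule: >= ",
            if (is.null(measured_min_count))
              ceiling(measured_min_frac * ncol(de)) else measured_min_count,
            " of ", ncol(de), " datasets)")
    der <- compute_der(de[kept, , drop = FALSE])
    der <- der[der$gene_id %in% universe, , drop = FALSE]
    message("DER comparisons use ", nrow(der), " of ", length(universe),
            " profiled genes")
    ladder <- class_ladder(der$der, classes[der$gene_id],
                           kind = "rank_sum", alternative = alternative)
    report$der <- list(table = der, ladder = ladder,
                       medians = attr(ladder, "class_summary"),
                       n_filtered = length(kept), n_matrix = nrow(de))
  } else skipped <- c(skipped, "der")

  # --- annotation flags ---------------------------------------------
  lists <- list(disease = disease, driver = driver,
                duplicate = duplicate, singleton = singleton)
  got <- !vapply(lists, is.null, logical(1))
  if (any(got)) {
    sets <- lapply(lists, function(p) if (is.null(p)) character() else read_gene_list(p))
    for (nm in names(sets)[got]) check_overlap(sets[[nm]], paste(nm, "list"))
    flags <- build_flags(universe, disease = sets$disease,
                         driver = sets$driver, duplicate = sets$duplicate,
                         singleton = sets$singleton)
    report$flags <- flags
    if (got[["driver"]]) {
      v <- flags$is_cancer_driver
      ladder <- class_ladder(v, classes[flags$gene_id], kind = "fisher",
                             alternative = alternative)
      report$driver <- list(ladder = ladder,
                            fractions = attr(ladder, "class_summary"))
    } else skipped <- c(skipped, "driver")
    if (got[["disease"]]) {
      v <- flags$is_disease
      ladder <- class_ladder(v, classes[flags$gene_id], kind = "fisher",
                             alternative = alternative)
      report$disease <- list(ladder = ladder,
                             fractions = attr(ladder, "class_summary"))
    } else skipped <- c(skipped, "disease")
    if (got[["duplicate"]] && got[["singleton"]]) {
      known <- flags$is_duplicate | flags$is_singleton
      message("duplicability comparisons use ", sum(known), " of ",
              length(universe), " genes with known duplicability")
      v <- ifelse(known, flags$is_duplicate, NA)
      ladder <- class_ladder(v, classes[flags$gene_id], kind = "fisher",
                             alternative = alternative)
      report$duplicate <- list(ladder = ladder,
                               fractions = attr(ladder, "class_summary"),
                               n_known = sum(known))
    } else skipped <- c(skipped, "duplicate")
  } else skipped <- c(skipped, "driver", "disease", "duplicate")

  # --- gene structure ------------------------------------------------
  if (!is.null(gene_models)) {
    models <- read_bed12(gene_models, tx2gene = tx2gene)
    check_overlap(unique(models$gene_id), "gene models")
    rep_tx <- select_representative(models, longest = longest)
    metrics <- structure_metrics(rep_tx, utr_mode = utr_mode)
    metrics <- metrics[metrics$gene_id %in% universe, , drop = FALSE]
    message("structure metrics for ", nrow(metrics), " profiled genes (",
            nrow(models), " transcripts read)")
    mcls <- classes[metrics$gene_id]
    ladders <- lapply(structure_metric_names(), function(mn) {
      class_ladder(metrics[[mn]], mcls, kind = "rank_sum",
                   alternative = alternative)
    })
    names(ladders) <- structure_metric_names()
    medians <- vapply(ladders, function(l) attr(l, "class_summary")$summary,
                      numeric(4))
    medians <- t(medians)                    # 8 metrics x 4 classes
    colnames(medians) <- promoter_classes()
    report$structure <- list(metrics = metrics, ladders = ladders,
                             medians = medians)
  } else skipped <- c(skipped, "structure")

  # --- network degree ------------------------------------------------
  if (!is.null(edges)) {
    raw <- read_edge_list(edges)
    g <- clean_network(raw)
    message("network cleaned: ", nrow(raw), " raw pairs -> ",
            nrow(g$edges), " edges over ", length(g$nodes), " nodes")
    check_overlap(g$nodes, "interaction network")
    deg <- degree_table(g)
    degv <- deg$degree[match(universe, deg$id)]
    if (absent_degree == "zero") degv[is.na(degv)] <- 0L
    message("degree comparisons use ", sum(!is.na(degv)), " of ",
            length(universe), " profiled genes")
    ladder <- class_ladder(degv, classes, kind = "rank_sum",
                           alternative = alternative)
    mean_by_class <- tapply(degv, classes, mean, na.rm = TRUE)
    report$degree <- list(table = deg, ladder = ladder,
                          medians = attr(ladder, "class_summary"),
                          means = mean_by_class)
  } else skipped <- c(skipped, "degree")

  report$skipped <- skipped
  report$provenance <- list(
    version = as.character(utils::packageVersion("promdiver")),
    inputs = .input_hashes(list(tss = tss, de_matrix = de_matrix,
                                gene_models = gene_models, disease = disease,
                                driver = driver, duplicate = duplicate,
                                singleton = singleton, edges = edges)))
  class(report) <- "ap_report"
  report
}

.input_hashes <- function(inputs) {
  lapply(inputs, function(p) {
    if (is.null(p)) return(NULL)
    if (length(p) == 1L && !grepl("[\t\n]", p) && file.exists(p)) {
      unname(tools::md5sum(p))
    } else "inline"
  })
}

#' @export
print.ap_report <- function(x, ...) {
  cat("Alternative-promoter association report\n")
  cat("  genes profiled:", x$n_genes, "\n")
  cat("  class sizes:   ",
      paste(sprintf("%s=%d", names(x$class_sizes), x$class_sizes),
            collapse = ", "), "\n")
  if (!is.null(x$der)) {
    med <- x$der$medians
    cat("  DER medians:   ",
        paste(sprintf("%s=%.2f", med$class, med$summary), collapse = ", "),
        "\n")
  }
  for (nm in c("driver", "disease", "duplicate")) {
    if (!is.null(x[[nm]])) {
      fr <- x[[nm]]$fractions
      cat(sprintf("  %-9s %%:    %s\n", nm,
                  paste(sprintf("%s=%.1f", fr$class, fr$summary),
                        collapse = ", ")))
    }
  }
  if (!is.null(x$degree)) {
    cat("  degree means:  ",
        paste(sprintf("%s=%.1f", names(x$degree$means), x$degree$means),
              collapse = ", "), "\n")
  }
  if (length(x$skipped) > 0L) {
    cat("  skipped stages:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.ap_report <- function(object, ...) {
  ladders <- .collect_ladders(object)
  cat("Ladder comparisons (", nrow(ladders), " tests, no multiplicity ",
      "correction applied):\n", sep = "")
  print(ladders, row.names = FALSE, digits = 4)
  if (!is.null(object$structure)) {
    cat("\nStructure medians (metric x class):\n")
    print(object$structure$medians)
  }
  invisible(ladders)
}

.collect_ladders <- function(report) {
  out <- list()
  add <- function(analysis, ladder) {
    if (is.null(ladder) || nrow(ladder) == 0L) return()
    ladder$analysis <- analysis
    out[[length(out) + 1L]] <<- ladder
  }
  if (!is.null(report$der)) add("der", report$der$ladder)
  for (nm in c("driver", "disease", "duplicate")) {
    if (!is.null(report[[nm]])) add(nm, report[[nm]]$ladder)
  }
  if (!is.null(report$structure)) {
    for (mn in names(report$structure$ladders)) {
      add(paste0("structure_", mn), report$structure$ladders[[mn]])
    }
  }
  if (!is.null(report$degree)) add("degree", report$degree$ladder)
  if (length(out) == 0L) return(data.frame())
  res <- do.call(rbind, out)
  res[, c("analysis", setdiff(names(res), "analysis"))]
}

#' Write an analysis report to disk
#'
#' Writes one TSV per analysis (class sizes, each ladder, the structure
#' median matrix) and, with `format = "json"`, a single JSON document of
#' the whole report.  Displayed p-values below 2.2e-16 are rendered as
#' `"<2.2e-16"`; stored values keep full precision.
#'
#' @param report An `ap_report` from [ap_analyze()].
#' @param dir Output directory (created if missing).
#' @param format `"tsv"`, `"json"`, or both.
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(report, dir, format = c("tsv", "json")) {
  if (!inherits(report, "ap_report")) stop("'report' must be an ap_report")
  bad <- setdiff(format, c("tsv", "json"))
  if (length(bad) > 0L) stop("unknown format: ", paste(bad, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  wtsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
  }
  if ("tsv" %in% format) {
    wtsv(data.frame(class = names(report$class_sizes),
                    n = as.integer(report$class_sizes)), "class_sizes.tsv")
    ladders <- .collect_ladders(report)
    if (nrow(ladders) > 0L) wtsv(ladders, "ladders.tsv")
    if (!is.null(report$structure)) {
      med <- data.frame(metric = rownames(report$structure$medians),
                        report$structure$medians, check.names = FALSE)
      wtsv(med, "table1_medians.tsv")
    }
    if (!is.null(report$der)) {
      p <- file.path(dir, "der.tsv")
      write_der_table(report$der$table, p)
      written <- c(written, p)
    }
  }
  if ("json" %in% format) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(as_report_list(report), p, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, p)
  }
  invisible(written)
}

#' Plain-list form of an `ap_report` (JSON-ready)
#'
#' @param report An `ap_report`.
#' @return A nested list of numbers, strings and data.frames.
#' @export
as_report_list <- function(report) {
  num_ladder <- function(l) {
    if (is.null(l)) return(NULL)
    attr(l, "class_summary") <- NULL
    l
  }
  out <- list(
    n_genes = report$n_genes,
    class_sizes = as.list(stats::setNames(as.integer(report$class_sizes),
                                          names(report$class_sizes))),
    options = report$options,
    skipped = report$skipped,
    provenance = report$provenance)
  if (!is.null(report$der)) {
    out$der <- list(medians = report$der$medians,
                    ladder = num_ladder(report$der$ladder),
                    n_filtered = report$der$n_filtered,
                    n_matrix = report$der$n_matrix)
  }
  for (nm in c("driver", "disease", "duplicate")) {
    if (!is.null(report[[nm]])) {
      out[[nm]] <- list(fractions = report[[nm]]$fractions,
                        ladder = num_ladder(report[[nm]]$ladder))
    }
  }
  if (!is.null(report$structure)) {
    out$structure <- list(
      medians = as.data.frame(report$structure$medians),
      ladders = lapply(report$structure$ladders, num_ladder))
  }
  if (!is.null(report$degree)) {
    out$degree <- list(medians = report$degree$medians,
                       means = as.list(report$degree$means),
                       ladder = num_ladder(report$degree$ladder))
  }
  out
}
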