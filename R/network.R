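# Protein-interaction edge list -> cleaned undirected graph and degrees.

#' Read a raw interaction edge list
#'
#' Accepts a two-column tab-separated edge list, or SIF (three or more
#' whitespace-separated columns, where the middle interaction-type column
#' is ignored and all columns past the second SIF column are extra
#' targets).  No cleaning is applied: duplicates and self-pairs are kept
#' as read.
#'
#' @param path Path to the file, or a character vector of lines.
#' @return A data.frame with character columns `from`, `to`.
#' @export
read_edge_list <- function(path) {
  lines <- .read_input_lines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop("edge list line ", idx[which(nf < 2L)[1L]], ": fewer than 2 columns")
  }
  from <- character(0); to <- character(0)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) == 2L) {              # plain 2-column TSV
      from <- c(from, f[1L]); to <- c(to, f[2L])
    } else {                            # SIF: source, type, target(s)
      from <- c(from, rep(f[1L], length(f) - 2L))
      to <- c(to, f[-(1:2)])
    }
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

#' Clean a raw edge list into a simple undirected graph
#'
#' Drops self-interactions, unifies (A,B) with (B,A) and collapses
#' duplicate edges.  Cleaning is idempotent.
#'
#' @param raw A data.frame with columns `from`, `to` (see
#'   [read_edge_list()]), or an `interaction_graph`.
#' @return An object of class `interaction_graph`: a list with `nodes`
#'   (sorted character vector) and `edges` (two-column data.frame with
#'   `a < b` lexicographically).
#' @export
clean_network <- function(raw) {
  if (inherits(raw, "interaction_graph")) {
    raw <- data.frame(from = raw$edges$a, to = raw$edges$b,
                      stringsAsFactors = FALSE)
  }
  keep <- raw$from != raw$to
  a <- pmin(raw$from[keep], raw$to[keep])
  b <- pmax(raw$from[keep], raw$to[keep])
  dup <- duplicated(paste(a, b, sep = "\r"))
  edges <- data.frame(a = a[!dup], b = b[!dup], stringsAsFactors = FALSE)
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(edges$a, edges$b))), edges = edges),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("interaction_graph:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Per-node degree of a cleaned interaction graph
#'
#' Degree is the number of distinct interaction partners.  The degree sum
#' equals twice the edge count (handshake lemma).
#'
#' @param g An `interaction_graph` from [clean_network()].
#' @return A data.frame with columns `id`, `degree`, sorted by `id`.
#' @export
degree_table <- function(g) {
  if (!inherits(g, "interaction_graph")) stop("'g' must be an interaction_graph")
  if (length(g$nodes) == 0L) {
    return(data.frame(id = character(), degree = integer(),
                      stringsAsFactors = FALSE))
  }
  deg <- table(factor(c(g$edges$a, g$edges$b), levels = g$nodes))
  data.frame(id = g$nodes, degree = as.integer(deg),
             stringsAsFactors = FALSE)
}
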