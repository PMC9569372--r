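## Two-layer interactome: protein nodes carrying undirected PPI edges and
## RNA nodes reached by directed TF -> target regulatory edges.

#' Load a STRING-style PPI edge list
#'
#' Reads rows of (protein1, protein2, combined score) into a deduplicated,
#' undirected edge table.  Scores are rescaled to confidences in (0, 1]:
#' \code{score_scale = "thousand"} divides by 1000 (the STRING convention),
#' \code{"unit"} takes scores as-is.  Self-loops are dropped; symmetric or
#' repeated pairs are merged keeping the maximum confidence, so row order
#' never affects the result.
#'
#' @param table data.frame with columns \code{protein1}, \code{protein2},
#'   \code{combined_score} (or any three columns in that order), or a path
#'   to a tab-separated file (gzip transparent).
#' @param score_scale \code{"unit"} for scores already in (0,1],
#'   \code{"thousand"} for 0--1000 integer scores.
#' @return data.frame with columns \code{a}, \code{b} (normalized symbols,
#'   \code{a < b}), \code{confidence}.
#' @examples
#' load_ppi(data.frame(protein1 = c("A", "B"), protein2 = c("B", "A"),
#'                     combined_score = c(700, 900)), "thousand")
#' @export
load_ppi <- function(table, score_scale = c("thousand", "unit")) {
  score_scale <- match.arg(score_scale)
  if (is.character(table) && length(table) == 1L)
    table <- utils::read.delim(table, stringsAsFactors = FALSE)
  if (nrow(table) == 0L) {
    warning("empty PPI table: returning zero edges")
    return(data.frame(a = character(), b = character(),
                      confidence = numeric(), stringsAsFactors = FALSE))
  }
  p1 <- norm_gene(table[[1L]]); p2 <- norm_gene(table[[2L]])
  score <- as.numeric(table[[3L]])
  hi <- if (score_scale == "thousand") 1000 else 1
  bad <- which(!is.finite(score) | score < 0 | score > hi)
  if (length(bad))
    stop_malformed("PPI score out of declared %s scale at row %d (score=%s)",
                   score_scale, bad[1L], format(score[bad[1L]]))
  conf <- score / hi
  keep <- p1 != p2 & nzchar(p1) & nzchar(p2) & conf > 0
  p1 <- p1[keep]; p2 <- p2[keep]; conf <- conf[keep]
  a <- pmin(p1, p2); b <- pmax(p1, p2)
  key <- paste(a, b, sep = "\r")
  conf <- tapply(conf, key, max)
  parts <- strsplit(names(conf), "\r", fixed = TRUE)
  out <- data.frame(a = vapply(parts, `[`, "", 1L),
                    b = vapply(parts, `[`, "", 2L),
                    confidence = as.numeric(conf),
                    stringsAsFactors = FALSE)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load TF -> target regulon tables
#'
#' Rows of (tf, target, source) from one or more regulon databases are
#' collapsed to unique (tf, target) relations carrying the number of
#' distinct supporting sources.  TF self-regulation is retained: the TF's
#' protein node and its own RNA node are different nodes.
#'
#' @param tables data.frame with columns \code{tf}, \code{target},
#'   \code{source}, a path to a TSV file, or a list of either.
#' @return data.frame with columns \code{tf}, \code{target} (normalized
#'   symbols) and \code{n_sources}.
#' @export
load_regulons <- function(tables) {
  if (is.data.frame(tables) || (is.character(tables) && length(tables) == 1L))
    tables <- list(tables)
  tabs <- lapply(tables, function(t) {
    if (is.character(t)) t <- utils::read.delim(t, stringsAsFactors = FALSE)
    t
  })
  tab <- do.call(rbind, lapply(tabs, function(t)
    data.frame(tf = as.character(t[[1L]]), target = as.character(t[[2L]]),
               source = if (ncol(t) >= 3L) as.character(t[[3L]]) else "unspecified",
               stringsAsFactors = FALSE)))
  if (is.null(tab) || nrow(tab) == 0L) {
    warning("empty regulon table: returning zero relations")
    return(data.frame(tf = character(), target = character(),
                      n_sources = integer(), stringsAsFactors = FALSE))
  }
  tf <- norm_gene(tab$tf); tg <- norm_gene(tab$target)
  keep <- nzchar(tf) & nzchar(tg)
  key <- paste(tf[keep], tg[keep], sep = "\r")
  ns <- tapply(tab$source[keep], key, function(s) length(unique(s)))
  parts <- strsplit(names(ns), "\r", fixed = TRUE)
  out <- data.frame(tf = vapply(parts, `[`, "", 1L),
                    target = vapply(parts, `[`, "", 2L),
                    n_sources = as.integer(ns), stringsAsFactors = FALSE)
  out <- out[order(out$tf, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the two-layer interactome
#'
#' Protein nodes are the union of PPI endpoints and regulon TFs; RNA nodes
#' are the regulon targets.  PPI edge costs come from the cost rule
#' (default \code{1 - confidence}, clamped below at \code{cost_floor} so
#' reliable edges stay cheap but strictly positive); every regulatory edge
#' carries the constant \code{reg_edge_cost} because regulon evidence is
#' binary across source databases.
#'
#' @param ppi_edges output of [load_ppi()].
#' @param reg_relations output of [load_regulons()].
#' @param ppi_cost_rule function(confidence) -> cost; default
#'   \code{1 - confidence} with floor.
#' @param reg_edge_cost positive cost for every TF->RNA edge.
#' @param cost_floor lower clamp applied to PPI costs.
#' @return an object of class \code{interactome}: list with \code{nodes}
#'   (gene, layer) and \code{edges}
#'   (u, u_layer, v, v_layer, kind, confidence, cost, n_sources).
#' @export
assemble_interactome <- function(ppi_edges, reg_relations,
                                 ppi_cost_rule = NULL,
                                 reg_edge_cost = 0.5,
                                 cost_floor = 0.01) {
  if (!is.numeric(reg_edge_cost) || reg_edge_cost <= 0)
    stop_malformed("reg_edge_cost must be a positive number")
  if (is.null(ppi_cost_rule))
    ppi_cost_rule <- function(conf) pmax(1 - conf, cost_floor)

  prot <- sort(unique(c(ppi_edges$a, ppi_edges$b, reg_relations$tf)))
  rna <- sort(unique(reg_relations$target))
  nodes <- rbind(
    data.frame(gene = prot, layer = rep("protein", length(prot)),
               stringsAsFactors = FALSE),
    data.frame(gene = rna, layer = rep("rna", length(rna)),
               stringsAsFactors = FALSE))
  rownames(nodes) <- NULL

  pe <- if (nrow(ppi_edges)) data.frame(
    u = ppi_edges$a, u_layer = "protein",
    v = ppi_edges$b, v_layer = "protein",
    kind = "ppi", confidence = ppi_edges$confidence,
    cost = ppi_cost_rule(ppi_edges$confidence),
    n_sources = NA_integer_, stringsAsFactors = FALSE) else NULL
  re <- if (nrow(reg_relations)) data.frame(
    u = reg_relations$tf, u_layer = "protein",
    v = reg_relations$target, v_layer = "rna",
    kind = "regulatory", confidence = NA_real_,
    cost = reg_edge_cost, n_sources = reg_relations$n_sources,
    stringsAsFactors = FALSE) else NULL
  edges <- rbind(pe, re)
  if (is.null(edges))
    edges <- data.frame(u = character(), u_layer = character(),
                        v = character(), v_layer = character(),
                        kind = character(), confidence = numeric(),
                        cost = numeric(), n_sources = integer(),
                        stringsAsFactors = FALSE)
  if (any(edges$cost <= 0)) stop_malformed("non-positive edge cost produced")
  rownames(edges) <- NULL
  obj <- structure(list(nodes = nodes, edges = edges), class = "interactome")
  message(sprintf("interactome: %d protein nodes, %d rna nodes, %d ppi edges, %d regulatory edges",
                  length(prot), length(rna),
                  sum(edges$kind == "ppi"), sum(edges$kind == "regulatory")))
  obj
}

#' @export
print.interactome <- function(x, ...) {
  cat("Two-layer interactome\n")
  cat(sprintf("  nodes: %d protein, %d rna\n",
              sum(x$nodes$layer == "protein"), sum(x$nodes$layer == "rna")))
  cat(sprintf("  edges: %d ppi, %d regulatory\n",
              sum(x$edges$kind == "ppi"), sum(x$edges$kind == "regulatory")))
  invisible(x)
}

#' Convert an interactome to an igraph graph
#'
#' Regulatory edges keep their direction only when \code{directed = TRUE};
#' the undirected view is what the Steiner solver optimizes over.
#'
#' @param x interactome.
#' @param directed logical.
#' @return igraph graph with vertex attributes \code{gene}, \code{layer}
#'   and edge attributes \code{kind}, \code{confidence}, \code{cost}.
#' @export
interactome_graph <- function(x, directed = FALSE) {
  vk <- node_key(x$nodes$gene, x$nodes$layer)
  el <- cbind(node_key(x$edges$u, x$edges$u_layer),
              node_key(x$edges$v, x$edges$v_layer))
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1L], to = el[, 2L],
               kind = x$edges$kind, confidence = x$edges$confidence,
               cost = x$edges$cost, stringsAsFactors = FALSE),
    directed = directed,
    vertices = data.frame(name = vk, gene = x$nodes$gene,
                          layer = x$nodes$layer, stringsAsFactors = FALSE))
  g
}

#' Write an interactome to flat TSV tables and GraphML
#'
#' @param x interactome.
#' @param prefix path prefix; writes \code{<prefix>_nodes.tsv},
#'   \code{<prefix>_edges.tsv} and \code{<prefix>.graphml}.
#' @param graphml also write GraphML via igraph.
#' @return invisibly, the written file paths.
#' @export
write_interactome <- function(x, prefix, graphml = TRUE) {
  nf <- paste0(prefix, "_nodes.tsv"); ef <- paste0(prefix, "_edges.tsv")
  utils::write.table(x$nodes, nf, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$edges, ef, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(nf, ef)
  if (graphml) {
    gf <- paste0(prefix, ".graphml")
    igraph::write_graph(interactome_graph(x, directed = TRUE), gf,
                        format = "graphml")
    paths <- c(paths, gf)
  }
  invisible(paths)
}

#' Read an interactome written by [write_interactome()]
#'
#' @param prefix path prefix used when writing.
#' @return interactome object.
#' @export
read_interactome <- function(prefix) {
  nodes <- utils::read.delim(paste0(prefix, "_nodes.tsv"),
                             stringsAsFactors = FALSE)
  edges <- utils::read.delim(paste0(prefix, "_edges.tsv"),
                             stringsAsFactors = FALSE)
  edges$n_sources <- as.integer(edges$n_sources)
  structure(list(nodes = nodes, edges = edges), class = "interactome")
}
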