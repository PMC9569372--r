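## From optimized forest back to a transcriptional regulatory network:
## induced subgraph, regulator extraction, ranking, focal-regulator
## interactor and shared-target analyses.

#' Induce the regulatory network from a forest
#'
#' The network's node set is exactly the forest's node set; its edge set
#' is every interactome edge (PPI and regulatory, original direction and
#' kind preserved) with both endpoints in the forest.  A superset of the
#' forest's own edges.
#'
#' @param forest steiner_forest.
#' @param interactome assembled interactome.
#' @return object of class \code{regulatory_network}: list with
#'   \code{nodes} (gene, layer) and \code{edges} (u, u_layer, v, v_layer,
#'   kind, confidence, cost).
#' @export
induce_network <- function(forest, interactome) {
  ikey <- node_key(interactome$nodes$gene, interactome$nodes$layer)
  fkey <- unique(forest$nodes$node)
  if (!all(fkey %in% ikey))
    stop_malformed("forest node '%s' missing from interactome",
                   setdiff(fkey, ikey)[1L])
  nodes <- interactome$nodes[match(fkey, ikey), , drop = FALSE]
  e <- interactome$edges
  inset <- node_key(e$u, e$u_layer) %in% fkey &
    node_key(e$v, e$v_layer) %in% fkey
  edges <- e[inset, , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("Regulatory network: %d nodes (%d protein, %d rna), %d edges (%d ppi, %d regulatory)\n",
              nrow(x$nodes), sum(x$nodes$layer == "protein"),
              sum(x$nodes$layer == "rna"), nrow(x$edges),
              sum(x$edges$kind == "ppi"), sum(x$edges$kind == "regulatory")))
  invisible(x)
}

#' Transcriptional regulators of a network
#'
#' Protein-layer nodes with at least one regulatory out-edge to an
#' RNA-layer node inside the network.
#'
#' @param network regulatory_network.
#' @return sorted character vector of regulator gene symbols (normalized).
#' @export
find_regulators <- function(network) {
  e <- network$edges
  reg <- e$kind == "regulatory" & e$u_layer == "protein" & e$v_layer == "rna"
  sort(unique(norm_gene(e$u[reg])))
}

## in-network regulatory target set of one regulator
.reg_targets <- function(network, gene) {
  e <- network$edges
  sel <- e$kind == "regulatory" & norm_gene(e$u) == norm_gene(gene)
  sort(unique(norm_gene(e$v[sel])))
}

.dense_rank_desc <- function(x) match(x, sort(unique(x), decreasing = TRUE))

#' Rank transcriptional regulators
#'
#' Each regulator gets its early-contrast log2 fold change (0 when absent
#' from the table) and its count of in-network regulatory targets that are
#' significantly up-regulated in the late contrast.  Both criteria are
#' turned into descending dense ranks; the composite rank is their mean,
#' ties broken alphabetically, and the list is sorted by composite rank.
#'
#' @param regulators character vector from [find_regulators()].
#' @param de_early,de_late DE tables for the two contrasts.
#' @param network regulatory_network the regulators live in.
#' @param fdr_max significance cutoff for target up/down classification.
#' @return data.frame of class \code{regulator_ranking} with columns gene,
#'   early_log2fc, n_up_targets, n_down_targets, rank_by_lfc,
#'   rank_by_targets, composite_rank.
#' @export
rank_regulators <- function(regulators, de_early, de_late, network,
                            fdr_max = 0.01) {
  regulators <- norm_gene(regulators)
  netreg <- find_regulators(network)
  if (!all(regulators %in% netreg))
    stop_malformed("'%s' is not a regulator of the network",
                   setdiff(regulators, netreg)[1L])
  up_late <- select_up_genes(de_late, fdr_max = fdr_max)
  dn_late <- de_late$gene[!is.na(de_late$padj) & de_late$padj < fdr_max &
                            de_late$log2fc < 0]
  lfc <- stats::setNames(de_early$log2fc, de_early$gene)
  rec <- do.call(rbind, lapply(regulators, function(g) {
    tg <- .reg_targets(network, g)
    data.frame(gene = g,
               early_log2fc = if (g %in% names(lfc)) unname(lfc[g]) else 0,
               n_up_targets = length(intersect(tg, up_late)),
               n_down_targets = length(intersect(tg, dn_late)),
               stringsAsFactors = FALSE)
  }))
  rec$rank_by_lfc <- .dense_rank_desc(rec$early_log2fc)
  rec$rank_by_targets <- .dense_rank_desc(rec$n_up_targets)
  rec$composite_rank <- (rec$rank_by_lfc + rec$rank_by_targets) / 2
  rec <- rec[order(rec$composite_rank, rec$gene), , drop = FALSE]
  rownames(rec) <- NULL
  class(rec) <- c("regulator_ranking", class(rec))
  rec
}

#' @export
print.regulator_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("Regulator ranking (%d regulators; composite = mean of fold-change and up-target dense ranks)\n",
              nrow(x)))
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat(sprintf("  ... %d more\n", nrow(x) - n))
  invisible(x)
}

#' Interactors of a focal regulator and their shared targets
#'
#' For every regulator sharing a PPI edge with the focal regulator:
#' the shared in-network regulatory targets, how many of those are
#' up- and down-regulated in the late contrast (padj < fdr_max, sign of
#' log2FC), and which reprogramming factors are among the shared targets.
#'
#' @param network regulatory_network.
#' @param focal_gene gene symbol of the focal regulator.
#' @param de_late DE table for the late contrast.
#' @param reprogramming_set character vector of reprogramming-factor
#'   symbols; default Pou5f1/Nanog/Sox2/Klf4/Myc.
#' @param fdr_max significance cutoff.
#' @return data.frame: interactor, n_shared_targets, n_shared_up,
#'   n_shared_down, shared_reprogramming (comma-collapsed), plus the
#'   shared target sets as a list attribute \code{shared_targets}.
#' @export
focal_interactors <- function(network, focal_gene, de_late,
                              reprogramming_set = c("Pou5f1", "Nanog",
                                                    "Sox2", "Klf4", "Myc"),
                              fdr_max = 0.01) {
  focal <- norm_gene(focal_gene)
  if (!focal %in% find_regulators(network))
    stop_malformed("focal gene '%s' is not a regulator of the network",
                   focal_gene)
  reprog <- norm_gene(reprogramming_set)
  e <- network$edges
  ppi <- e$kind == "ppi"
  nb <- unique(c(norm_gene(e$v[ppi & norm_gene(e$u) == focal]),
                 norm_gene(e$u[ppi & norm_gene(e$v) == focal])))
  nb <- sort(intersect(nb, find_regulators(network)))
  ft <- .reg_targets(network, focal)
  up <- select_up_genes(de_late, fdr_max = fdr_max)
  dn <- de_late$gene[!is.na(de_late$padj) & de_late$padj < fdr_max &
                       de_late$log2fc < 0]
  shared_list <- lapply(nb, function(g) intersect(.reg_targets(network, g), ft))
  names(shared_list) <- nb
  out <- data.frame(
    interactor = nb,
    n_shared_targets = unname(lengths(shared_list)),
    n_shared_up = vapply(shared_list, function(s)
      length(intersect(s, up)), 0L, USE.NAMES = FALSE),
    n_shared_down = vapply(shared_list, function(s)
      length(intersect(s, dn)), 0L, USE.NAMES = FALSE),
    shared_reprogramming = vapply(shared_list, function(s)
      paste(sort(intersect(s, reprog)), collapse = ","), "",
      USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "shared_targets") <- shared_list
  out
}

#' Candidate regulators that are regulatory targets of a focal regulator
#'
#' @param network regulatory_network.
#' @param focal_gene focal regulator gene symbol.
#' @param candidate_regulators character vector of candidates.
#' @return sorted subset of candidates whose RNA-layer node is a
#'   regulatory target of the focal gene in the network.
#' @export
focal_target_overlap <- function(network, focal_gene, candidate_regulators) {
  tg <- .reg_targets(network, focal_gene)
  sort(unique(norm_gene(candidate_regulators)[
    norm_gene(candidate_regulators) %in% tg]))
}

#' Write a regulatory network with regulator annotations
#'
#' Node tables carry \code{is_regulator} and \code{is_reprogramming}
#' flags; GraphML written via igraph.
#'
#' @param network regulatory_network.
#' @param prefix output path prefix.
#' @param reprogramming_set reprogramming factor symbols for flagging.
#' @export
write_network <- function(network, prefix,
                          reprogramming_set = c("Pou5f1", "Nanog", "Sox2",
                                                "Klf4", "Myc")) {
  nodes <- network$nodes
  nodes$is_regulator <- norm_gene(nodes$gene) %in% find_regulators(network) &
    nodes$layer == "protein"
  nodes$is_reprogramming <- norm_gene(nodes$gene) %in%
    norm_gene(reprogramming_set)
  utils::write.table(nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(network$edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = node_key(network$edges$u, network$edges$u_layer),
               to = node_key(network$edges$v, network$edges$v_layer),
               kind = network$edges$kind, cost = network$edges$cost,
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = node_key(nodes$gene, nodes$layer),
                          gene = nodes$gene, layer = nodes$layer,
                          is_regulator = nodes$is_regulator,
                          is_reprogramming = nodes$is_reprogramming,
                          stringsAsFactors = FALSE))
  igraph::write_graph(g, paste0(prefix, ".graphml"), format = "graphml")
  invisible(prefix)
}
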