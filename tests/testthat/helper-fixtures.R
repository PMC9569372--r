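## Shared fixtures, built in code.

## toy interactome: triangle A-B-C of PPI edges, TF A regulating g1, g2
toy_tables <- function() {
  list(
    ppi = data.frame(protein1 = c("A", "A", "B"),
                     protein2 = c("B", "C", "C"),
                     combined_score = c(900, 800, 700)),
    regs = data.frame(tf = c("A", "A"), target = c("g1", "g2"),
                      source = "src"))
}

toy_interactome <- function() {
  tt <- toy_tables()
  suppressMessages(assemble_interactome(load_ppi(tt$ppi, "thousand"),
                                        load_regulons(tt$regs)))
}

## 3-node path instance: A-B-C, costs 1, prizes 5, 0, 5
path_instance <- function() {
  mk_instance(c("A", "B", "C"), c(5, 0, 5),
              cbind(c("A", "B"), c("B", "C")), c(1, 1))
}

mk_instance <- function(genes, prizes, el, costs) {
  pcst_instance(
    data.frame(gene = genes, layer = "protein", prize = prizes,
               stringsAsFactors = FALSE),
    data.frame(u = el[, 1L], u_layer = "protein",
               v = el[, 2L], v_layer = "protein",
               cost = costs, kind = "ppi", stringsAsFactors = FALSE))
}

## independent brute-force oracle for the rooted objective
## (edge costs + omega per tree + forfeited prizes): enumerate all edge
## subsets forming valid multi-node forests; each node outside them
## either forfeits its prize or (omega > 0) opens a singleton tree at
## cost omega, whichever is cheaper.  Used only to validate solve_exact.
brute_force_optimum <- function(inst, omega = 0) {
  e <- inst$edges; n <- length(inst$prize); ne <- nrow(e)
  p <- inst$prize
  free_cost <- function(v) if (omega > 0) sum(pmin(p[v], omega)) else sum(p[v])
  best <- free_cost(seq_len(n))   # no multi-node tree at all
  for (m in seq_len(max(0L, 2^ne - 1L))) {
    sel <- which(bitwAnd(m, 2^(0:(ne - 1))) != 0L)
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, rbind(e$i[sel], e$j[sel]))
    comp <- igraph::components(g)
    nodes_in <- which(igraph::degree(g) > 0)
    multi <- comp$csize[comp$csize >= 2]
    if (length(sel) != sum(multi - 1)) next      # cycle somewhere
    obj <- sum(e$cost[sel]) + omega * length(multi) +
      free_cost(setdiff(seq_len(n), nodes_in))
    if (obj < best) best <- obj
  }
  best
}

## forest validity: trees connected, acyclic, node-disjoint, all edges in
## the instance graph
expect_valid_forest <- function(forest, inst) {
  if (nrow(forest$nodes) == 0L) {
    expect_identical(forest$n_trees, 0L)
    return(invisible(TRUE))
  }
  expect_false(anyDuplicated(forest$nodes$node) > 0)
  expect_true(all(forest$nodes$node %in% inst$key))
  ekey <- paste(pmin(inst$key[inst$edges$i], inst$key[inst$edges$j]),
                pmax(inst$key[inst$edges$i], inst$key[inst$edges$j]))
  if (nrow(forest$edges))
    expect_true(all(paste(pmin(forest$edges$u, forest$edges$v),
                          pmax(forest$edges$u, forest$edges$v)) %in% ekey))
  for (t in seq_len(forest$n_trees)) {
    vn <- forest$nodes$node[forest$nodes$tree == t]
    ed <- forest$edges[forest$edges$tree == t, , drop = FALSE]
    expect_identical(nrow(ed), length(vn) - 1L)  # acyclic if connected
    if (length(vn) > 1L) {
      g <- igraph::graph_from_data_frame(ed[, c("u", "v")],
                                         directed = FALSE, vertices = vn)
      expect_equal(igraph::components(g)$no, 1)
    }
    expect_true(all(c(ed$u, ed$v) %in% vn))
  }
  ## stored objective is recomputable
  expect_equal(pcst_objective(inst, forest), forest$objective,
               tolerance = 1e-9)
  invisible(TRUE)
}

rooted_obj <- function(forest, omega) forest$objective + omega * forest$n_trees

## hand-built 8-node regulatory fixture (proteins TF1, TF2, TF3, PX;
## rna G1, G2, G3, G4 plus TF2's own rna node)
regnet_fixture <- function() {
  ppi <- load_ppi(data.frame(
    protein1 = c("TF1", "TF1", "TF2", "TF1"),
    protein2 = c("TF2", "PX", "PX", "TF3"),
    combined_score = c(900, 800, 700, 600)), "thousand")
  regs <- load_regulons(data.frame(
    tf = c("TF1", "TF1", "TF2", "TF2", "TF3", "TF1"),
    target = c("G1", "G2", "G2", "G1", "G4", "TF2"),
    source = "src"))
  inter <- suppressMessages(assemble_interactome(ppi, regs))
  de_early <- read_de_table(data.frame(
    gene = c("TF1", "TF2", "TF3", "PX"),
    log2FoldChange = c(3, 2, 5, 1),
    padj = c(1e-5, 1e-4, 0.5, 1e-3)), "early")
  de_late <- read_de_table(data.frame(
    gene = c("G1", "G2", "G3", "G4"),
    log2FoldChange = c(4, -3, 5, 2),
    padj = c(1e-6, 1e-6, 1e-6, 0.2)), "late")
  list(inter = inter, de_early = de_early, de_late = de_late)
}
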