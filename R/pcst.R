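## Prize-Collecting Steiner Forest on the prized interactome.
##
## Minimization form: objective(F) = sum of edge costs in F + sum of prizes
## of nodes outside F.  Maximizing (collected prize - edge cost) differs
## from this only by the constant total prize, so both select the same
## forests.  A forest is a set of node-disjoint trees, each with at least
## two nodes; an isolated node simply forfeits its prize.  The exact
## solver (subset dynamic program) and the Goemans-Williamson primal-dual
## heuristic search the same space, so their objective ratio is >= 1 and
## the classic factor-2 guarantee is checkable empirically.

#' Construct a PCST instance
#'
#' Either supply \code{nodes}/\code{edges} tables directly, or use
#' [prized_instance()] to build one from an \code{interactome} plus a
#' \code{prize_assignment}.  Regulatory edges are treated as undirected
#' connectable links during optimization; direction is restored downstream
#' when the regulatory network is induced.
#'
#' @param nodes data.frame(gene, layer, prize).
#' @param edges data.frame(u, u_layer, v, v_layer, cost, kind).
#' @param omega default root-opening cost for the forest formulation.
#' @return object of class \code{pcst_instance}.
#' @export
pcst_instance <- function(nodes, edges, omega = 1.0) {
  stopifnot(all(c("gene", "layer", "prize") %in% names(nodes)))
  if (!"kind" %in% names(edges)) edges$kind <- "ppi"
  key <- node_key(nodes$gene, nodes$layer)
  if (anyDuplicated(key)) stop_malformed("duplicate (gene, layer) node identities")
  if (any(nodes$prize < 0)) stop_malformed("negative prizes")
  if (nrow(edges)) {
    if (any(!is.finite(edges$cost) | edges$cost <= 0))
      stop_malformed("edge costs must be finite and strictly positive")
    iu <- match(node_key(edges$u, edges$u_layer), key)
    iv <- match(node_key(edges$v, edges$v_layer), key)
    if (any(is.na(iu) | is.na(iv)))
      stop_malformed("edge endpoint missing from node table")
    if (any(iu == iv)) stop_malformed("self-loop edge in instance")
  } else iu <- iv <- integer()
  if (!is.numeric(omega) || omega <= 0)
    stop_malformed("omega must be positive")
  a <- pmin(key[iu], key[iv]); b <- pmax(key[iu], key[iv])
  ord <- order(a, b)
  structure(list(
    key = key, gene = nodes$gene, layer = nodes$layer,
    prize = as.numeric(nodes$prize),
    edges = data.frame(i = iu[ord], j = iv[ord],
                       cost = as.numeric(edges$cost[ord]),
                       kind = as.character(edges$kind[ord]),
                       stringsAsFactors = FALSE),
    omega = omega), class = "pcst_instance")
}

#' Build a PCST instance from an interactome and a prize assignment
#'
#' @param interactome assembled interactome.
#' @param prizes prize_assignment from [assign_prizes()].
#' @param omega root-opening cost.
#' @return pcst_instance.
#' @export
prized_instance <- function(interactome, prizes, omega = 1.0) {
  nodes <- interactome$nodes
  pz <- rep(0, nrow(nodes))
  idx <- match(node_key(prizes$gene, prizes$layer),
               node_key(nodes$gene, nodes$layer))
  ok <- !is.na(idx)
  pz[idx[ok]] <- prizes$prize[ok]
  nodes$prize <- pz
  pcst_instance(nodes, interactome$edges, omega = omega)
}

#' @export
print.pcst_instance <- function(x, ...) {
  cat(sprintf("PCST instance: %d nodes (%d prized, total prize %.4g), %d edges, omega %.3g\n",
              length(x$prize), sum(x$prize > 0), sum(x$prize),
              nrow(x$edges), x$omega))
  invisible(x)
}

## ---- forest container ------------------------------------------------

new_forest <- function(instance, tree_nodes, tree_edges, params = list()) {
  ## tree_nodes: list of integer index vectors; tree_edges: list of
  ## data.frames with columns i, j, cost, kind
  if (length(tree_nodes)) {
    ord <- order(vapply(tree_nodes, function(ix) min(instance$key[ix]), ""))
    tree_nodes <- tree_nodes[ord]; tree_edges <- tree_edges[ord]
  }
  nt <- length(tree_nodes)
  nodes <- if (nt) data.frame(
    node = unlist(lapply(tree_nodes, function(ix) instance$key[ix])),
    gene = unlist(lapply(tree_nodes, function(ix) instance$gene[ix])),
    layer = unlist(lapply(tree_nodes, function(ix) instance$layer[ix])),
    tree = rep(seq_len(nt), lengths(tree_nodes)),
    stringsAsFactors = FALSE)
  else data.frame(node = character(), gene = character(), layer = character(),
                  tree = integer(), stringsAsFactors = FALSE)
  ed <- if (nt) do.call(rbind, lapply(seq_len(nt), function(t) {
    e <- tree_edges[[t]]
    if (is.null(e) || nrow(e) == 0L)
      return(data.frame(u = character(), v = character(), cost = numeric(),
                        kind = character(), tree = integer(),
                        stringsAsFactors = FALSE))
    o <- data.frame(u = pmin(instance$key[e$i], instance$key[e$j]),
                    v = pmax(instance$key[e$i], instance$key[e$j]),
                    cost = e$cost, kind = e$kind, tree = t,
                    stringsAsFactors = FALSE)
    o[order(o$u, o$v), , drop = FALSE]
  }))
  else data.frame(u = character(), v = character(), cost = numeric(),
                  kind = character(), tree = integer(), stringsAsFactors = FALSE)
  rownames(nodes) <- rownames(ed) <- NULL
  in_forest <- instance$key %in% nodes$node
  objective <- sum(ed$cost) + sum(instance$prize[!in_forest])
  structure(list(nodes = nodes, edges = ed, objective = objective,
                 n_trees = nt, params = params), class = "steiner_forest")
}

#' @export
print.steiner_forest <- function(x, ...) {
  cat(sprintf("Steiner forest: %d tree(s), %d nodes, %d edges, objective %.6g\n",
              x$n_trees, nrow(x$nodes), nrow(x$edges), x$objective))
  invisible(x)
}

#' Plot a Steiner forest
#'
#' Protein nodes as circles, RNA nodes as squares.
#'
#' @param x steiner_forest.
#' @param ... passed to \code{igraph::plot.igraph}.
#' @export
plot.steiner_forest <- function(x, ...) {
  if (nrow(x$nodes) == 0L) {
    graphics::plot.new(); graphics::title("empty forest"); return(invisible(x))
  }
  g <- igraph::graph_from_data_frame(
    x$edges[, c("u", "v")], directed = FALSE,
    vertices = x$nodes[, "node", drop = FALSE])
  m <- match(igraph::V(g)$name, x$nodes$node)
  igraph::plot.igraph(g,
                      vertex.shape = ifelse(x$nodes$layer[m] == "rna",
                                            "square", "circle"),
                      vertex.label = x$nodes$gene[m], ...)
  invisible(x)
}

#' Assemble a forest object from explicit trees (with validation)
#'
#' Mainly for tests and for evaluating hand-built candidate forests with
#' [pcst_objective()].  Trees may have a single node here (such trees are
#' never produced by the solvers, which let isolated nodes forfeit their
#' prize instead).
#'
#' @param instance pcst_instance.
#' @param trees list; each element a list with \code{nodes} (character
#'   node keys, or bare gene symbols when unambiguous across layers) and
#'   \code{edges} (2-column matrix/data.frame of node keys; may be absent).
#' @return steiner_forest.
#' @export
forest_from_trees <- function(instance, trees) {
  resolve <- function(x) {
    ix <- match(x, instance$key)
    amb <- is.na(ix)
    if (any(amb)) {
      g <- norm_gene(x[amb])
      ng <- norm_gene(instance$gene)
      cand <- match(g, ng)
      cand[g %in% ng[duplicated(ng)]] <- NA
      ix[amb] <- cand
    }
    if (any(is.na(ix)))
      stop_malformed("forest node '%s' not in instance", x[is.na(ix)][1L])
    ix
  }
  ekey <- paste(pmin(instance$edges$i, instance$edges$j),
                pmax(instance$edges$i, instance$edges$j))
  tn <- list(); te <- list()
  for (t in seq_along(trees)) {
    ix <- sort(resolve(trees[[t]]$nodes))
    e <- trees[[t]]$edges
    if (is.null(e) || NROW(e) == 0L) {
      ef <- data.frame(i = integer(), j = integer(), cost = numeric(),
                       kind = character(), stringsAsFactors = FALSE)
    } else {
      e <- as.matrix(e)
      ei <- resolve(e[, 1L]); ej <- resolve(e[, 2L])
      pos <- match(paste(pmin(ei, ej), pmax(ei, ej)), ekey)
      if (any(is.na(pos)))
        stop_malformed("forest edge not present in instance graph")
      ef <- instance$edges[pos, , drop = FALSE]
    }
    if (nrow(ef) != length(ix) - 1L)
      stop_malformed("tree %d is not a tree (|E| != |V| - 1)", t)
    if (length(ix) > 1L) {
      g <- igraph::make_empty_graph(length(ix), directed = FALSE)
      g <- igraph::add_edges(g, rbind(match(ef$i, ix), match(ef$j, ix)))
      if (igraph::components(g)$no != 1L)
        stop_malformed("tree %d is disconnected", t)
    }
    tn[[t]] <- ix; te[[t]] <- ef
  }
  if (anyDuplicated(unlist(tn)))
    stop_malformed("trees share nodes; forest must be node-disjoint")
  new_forest(instance, tn, te)
}

#' Objective value of a forest on an instance
#'
#' Edge costs paid plus prizes forfeited by excluded nodes; recomputed
#' from scratch, independent of the value stored on the forest.
#'
#' @param instance pcst_instance.
#' @param forest steiner_forest.
#' @return numeric objective (minimization form).
#' @export
pcst_objective <- function(instance, forest) {
  ecost <- 0
  if (nrow(forest$edges)) {
    ekey <- paste(pmin(instance$key[instance$edges$i],
                       instance$key[instance$edges$j]),
                  pmax(instance$key[instance$edges$i],
                       instance$key[instance$edges$j]), sep = "\r")
    fkey <- paste(pmin(forest$edges$u, forest$edges$v),
                  pmax(forest$edges$u, forest$edges$v), sep = "\r")
    pos <- match(fkey, ekey)
    if (any(is.na(pos)))
      stop_malformed("forest contains an edge unknown to the instance")
    ecost <- sum(instance$edges$cost[pos])
  }
  ecost + sum(instance$prize[!(instance$key %in% forest$nodes$node)])
}

## ---- exact solver (subset dynamic program) ---------------------------

## Prim MST over an induced node subset of a dense cost matrix.
## Returns list(cost, edges = 2-col matrix of global node indices), or
## NULL when the induced subgraph is disconnected.
.prim_subset <- function(W, sub) {
  k <- length(sub)
  Wi <- W[sub, sub, drop = FALSE]
  intree <- rep(FALSE, k); intree[1L] <- TRUE
  best <- Wi[1L, ]; from <- rep(1L, k); best[1L] <- Inf
  edges <- matrix(0L, k - 1L, 2L); tot <- 0
  for (step in seq_len(k - 1L)) {
    cand <- which(!intree)
    v <- cand[which.min(best[cand])]
    if (!is.finite(best[v])) return(NULL)
    tot <- tot + best[v]
    edges[step, ] <- c(sub[from[v]], sub[v])
    intree[v] <- TRUE
    upd <- !intree & Wi[v, ] < best
    from[upd] <- v; best[upd] <- Wi[v, upd]
  }
  list(cost = tot, edges = edges)
}

#' Exact Prize-Collecting Steiner Forest solver (oracle for small instances)
#'
#' Dynamic program over node subsets: every candidate tree is a connected
#' node set spanned at minimum-spanning-tree cost, and the optimal forest
#' is the cheapest disjoint packing of candidate trees, each paying an
#' optional opening cost \code{omega} (default 0 = the plain objective).
#' With \code{omega > 0} (the rooted forest formulation) a tree may be a
#' single prized node; with \code{omega = 0} trees need at least two
#' nodes, otherwise every node would trivially join the forest.
#' Ties are broken toward fewer trees, then larger collected prize, then
#' lexicographically smaller node sets, so runs are deterministic and
#' parameter sweeps are monotone.  Cost grows as 3^n; refuse big inputs.
#'
#' @param instance pcst_instance.
#' @param max_nodes refuse instances larger than this.
#' @param omega per-tree opening cost added inside the DP (the reported
#'   forest objective never includes it).
#' @return steiner_forest attaining the global optimum (possibly empty).
#' @export
solve_exact <- function(instance, max_nodes = 15, omega = 0) {
  n <- length(instance$prize)
  if (n > max_nodes)
    stop_malformed("instance has %d nodes (> %d): use solve_pcsf()", n, max_nodes)
  params <- list(solver = "exact", omega = omega)
  if (n == 0L) return(new_forest(instance, list(), list(), params = params))
  p <- instance$prize
  W <- matrix(Inf, n, n)
  if (nrow(instance$edges)) {
    e <- instance$edges
    for (r in seq_len(nrow(e))) {
      c0 <- min(W[e$i[r], e$j[r]], e$cost[r])
      W[e$i[r], e$j[r]] <- c0; W[e$j[r], e$i[r]] <- c0
    }
  }
  pow2 <- bitwShiftL(1L, 0:(n - 1L))
  full <- bitwShiftL(1L, n) - 1L
  bitlist <- vector("list", full + 1L)
  for (m in 0:full) bitlist[[m + 1L]] <- which(bitwAnd(m, pow2) != 0L)

  ## candidate trees: connected subsets with >= 2 nodes, MST cost
  mstc <- rep(NA_real_, full + 1L)
  for (m in seq_len(full)) {
    bl <- bitlist[[m + 1L]]
    if (length(bl) < 2L) next
    r <- .prim_subset(W, bl)
    if (!is.null(r)) mstc[m + 1L] <- r$cost
  }
  tree_masks <- which(!is.na(mstc)) - 1L
  tree_prize <- vapply(tree_masks,
                       function(m) sum(p[bitlist[[m + 1L]]]), 0)
  trees_by_node <- lapply(seq_len(n), function(v) {
    sel <- bitwAnd(tree_masks, pow2[v]) != 0L
    list(mask = tree_masks[sel], cost = mstc[tree_masks[sel] + 1L],
         prize = tree_prize[sel])
  })

  fobj <- numeric(full + 1L); ftr <- integer(full + 1L)
  fpr <- numeric(full + 1L); choice <- integer(full + 1L)
  tol <- 1e-9
  for (m in seq_len(full)) {
    v <- bitlist[[m + 1L]][1L]
    rest0 <- m - pow2[v]
    objs <- p[v] + fobj[rest0 + 1L]
    trs <- ftr[rest0 + 1L]
    prs <- fpr[rest0 + 1L]
    chs <- 0L
    if (omega > 0) {  # singleton tree: pay omega, collect p(v), no edges
      objs <- c(objs, omega + fobj[rest0 + 1L])
      trs <- c(trs, 1L + ftr[rest0 + 1L])
      prs <- c(prs, p[v] + fpr[rest0 + 1L])
      chs <- c(chs, pow2[v])
    }
    tb <- trees_by_node[[v]]
    ok <- bitwAnd(tb$mask, m) == tb$mask
    if (any(ok)) {
      Ts <- tb$mask[ok]; rests <- m - Ts
      objs <- c(objs, tb$cost[ok] + omega + fobj[rests + 1L])
      trs <- c(trs, 1L + ftr[rests + 1L])
      prs <- c(prs, tb$prize[ok] + fpr[rests + 1L])
      chs <- c(chs, Ts)
    }
    cand <- which(objs <= min(objs) + tol)
    cand <- cand[trs[cand] == min(trs[cand])]
    cand <- cand[prs[cand] >= max(prs[cand]) - tol]
    k <- cand[1L]
    fobj[m + 1L] <- objs[k]; ftr[m + 1L] <- trs[k]
    fpr[m + 1L] <- prs[k]; choice[m + 1L] <- chs[k]
  }

  tn <- list(); te <- list(); m <- full
  ekey <- paste(pmin(instance$edges$i, instance$edges$j),
                pmax(instance$edges$i, instance$edges$j))
  while (m > 0L) {
    ch <- choice[m + 1L]
    if (ch == 0L) {
      m <- m - pow2[bitlist[[m + 1L]][1L]]
    } else if (length(bitlist[[ch + 1L]]) == 1L) {  # singleton tree
      tn[[length(tn) + 1L]] <- bitlist[[ch + 1L]]
      te[[length(te) + 1L]] <- instance$edges[0L, , drop = FALSE]
      m <- m - ch
    } else {
      bl <- bitlist[[ch + 1L]]
      mst <- .prim_subset(W, bl)
      pos <- match(paste(pmin(mst$edges[, 1L], mst$edges[, 2L]),
                         pmax(mst$edges[, 1L], mst$edges[, 2L])), ekey)
      tn[[length(tn) + 1L]] <- bl
      te[[length(te) + 1L]] <- instance$edges[pos, , drop = FALSE]
      m <- m - ch
    }
  }
  new_forest(instance, tn, te, params = params)
}

## ---- strong pruning --------------------------------------------------

#' Strong pruning of a single tree
#'
#' Leaf-to-root dynamic program: the payoff of a subtree is its prize sum
#' plus the (clamped at zero) payoff of its children beyond their linking
#' edges; any subtree whose payoff is below the cost of its attaching edge
#' is removed.  Never increases the objective; idempotent.
#'
#' @param edges data.frame/matrix with columns u, v, cost (node keys).
#' @param prizes named numeric vector; missing nodes count as prize 0.
#' @param root node at which to anchor the DP; default the
#'   lexicographically smallest node (kept in the result by construction).
#' @return list(nodes, edges) of the pruned tree (edges as a data.frame
#'   with u, v, cost).
#' @export
strong_prune <- function(edges, prizes, root = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges)[1:3] <- c("u", "v", "cost")
  edges$cost <- as.numeric(edges$cost)
  verts <- sort(unique(c(edges$u, edges$v)))
  if (nrow(edges) != length(verts) - 1L)
    stop_malformed("input is not a tree (|E| != |V| - 1)")
  g <- igraph::graph_from_data_frame(edges[, c("u", "v")], directed = FALSE,
                                     vertices = verts)
  if (igraph::components(g)$no != 1L || any(igraph::which_loop(g)))
    stop_malformed("input is not a tree (disconnected or self-loop)")
  if (is.null(root)) root <- verts[1L]
  if (!root %in% verts) stop_malformed("root '%s' not in tree", root)
  pz <- function(v) { x <- prizes[v]; ifelse(is.na(x), 0, x) }

  ## orient away from root (BFS order), then DP leaves-to-root
  adj <- lapply(stats::setNames(seq_along(verts), verts), function(i) integer())
  for (r in seq_len(nrow(edges))) {
    adj[[edges$u[r]]] <- c(adj[[edges$u[r]]], r)
    adj[[edges$v[r]]] <- c(adj[[edges$v[r]]], r)
  }
  parent_edge <- stats::setNames(rep(NA_integer_, length(verts)), verts)
  order_bfs <- character(0); queue <- root; seen <- stats::setNames(
    logical(length(verts)), verts); seen[root] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]; order_bfs <- c(order_bfs, v)
    for (r in adj[[v]]) {
      w <- if (edges$u[r] == v) edges$v[r] else edges$u[r]
      if (!seen[w]) { seen[w] <- TRUE; parent_edge[w] <- r; queue <- c(queue, w) }
    }
  }
  value <- stats::setNames(unname(pz(verts)), verts)
  keep_edge <- rep(TRUE, nrow(edges))
  for (v in rev(order_bfs)) {
    if (v == root) next
    r <- parent_edge[[v]]
    net <- value[[v]] - edges$cost[r]
    if (net < -1e-12) {      # subtree prize < attaching cost: prune
      keep_edge[r] <- FALSE
    } else {
      par <- if (edges$u[r] == v) edges$v[r] else edges$u[r]
      value[[par]] <- value[[par]] + max(0, net)
    }
  }
  ## drop everything disconnected from root after edge removal
  kept <- edges[keep_edge, , drop = FALSE]
  g2 <- igraph::graph_from_data_frame(
    if (nrow(kept)) kept[, c("u", "v")] else data.frame(u = character(),
                                                        v = character()),
    directed = FALSE, vertices = verts)
  comp <- igraph::components(g2)
  inroot <- comp$membership == comp$membership[match(root, verts)]
  keep_nodes <- verts[inroot]
  kept <- kept[kept$u %in% keep_nodes & kept$v %in% keep_nodes, , drop = FALSE]
  rownames(kept) <- NULL
  list(nodes = keep_nodes, edges = kept)
}

## ---- Goemans-Williamson primal-dual heuristic ------------------------

#' Solve the prized instance with the primal-dual moat-growing heuristic
#'
#' A dummy root is attached to every positive-prize node at cost
#' \code{omega}; clusters grow dual moats uniformly (a cluster is active
#' while its remaining prize potential is positive and it does not contain
#' the root), edges going tight merge clusters, exhausted clusters
#' deactivate.  The tight-edge tree containing the root is then strongly
#' pruned at the root and the root removed, yielding node-disjoint trees.
#' A tree may be a single node: it paid \code{omega} for its root edge and
#' collects its prize (the factor-2 guarantee of the rooted formulation is
#' stated over forests including such singletons).  Tie-breaking is
#' lexicographic in the canonical edge order, so the result is
#' deterministic.
#'
#' @param instance pcst_instance.
#' @param omega root-edge cost; defaults to the instance's omega.
#' @param pruning \code{"strong"} (default) or \code{"none"}.
#' @return steiner_forest.
#' @export
solve_pcsf <- function(instance, omega = NULL, pruning = c("strong", "none")) {
  pruning <- match.arg(pruning)
  if (is.null(omega)) omega <- instance$omega
  if (!is.numeric(omega) || omega <= 0) stop_malformed("omega must be positive")
  n <- length(instance$prize)
  params <- list(solver = "gw", omega = omega, pruning = pruning)
  prized <- which(instance$prize > 0)
  if (n == 0L || length(prized) == 0L)
    return(new_forest(instance, list(), list(), params = params))

  root <- n + 1L
  ei <- c(instance$edges$i, prized)
  ej <- c(instance$edges$j, rep(root, length(prized)))
  ecost <- c(instance$edges$cost, rep(omega, length(prized)))
  ne <- length(ei)
  slack <- ecost
  comp <- seq_len(root)
  pot <- c(instance$prize, Inf)
  act <- c(instance$prize > 0, FALSE)
  merge_edges <- integer(0)
  tol <- 1e-12

  while (any(act)) {
    ci <- comp[ei]; cj <- comp[ej]
    inter <- ci != cj
    rate <- (act[ci] + act[cj]) * inter
    te <- ifelse(rate > 0, slack / rate, Inf)
    arep <- which(act)
    td <- pot[arep]
    tmin <- min(c(te, td))
    edge_hit <- which(te <= tmin + tol)
    if (length(edge_hit)) {
      ev <- edge_hit[1L]           # canonical order: real edges first
      dt <- te[ev]
      slack <- slack - dt * rate
      pot[arep] <- pot[arep] - dt
      slack[ev] <- 0
      r1 <- comp[ei[ev]]; r2 <- comp[ej[ev]]
      rnew <- min(r1, r2)
      comp[comp == r1 | comp == r2] <- rnew
      pot[rnew] <- pot[r1] + pot[r2]
      has_root <- comp[root] == rnew
      act[rnew] <- !has_root && pot[rnew] > tol
      if (has_root) pot[rnew] <- Inf
      merge_edges <- c(merge_edges, ev)
    } else {
      dv <- arep[which(td <= tmin + tol)][1L]
      dt <- pot[dv]
      slack <- slack - dt * rate
      pot[arep] <- pot[arep] - dt
      pot[dv] <- 0
      act[dv] <- FALSE
    }
  }

  ## keep the root component of the tight-edge forest
  g <- igraph::make_empty_graph(root, directed = FALSE)
  g <- igraph::add_edges(g, rbind(ei[merge_edges], ej[merge_edges]))
  memb <- igraph::components(g)$membership
  keep <- merge_edges[memb[ei[merge_edges]] == memb[root] &
                        memb[ej[merge_edges]] == memb[root]]
  if (!length(keep))
    return(new_forest(instance, list(), list(), params = params))

  vname <- c(instance$key, ".ROOT.")
  ed <- data.frame(u = vname[ei[keep]], v = vname[ej[keep]],
                   cost = ecost[keep], stringsAsFactors = FALSE)
  if (pruning == "strong") {
    pr <- stats::setNames(instance$prize, instance$key)
    pruned <- strong_prune(ed, pr, root = ".ROOT.")
    ed <- pruned$edges
  }
  kept_nodes <- setdiff(unique(c(ed$u, ed$v)), ".ROOT.")
  ed <- ed[ed$u != ".ROOT." & ed$v != ".ROOT.", , drop = FALSE]

  ## split into trees; nodes attached only to the root survive as
  ## singleton trees (they paid omega and collect their prize)
  if (!length(kept_nodes))
    return(new_forest(instance, list(), list(), params = params))
  verts <- kept_nodes[order(kept_nodes)]
  g2 <- igraph::graph_from_data_frame(ed[, c("u", "v")], directed = FALSE,
                                      vertices = verts)
  cm <- igraph::components(g2)$membership
  ekey <- paste(pmin(instance$edges$i, instance$edges$j),
                pmax(instance$edges$i, instance$edges$j))
  tn <- list(); te_ <- list()
  for (t in seq_len(max(cm))) {
    vset <- verts[cm == t]
    ix <- sort(match(vset, instance$key))
    sel <- ed$u %in% vset & ed$v %in% vset
    eu <- match(ed$u[sel], instance$key); ev2 <- match(ed$v[sel], instance$key)
    pos <- match(paste(pmin(eu, ev2), pmax(eu, ev2)), ekey)
    tn[[length(tn) + 1L]] <- ix
    te_[[length(te_) + 1L]] <- instance$edges[pos, , drop = FALSE]
  }
  new_forest(instance, tn, te_, params = params)
}

## ---- serialization ---------------------------------------------------

#' Write a PCST instance as TSV node and edge tables
#' @param instance pcst_instance.
#' @param prefix path prefix (writes \code{<prefix>_nodes.tsv},
#'   \code{<prefix>_edges.tsv}).
#' @export
write_pcst_instance <- function(instance, prefix) {
  utils::write.table(
    data.frame(gene = instance$gene, layer = instance$layer,
               prize = instance$prize),
    paste0(prefix, "_nodes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  e <- instance$edges
  utils::write.table(
    data.frame(u_gene = instance$gene[e$i], u_layer = instance$layer[e$i],
               v_gene = instance$gene[e$j], v_layer = instance$layer[e$j],
               cost = e$cost, kind = e$kind),
    paste0(prefix, "_edges.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read a PCST instance written by [write_pcst_instance()]
#' @param prefix path prefix.
#' @param omega root-opening cost to store on the instance.
#' @export
read_pcst_instance <- function(prefix, omega = 1.0) {
  nodes <- utils::read.delim(paste0(prefix, "_nodes.tsv"),
                             stringsAsFactors = FALSE)
  e <- utils::read.delim(paste0(prefix, "_edges.tsv"),
                         stringsAsFactors = FALSE)
  pcst_instance(nodes,
                data.frame(u = e$u_gene, u_layer = e$u_layer,
                           v = e$v_gene, v_layer = e$v_layer,
                           cost = e$cost, kind = e$kind,
                           stringsAsFactors = FALSE),
                omega = omega)
}

#' Write a forest as a TSV edge table plus a JSON run manifest
#'
#' @param forest steiner_forest.
#' @param prefix path prefix (writes \code{<prefix>_forest_edges.tsv},
#'   \code{<prefix>_forest_nodes.tsv}, \code{<prefix>_manifest.json}).
#' @export
write_forest <- function(forest, prefix) {
  utils::write.table(forest$edges, paste0(prefix, "_forest_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(forest$nodes, paste0(prefix, "_forest_nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(forest$params,
                list(objective = forest$objective, n_trees = forest$n_trees,
                     n_nodes = nrow(forest$nodes), n_edges = nrow(forest$edges)))
  jsonlite::write_json(manifest, paste0(prefix, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
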