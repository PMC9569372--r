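test_that("objective counts paid edges plus forfeited prizes", {
  inst <- path_instance()
  expect_equal(pcst_objective(inst, forest_from_trees(inst, list())), 10)
  full <- forest_from_trees(inst, list(list(
    nodes = c("A", "B", "C"), edges = rbind(c("A", "B"), c("B", "C")))))
  expect_equal(pcst_objective(inst, full), 2.0)
  single <- forest_from_trees(inst, list(list(nodes = "A")))
  expect_equal(pcst_objective(inst, single), 5.0)
  ## unknown edge rejected
  bogus <- full
  bogus$edges$v[1] <- "C|protein"
  bogus$edges$u[1] <- "A|protein"
  expect_error(pcst_objective(inst, bogus), "unknown")
})

test_that("exact solver reproduces hand-enumerated optima", {
  inst <- path_instance()
  ex <- solve_exact(inst)
  expect_equal(ex$objective, 2.0)
  expect_identical(sort(ex$nodes$gene), c("A", "B", "C"))
  ## all prizes zero -> empty forest
  z <- mk_instance(c("A", "B"), c(0, 0), cbind("A", "B"), 1)
  expect_identical(solve_exact(z)$n_trees, 0L)
  expect_equal(solve_exact(z)$objective, 0)
  ## star, edge cost 10, prizes 1 -> empty, objective 5
  star <- mk_instance(c("C0", paste0("L", 1:4)), rep(1, 5),
                      cbind(rep("C0", 4), paste0("L", 1:4)), rep(10, 4))
  exs <- solve_exact(star)
  expect_identical(exs$n_trees, 0L)
  expect_equal(exs$objective, 5)
  expect_error(solve_exact(gen_small_pcst_instance(12, "random", seed = 1),
                           max_nodes = 10), "solve_pcsf")
})

test_that("exact solver matches an independent edge-subset enumeration", {
  set.seed(99)
  for (s in 1:12) {
    inst <- gen_small_pcst_instance(sample(4:7, 1),
                                    sample(c("random", "path", "star"), 1),
                                    seed = 1000 + s)
    for (om in c(0, 1)) {
      ex <- solve_exact(inst, omega = om)
      expect_equal(rooted_obj(ex, om), brute_force_optimum(inst, om),
                   tolerance = 1e-9)
      expect_valid_forest(ex, inst)
    }
  }
})

test_that("strong pruning removes unprofitable subtrees and is idempotent", {
  ## leaf with prize 0 on a cost-1 edge disappears
  pr <- c(r = 5, a = 0)
  sp <- strong_prune(data.frame(u = "r", v = "a", cost = 1), pr, root = "r")
  expect_identical(sp$nodes, "r")
  ## fully profitable tree unchanged
  pr2 <- c(r = 1, a = 2, b = 3)
  ed2 <- data.frame(u = c("r", "a"), v = c("a", "b"), cost = c(1, 1))
  sp2 <- strong_prune(ed2, pr2, root = "r")
  expect_identical(sort(sp2$nodes), c("a", "b", "r"))
  ## chain r-a-b, costs 1,3, prizes 5,0,2: b pruned (prize 2 < cost 3),
  ## then a (subtree prize 0 < cost 1) -- the DP removes both
  ed3 <- data.frame(u = c("r", "a"), v = c("a", "b"), cost = c(1, 3))
  sp3 <- strong_prune(ed3, c(r = 5, a = 0, b = 2), root = "r")
  expect_false("b" %in% sp3$nodes)
  expect_identical(sp3$nodes, "r")
  ## idempotent on a profitable result
  sp4 <- strong_prune(sp2$edges, pr2, root = "r")
  expect_identical(sp4, sp2)
  expect_error(strong_prune(data.frame(u = c("a", "b"), v = c("b", "a"),
                                       cost = c(1, 1)), pr), "not a tree")
})

test_that("primal-dual heuristic agrees with the oracle on the fixtures", {
  inst <- path_instance()
  ## omega below the tree's net profit: same forest as the exact solver
  h <- solve_pcsf(inst, omega = 5)
  expect_identical(sort(h$nodes$gene), c("A", "B", "C"))
  expect_equal(h$objective, 2.0)
  ## two profitable components separated by an expensive bridge
  inst2 <- mk_instance(c("A", "B", "X", "Y"), c(5, 5, 4, 4),
                       rbind(c("A", "B"), c("X", "Y"), c("B", "X")),
                       c(1, 1, 100))
  h2 <- solve_pcsf(inst2, omega = 1)
  expect_identical(h2$n_trees, 2L)
  expect_identical(sort(h2$nodes$gene), c("A", "B", "X", "Y"))
  ## omega above the total prize: nothing can pay its opening cost
  h3 <- solve_pcsf(inst2, omega = 100)
  expect_identical(h3$n_trees, 0L)
  expect_equal(h3$objective, 18)
})

test_that("heuristic stays within factor 2 of the rooted optimum", {
  set.seed(5)
  for (s in 1:30) {
    inst <- gen_small_pcst_instance(sample(4:10, 1),
                                    sample(c("random", "path", "star"), 1),
                                    seed = 2000 + s)
    om <- sample(c(0.5, 1, 2), 1)
    ex <- solve_exact(inst, omega = om)
    he <- solve_pcsf(inst, omega = om)
    expect_valid_forest(he, inst)
    re <- rooted_obj(ex, om); rh <- rooted_obj(he, om)
    if (re < 1e-12) expect_lt(rh, 1e-9) else expect_lte(rh / re, 2)
  }
})

test_that("solver runs are deterministic and serialize byte-identically", {
  inst <- gen_small_pcst_instance(10, "random", seed = 3)
  f1 <- solve_pcsf(inst, omega = 1)
  f2 <- solve_pcsf(inst, omega = 1)
  expect_identical(f1, f2)
  d <- tempdir()
  write_forest(f1, file.path(d, "runA"))
  write_forest(f2, file.path(d, "runB"))
  for (suf in c("_forest_edges.tsv", "_forest_nodes.tsv", "_manifest.json"))
    expect_identical(readLines(file.path(d, paste0("runA", suf))),
                     readLines(file.path(d, paste0("runB", suf))))
  ## instance round-trip
  write_pcst_instance(inst, file.path(d, "inst"))
  inst2 <- read_pcst_instance(file.path(d, "inst"))
  expect_equal(inst$prize, inst2$prize, tolerance = 1e-9)
  expect_equal(inst$edges$cost, inst2$edges$cost, tolerance = 1e-9)
  expect_identical(solve_pcsf(inst2, omega = 1)$nodes, f1$nodes)
})
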