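test_that("network induction keeps every in-set interactome edge", {
  fx <- regnet_fixture()
  inst <- prized_instance(fx$inter,
                          suppressMessages(assign_prizes(fx$inter, fx$de_early,
                                                         fx$de_late)))
  forest <- forest_from_trees(inst, list(list(
    nodes = c("TF1|protein", "TF2|protein", "PX|protein", "G1|rna", "G2|rna"),
    edges = rbind(c("TF1|protein", "TF2|protein"),
                  c("TF1|protein", "PX|protein"),
                  c("TF1|protein", "G1|rna"),
                  c("TF1|protein", "G2|rna")))))
  net <- induce_network(forest, fx$inter)
  expect_identical(nrow(net$nodes), 5L)
  expect_identical(nrow(net$edges), 7L)   # 4 tree edges + 3 extra in-set
  ## direction and kind preserved for the extra regulatory edges
  expect_true(any(net$edges$u == "TF2" & net$edges$v == "G2" &
                    net$edges$kind == "regulatory"))
  expect_false(any(net$edges$u == "TF3" | net$edges$v == "TF3"))
  ## empty forest -> empty network
  e0 <- induce_network(forest_from_trees(inst, list()), fx$inter)
  expect_identical(nrow(e0$nodes), 0L)
  expect_identical(nrow(e0$edges), 0L)
})

test_that("regulators are protein nodes with in-network regulatory edges", {
  fx <- regnet_fixture()
  inst <- prized_instance(fx$inter,
                          suppressMessages(assign_prizes(fx$inter, fx$de_early,
                                                         fx$de_late)))
  forest <- forest_from_trees(inst, list(list(
    nodes = c("TF1|protein", "TF2|protein", "PX|protein", "G1|rna", "G2|rna"),
    edges = rbind(c("TF1|protein", "TF2|protein"),
                  c("TF1|protein", "PX|protein"),
                  c("TF1|protein", "G1|rna"),
                  c("TF1|protein", "G2|rna")))))
  net <- induce_network(forest, fx$inter)
  expect_identical(find_regulators(net), c("TF1", "TF2"))  # PX: PPI only

  rk <- rank_regulators(c("TF1", "TF2"), fx$de_early, fx$de_late, net)
  expect_identical(rk$gene, c("TF1", "TF2"))
  expect_equal(rk$early_log2fc, c(3, 2))
  expect_identical(rk$n_up_targets, c(1L, 1L))    # G1 up; G2 down
  expect_identical(rk$n_down_targets, c(1L, 1L))
  expect_identical(rk$rank_by_lfc, c(1L, 2L))
  expect_identical(rk$rank_by_targets, c(1L, 1L)) # dense tie
  expect_equal(rk$composite_rank, c(1, 1.5))
  ## output is a permutation of the input
  expect_setequal(rk$gene, c("TF1", "TF2"))
})

test_that("focal interactor analysis reports shared-target splits", {
  fx <- regnet_fixture()
  inst <- prized_instance(fx$inter,
                          suppressMessages(assign_prizes(fx$inter, fx$de_early,
                                                         fx$de_late)))
  forest <- forest_from_trees(inst, list(list(
    nodes = c("TF1|protein", "TF2|protein", "PX|protein", "G1|rna", "G2|rna"),
    edges = rbind(c("TF1|protein", "TF2|protein"),
                  c("TF1|protein", "PX|protein"),
                  c("TF1|protein", "G1|rna"),
                  c("TF1|protein", "G2|rna")))))
  net <- induce_network(forest, fx$inter)
  fi <- focal_interactors(net, "TF1", fx$de_late,
                          reprogramming_set = c("G1"))
  expect_identical(fi$interactor, "TF2")   # PX is not a regulator
  expect_identical(fi$n_shared_targets, 2L)
  expect_identical(fi$n_shared_up, 1L)    # G1
  expect_identical(fi$n_shared_down, 1L)  # G2
  expect_identical(fi$shared_reprogramming, "G1")
  expect_error(focal_interactors(net, "PX", fx$de_late), "not a regulator")

  ## focal regulator without PPI neighbours -> empty record list
  f2 <- forest_from_trees(inst, list(list(
    nodes = c("TF3|protein", "G4|rna"),
    edges = rbind(c("TF3|protein", "G4|rna")))))
  n2 <- induce_network(f2, fx$inter)
  expect_identical(nrow(focal_interactors(n2, "TF3", fx$de_late)), 0L)
})

test_that("focal target overlap finds regulators that are RNA targets", {
  fx <- regnet_fixture()
  inst <- prized_instance(fx$inter,
                          suppressMessages(assign_prizes(fx$inter, fx$de_early,
                                                         fx$de_late)))
  forest <- forest_from_trees(inst, list(list(
    nodes = c("TF1|protein", "TF2|protein", "TF2|rna", "G1|rna"),
    edges = rbind(c("TF1|protein", "TF2|protein"),
                  c("TF1|protein", "TF2|rna"),
                  c("TF1|protein", "G1|rna")))))
  net <- induce_network(forest, fx$inter)
  ov <- focal_target_overlap(net, "TF1", c("TF2", "TF3", "PX"))
  expect_identical(ov, "TF2")   # TF3 absent; PX connected by PPI only
})

test_that("composite ranks respond monotonically to improvement", {
  fx <- regnet_fixture()
  inst <- prized_instance(fx$inter,
                          suppressMessages(assign_prizes(fx$inter, fx$de_early,
                                                         fx$de_late)))
  forest <- forest_from_trees(inst, list(list(
    nodes = c("TF1|protein", "TF2|protein", "PX|protein", "G1|rna", "G2|rna"),
    edges = rbind(c("TF1|protein", "TF2|protein"),
                  c("TF1|protein", "PX|protein"),
                  c("TF1|protein", "G1|rna"),
                  c("TF1|protein", "G2|rna")))))
  net <- induce_network(forest, fx$inter)
  base <- rank_regulators(c("TF1", "TF2"), fx$de_early, fx$de_late, net)
  r_tf2 <- base$composite_rank[base$gene == "TF2"]
  ## raise TF2's early fold change above TF1's: its rank must not worsen
  de2 <- fx$de_early
  de2$log2fc[de2$gene == "TF2"] <- 10
  improved <- rank_regulators(c("TF1", "TF2"), de2, fx$de_late, net)
  expect_lte(improved$composite_rank[improved$gene == "TF2"], r_tf2)
  expect_identical(improved$gene[1], "TF2")
})
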