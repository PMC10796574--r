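test_that("triplets extracted from distances use the strict-minimum rule", {
  D <- converged_distances(balanced(1))
  tt <- triplets_from_distances(D)
  expect_true(any(tt$a == "x" & tt$b == "y" & tt$out == "z"))
  # and that triplet is NOT induced by the tree: topology is distorted
  want <- induced_triplets(balanced(1)$tree)
  expect_false(any(want$a == "x" & want$b == "y" & want$out == "z"))

  D0 <- converged_distances(balanced(1 / 100))
  expect_equal(triplets_from_distances(D0),
               induced_triplets(balanced(1)$tree), ignore_attr = TRUE)

  Deq <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(Deq) <- 0
  expect_equal(nrow(triplets_from_distances(Deq)), 0L)
})

test_that("Build assembles dense consistent triplet sets into the tree", {
  one <- data.frame(a = "x", b = "y", out = "z")
  expect_equal(build_tree(one)$newick, "((x,y),z);")
  contra <- data.frame(a = c("x", "y"), b = c("y", "z"), out = c("z", "x"))
  expect_error(build_tree(contra), "incompatible")
  expect_error(build_tree(one, labels = character(0)), "empty")

  sc <- balanced(1)
  expect_equal(build_tree(induced_triplets(sc$tree))$newick,
               "((t,x),(y,z));")

  set.seed(101)
  for (i in 1:5) {
    tr <- random_equidistant_tree(sample(5:9, 1))
    expect_identical(build_tree(induced_triplets(tr))$newick,
                     topology_newick(tr))
  }
})

test_that("half the maximum dissimilarity recovers the height when valid", {
  tr <- balanced(1)$tree
  expect_equal(recover_height(tree_distances(tr)), 2)
  # distorted balanced example underestimates: max entry 7/2
  expect_equal(recover_height(converged_distances(balanced(1))), 7 / 4)
  set.seed(111)
  tr2 <- random_equidistant_tree(6, height = 5)
  expect_equal(recover_height(tree_distances(tr2)), 5)
})

test_that("confounding configurations classify the worked examples", {
  expect_equal(confounding_configuration(balanced(1 / 4)), "B")
  expect_equal(confounding_configuration(caterpillar(1 / 2)), "none")
  expect_equal(root_placement_case(caterpillar(1 / 2)), "e")
  expect_equal(root_placement_case(balanced(1 / 4)), "none")

  set.seed(121)
  tr <- random_equidistant_tree(6)
  scA <- random_scenario(tr, epsilon = 0.25, target = "sibling_pairs")
  # sibling pairs below a non-root vertex: family A
  if (scA$tree$parent[scA$r$node] != scA$tree$root)
    expect_equal(confounding_configuration(scA), "A")
})

test_that("placement cases and confounding families are complementary", {
  for (sc in sample_scenarios(18, seed = 131)) {
    case <- root_placement_case(sc)
    cfg <- confounding_configuration(sc)
    expect_equal(case %in% c("a", "b", "c", "d", "e"),
                 !(cfg %in% c("B", "C")),
                 info = paste("case", case, "cfg", cfg))
  }
})

test_that("height identifiability runs both directions on the examples", {
  # caterpillar: identifiable, recovered height = 2 + delta exactly
  rep <- assess_height_identifiability(caterpillar(1 / 2, delta = 1 / 100))
  expect_true(rep$identifiable)
  expect_equal(rep$recovered_height, 2 + 1 / 100)
  expect_error(construct_confounder(caterpillar(1 / 2)), "identifiable")

  # balanced: family B, not identifiable; the explicit confounder keeps
  # the dissimilarity and shifts the height by epsilon*delta
  sc <- balanced(1 / 4)
  rep2 <- assess_height_identifiability(sc, delta = 1 / 8)
  expect_false(rep2$identifiable)
  cf <- rep2$confounder
  expect_equal(cf$height, 2 + 1 / 32)
  D1 <- converged_distances(sc)
  D2 <- converged_distances(cf$scenario)[rownames(D1), colnames(D1)]
  expect_equal(D1, D2)

  # hypothesis violated (not triplet respecting at eps = 1): refuse
  expect_error(assess_height_identifiability(balanced(1)),
               "triplet-respecting metric")
})

test_that("confounders exist exactly for families A, B, C", {
  for (sc0 in sample_scenarios(15, seed = 141,
                               targets = c("sibling_pairs", "root_tops",
                                           "pair_below_child", "cherry",
                                           "split_pair", "unconstrained"))) {
    sc <- set_epsilon(sc0, tr_metric_cap(sc0) / 2)
    rep <- assess_height_identifiability(sc)
    if (rep$identifiable) {
      expect_equal(rep$recovered_height, sc$tree$h_root)
    } else {
      cf <- rep$confounder
      D1 <- converged_distances(sc)
      D2 <- converged_distances(cf$scenario)[rownames(D1), colnames(D1)]
      expect_equal(D1, D2, tolerance = 1e-9)
      expect_gt(cf$height, sc$tree$h_root)  # root rises by epsilon*delta > 0
    }
    # a triplet-respecting tree metric is never identifiable
    dg <- diagnose(sc, oracle = FALSE)
    if (isTRUE(dg$verdicts$is_tree_metric)) expect_false(rep$identifiable)
  }
})
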