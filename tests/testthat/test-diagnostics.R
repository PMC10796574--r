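test_that("distance threshold matches the worked example and is strict", {
  sc <- balanced(1)
  expect_equal(distance_threshold(sc), 4 / 3)
  # algebraic identity: threshold * (beta - alpha) = h(lca(R))
  expect_equal(distance_threshold(sc) * (sc$beta - sc$alpha),
               scenario_lca(sc)$height)

  for (sc in sample_scenarios(5, seed = 51)) {
    thr <- distance_threshold(sc)
    below <- check_distance_axioms(
      converged_distances(set_epsilon(sc, thr * (1 - 1/64))), "distance")
    above <- check_distance_axioms(
      converged_distances(set_epsilon(sc, thr * (1 + 1/64))), "distance")
    expect_true(below$ok)
    expect_false(above$ok)
    expect_match(above$reason, "non-positive")
  }
})

test_that("cherry scenarios are recognised and always triplet respecting", {
  sc <- balanced(1)
  expect_false(is_cherry_scenario(sc))
  expect_false(is_cherry_scenario(caterpillar(1 / 2)))

  set.seed(55)
  tr <- random_equidistant_tree(6)
  ch <- random_scenario(tr, epsilon = 0.5, target = "cherry")
  expect_true(is_cherry_scenario(ch))
  expect_equal(triplet_threshold(ch), Inf)
  expect_equal(internal_edge_bound(ch), Inf)
  eps_ok <- distance_threshold(ch) * (1 - 1/64)
  expect_true(is_triplet_respecting(set_epsilon(ch, eps_ok)))
})

test_that("triplet threshold matches the worked examples", {
  expect_equal(triplet_threshold(balanced(1)), 1 / 3)
  # caterpillar example: threshold exactly 1 for any delta > 0
  for (d in c(1 / 100, 1 / 5, 1))
    expect_equal(triplet_threshold(caterpillar(1 / 2, delta = d)), 1)

  # definitional check agrees on both sides of the threshold
  expect_true(is_triplet_respecting(balanced(1 / 4)))
  expect_false(is_triplet_respecting(balanced(1)))
  # strictness: at the threshold the property already fails
  expect_false(is_triplet_respecting(balanced(1 / 3)))
  # eps = 0 is always triplet respecting
  expect_true(is_triplet_respecting(caterpillar(0)))
})

test_that("internal-edge bound is sufficient but not necessary", {
  sc <- balanced(1)
  expect_equal(internal_edge_bound(sc), 1 / 3)  # min(1, 1/2) / (3/2)
  # the caterpillar example shows the bound is not necessary:
  # bound = delta / (beta - alpha) while the true threshold stays 1
  sc4 <- caterpillar(1 / 2, delta = 1 / 100)
  expect_equal(internal_edge_bound(sc4), 1 / 100)
  expect_equal(triplet_threshold(sc4), 1)
  expect_true(is_triplet_respecting(sc4))

  # rescaling weights and (beta - alpha) jointly leaves the bound unchanged
  tr_big <- read_equidistant("((t:2,x:2):2,(y:3,z:3):1);")
  sc_big <- convergence_scenario(tr_big,
    r = tree_point(tr_big, c("t", "x"), 7 / 2),
    s = tree_point(tr_big, c("y", "z"), 7 / 2),
    r_prime = tree_point(tr_big, "x", 1 / 2),
    s_prime = tree_point(tr_big, "y", 1 / 2), epsilon = 1)
  expect_equal(internal_edge_bound(sc_big), internal_edge_bound(sc))

  for (sc in sample_scenarios(8, seed = 61)) {
    if (is_cherry_scenario(sc)) next
    expect_lte(internal_edge_bound(sc), triplet_threshold(sc) + 1e-12)
  }
})

test_that("metric threshold matches hand computation and the triangle oracle", {
  sc <- balanced(1)
  # qualifying triples: (x,t;z) gives 2/(2(1-1/4)) = 4/3,
  # (y,z;x) gives 3/(2(3/2-1/4)) = 6/5; minimum 6/5
  expect_equal(metric_threshold(sc), 6 / 5)

  sc14 <- balanced(1 / 4)
  expect_true(check_distance_axioms(converged_distances(sc14), "metric")$ok)

  for (sc in sample_scenarios(6, seed = 71)) {
    thr <- metric_threshold(sc)
    cap <- min(distance_threshold(sc), triplet_threshold(sc))
    eb <- min(thr, cap) * (1 - 1/64)
    expect_true(check_distance_axioms(
      converged_distances(set_epsilon(sc, eb)), "metric")$ok)
    # every qualifying ratio exceeds 1, so eps <= 1 implies a metric
    expect_gt(thr, 1)
    if (is.finite(thr) && thr * (1 + 1/64) < cap) {
      expect_false(check_distance_axioms(
        converged_distances(set_epsilon(sc, thr * (1 + 1/64))), "metric")$ok)
    }
  }
})

test_that("axiom oracles detect failures with witnesses", {
  D <- converged_distances(balanced(1))
  expect_true(check_distance_axioms(D, "metric")$ok)
  four <- check_distance_axioms(D, "tree_metric")
  expect_false(four$ok)
  expect_setequal(four$witness, c("t", "x", "y", "z"))
  # the witness quadruple has sums 9/2, 5, 6: maximum attained once
  sums <- c(D["x", "y"] + D["z", "t"], D["x", "t"] + D["z", "y"],
            D["x", "z"] + D["y", "t"])
  expect_equal(sort(sums), c(9 / 2, 5, 6))

  Dneg <- D; Dneg["x", "y"] <- Dneg["y", "x"] <- -1
  expect_false(check_distance_axioms(Dneg, "distance")$ok)
  Dasym <- D; Dasym["x", "y"] <- 99
  expect_error(check_distance_axioms(Dasym, "distance"), "symmetric")
})

test_that("placement families decide tree-metricity with the strength bound", {
  # sibling paths (family a): ultrametric whenever triplet respecting
  set.seed(81)
  tr <- random_equidistant_tree(6)
  sca <- random_scenario(tr, epsilon = 0.5, target = "sibling_pairs")
  expect_equal(tree_metric_configuration(sca), "a")
  eps_a <- tr_metric_cap(sca) * (1 - 1/64)
  Da <- converged_distances(set_epsilon(sca, eps_a))
  expect_true(check_distance_axioms(Da, "ultrametric")$ok)

  # balanced example: no family, metric but never a tree metric
  expect_equal(tree_metric_configuration(balanced(1)), "none")
  expect_true(is.na(tree_metric_bound(balanced(1))))

  # family c with two leaves below the bottom point: the positional
  # classification alone is not enough -- the strength bound decides
  tr_c <- read_equidistant("((a:1,(b:0.5,c:0.5):0.5):9,d:10);")
  mk <- function(eps) convergence_scenario(tr_c,
    r = tree_point(tr_c, c("a", "b"), 5 / 4),
    s = tree_point(tr_c, "d", 5 / 4),
    r_prime = tree_point(tr_c, c("b", "c"), 3 / 4),
    s_prime = tree_point(tr_c, "d", 3 / 4), epsilon = eps)
  expect_equal(tree_metric_configuration(mk(1)), "c")
  expect_equal(tree_metric_bound(mk(1)), 2)  # (h(u)-h(v))/(h(u)-alpha)
  for (eps in c(1, 3)) {
    sc <- mk(eps)
    dg <- diagnose(sc, oracle = TRUE)
    expect_true(dg$verdicts$is_triplet_respecting)
    expect_true(dg$verdicts$is_metric)
    expect_equal(dg$verdicts$is_tree_metric, eps <= 2)
    expect_equal(dg$oracle$tree_metric$ok, eps <= 2)
  }
})

test_that("verdict chain is monotone across random scenarios", {
  for (sc0 in sample_scenarios(8, seed = 91, n_range = 4:7)) {
    cap <- distance_threshold(sc0)
    for (f in c(0.2, 0.7, 1.1)) {
      dg <- diagnose(set_epsilon(sc0, cap * f), oracle = FALSE)
      v <- dg$verdicts
      if (isTRUE(v$is_ultrametric)) expect_true(v$is_tree_metric)
      if (isTRUE(v$is_tree_metric)) expect_true(v$is_metric)
      if (isTRUE(v$is_metric)) expect_true(v$is_triplet_respecting)
      if (isTRUE(v$is_triplet_respecting)) expect_true(v$is_distance)
      # verdicts under failed hypotheses are withheld, not extrapolated
      if (!isTRUE(v$is_triplet_respecting)) expect_true(is.na(v$is_metric))
      if (!isTRUE(v$is_metric)) expect_true(is.na(v$is_ultrametric))
    }
  }
})
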