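test_that("scenario validation enforces the model invariants", {
  tr <- read_equidistant("((t:1,x:1):1,(y:1.5,z:1.5):0.5);")
  mk <- function(beta = 7/4, alpha = 1/4, rp_leaf = "x")
    convergence_scenario(tr,
      r = tree_point(tr, c("t", "x"), beta),
      s = tree_point(tr, c("y", "z"), beta),
      r_prime = tree_point(tr, rp_leaf, alpha),
      s_prime = tree_point(tr, "y", alpha),
      epsilon = 1)
  expect_s3_class(mk(), "convergence_scenario")

  # beta colliding with an internal vertex height
  expect_error(convergence_scenario(tr,
    r = tree_point(tr, c("t","x"), 1.75), s = tree_point(tr, c("y","z"), 1.75),
    r_prime = tree_point(tr, "x", 0.25),
    s_prime = tree_point(tr, "y", 0.25), epsilon = -1),
    "non-negative")
  # alpha colliding with a vertex height elsewhere in the tree is rejected:
  # lca(b,c) sits at 1/2, and the points are strictly inside pendant edges
  tr2 <- read_equidistant("((a:1,(b:0.5,c:0.5):0.5):1,d:2);")
  expect_error(convergence_scenario(tr2,
    r = tree_point(tr2, "a", 3/4), s = tree_point(tr2, "d", 3/4),
    r_prime = tree_point(tr2, "a", 1/2),
    s_prime = tree_point(tr2, "d", 1/2), epsilon = 1),
    "differ from the height of every vertex")
  # bottom point not below its top point
  expect_error(mk(rp_leaf = "z"), "below")
  # non-generic tree
  ng <- read_equidistant("((a:1,b:1):1,(c:1,d:1):1);")
  expect_error(convergence_scenario(ng,
    r = tree_point(ng, c("a","b"), 1.75), s = tree_point(ng, c("c","d"), 1.75),
    r_prime = tree_point(ng, "a", 0.25),
    s_prime = tree_point(ng, "c", 0.25), epsilon = 1),
    "generic")
  # comparable top points: r above r2 on the same root path
  expect_error(convergence_scenario(tr,
    r = tree_point(tr, c("t","x"), 7/4), s = tree_point(tr, "x", 1/2),
    r_prime = tree_point(tr, "t", 1/4),
    s_prime = tree_point(tr, "x", 1/4), epsilon = 1),
    "equal height|incomparable")
})

test_that("leaf pairs classify as below / strictly below the set", {
  sc <- balanced(1)
  expect_equal(as.character(below_status(sc, "t", "z")), "below")
  expect_equal(as.character(below_status(sc, "x", "y")), "strictly_below")
  expect_equal(as.character(below_status(sc, "y", "z")), "not_below")
  expect_error(below_status(sc, "x", "x"), "distinct")
})

test_that("the convergence stop height matches the worked example", {
  sc <- balanced(1)
  expect_equal(convergence_stop_height(sc, "t", "z"), 3 / 2)
  expect_equal(convergence_stop_height(sc, "z", "t"), 3 / 2)  # symmetric
  expect_equal(convergence_stop_height(sc, "x", "y"), 1 / 4)  # alpha
  expect_error(convergence_stop_height(sc, "y", "z"), "not below")
})

test_that("adjusted dissimilarities follow the model formula", {
  sc <- balanced(1)
  D <- converged_distances(sc)
  expect_equal(D["x", "y"], 1)        # 4 - 3*eps at eps = 1
  expect_equal(D["t", "z"], 7 / 2)    # 4 - eps/2 at eps = 1
  expect_equal(D["y", "z"], 3)        # unmodified pair
  expect_equal(D["t", "x"], 2)        # same-side pair

  # eps = 0 leaves the tree metric untouched
  sc0 <- set_epsilon(sc, 0)
  expect_equal(converged_distances(sc0), tree_distances(sc$tree))

  set.seed(31)
  for (sc in sample_scenarios(6, seed = 31)) {
    D <- converged_distances(sc)
    D0 <- tree_distances(sc$tree)
    expect_equal(D, t(D))
    expect_true(all(D <= D0 + 1e-12))
    expect_equal(unname(diag(D)), rep(0, nrow(D)))
    labs <- rownames(D)
    for (i in seq_along(labs)) for (j in seq_along(labs)) {
      if (i >= j) next
      st <- below_status(sc, labs[i], labs[j])
      if (st == "not_below") {
        expect_equal(D[i, j], D0[i, j])
      } else {
        hR <- convergence_stop_height(sc, labs[i], labs[j])
        expect_gte(hR, sc$alpha - 1e-12)
        expect_lte(hR, sc$beta + 1e-12)
        expect_equal(D[i, j], D0[i, j] - 2 * sc$epsilon * (sc$beta - hR))
      }
    }
  }
})

test_that("restriction to three leaves reproduces the dissimilarity exactly", {
  sc <- balanced(1)
  rs <- restrict_scenario(sc, c("x", "y", "t"))
  expect_equal(attr(rs, "gamma"), 1 / 4)
  rs2 <- restrict_scenario(sc, c("x", "y", "z"))
  Y <- c("x", "y", "z")
  expect_equal(converged_distances(rs2)[Y, Y], converged_distances(sc)[Y, Y])

  # no pair of Y below the set: restriction is undefined
  expect_error(restrict_scenario(sc, c("y", "z", "t")), NA)
  sc_small <- set_epsilon(sc, 1 / 2)
  expect_error(restrict_scenario(sc_small, c("t", "x", "t")), "leaves|distinct")

  for (sc in sample_scenarios(12, seed = 41, n_range = 4:7)) {
    De <- converged_distances(sc)
    D0 <- tree_distances(sc$tree)
    for (Y in utils::combn(sc$tree$labels, 3, simplify = FALSE)) {
      if (max(abs(De[Y, Y] - D0[Y, Y])) < 1e-9) {
        expect_error(restrict_scenario(sc, Y), "unneeded")
      } else {
        rs <- restrict_scenario(sc, Y)
        expect_gte(attr(rs, "gamma"), sc$alpha - 1e-12)
        expect_equal(converged_distances(rs)[Y, Y], De[Y, Y],
                     tolerance = 1e-9)
      }
    }
  }
})
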