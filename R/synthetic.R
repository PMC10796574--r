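# Seeded generators for random generic equidistant trees and convergence
# scenarios, plus exact built-in worked examples.  All heights are drawn
# on a dyadic grid (multiples of 2^-16 of the relevant span) so that every
# derived quantity is exactly representable in double precision and the
# strict-inequality verdicts never hinge on rounding.

.dyadic_grid <- 2L^16L

# dyadic draw in (lo, hi) avoiding the values in `avoid`
.draw_height <- function(lo, hi, avoid = numeric(), tol = .tc_tol,
                         tries = 1000L) {
  for (i in seq_len(tries)) {
    k <- sample.int(.dyadic_grid - 1L, 1L)
    x <- lo + (hi - lo) * k / .dyadic_grid
    if (all(abs(x - avoid) > tol)) return(x)
  }
  stop("could not draw a height in (", lo, ", ", hi, ") avoiding ",
       length(avoid), " values")
}

#' Random generic equidistant tree
#'
#' Coalescent-style generator: `n - 1` pairwise-distinct internal-vertex
#' heights are drawn on a dyadic grid in `(0, height)` (the root at
#' `height`), then lineages are merged bottom-up in random pairs.  The
#' result is always a valid generic equidistant tree; output is
#' deterministic for a fixed seed.
#'
#' @param n number of leaves (at least 3); labels are `t1 ... tn`.
#' @param height tree height (root height), default 1.
#' @param seed optional integer seed (`set.seed` is called when given).
#' @return An `equidistant` tree.
#' @examples
#' tr <- random_equidistant_tree(5, seed = 1)
#' tr$generic   # TRUE by construction
#' @export
random_equidistant_tree <- function(n, height = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 3L) stop("need n >= 3")
  if (height <= 0) stop("height must be positive")
  hs <- numeric(0)
  while (length(hs) < n - 2L) {
    x <- .draw_height(0, height, avoid = c(hs, height))
    hs <- c(hs, x)
  }
  hs <- c(sort(hs), height)
  lab <- paste0("t", seq_len(n))
  part <- as.list(lab)
  part_h <- rep(0, n)
  for (h in hs) {
    i <- sample.int(length(part), 2L)
    merged <- sprintf("(%s:%s,%s:%s)",
                      part[[i[1L]]], .fmt_num(h - part_h[i[1L]]),
                      part[[i[2L]]], .fmt_num(h - part_h[i[2L]]))
    part <- c(part[-i], merged)
    part_h <- c(part_h[-i], h)
  }
  read_equidistant(text = paste0(part[[1L]], ";"))
}

# descend from `node` to the child endpoint of the edge crossing height `a`
.descend_to <- function(tree, node, a) {
  w <- node
  while (tree$height[w] > a) {
    ch <- tree$children[[w]]
    w <- if (length(ch) == 1L) ch else ch[sample.int(length(ch), 1L)]
  }
  w
}

.vertex_heights <- function(tree)
  tree$height[seq.int(tree$n + 1L, tree$nnode)]

#' Random convergence scenario on a tree
#'
#' Samples heights `alpha < beta` on the dyadic grid (avoiding all vertex
#' heights), places the top points on two distinct edges crossing `beta`
#' and walks each converging path down to height `alpha`.  A target
#' placement family can be requested; sampling is rejection-based and
#' errors after `max_tries` failures.
#'
#' @param tree a generic `equidistant` tree.
#' @param epsilon convergence strength: a single value, or a range
#'   `c(lo, hi)` to draw from on the dyadic grid (default `c(0, 1)`).
#' @param target placement family: `"unconstrained"`; `"cherry"` (both
#'   paths inside the pendant edges of a cherry); `"sibling_pairs"` (paths
#'   inside two sibling edges below a common non-root vertex, the
#'   confounding family A); `"root_tops"` (top points in the two root
#'   edges, family B); `"pair_below_child"` (one path inside a root edge,
#'   the other inside an edge just below the opposite root child, family
#'   C); `"split_pair"` (one path inside a root edge; on the other side the
#'   top in the root edge and the bottom in an edge below that root child);
#'   `"top_below_child"` (one path inside a root edge; the opposite top
#'   inside an edge joining the other root child to one of its children,
#'   with its bottom strictly below that child).
#' @param seed optional integer seed.
#' @param max_tries rejection bound.
#' @return A `convergence_scenario`.
#' @export
random_scenario <- function(tree, epsilon = c(0, 1),
                            target = c("unconstrained", "cherry",
                                       "sibling_pairs", "root_tops",
                                       "pair_below_child", "split_pair",
                                       "top_below_child"),
                            seed = NULL, max_tries = 1000L) {
  target <- match.arg(target)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(tree, "equidistant"))
  if (!tree$generic) stop("scenario generation requires a generic tree")
  vh <- .vertex_heights(tree)
  eps_of <- function() {
    if (length(epsilon) == 1L) epsilon
    else .draw_height(epsilon[1L], epsilon[2L], avoid = epsilon[1L])
  }
  rc <- tree$children[[tree$root]]

  one_try <- function() {
    if (target == "cherry") {
      chs <- find_cherries(tree)
      ab <- chs[[sample.int(length(chs), 1L)]]
      hp <- tree$height[tree$parent[.leaf_id(tree, ab[1L])]]
      beta <- .draw_height(0, hp, avoid = vh)
      alpha <- .draw_height(0, beta, avoid = c(vh, beta))
      return(convergence_scenario(
        tree,
        r = tree_point(tree, ab[1L], beta),
        s = tree_point(tree, ab[2L], beta),
        r_prime = tree_point(tree, ab[1L], alpha),
        s_prime = tree_point(tree, ab[2L], alpha),
        epsilon = eps_of()))
    }
    if (target == "sibling_pairs") {
      cand <- setdiff(seq.int(tree$n + 1L, tree$nnode), tree$root)
      if (!length(cand)) stop("no non-root internal vertex")
      v <- cand[sample.int(length(cand), 1L)]
      ch <- tree$children[[v]]
      lo <- max(tree$height[ch])
      beta <- .draw_height(lo, tree$height[v], avoid = vh)
      alpha <- .draw_height(lo, beta, avoid = c(vh, beta))
      return(convergence_scenario(
        tree,
        r = tree_point(tree, ch[1L], beta),
        s = tree_point(tree, ch[2L], beta),
        r_prime = tree_point(tree, ch[1L], alpha),
        s_prime = tree_point(tree, ch[2L], alpha),
        epsilon = eps_of()))
    }
    if (target == "root_tops") {
      lo <- max(tree$height[rc])
      beta <- .draw_height(lo, tree$h_root, avoid = vh)
      alpha <- .draw_height(0, beta, avoid = c(vh, beta))
      rp <- .descend_to(tree, rc[1L], alpha)
      sp <- .descend_to(tree, rc[2L], alpha)
      return(convergence_scenario(
        tree,
        r = tree_point(tree, rc[1L], beta),
        s = tree_point(tree, rc[2L], beta),
        r_prime = tree_point(tree, rp, alpha),
        s_prime = tree_point(tree, sp, alpha),
        epsilon = eps_of()))
    }
    if (target %in% c("pair_below_child", "split_pair", "top_below_child")) {
      u <- rc[which.max(tree$height[rc])]
      u2 <- setdiff(rc, u)
      if (u <= tree$n) stop("higher root child is a leaf")
      ch <- tree$children[[u]]
      v1 <- ch[sample.int(length(ch), 1L)]
      if (target == "pair_below_child") {
        lo <- max(tree$height[v1], tree$height[u2])
        beta <- .draw_height(lo, tree$height[u], avoid = vh)
        alpha <- .draw_height(lo, beta, avoid = c(vh, beta))
        return(convergence_scenario(
          tree,
          r = tree_point(tree, v1, beta),
          s = tree_point(tree, u2, beta),
          r_prime = tree_point(tree, v1, alpha),
          s_prime = tree_point(tree, u2, alpha),
          epsilon = eps_of()))
      }
      if (target == "split_pair") {
        # r in the root edge above u, r' one level down in edge (u, v1)
        beta <- .draw_height(tree$height[u], tree$h_root, avoid = vh)
        lo <- max(tree$height[v1], tree$height[u2])
        alpha <- .draw_height(lo, tree$height[u], avoid = c(vh, beta))
        return(convergence_scenario(
          tree,
          r = tree_point(tree, u, beta),
          s = tree_point(tree, u2, beta),
          r_prime = tree_point(tree, v1, alpha),
          s_prime = tree_point(tree, u2, alpha),
          epsilon = eps_of()))
      }
      # top_below_child: r inside edge (u, v1), r' strictly below v1
      if (v1 <= tree$n || tree$height[v1] <= tree$height[u2])
        stop("no room below v1 for the bottom point")
      beta <- .draw_height(max(tree$height[v1], tree$height[u2]),
                           tree$height[u], avoid = vh)
      alpha <- .draw_height(tree$height[u2], tree$height[v1],
                            avoid = c(vh, beta))
      rp <- .descend_to(tree, v1, alpha)
      return(convergence_scenario(
        tree,
        r = tree_point(tree, v1, beta),
        s = tree_point(tree, u2, beta),
        r_prime = tree_point(tree, rp, alpha),
        s_prime = tree_point(tree, u2, alpha),
        epsilon = eps_of()))
    }
    # unconstrained
    beta <- .draw_height(0, tree$h_root, avoid = vh)
    cross <- Filter(function(v) {
      !is.na(tree$parent[v]) && tree$height[v] < beta &&
        tree$height[tree$parent[v]] > beta
    }, seq_len(tree$nnode))
    if (length(cross) < 2L) stop("fewer than two edges cross beta")
    e <- cross[sample.int(length(cross), 2L)]
    alpha <- .draw_height(0, beta, avoid = c(vh, beta))
    rp <- .descend_to(tree, e[1L], alpha)
    sp <- .descend_to(tree, e[2L], alpha)
    convergence_scenario(
      tree,
      r = tree_point(tree, e[1L], beta),
      s = tree_point(tree, e[2L], beta),
      r_prime = tree_point(tree, rp, alpha),
      s_prime = tree_point(tree, sp, alpha),
      epsilon = eps_of())
  }

  for (i in seq_len(max_tries)) {
    sc <- tryCatch(one_try(), error = function(e) NULL)
    if (!is.null(sc)) return(sc)
  }
  stop("could not sample a valid scenario with target '", target,
       "' in ", max_tries, " tries")
}

#' Built-in worked example scenarios
#'
#' Exact reconstructions of the package's two reference scenarios:
#' \describe{
#'   \item{`"balanced_quartet"`}{the balanced tree `((t,x),(y,z))` with
#'     lca heights 1 and 3/2 and root height 2; `alpha = 1/4`,
#'     `beta = 7/4`; top points on the two root edges, bottom points on
#'     the pendant edges of `x` and `y`.  Admissible strengths are
#'     `0 < epsilon < 4/3` (the distance threshold).  Its dissimilarity is
#'     a metric but never a tree metric, and its height is not
#'     identifiable (confounding family B).}
#'   \item{`"caterpillar_quartet"`}{the caterpillar `(((x,z),y),t)` with
#'     lca heights 1 and 2 and root height `2 + delta`; `alpha = 1/2`,
#'     `beta = 3/2`; top point `r` inside the internal edge, `r'` on `x`'s
#'     pendant edge, `s` and `s'` both on `y`'s pendant edge.  Its triplet
#'     threshold is exactly 1 for every `delta > 0` while the sufficient
#'     internal-edge bound degenerates to `delta`, and its height is
#'     identifiable.}
#' }
#'
#' @param name which example.
#' @param epsilon convergence strength; for `"balanced_quartet"` must lie
#'   in `(0, 4/3)`.
#' @param delta root-edge length of the caterpillar example (`> 0`).
#' @return A `convergence_scenario`.
#' @examples
#' sc <- example_scenario("balanced_quartet", epsilon = 1)
#' converged_distances(sc)["x", "y"]   # 1
#' @export
example_scenario <- function(name = c("balanced_quartet",
                                      "caterpillar_quartet"),
                             epsilon, delta = 1/100) {
  name <- match.arg(name)
  if (name == "balanced_quartet") {
    if (epsilon <= 0 || epsilon >= 4/3)
      stop("balanced_quartet requires 0 < epsilon < 4/3")
    tr <- read_equidistant("((t:1,x:1):1,(y:1.5,z:1.5):0.5);")
    return(convergence_scenario(
      tr,
      r = tree_point(tr, c("t", "x"), 7/4),
      s = tree_point(tr, c("y", "z"), 7/4),
      r_prime = tree_point(tr, "x", 1/4),
      s_prime = tree_point(tr, "y", 1/4),
      epsilon = epsilon))
  }
  if (delta <= 0) stop("caterpillar_quartet requires delta > 0")
  if (epsilon < 0) stop("epsilon must be non-negative")
  tr <- read_equidistant(sprintf(
    "(((x:1,z:1):1,y:2):%s,t:%s);", .fmt_num(delta), .fmt_num(2 + delta)))
  convergence_scenario(
    tr,
    r = tree_point(tr, c("x", "z"), 3/2),
    s = tree_point(tr, "y", 3/2),
    r_prime = tree_point(tr, "x", 1/2),
    s_prime = tree_point(tr, "y", 1/2),
    epsilon = epsilon)
}
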