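# Convergence scenarios: a generic equidistant tree, four points
# r, r', s, s' (two converging paths [r,r'] and [s,s'] spanning heights
# beta down to alpha), and a convergence strength epsilon >= 0.

#' Construct and validate a convergence scenario
#'
#' A convergence scenario consists of (1) a *generic* equidistant tree,
#' (2) two top points `r`, `s` at common height `beta` and two bottom
#' points `r_prime` (below `r`) and `s_prime` (below `s`) at common height
#' `alpha`, each strictly inside an edge, with `0 < alpha < beta < h(root)`
#' and `alpha`, `beta` distinct from every vertex height, the two converging
#' paths being disjoint (neither top point above the other), and (3) a
#' convergence strength `epsilon >= 0`.  The model reduces the tree distance
#' of every leaf pair split across the two paths by
#' `2 * epsilon * (beta - h_R(x, y))`, where `h_R` is the height at which
#' the pair's lineages stop tracking the converging paths (see
#' [convergence_stop_height()]).
#'
#' @param tree an `equidistant` tree (generic, at least 3 leaves).
#' @param r,s top points (`tree_point`, see [tree_point()]) at equal height.
#' @param r_prime bottom point below `r`; `s_prime` bottom point below `s`.
#' @param s_prime see `r_prime`.
#' @param epsilon non-negative convergence strength.
#' @param strict internal switch: restricted scenarios produced by
#'   [restrict_scenario()] may legitimately place bottom points at vertex
#'   heights of the reduced tree, which `strict = FALSE` permits.
#' @return An object of class `convergence_scenario` with fields `tree`,
#'   `r`, `s`, `r_prime`, `s_prime`, `alpha`, `beta`, `epsilon`.
#' @examples
#' tr <- read_equidistant("((t:1,x:1):1,(y:1.5,z:1.5):0.5);")
#' sc <- convergence_scenario(tr,
#'   r = tree_point(tr, c("t", "x"), 7/4), s = tree_point(tr, c("y", "z"), 7/4),
#'   r_prime = tree_point(tr, "x", 1/4), s_prime = tree_point(tr, "y", 1/4),
#'   epsilon = 1)
#' @export
convergence_scenario <- function(tree, r, s, r_prime, s_prime, epsilon,
                                 strict = TRUE) {
  stopifnot(inherits(tree, "equidistant"))
  if (tree$n < 3L) stop("scenario requires a tree with at least 3 leaves")
  if (!tree$generic)
    stop("scenario requires a generic tree (pairwise-distinct internal vertex heights)")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
    stop("`epsilon` must be a single non-negative number")
  pts <- list(r = r, s = s, r_prime = r_prime, s_prime = s_prime)
  for (nm in names(pts))
    if (!inherits(pts[[nm]], "tree_point"))
      stop("`", nm, "` must be a tree_point")
  tol <- tree$tol
  beta <- r$height
  alpha <- r_prime$height
  if (abs(s$height - beta) > tol)
    stop("top points r and s must have equal height beta")
  if (abs(s_prime$height - alpha) > tol)
    stop("bottom points r' and s' must have equal height alpha")
  if (!(alpha > tol && beta > alpha + tol && beta < tree$h_root - tol))
    stop("heights must satisfy 0 < alpha < beta < h(root)")
  if (strict) {
    vh <- tree$height[seq.int(tree$n + 1L, tree$nnode)]
    if (any(abs(vh - alpha) <= tol) || any(abs(vh - beta) <= tol))
      stop("alpha and beta must differ from the height of every vertex")
    # points strictly inside their edges
    for (nm in names(pts)) {
      p <- pts[[nm]]
      lo <- tree$height[p$node]; hi <- tree$height[tree$parent[p$node]]
      if (!(p$height > lo + tol && p$height < hi - tol))
        stop("`", nm, "` must lie strictly inside an edge")
    }
  }
  # four pairwise distinct points
  key <- vapply(pts, function(p) paste(p$node, .fmt_num(p$height)), "")
  if (anyDuplicated(key)) stop("the four points of R must be pairwise distinct")
  if (!point_below(tree, r_prime, r))
    stop("r' must be strictly below r")
  if (!point_below(tree, s_prime, s))
    stop("s' must be strictly below s")
  # disjoint converging paths: neither top point above the other
  if (point_below(tree, r, s) || point_below(tree, s, r))
    stop("top points must be incomparable (the converging paths are disjoint)")
  structure(list(tree = tree, r = r, s = s, r_prime = r_prime,
                 s_prime = s_prime, alpha = alpha, beta = beta,
                 epsilon = epsilon), class = "convergence_scenario")
}

#' @export
print.convergence_scenario <- function(x, ...) {
  cat("Convergence scenario on", x$tree$n, "leaves\n")
  cat("  tree:   ", write_newick(x$tree), "\n")
  cat(sprintf("  alpha = %s, beta = %s, epsilon = %s\n",
              .fmt_num(x$alpha), .fmt_num(x$beta), .fmt_num(x$epsilon)))
  cat(sprintf("  r  on edge above-child %d, r' on %d; s on %d, s' on %d\n",
              x$r$node, x$r_prime$node, x$s$node, x$s_prime$node))
  invisible(x)
}

#' Re-evaluate a scenario at a different strength
#'
#' The convergence strength enters the model only through the adjusted
#' dissimilarity, so the same placement can be swept over an epsilon grid.
#'
#' @param scenario a `convergence_scenario`.
#' @param epsilon new non-negative strength.
#' @return The scenario with `epsilon` replaced.
#' @export
set_epsilon <- function(scenario, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
    stop("`epsilon` must be a single non-negative number")
  scenario$epsilon <- epsilon
  scenario
}

#' Least common ancestor of the convergence set
#'
#' The lca of the two top points, always a vertex of the tree.
#'
#' @param scenario a `convergence_scenario`.
#' @return A vertex `tree_point`.
#' @export
scenario_lca <- function(scenario)
  point_lca(scenario$tree, scenario$r, scenario$s)

# which side of R a leaf is under: "r", "s" or NA
.leaf_side <- function(scenario, leaf) {
  tr <- scenario$tree
  if (point_below(tr, leaf, scenario$r)) "r"
  else if (point_below(tr, leaf, scenario$s)) "s"
  else NA_character_
}

#' Classify a leaf pair relative to the convergence set
#'
#' A pair `x`, `y` is *below* the convergence set when one leaf is below
#' each top point, and *strictly below* when additionally each is below the
#' bottom point on its side. Only pairs below the set have their distance
#' modified.
#'
#' @param scenario a `convergence_scenario`.
#' @param x,y distinct leaf labels.
#' @return One of `"not_below"`, `"below"`, `"strictly_below"`, with
#'   attribute `side` naming which of `x`, `y` sits under the top point `r`.
#' @export
below_status <- function(scenario, x, y) {
  if (identical(x, y)) stop("`x` and `y` must be distinct leaves")
  tr <- scenario$tree
  sx <- .leaf_side(scenario, x); sy <- .leaf_side(scenario, y)
  if (is.na(sx) || is.na(sy) || sx == sy)
    return(structure("not_below", side = NA_character_))
  # orient: which leaf is on r's side
  xr <- if (sx == "r") x else y
  ys <- if (sx == "r") y else x
  strict <- point_below(tr, xr, scenario$r_prime) &&
    point_below(tr, ys, scenario$s_prime)
  structure(if (strict) "strictly_below" else "below",
            side = if (sx == "r") "x" else "y")
}

#' Height at which convergence stops acting on a pair
#'
#' For a pair `x`, `y` below the convergence set (with `x` matched to the
#' `r`-side), this is `max{ h(lca(r', x)), h(lca(s', y)) }`: the height at
#' which the last of the two lineages detaches from its converging path.
#' It always lies in `[alpha, beta]`, and the model subtracts
#' `2 * epsilon * (beta - value)` from the pair's tree distance.
#'
#' @param scenario a `convergence_scenario`.
#' @param x,y distinct leaf labels forming a pair below the convergence set.
#' @return A height (length units).
#' @export
convergence_stop_height <- function(scenario, x, y) {
  st <- below_status(scenario, x, y)
  if (st == "not_below")
    stop("pair (", x, ", ", y, ") is not below the convergence set")
  tr <- scenario$tree
  if (attr(st, "side") != "x") { tmp <- x; x <- y; y <- tmp }
  max(point_lca(tr, scenario$r_prime, x)$height,
      point_lca(tr, scenario$s_prime, y)$height)
}

#' Convergence-adjusted dissimilarity matrix
#'
#' Computes `d_eps(x, y) = d_T(x, y) - 2 * epsilon * (beta - h_R(x, y))`
#' for every pair below the convergence set and `d_T(x, y)` otherwise.
#' The result is symmetric with zero diagonal, entrywise at most `d_T`,
#' and may contain negative entries (a dissimilarity map) when `epsilon`
#' exceeds the distance threshold.
#'
#' @param scenario a `convergence_scenario`.
#' @return A labelled symmetric matrix.
#' @seealso [tree_distances()], [distance_threshold()]
#' @export
converged_distances <- function(scenario) {
  tr <- scenario$tree
  D <- tree_distances(tr)
  labs <- tr$labels
  n <- length(labs)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    st <- below_status(scenario, labs[i], labs[j])
    if (st != "not_below") {
      hR <- convergence_stop_height(scenario, labs[i], labs[j])
      D[i, j] <- D[j, i] <-
        D[i, j] - 2 * scenario$epsilon * (scenario$beta - hR)
    }
  }
  D
}

# ---- restriction to a 3-leaf subset ----------------------------------------

#' Restrict a scenario to three leaves
#'
#' Produces the 3-leaf scenario whose adjusted dissimilarity equals the
#' restriction of the full one: the tree is [restrict_tree()] of `Y`, the
#' top points keep their positions (mapped into the reduced tree), and the
#' bottom points are raised to the common height
#' `gamma = max{h_r', h_s', alpha}` where `h_r'`, `h_s'` are the heights at
#' which the upward paths from the original bottom points first meet the
#' reduced tree. Only defined when the restriction differs from the plain
#' tree distance on `Y` (at least two leaves of `Y` below the set).
#'
#' @param scenario a `convergence_scenario`.
#' @param Y three distinct leaf labels.
#' @return A `convergence_scenario` on the 3-leaf tree, with attributes
#'   `gamma` and `case` (a structural code `below-tops/below-bottoms`
#'   recording which leaves of `Y` sit below which points).
#' @export
restrict_scenario <- function(scenario, Y) {
  tr <- scenario$tree
  if (!all(Y %in% tr$labels)) stop("`Y` must be leaves of the scenario tree")
  Q <- restrict_tree(tr, Y)
  DT <- tree_distances(tr)[Y, Y]
  DE <- converged_distances(scenario)[Y, Y]
  if (max(abs(DT - DE)) <= tr$tol)
    stop("restriction unneeded: the adjusted dissimilarity equals the tree ",
         "distance on Y (fewer than two leaves of Y below the convergence set)")

  below_r <- Y[vapply(Y, function(a) point_below(tr, a, scenario$r), TRUE)]
  below_s <- Y[vapply(Y, function(a) point_below(tr, a, scenario$s), TRUE)]

  # u = internal vertex of Q (the cherry of the induced triplet)
  u <- Q$nnode  # tips 1..3, root 4, internal 5 by construction
  hu <- Q$height[u]
  cherry <- Q$labels[Q$children[[u]]]

  place_on_path <- function(leaf, height) {
    # point of Q at `height` on the path from `leaf` to the root
    i <- .leaf_id(Q, leaf)
    if (leaf %in% cherry && abs(height - hu) <= Q$tol)
      return(.vertex_point(Q, u))
    node <- if (leaf %in% cherry && height > hu + Q$tol) u else i
    tree_point(Q, node, height, strict = FALSE)
  }
  place_top <- function(below_set, height) {
    stopifnot(length(below_set) >= 1L)
    place_on_path(below_set[[1L]], height)
  }
  join_height <- function(bottom) {
    min(vapply(Y, function(a) point_lca(tr, bottom, a)$height, 0))
  }
  join_leaf <- function(bottom, below_set) {
    j <- vapply(below_set, function(a) point_lca(tr, bottom, a)$height, 0)
    below_set[[which.min(j)]]
  }

  h_rp <- join_height(scenario$r_prime)
  h_sp <- join_height(scenario$s_prime)
  gamma <- max(h_rp, h_sp, scenario$alpha)

  r_new <- place_top(below_r, scenario$beta)
  s_new <- place_top(below_s, scenario$beta)
  rp_new <- place_on_path(join_leaf(scenario$r_prime, below_r), gamma)
  sp_new <- place_on_path(join_leaf(scenario$s_prime, below_s), gamma)

  out <- convergence_scenario(Q, r_new, s_new, rp_new, sp_new,
                              scenario$epsilon, strict = FALSE)
  attr(out, "gamma") <- gamma
  attr(out, "case") <- paste0(
    "tops:", length(below_r), "|", length(below_s),
    ";bottoms:",
    sum(vapply(Y, function(a) point_below(tr, a, scenario$r_prime), TRUE)),
    "|",
    sum(vapply(Y, function(a) point_below(tr, a, scenario$s_prime), TRUE)))
  out
}
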