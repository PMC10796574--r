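# Topology recovery from dissimilarities via rooted triplets and the
# Build (Aho) algorithm, plus height identifiability: classification of
# the convergence-set placements that confound the tree height, explicit
# confounder constructions, and the half-max height estimator.

#' Rooted triplets read off a dissimilarity matrix
#'
#' For every 3-subset, emits `((a,b),c)` when `D(a,b)` is strictly smaller
#' than both `D(a,c)` and `D(b,c)`; ties emit nothing, so the result may
#' cover fewer than `choose(n,3)` subsets.
#'
#' @param D labelled symmetric matrix.
#' @param tol tie tolerance; differences within `tol` count as ties.
#' @return A `triplet_set` with attribute `provenance = "distance"`.
#' @export
triplets_from_distances <- function(D, tol = .tc_tol) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("`D` must be square")
  if (max(abs(D - t(D))) > tol) stop("`D` must be symmetric")
  if (is.null(rownames(D))) stop("`D` must have row/column labels")
  .triplets_from_lca_heights(D, tol = tol, provenance = "distance")
}

#' Build a rooted tree displaying a set of triplets (Aho's algorithm)
#'
#' Recursive component partition: leaves `a`, `b` are linked for every
#' triplet `((a,b),c)` fully contained in the current leaf set; the
#' connected components become the root's subtrees and the procedure
#' recurses.  A single component on more than one leaf means the triplets
#' are incompatible. A dense consistent triplet set (one triplet per
#' 3-subset) yields the unique binary topology.  Components and children
#' are ordered by smallest contained leaf label, so output is
#' deterministic.
#'
#' @param triplets a `triplet_set` (or data frame with columns `a`, `b`,
#'   `out`).
#' @param labels the full taxon set; defaults to all labels in `triplets`.
#' @return An object of class `recovered_topology`: list with the `newick`
#'   topology string (no branch lengths) and the displayed `triplets`.
#' @export
build_tree <- function(triplets, labels = NULL) {
  if (is.null(labels))
    labels <- sort(unique(c(triplets$a, triplets$b, triplets$out)))
  if (!length(labels)) stop("empty taxon set")
  rec <- function(X) {
    if (length(X) == 1L) return(X)
    idx <- triplets$a %in% X & triplets$b %in% X & triplets$out %in% X
    comp <- stats::setNames(seq_along(X), X)
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    for (k in which(idx)) {
      i <- find(match(triplets$a[k], X)); j <- find(match(triplets$b[k], X))
      if (i != j) comp[max(i, j)] <- min(i, j)
    }
    roots <- vapply(seq_along(X), find, 1L)
    groups <- split(X, roots)
    if (length(groups) == 1L)
      stop("incompatible triplet set: no partition of {",
           paste(X, collapse = ","), "}")
    groups <- groups[order(vapply(groups, min, ""), method = "radix")]
    paste0("(", paste(vapply(groups, rec, ""), collapse = ","), ")")
  }
  nwk <- paste0(if (length(labels) == 1L) labels else rec(sort(labels)), ";")
  structure(list(newick = nwk, triplets = triplets),
            class = "recovered_topology")
}

#' @export
print.recovered_topology <- function(x, ...) {
  cat("Recovered rooted topology:", x$newick, "\n")
  invisible(x)
}

#' Height estimate from a dissimilarity matrix
#'
#' Half the maximum off-diagonal entry.  Equals the true tree height
#' exactly when the scenario's height is identifiable (placement
#' configuration `"none"` under the triplet-respecting-metric hypothesis);
#' on other matrices it is well defined but underestimates the height.
#'
#' @param D labelled symmetric matrix with at least two taxa.
#' @return Half the maximum entry.
#' @export
recover_height <- function(D) {
  if (!is.matrix(D) || nrow(D) < 2L) stop("need a matrix on >= 2 taxa")
  max(D[upper.tri(D)]) / 2
}

#' Convergence-set placements that confound the tree height
#'
#' Classifies the placement of the four convergence points into the three
#' families for which an alternative edge weighting and convergence set
#' (same strength) reproduces the dissimilarity with a different root
#' height:
#' \describe{
#'   \item{`"A"`}{each converging path inside a single edge, the two edges
#'     sharing a non-root vertex (their common parent);}
#'   \item{`"B"`}{the two top points sit one in each root edge (bottom
#'     points anywhere below);}
#'   \item{`"C"`}{one path inside a single root edge, the other inside a
#'     single edge hanging directly below the opposite root child.}
#' }
#' Sibling paths under the root itself fall under `"B"`. `"none"` means no
#' confounder exists and the height is identifiable (given a
#' triplet-respecting metric).
#'
#' @param scenario a `convergence_scenario`.
#' @return One of `"A"`, `"B"`, `"C"`, `"none"`.
#' @export
confounding_configuration <- function(scenario) {
  tr <- scenario$tree
  rc <- tr$children[[tr$root]]
  rn <- scenario$r$node; rpn <- scenario$r_prime$node
  sn <- scenario$s$node; spn <- scenario$s_prime$node
  pr <- rn == rpn; ps <- sn == spn
  if (rn %in% rc && sn %in% rc) return("B")
  if (pr && ps) {
    if (tr$parent[rn] == tr$parent[sn] && tr$parent[rn] != tr$root)
      return("A")
    cfun <- function(n1, n2)
      n1 %in% rc && tr$parent[n2] == setdiff(rc, n1)
    if (cfun(rn, sn) || cfun(sn, rn)) return("C")
  }
  "none"
}

#' Root-relative placement case of the convergence set
#'
#' The complementary positional classification: exactly one of the cases
#' `"a"`-`"e"` holds precisely when the placement is not of the
#' height-confounding families `"B"`/`"C"` of
#' [confounding_configuration()] (the classification is independent of
#' edge weights):
#' \describe{
#'   \item{`"a"`}{one top point in a root edge with its bottom point
#'     strictly below that root child; the other path inside the opposite
#'     root subtree (below the opposite child);}
#'   \item{`"b"`}{one path inside a root edge; the other path strictly
#'     below a grandchild of the root on the opposite side;}
#'   \item{`"c"`}{one path inside a root edge; of the other path the top
#'     point sits in an edge joining the opposite root child to one of its
#'     children, with its bottom point below that child;}
#'   \item{`"d"`}{the top points sit below the two root children (neither
#'     in a root edge);}
#'   \item{`"e"`}{the whole convergence set inside one root subtree
#'     (its lca is not the root).}
#' }
#'
#' @param scenario a `convergence_scenario`.
#' @return One of `"a"`, `"b"`, `"c"`, `"d"`, `"e"`, `"none"`.
#' @export
root_placement_case <- function(scenario) {
  tr <- scenario$tree
  rc <- tr$children[[tr$root]]
  if (scenario_lca(scenario)$node != tr$root) return("e")
  rn <- scenario$r$node; sn <- scenario$s$node
  r_in <- rn %in% rc; s_in <- sn %in% rc
  if (r_in && s_in) return("none")                      # confounding "B"
  if (!r_in && !s_in) return("d")
  # exactly one top in a root edge; orient so it is (t1, b1)
  if (r_in) { t1 <- scenario$r; b1 <- scenario$r_prime
              t2 <- scenario$s; b2 <- scenario$s_prime }
  else      { t1 <- scenario$s; b1 <- scenario$s_prime
              t2 <- scenario$r; b2 <- scenario$r_prime }
  if (b1$node != t1$node) return("a")
  u <- setdiff(rc, t1$node)          # root child above the other path
  if (tr$parent[t2$node] == u) {
    if (b2$node == t2$node) return("none")              # confounding "C"
    return("c")
  }
  "b"
}

# rebuild a tree with edge-length adjustments (named by child node id;
# repeated names accumulate)
.adjust_tree <- function(tree, add) {
  add <- unlist(add)
  agg <- tapply(add, names(add), sum)
  phy <- tree$phy
  for (nm in names(agg)) {
    row <- which(phy$edge[, 2L] == as.integer(nm))
    phy$edge.length[row] <- phy$edge.length[row] + agg[[nm]]
  }
  as_equidistant(phy, tol = tree$tol)
}

#' Construct a height confounder for a non-identifiable scenario
#'
#' For a scenario whose placement falls in family `"A"`, `"B"` or `"C"` of
#' [confounding_configuration()], returns an alternative edge weighting and
#' convergence set (same tree topology, same strength) whose adjusted
#' dissimilarity is entrywise identical while the root height differs by
#' `epsilon * delta`:
#' \describe{
#'   \item{A}{root edges grow by `epsilon*delta`; the two sibling edges
#'     carrying the paths shrink by `epsilon*(beta-alpha)`, their parent
#'     edge grows by the same amount; the new paths (length `delta`) sit in
#'     the two root edges;}
#'   \item{B}{root edges grow by `epsilon*delta`; the top points rise by
#'     `delta` within their root edges, the bottom points stay;}
#'   \item{C}{root edges grow by `epsilon*delta`; the new top points sit at
#'     height `h(u)+delta` in the two root edges (`u` the root child above
#'     the non-root path) and the new bottom points at height
#'     `h(u)-(beta-alpha)`, one in the edge that carried the non-root path
#'     and one in the opposite root edge.}
#' }
#'
#' @param scenario a `convergence_scenario` with confounding placement.
#' @param delta positive drop of the new converging paths; default is a
#'   quarter of the configuration's slack. Must be small enough for the
#'   constructed points to fit their edges.
#' @return A list of class `confounder` with the alternative `scenario`,
#'   the `delta` used, the placement `config` and the new root `height`.
#' @export
construct_confounder <- function(scenario, delta = NULL) {
  cfg <- confounding_configuration(scenario)
  if (cfg == "none")
    stop("height is identifiable for this scenario; no confounder exists")
  tr <- scenario$tree
  eps <- scenario$epsilon
  l <- scenario$beta - scenario$alpha
  rc <- tr$children[[tr$root]]
  h <- tr$h_root

  if (cfg == "A") {
    v <- tr$parent[scenario$r$node]
    c_max <- max(tr$height[rc])
    if (is.null(delta)) delta <- (h - c_max) / 4
    if (eps < 1 && delta * (1 - eps) >= h - c_max)
      stop("`delta` too large for configuration A")
    e_r <- scenario$r$node; e_s <- scenario$s$node
    if (min(tr$edge_len[c(e_r, e_s)]) <= eps * l)
      stop("configuration A construction infeasible: edge shorter than epsilon*(beta-alpha)")
    add <- stats::setNames(
      c(eps * delta, eps * delta, -eps * l, -eps * l, eps * l),
      c(rc, e_r, e_s, v))
    tr2 <- .adjust_tree(tr, as.list(add))
    span_lo <- c_max + delta
    span_hi <- h + eps * delta
    beta2 <- span_lo + (span_hi - span_lo) * 2 / 3
    alpha2 <- beta2 - delta
    sc2 <- convergence_scenario(
      tr2,
      r = tree_point(tr2, rc[1L], beta2),
      s = tree_point(tr2, rc[2L], beta2),
      r_prime = tree_point(tr2, rc[1L], alpha2),
      s_prime = tree_point(tr2, rc[2L], alpha2),
      epsilon = eps)
  } else if (cfg == "B") {
    if (is.null(delta)) delta <- (h - scenario$beta) / 4
    if (eps < 1 && delta * (1 - eps) >= h - scenario$beta)
      stop("`delta` too large for configuration B")
    tr2 <- .adjust_tree(tr, stats::setNames(
      list(eps * delta, eps * delta), rc))
    sc2 <- convergence_scenario(
      tr2,
      r = tree_point(tr2, scenario$r$node, scenario$beta + delta),
      s = tree_point(tr2, scenario$s$node, scenario$beta + delta),
      r_prime = tree_point(tr2, scenario$r_prime$node,
                           scenario$r_prime$height),
      s_prime = tree_point(tr2, scenario$s_prime$node,
                           scenario$s_prime$height),
      epsilon = eps)
  } else { # C
    # orient: (tn, bn) the path inside a non-root edge below root child u
    if (scenario$r$node %in% rc) {
      u2 <- scenario$r$node; tn <- scenario$s$node
    } else {
      u2 <- scenario$s$node; tn <- scenario$r$node
    }
    u <- tr$parent[tn]
    stopifnot(u %in% rc)
    hu <- tr$height[u]
    if (is.null(delta)) delta <- (h - hu) / 4
    if (eps < 1 && delta * (1 - eps) >= h - hu)
      stop("`delta` too large for configuration C")
    tr2 <- .adjust_tree(tr, stats::setNames(
      list(eps * delta, eps * delta), rc))
    beta2 <- hu + delta
    alpha2 <- hu - l
    mk <- function(node, height) tree_point(tr2, node, height, strict = FALSE)
    sc2 <- tryCatch(
      convergence_scenario(
        tr2,
        r = tree_point(tr2, u, beta2),
        s = tree_point(tr2, u2, beta2),
        r_prime = mk(tn, alpha2),
        s_prime = mk(u2, alpha2),
        epsilon = eps),
      error = function(e)
        convergence_scenario(
          tr2,
          r = mk(u, beta2), s = mk(u2, beta2),
          r_prime = mk(tn, alpha2), s_prime = mk(u2, alpha2),
          epsilon = eps, strict = FALSE))
  }
  structure(list(scenario = sc2, delta = delta, config = cfg,
                 height = sc2$tree$h_root),
            class = "confounder")
}

#' @export
print.confounder <- function(x, ...) {
  cat("Height confounder (configuration ", x$config, ", delta = ",
      .fmt_num(x$delta), ")\n", sep = "")
  cat("  alternative root height:", .fmt_num(x$height), "\n")
  invisible(x)
}

#' Decide whether the tree height is identifiable
#'
#' Under the hypothesis that the adjusted dissimilarity is a
#' triplet-respecting metric (verified; an error otherwise), the tree
#' height is identifiable exactly when the convergence-set placement is in
#' no confounding family, in which case it equals half the maximum
#' dissimilarity entry.  When not identifiable, an explicit confounder with
#' a different root height is attached.  A triplet-respecting *tree metric*
#' is never identifiable (its placement is always confounding).
#'
#' @param scenario a `convergence_scenario`.
#' @param delta optional drop for [construct_confounder()].
#' @return An object of class `height_identifiability`: list with
#'   `configuration`, `placement_case`, `identifiable`, `recovered_height`
#'   (when identifiable) and `confounder` (when not).
#' @export
assess_height_identifiability <- function(scenario, delta = NULL) {
  dg <- diagnose(scenario, oracle = FALSE)
  if (!isTRUE(dg$verdicts$is_metric))
    stop("height identifiability is only characterised for scenarios whose ",
         "dissimilarity is a triplet-respecting metric")
  cfg <- confounding_configuration(scenario)
  case <- root_placement_case(scenario)
  identifiable <- cfg == "none"
  out <- list(configuration = cfg, placement_case = case,
              identifiable = identifiable,
              true_height = scenario$tree$h_root,
              recovered_height = NA_real_, confounder = NULL)
  if (identifiable) {
    out$recovered_height <- recover_height(converged_distances(scenario))
  } else {
    out$confounder <- construct_confounder(scenario, delta)
  }
  structure(out, class = "height_identifiability")
}

#' @export
print.height_identifiability <- function(x, ...) {
  cat("Height identifiability: ",
      if (x$identifiable) "identifiable" else "NOT identifiable",
      " (confounding configuration ", x$configuration,
      ", placement case ", x$placement_case, ")\n", sep = "")
  if (x$identifiable)
    cat("  recovered height:", .fmt_num(x$recovered_height),
        "| true height:", .fmt_num(x$true_height), "\n")
  else
    cat("  confounder height:", .fmt_num(x$confounder$height),
        "| true height:", .fmt_num(x$true_height), "\n")
  invisible(x)
}
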