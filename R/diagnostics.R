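# Closed-form thresholds and verdicts for the convergence model's
# characterization results, plus the assembled diagnostic report.  All the
# characterizations are strict-inequality bounds on epsilon; at epsilon
# equal to a threshold the corresponding property fails.

# leaves (labels) below a point
.leaves_below <- function(tree, p) {
  tree$labels[vapply(seq_len(tree$n),
                     function(i) point_below(tree, tree$labels[i], p), TRUE)]
}

#' Supremum of strengths for which the dissimilarity is a distance
#'
#' The adjusted dissimilarity is a distance (positive off-diagonal) if and
#' only if `epsilon < h(lca(R)) / (beta - alpha)`, where `lca(R)` is the
#' least common ancestor of the two top points.
#'
#' @param scenario a `convergence_scenario`.
#' @return The threshold (a positive number).
#' @export
distance_threshold <- function(scenario) {
  scenario_lca(scenario)$height / (scenario$beta - scenario$alpha)
}

#' Is the convergence set confined to a cherry?
#'
#' TRUE when all four points lie in the two pendant edges of a cherry
#' (each converging path inside one pendant edge). Cherry scenarios always
#' yield a triplet-respecting dissimilarity.
#'
#' @param scenario a `convergence_scenario`.
#' @return Logical.
#' @export
is_cherry_scenario <- function(scenario) {
  tr <- scenario$tree
  a <- scenario$r$node; b <- scenario$s$node
  a == scenario$r_prime$node && b == scenario$s_prime$node &&
    a <= tr$n && b <= tr$n && tr$parent[a] == tr$parent[b]
}

# ordered pairs (x, z) with x below one bottom point and z below the other
.strict_pairs <- function(scenario) {
  tr <- scenario$tree
  A <- .leaves_below(tr, scenario$r_prime)
  B <- .leaves_below(tr, scenario$s_prime)
  rbind(expand.grid(x = A, z = B, stringsAsFactors = FALSE),
        expand.grid(x = B, z = A, stringsAsFactors = FALSE))
}

#' Supremum of strengths preserving all rooted triplets
#'
#' For a non-cherry scenario whose dissimilarity is a distance, the
#' triplet set read off the dissimilarity equals the tree's if and only if
#' `epsilon < min (d_T(x,z) - d_T(x,y)) / (2 (beta - alpha))`, the minimum
#' running over ordered pairs `x`, `z` strictly below the convergence set
#' and leaves `y` with `((x,y),z)` an induced triplet.  Cherry scenarios
#' return `Inf` (always triplet respecting), as does an empty minimum.
#'
#' @param scenario a `convergence_scenario`.
#' @return The threshold, possibly `Inf`.
#' @export
triplet_threshold <- function(scenario) {
  if (is_cherry_scenario(scenario)) return(Inf)
  tr <- scenario$tree
  H <- .lca_height_matrix(tr)
  prs <- .strict_pairs(scenario)
  best <- Inf
  for (k in seq_len(nrow(prs))) {
    x <- prs$x[k]; z <- prs$z[k]
    if (x == z) next
    ys <- setdiff(tr$labels, c(x, z))
    ok <- ys[H[x, ys] < H[x, z] - tr$tol]   # ((x,y),z) induced
    if (length(ok)) {
      ratio <- (H[x, z] - max(H[x, ok])) / (scenario$beta - scenario$alpha)
      best <- min(best, ratio)
    }
  }
  best
}

#' Sufficient internal-edge bound for triplet respect
#'
#' `epsilon < min w(e) / (beta - alpha)` over edges `e` not containing a
#' leaf is sufficient (not necessary) for the dissimilarity to be triplet
#' respecting, for non-cherry scenarios.  The bound never exceeds
#' [triplet_threshold()].
#'
#' @param scenario a `convergence_scenario`.
#' @return The bound; `Inf` for cherry scenarios (not applicable).
#' @export
internal_edge_bound <- function(scenario) {
  if (is_cherry_scenario(scenario)) return(Inf)
  tr <- scenario$tree
  internal <- setdiff(seq.int(tr$n + 1L, tr$nnode), tr$root)
  if (!length(internal)) return(Inf)
  min(tr$edge_len[internal]) / (scenario$beta - scenario$alpha)
}

#' Supremum of strengths preserving the triangle inequality
#'
#' For a scenario whose dissimilarity is a triplet-respecting distance, it
#' is a metric if and only if
#' `epsilon < min d_T(x,y) / (2 (min{beta, h(lca(x,y))} - alpha))`, the
#' minimum over ordered pairs `x`, `z` strictly below the convergence set
#' and leaves `y` with `((x,y),z)` induced and `lca(x,y)` not below a
#' bottom point.  An empty minimum yields `Inf`. Every qualifying ratio
#' exceeds 1, so `epsilon <= 1` always gives a metric.
#'
#' @param scenario a `convergence_scenario`.
#' @return The threshold, possibly `Inf`.
#' @export
metric_threshold <- function(scenario) {
  tr <- scenario$tree
  H <- .lca_height_matrix(tr)
  prs <- .strict_pairs(scenario)
  best <- Inf
  for (k in seq_len(nrow(prs))) {
    x <- prs$x[k]; z <- prs$z[k]
    if (x == z) next
    ys <- setdiff(tr$labels, c(x, z))
    ys <- ys[H[x, ys] < H[x, z] - tr$tol]
    for (y in ys) {
      l <- mrca_node(tr, c(x, y))
      if (point_below(tr, .vertex_point(tr, l), scenario$r_prime) ||
          point_below(tr, .vertex_point(tr, l), scenario$s_prime)) next
      denom <- 2 * (min(scenario$beta, H[x, y]) - scenario$alpha)
      best <- min(best, 2 * H[x, y] / denom)
    }
  }
  best
}

#' Positional classification deciding tree-metricity
#'
#' Under the hypothesis that the dissimilarity is a triplet-respecting
#' metric, it is a tree metric if and only if the convergence set sits in
#' precisely one of three edge placements:
#' \describe{
#'   \item{`"a"`}{each converging path inside a single edge, the two edges
#'     sharing a vertex (sibling edges);}
#'   \item{`"b"`}{one path inside a root edge, the other inside a single
#'     edge hanging directly below the opposite child of the root;}
#'   \item{`"c"`}{one path inside a root edge; of the other path, the top
#'     point sits in the opposite root edge and the bottom point in an edge
#'     directly below that root edge's child.}
#' }
#' It is an ultrametric if and only if `"a"` holds.  The classification is
#' purely positional and is returned regardless of the hypothesis; verdicts
#' are only asserted by [diagnose()] when the hypothesis holds.
#'
#' @param scenario a `convergence_scenario`.
#' @return One of `"a"`, `"b"`, `"c"`, `"none"`.
#' @export
tree_metric_configuration <- function(scenario) {
  tr <- scenario$tree
  rc <- tr$children[[tr$root]]
  rn <- scenario$r$node; rpn <- scenario$r_prime$node
  sn <- scenario$s$node; spn <- scenario$s_prime$node
  pr <- rn == rpn   # r-path within a single edge
  ps <- sn == spn
  if (pr && ps && tr$parent[rn] == tr$parent[sn]) return("a")
  other_rc <- function(u) setdiff(rc, u)
  # (b): pair in root edge + pair in edge below the other root child
  bfun <- function(n1, n2)
    n1 %in% rc && tr$parent[n2] == other_rc(n1)
  if (pr && ps && (bfun(rn, sn) || bfun(sn, rn))) return("b")
  # (c): pair in root edge; split pair: top in other root edge, bottom below it
  cfun <- function(pn, top, bot)
    pn %in% rc && top == other_rc(pn) && tr$parent[bot] == top
  if (ps && !pr && cfun(sn, rn, rpn)) return("c")
  if (pr && !ps && cfun(rn, sn, spn)) return("c")
  "none"
}

#' Strength bound completing the tree-metric decision
#'
#' The placement families of [tree_metric_configuration()] are necessary
#' for the (triplet-respecting metric) dissimilarity to be a tree metric,
#' and family `"a"` is sufficient on its own.  In families `"b"` and `"c"`,
#' however, when at least two leaves hang below the bottom point of the
#' path that is *not* confined to a root edge, quadruples mixing two such
#' leaves with a leaf outside that subtree and one from the far side of the
#' root obey the four-point condition only up to an explicit strength
#' bound.  Writing `u` for the root child above that path and `v` for the
#' child endpoint of the bottom point's edge, the dissimilarity is a tree
#' metric iff (non-strictly)
#' \describe{
#'   \item{family `"b"`}{`epsilon <= (h(u) - h(v)) / (beta - alpha)`;}
#'   \item{family `"c"`}{`epsilon <= (h(u) - h(v)) / (h(u) - alpha)`.}
#' }
#' This function returns that bound: `Inf` for family `"a"`, for cherry
#' placements, and for `"b"`/`"c"` with a single leaf below `v` (no
#' constraining quadruple), and `NA` for family `"none"` (never a tree
#' metric). The bound is verified against the brute-force four-point
#' oracle in the package's test suite.
#'
#' @param scenario a `convergence_scenario`.
#' @return A non-negative number, `Inf`, or `NA`.
#' @export
tree_metric_bound <- function(scenario) {
  cfg <- tree_metric_configuration(scenario)
  if (cfg == "none") return(NA_real_)
  if (cfg == "a") return(Inf)
  tr <- scenario$tree
  rc <- tr$children[[tr$root]]
  if (cfg == "b") {
    v <- if (scenario$r$node %in% rc) scenario$s$node else scenario$r$node
    if (v <= tr$n) return(Inf)
    u <- tr$parent[v]
    return((tr$height[u] - tr$height[v]) / (scenario$beta - scenario$alpha))
  }
  # family "c": bottom point of the split pair
  bot <- if (scenario$r$node %in% rc &&
             scenario$r_prime$node != scenario$r$node)
    scenario$r_prime else scenario$s_prime
  v <- bot$node
  if (v <= tr$n) return(Inf)
  u <- tr$parent[v]
  (tr$height[u] - tr$height[v]) / (tr$height[u] - scenario$alpha)
}

#' Definition-level triplet-respect check
#'
#' Extracts the triplet set from the adjusted dissimilarity by the
#' strict-minimum rule and compares it with the tree's induced triplets.
#' Requires the dissimilarity to be a distance. Always agrees with the
#' closed-form [triplet_threshold()] verdict.
#'
#' @param scenario a `convergence_scenario`.
#' @return Logical.
#' @export
is_triplet_respecting <- function(scenario) {
  D <- converged_distances(scenario)
  chk <- check_distance_axioms(D, "distance", tol = scenario$tree$tol)
  if (!chk$ok)
    stop("the adjusted dissimilarity is not a distance (",
         chk$reason, "); triplet respect is undefined")
  got <- triplets_from_distances(D, tol = scenario$tree$tol)
  want <- induced_triplets(scenario$tree)
  .same_triplets(got, want)
}

.same_triplets <- function(a, b) {
  key <- function(t) paste(t$a, t$b, t$out, sep = "\r")
  setequal(key(a), key(b)) && nrow(a) == nrow(b)
}

#' Full diagnostic report for a scenario
#'
#' Evaluates every closed-form threshold and assembles the verdict chain
#' (distance, triplet respecting, metric, tree metric, ultrametric), each
#' strict at its threshold.  Verdicts whose hypotheses fail (e.g.
#' the tree-metric classification when the dissimilarity is not a
#' triplet-respecting metric) are reported as `NA` rather than
#' extrapolated.  Optionally cross-checks each verdict against the
#' brute-force axiom oracles of [check_distance_axioms()] (on by default
#' for trees with at most 12 leaves).
#'
#' @param scenario a `convergence_scenario`.
#' @param oracle run the brute-force oracles (`NULL` = auto: `n <= 12`).
#' @return An object of class `scenario_diagnostics`.
#' @export
diagnose <- function(scenario, oracle = NULL) {
  eps <- scenario$epsilon
  thr_d <- distance_threshold(scenario)
  cherry <- is_cherry_scenario(scenario)
  thr_t <- triplet_threshold(scenario)
  bound <- internal_edge_bound(scenario)
  thr_m <- metric_threshold(scenario)
  cfg <- tree_metric_configuration(scenario)
  tmb <- tree_metric_bound(scenario)

  is_distance <- eps < thr_d
  is_tr <- if (is_distance) (cherry || eps < thr_t) else NA
  is_metric <- if (isTRUE(is_tr)) eps < thr_m else NA
  is_tm <- if (isTRUE(is_metric))
    cfg != "none" && eps <= tmb + scenario$tree$tol else NA
  is_um <- if (isTRUE(is_metric)) cfg == "a" else NA

  if (is.null(oracle)) oracle <- scenario$tree$n <= 12L
  orc <- NULL
  if (oracle) {
    D <- converged_distances(scenario)
    orc <- lapply(
      c(distance = "distance", metric = "metric",
        tree_metric = "tree_metric", ultrametric = "ultrametric"),
      function(l) check_distance_axioms(D, l, tol = scenario$tree$tol))
  }

  structure(list(
    epsilon = eps,
    thresholds = c(distance = thr_d, triplet = thr_t,
                   internal_edge = bound, metric = thr_m,
                   tree_metric = tmb),
    cherry_scenario = cherry,
    configuration = cfg,
    verdicts = list(is_distance = is_distance,
                    is_triplet_respecting = is_tr,
                    is_metric = is_metric,
                    is_tree_metric = is_tm,
                    is_ultrametric = is_um),
    oracle = orc
  ), class = "scenario_diagnostics")
}

.fmt_thr <- function(x) ifelse(is.infinite(x), "inf", .fmt_num(x))

#' @export
print.scenario_diagnostics <- function(x, ...) {
  cat("Convergence-scenario diagnostics (epsilon =",
      .fmt_num(x$epsilon), ")\n")
  th <- x$thresholds
  cat(sprintf("  thresholds: distance < %s | triplet < %s (edge bound %s) | metric < %s\n",
              .fmt_thr(th["distance"]), .fmt_thr(th["triplet"]),
              .fmt_thr(th["internal_edge"]), .fmt_thr(th["metric"])))
  cat("  cherry scenario:", x$cherry_scenario,
      "| placement configuration:", x$configuration, "\n")
  v <- x$verdicts
  cat(sprintf("  verdicts: distance=%s triplet_respecting=%s metric=%s tree_metric=%s ultrametric=%s\n",
              v$is_distance, v$is_triplet_respecting, v$is_metric,
              v$is_tree_metric, v$is_ultrametric))
  if (!is.null(x$oracle)) {
    ok <- vapply(x$oracle, function(o) o$ok, TRUE)
    cat("  oracle:  ", paste(names(ok), ok, sep = "=", collapse = " "), "\n")
    for (nm in names(x$oracle))
      if (!x$oracle[[nm]]$ok)
        cat("    ", nm, "witness:",
            paste(x$oracle[[nm]]$witness, collapse = ","),
            "-", x$oracle[[nm]]$reason, "\n")
  }
  invisible(x)
}
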