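# Comparison tolerance used throughout for float-mode verdicts.  All built-in
# generators draw heights on a dyadic grid, so sums/differences are exact in
# double precision and the tolerance only guards externally supplied data.
.tc_tol <- 1e-9

#' Rooted binary equidistant tree
#'
#' Validates an [ape::phylo] object as a rooted binary equidistant
#' (molecular-clock) tree and caches node heights, parent pointers and
#' subtree intervals used by the scenario machinery.  In an equidistant tree
#' every root-to-leaf path has the same total length; the height `h(v)` of a
#' vertex is the path length from `v` down to any leaf below it, so leaves
#' sit at height 0 and the root at the tree height.
#'
#' A tree is *generic* when no two internal vertices share a height; the
#' convergence model requires a generic tree, but parsing accepts (and
#' flags) non-generic ones.
#'
#' @param phy an object of class `phylo` (rooted, with branch lengths).
#' @param tol absolute tolerance for the equidistance and genericity checks.
#' @return An object of class `equidistant`: a list with the original
#'   `phylo`, leaf `labels`, per-node `height`, `parent`/`children` maps and
#'   a `generic` flag.
#' @seealso [read_equidistant()], [write_newick()], [tree_distances()]
#' @export
as_equidistant <- function(phy, tol = .tc_tol) {
  if (!inherits(phy, "phylo")) stop("`phy` must be an ape 'phylo' object")
  n <- length(phy$tip.label)
  if (n < 2L) stop("tree must have at least 2 leaves")
  if (anyDuplicated(phy$tip.label)) stop("leaf labels must be unique")
  if (is.null(phy$edge.length) || anyNA(phy$edge.length))
    stop("every edge must carry a branch length")
  if (any(phy$edge.length <= 0))
    stop("all edge weights must be strictly positive")
  nnode <- n + phy$Nnode
  root <- n + 1L
  parent <- rep(NA_integer_, nnode)
  edge_len <- rep(NA_real_, nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  edge_len[phy$edge[, 2L]] <- phy$edge.length
  children <- vector("list", nnode)
  for (i in seq_len(nrow(phy$edge)))
    children[[phy$edge[i, 1L]]] <- c(children[[phy$edge[i, 1L]]], phy$edge[i, 2L])
  deg <- lengths(children)
  if (deg[root] != 2L)
    stop("root must have exactly 2 children (found ", deg[root], ")")
  internal <- setdiff(which(deg > 0L), root)
  if (any(deg[internal] != 2L))
    stop("tree must be binary: every internal vertex needs exactly 2 children")

  # depth from root, then height = max depth - depth
  depth <- rep(NA_real_, nnode)
  depth[root] <- 0
  ord <- integer(0)        # preorder
  stack <- root
  tin <- tout <- integer(nnode)
  clock <- 0L
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v > 0L) {
      clock <- clock + 1L
      tin[v] <- clock
      ord <- c(ord, v)
      stack <- c(stack, -v, rev(children[[v]]))
      for (ch in children[[v]]) depth[ch] <- depth[v] + edge_len[ch]
    } else {
      tout[-v] <- clock
    }
  }
  tip_depth <- depth[seq_len(n)]
  h_root <- max(tip_depth)
  if (diff(range(tip_depth)) > tol)
    stop("tree is not equidistant: root-to-leaf path lengths differ (",
         format(min(tip_depth)), " vs ", format(max(tip_depth)), ")")
  height <- h_root - depth
  height[seq_len(n)] <- 0

  int_h <- height[setdiff(which(deg > 0L), integer(0))]
  generic <- all(abs(diff(sort(int_h))) > tol)

  # smallest descendant leaf label per node, for canonical serialization
  min_lab <- character(nnode)
  for (v in rev(ord)) {
    min_lab[v] <- if (deg[v] == 0L) phy$tip.label[v] else
      min(min_lab[children[[v]]])
  }

  structure(list(
    phy = phy, n = n, labels = phy$tip.label, nnode = nnode, root = root,
    parent = parent, children = children, edge_len = edge_len,
    height = height, h_root = h_root, tin = tin, tout = tout,
    min_lab = min_lab, generic = generic, tol = tol
  ), class = "equidistant")
}

#' Read an equidistant tree from Newick
#'
#' Parses rooted Newick text (branch lengths mandatory on every edge) and
#' validates the result as a binary equidistant tree.
#'
#' @param text Newick string.
#' @param file path to a Newick file (alternative to `text`).
#' @param tol comparison tolerance, see [as_equidistant()].
#' @return An `equidistant` tree.
#' @examples
#' tr <- read_equidistant("((t:1,x:1):1,(y:1.5,z:1.5):0.5);")
#' tr$h_root   # 2
#' @export
read_equidistant <- function(text = NULL, file = NULL, tol = .tc_tol) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  phy <- if (!is.null(text)) ape::read.tree(text = text) else
    ape::read.tree(file = file)
  if (is.null(phy)) stop("could not parse Newick input")
  as_equidistant(phy, tol = tol)
}

# canonical child order: by smallest descendant leaf label
.canon_children <- function(tree, v) {
  ch <- tree$children[[v]]
  ch[order(tree$min_lab[ch], method = "radix")]
}

# shortest decimal that round-trips the double exactly (17 significant
# digits always suffice; fewer are used when lossless)
.fmt_num <- function(x) {
  one <- function(v) {
    for (d in c(15L, 16L, 17L)) {
      s <- format(v, digits = d, scientific = FALSE, trim = TRUE)
      if (grepl(".", s, fixed = TRUE)) s <- sub("\\.?0+$", "", s)
      if (as.numeric(s) == v) return(s)
    }
    s
  }
  vapply(x, one, "")
}

#' Serialize an equidistant tree to Newick
#'
#' Deterministic writer: children are emitted in order of their smallest
#' descendant leaf label, so `write_newick(read_equidistant(s))` is a
#' canonical form. Round-trips topology and weights exactly.
#'
#' @param tree an `equidistant` tree.
#' @param weights include branch lengths (default `TRUE`).
#' @return A Newick string terminated by `;`.
#' @export
write_newick <- function(tree, weights = TRUE) {
  rec <- function(v) {
    lab <- if (v <= tree$n) tree$labels[v] else {
      ch <- .canon_children(tree, v)
      paste0("(", paste(vapply(ch, rec, ""), collapse = ","), ")")
    }
    if (weights && !is.na(tree$edge_len[v]))
      paste0(lab, ":", .fmt_num(tree$edge_len[v])) else lab
  }
  paste0(rec(tree$root), ";")
}

#' @export
print.equidistant <- function(x, ...) {
  cat("Equidistant tree on", x$n, "leaves:",
      paste(x$labels, collapse = ", "), "\n")
  cat("  height:", .fmt_num(x$h_root),
      if (x$generic) " (generic)" else " (NOT generic)", "\n")
  cat(" ", write_newick(x), "\n")
  invisible(x)
}

# ---- nodes, ancestry and points --------------------------------------------

.leaf_id <- function(tree, label) {
  i <- match(label, tree$labels)
  if (anyNA(i)) stop("unknown leaf label(s): ",
                     paste(label[is.na(i)], collapse = ", "))
  i
}

.is_ancestor <- function(tree, anc, v) {
  tree$tin[anc] <= tree$tin[v] & tree$tout[anc] >= tree$tin[v]
}

.node_lca <- function(tree, u, v) {
  while (!.is_ancestor(tree, u, v)) u <- tree$parent[u]
  u
}

#' Least common ancestor vertex of a set of leaves
#'
#' @param tree an `equidistant` tree.
#' @param labels character vector of leaf labels (or integer node ids).
#' @return The internal node id of the lca vertex.
#' @export
mrca_node <- function(tree, labels) {
  ids <- if (is.character(labels)) .leaf_id(tree, labels) else as.integer(labels)
  Reduce(function(u, v) .node_lca(tree, u, v), ids)
}

#' A point on an edge of an equidistant tree
#'
#' Addresses a location on the tree, viewed as a continuous object, by the
#' child endpoint of the edge it sits on plus its absolute height above leaf
#' level (heights are globally comparable because the tree is equidistant).
#' A point strictly between the endpoint heights is *inside* the edge;
#' `height` equal to the child's height denotes the vertex itself.
#'
#' @param tree an `equidistant` tree.
#' @param edge the child endpoint of the edge: a leaf label, an internal
#'   node id, or a character vector of two or more leaf labels whose lca
#'   vertex is taken as the child endpoint.
#' @param height height of the point, in branch-length units above leaf
#'   level; must satisfy `h(child) <= height < h(parent)` (strict on both
#'   sides for a point inside the edge).
#' @param strict require the point to be strictly inside the edge
#'   (default `TRUE`); with `FALSE`, `height == h(child)` gives the vertex.
#' @return An object of class `tree_point` with fields `node` and `height`.
#' @examples
#' tr <- read_equidistant("((t:1,x:1):1,(y:1.5,z:1.5):0.5);")
#' tree_point(tr, "x", 0.25)               # on x's pendant edge
#' tree_point(tr, c("t", "x"), 1.75)       # on the edge above lca(t, x)
#' @export
tree_point <- function(tree, edge, height, strict = TRUE) {
  node <- if (is.character(edge)) {
    if (length(edge) == 1L) .leaf_id(tree, edge) else mrca_node(tree, edge)
  } else as.integer(edge)
  if (node < 1L || node > tree$nnode) stop("edge child id out of range")
  if (node == tree$root)
    stop("the root has no edge above it; pick a non-root child endpoint")
  lo <- tree$height[node]
  hi <- tree$height[tree$parent[node]]
  tol <- tree$tol
  if (strict) {
    if (!(height > lo + tol && height < hi - tol))
      stop(sprintf("point height %s is not strictly inside edge (%s, %s)",
                   .fmt_num(height), .fmt_num(lo), .fmt_num(hi)))
  } else {
    if (height < lo - tol || height > hi - tol)
      stop("point height outside the edge span")
  }
  structure(list(node = node, height = height), class = "tree_point")
}

# vertex as a point
.vertex_point <- function(tree, v)
  structure(list(node = as.integer(v), height = tree$height[v]),
            class = "tree_point")

.as_point <- function(tree, p) {
  if (inherits(p, "tree_point")) return(p)
  if (is.character(p)) return(.vertex_point(tree, .leaf_id(tree, p)))
  .vertex_point(tree, as.integer(p))
}

#' @export
print.tree_point <- function(x, ...) {
  cat(sprintf("<tree point: edge child %d, height %s>\n",
              x$node, .fmt_num(x$height)))
  invisible(x)
}

#' Is one point below another?
#'
#' `b` is below `a` when the (continuous) path from the root to `b` passes
#' through `a`; every point is below itself.
#'
#' @param tree an `equidistant` tree.
#' @param b,a points (`tree_point`), leaf labels or vertex ids.
#' @return Logical.
#' @export
point_below <- function(tree, b, a) {
  b <- .as_point(tree, b); a <- .as_point(tree, a)
  if (!.is_ancestor(tree, a$node, b$node)) return(FALSE)
  if (b$node == a$node) return(b$height <= a$height + tree$tol)
  TRUE
}

#' Least common ancestor of two points
#'
#' The lowest point of the tree lying above both arguments; `lca(a, a) = a`.
#' When neither point is below the other this is always a vertex.
#'
#' @inheritParams point_below
#' @param a,b points, leaf labels or vertex ids.
#' @return A `tree_point` (possibly a vertex point).
#' @export
point_lca <- function(tree, a, b) {
  a <- .as_point(tree, a); b <- .as_point(tree, b)
  if (point_below(tree, b, a)) return(a)
  if (point_below(tree, a, b)) return(b)
  .vertex_point(tree, .node_lca(tree, a$node, b$node))
}

#' Ancestry relation and lca of two locations
#'
#' @inheritParams point_lca
#' @return A list with `is_below` (is `b` below `a`?), the `lca` point and
#'   its `lca_height`.
#' @export
point_ancestry <- function(tree, a, b) {
  l <- point_lca(tree, a, b)
  list(is_below = point_below(tree, b, a), lca = l, lca_height = l$height)
}

# ---- induced distances, triplets, cherries ---------------------------------

# matrix of lca heights over all leaf pairs
.lca_height_matrix <- function(tree) {
  n <- tree$n
  H <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    h <- tree$height[.node_lca(tree, i, j)]
    H[i, j] <- H[j, i] <- h
  }
  H
}

#' Path-length distances induced by an equidistant tree
#'
#' For leaves of an equidistant tree the path length satisfies
#' `d_T(x, y) = 2 h(lca(x, y))`, an ultrametric.
#'
#' @param tree an `equidistant` tree.
#' @return A symmetric labelled matrix with zero diagonal.
#' @export
tree_distances <- function(tree) 2 * .lca_height_matrix(tree)

#' Rooted triplets induced by a tree
#'
#' Every 3-subset of leaves of a binary tree induces a rooted triplet
#' `((a, b), c)`: the pair whose lca is strictly lowest goes together. The
#' full set of `choose(n, 3)` triplets determines the topology.
#'
#' @param tree an `equidistant` tree with at least 3 leaves.
#' @return A `triplet_set`: data frame with columns `a`, `b` (the cherry
#'   pair, sorted) and `out` (the outgroup leaf), with attribute
#'   `provenance = "tree"`.
#' @export
induced_triplets <- function(tree) {
  if (tree$n < 3L) stop("need at least 3 leaves to induce triplets")
  H <- .lca_height_matrix(tree)
  .triplets_from_lca_heights(H, tol = tree$tol, provenance = "tree")
}

# shared core: emit ((a,b),c) iff value(a,b) strictly below the other two
.triplets_from_lca_heights <- function(H, tol, provenance) {
  labs <- rownames(H)
  combs <- utils::combn(labs, 3L)
  res <- vector("list", ncol(combs))
  k <- 0L
  for (j in seq_len(ncol(combs))) {
    tri <- combs[, j]
    v <- c(H[tri[1L], tri[2L]], H[tri[1L], tri[3L]], H[tri[2L], tri[3L]])
    pairs <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
    i_min <- which.min(v)
    others <- v[-i_min]
    if (all(v[i_min] < others - tol)) {
      ab <- sort(tri[pairs[i_min, ]])
      k <- k + 1L
      res[[k]] <- data.frame(a = ab[1L], b = ab[2L],
                             out = setdiff(tri, ab), stringsAsFactors = FALSE)
    }
  }
  out <- if (k) do.call(rbind, res[seq_len(k)]) else
    data.frame(a = character(), b = character(), out = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$a, out$b, out$out, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("triplet_set", "data.frame"),
            provenance = provenance)
}

#' @export
print.triplet_set <- function(x, ...) {
  cat("Triplet set (", nrow(x), " triplets, from ",
      attr(x, "provenance"), "):\n", sep = "")
  if (nrow(x))
    cat(paste0("  ((", x$a, ",", x$b, "),", x$out, ")", collapse = "\n"), "\n")
  invisible(x)
}

#' Cherries of a tree
#'
#' A cherry is a pair of leaves adjacent to a common vertex. Every binary
#' tree has at least one.
#'
#' @param tree an `equidistant` tree.
#' @return A list of sorted 2-element character vectors of leaf labels.
#' @export
find_cherries <- function(tree) {
  out <- list()
  for (v in seq.int(tree$n + 1L, tree$nnode)) {
    ch <- tree$children[[v]]
    if (all(ch <= tree$n))
      out[[length(out) + 1L]] <- sort(tree$labels[ch])
  }
  out[order(vapply(out, `[`, "", 1L), method = "radix")]
}

#' Weighted restriction of a tree to three leaves
#'
#' Returns the 3-leaf equidistant tree spanned by `Y`, with the edge
#' weighting induced by the original tree (degree-2 vertices suppressed):
#' the cherry pair of the induced triplet sits below an internal vertex at
#' the height of their lca, the root sits at the height of `lca(Y)`, and
#' all pairwise path lengths on `Y` are preserved.
#'
#' @param tree an `equidistant` tree.
#' @param Y character vector of exactly three leaf labels.
#' @return An `equidistant` tree on `Y`.
#' @export
restrict_tree <- function(tree, Y) {
  if (length(Y) != 3L || anyDuplicated(Y))
    stop("`Y` must be three distinct leaf labels")
  ids <- .leaf_id(tree, Y)
  H <- outer(seq_along(ids), seq_along(ids), Vectorize(function(i, j)
    if (i == j) 0 else tree$height[.node_lca(tree, ids[i], ids[j])]))
  pairs <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  vals <- apply(pairs, 1L, function(p) H[p[1L], p[2L]])
  i_min <- which.min(vals)
  xy <- Y[pairs[i_min, ]]
  z <- setdiff(Y, xy)
  m <- vals[i_min]
  h <- max(vals)   # height of lca(Y)
  phy <- structure(list(
    edge = matrix(c(4L, 5L, 5L, 4L, 5L, 1L, 2L, 3L), ncol = 2L),
    tip.label = c(xy, z),
    edge.length = c(h - m, m, m, h),
    Nnode = 2L
  ), class = "phylo")
  as_equidistant(phy, tol = tree$tol)
}

# canonical topology string (no branch lengths) for comparisons
#' Canonical topology string of a tree
#'
#' Newick without branch lengths, children sorted by smallest descendant
#' leaf label; equal strings iff equal rooted topologies.
#'
#' @param tree an `equidistant` tree.
#' @return A character scalar.
#' @export
topology_newick <- function(tree) write_newick(tree, weights = FALSE)
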