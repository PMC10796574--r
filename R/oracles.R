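# Brute-force axiom oracles for dissimilarity matrices.  These are the
# definition-level checks (positivity, all triangle inequalities, the
# four-point condition over all quadruples, the ultrametric three-point
# condition) used to cross-validate every closed-form verdict.

#' Brute-force check of distance axioms
#'
#' Checks a labelled symmetric matrix against one of four nested axiom
#' levels by exhaustive enumeration:
#' \describe{
#'   \item{`distance`}{symmetry, zero diagonal, strictly positive
#'     off-diagonal entries;}
#'   \item{`metric`}{additionally every triangle inequality
#'     `d(x,y) <= d(x,z) + d(z,y)`;}
#'   \item{`tree_metric`}{additionally the four-point condition: for all
#'     quadruples, `d(x,y)+d(u,v) <= max{d(x,u)+d(y,v), d(x,v)+d(y,u)}`;}
#'   \item{`ultrametric`}{additionally `d(x,y) <= max{d(x,z), d(y,z)}` for
#'     all triples (the two largest of the three values are equal).}
#' }
#' Each level implies the previous ones and all are checked cumulatively.
#'
#' @param D labelled symmetric numeric matrix.
#' @param level axiom level to verify.
#' @param tol comparison tolerance for the inequalities.
#' @return A list with `ok` (logical) and, on failure, `witness` (the
#'   labels of the offending tuple) and `reason`.
#' @export
check_distance_axioms <- function(D,
                                  level = c("distance", "metric",
                                            "tree_metric", "ultrametric"),
                                  tol = .tc_tol) {
  level <- match.arg(level)
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("`D` must be a square matrix")
  if (max(abs(D - t(D))) > tol) stop("`D` must be symmetric")
  labs <- rownames(D)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(D)))
  n <- nrow(D)
  fail <- function(witness, reason)
    list(ok = FALSE, witness = labs[witness], reason = reason)

  if (max(abs(diag(D))) > tol)
    return(fail(which.max(abs(diag(D))), "nonzero diagonal"))
  off <- D; diag(off) <- 1
  if (any(off <= tol)) {
    w <- which(off <= tol, arr.ind = TRUE)[1L, ]
    return(fail(w, "non-positive off-diagonal entry"))
  }
  if (level == "distance") return(list(ok = TRUE))

  tri <- if (n >= 3L) utils::combn(n, 3L) else matrix(integer(), 3L, 0L)
  for (j in seq_len(ncol(tri))) {
    i3 <- tri[, j]
    a <- D[i3[1L], i3[2L]]; b <- D[i3[1L], i3[3L]]; c <- D[i3[2L], i3[3L]]
    if (a > b + c + tol || b > a + c + tol || c > a + b + tol)
      return(fail(i3, "triangle inequality violated"))
  }
  if (level == "metric") return(list(ok = TRUE))

  if (level == "tree_metric") {
    quad <- if (n >= 4L) utils::combn(n, 4L) else matrix(integer(), 4L, 0L)
    for (j in seq_len(ncol(quad))) {
      q <- quad[, j]
      s1 <- D[q[1L], q[2L]] + D[q[3L], q[4L]]
      s2 <- D[q[1L], q[3L]] + D[q[2L], q[4L]]
      s3 <- D[q[1L], q[4L]] + D[q[2L], q[3L]]
      s <- sort(c(s1, s2, s3), decreasing = TRUE)
      if (s[1L] > s[2L] + tol)
        return(fail(q, "four-point condition violated (maximum sum attained once)"))
    }
    return(list(ok = TRUE))
  }

  # ultrametric: two largest of every triple equal
  for (j in seq_len(ncol(tri))) {
    i3 <- tri[, j]
    v <- sort(c(D[i3[1L], i3[2L]], D[i3[1L], i3[3L]], D[i3[2L], i3[3L]]),
              decreasing = TRUE)
    if (v[1L] > v[2L] + tol)
      return(fail(i3, "ultrametric condition violated"))
  }
  list(ok = TRUE)
}
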