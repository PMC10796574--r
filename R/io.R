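# Readers and writers: square PHYLIP / TSV distance matrices and
# JSON scenario configuration files.

#' Read a labelled distance matrix
#'
#' Square PHYLIP (taxon-count line, then one row per taxon: label followed
#' by n values) or tab-separated with a header row and a label column.
#' Symmetry is validated.
#'
#' @param path file path.
#' @param format `"phylip"` or `"tsv"`.
#' @param tol asymmetry tolerance.
#' @return A labelled symmetric matrix.
#' @export
read_distance_matrix <- function(path, format = c("phylip", "tsv"),
                                 tol = .tc_tol) {
  format <- match.arg(format)
  if (format == "phylip") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    n <- as.integer(trimws(lines[1L]))
    if (is.na(n) || length(lines) != n + 1L)
      stop("malformed PHYLIP matrix: expected a count line plus ", n, " rows")
    labs <- character(n)
    D <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) {
      parts <- strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1L]]
      if (length(parts) != n + 1L)
        stop("malformed PHYLIP row ", i, ": expected label + ", n, " values")
      labs[i] <- parts[1L]
      D[i, ] <- as.numeric(parts[-1L])
    }
    dimnames(D) <- list(labs, labs)
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            row.names = 1L, check.names = FALSE)
    D <- as.matrix(df)
    if (nrow(D) != ncol(D) || !identical(rownames(D), colnames(D)))
      stop("malformed TSV matrix: row and column labels must match")
  }
  if (anyNA(D)) stop("matrix contains non-numeric entries")
  asym <- abs(D - t(D))
  if (max(asym) > tol) {
    w <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    stop(sprintf("matrix is asymmetric at (%s, %s): %s vs %s",
                 rownames(D)[w[1L]], colnames(D)[w[2L]],
                 .fmt_num(D[w[1L], w[2L]]), .fmt_num(D[w[2L], w[1L]])))
  }
  D
}

#' Write a labelled distance matrix
#'
#' @param D labelled symmetric matrix.
#' @param path output file path.
#' @param format `"phylip"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path, format = c("phylip", "tsv")) {
  format <- match.arg(format)
  labs <- rownames(D)
  vals <- apply(D, 1L, function(r) paste(vapply(r, .fmt_num, ""),
                                         collapse = "\t"))
  if (format == "phylip") {
    writeLines(c(as.character(nrow(D)), paste(labs, vals, sep = "\t")), path)
  } else {
    writeLines(c(paste(c("", labs), collapse = "\t"),
                 paste(labs, vals, sep = "\t")), path)
  }
  invisible(path)
}

# point -> serializable form: edge child as leaf label set (for leaves and
# internal vertices via their descendant cherry) plus height
.point_to_config <- function(tree, p) {
  node <- p$node
  edge <- if (node <= tree$n) tree$labels[node] else {
    # identify an internal vertex by the leaves of its two child subtrees
    ch <- tree$children[[node]]
    vapply(ch, function(c0) {
      min(tree$labels[.is_ancestor(tree, c0, seq_len(tree$n))])
    }, "")
  }
  list(edge = as.list(edge), height = p$height)
}

.point_from_config <- function(tree, cfg) {
  tree_point(tree, unlist(cfg$edge), as.numeric(cfg$height), strict = FALSE)
}

#' Write a scenario configuration file (JSON)
#'
#' Serializes the tree (Newick), the four points (each as the edge's child
#' endpoint, identified by one leaf label or by a pair of leaf labels whose
#' lca is the endpoint, plus its height), `alpha`, `beta` and `epsilon`.
#'
#' @param scenario a `convergence_scenario`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  tr <- scenario$tree
  cfg <- list(
    tree = write_newick(tr),
    r = .point_to_config(tr, scenario$r),
    s = .point_to_config(tr, scenario$s),
    r_prime = .point_to_config(tr, scenario$r_prime),
    s_prime = .point_to_config(tr, scenario$s_prime),
    alpha = scenario$alpha, beta = scenario$beta,
    epsilon = scenario$epsilon)
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a scenario configuration file (JSON)
#'
#' @param path path to a file written by [write_scenario()] (or following
#'   the same schema).
#' @param epsilon optional override of the stored strength.
#' @return A `convergence_scenario`.
#' @export
read_scenario <- function(path, epsilon = NULL) {
  cfg <- jsonlite::fromJSON(readLines(path), simplifyVector = FALSE)
  tr <- read_equidistant(text = cfg$tree)
  convergence_scenario(
    tr,
    r = .point_from_config(tr, cfg$r),
    s = .point_from_config(tr, cfg$s),
    r_prime = .point_from_config(tr, cfg$r_prime),
    s_prime = .point_from_config(tr, cfg$s_prime),
    epsilon = if (is.null(epsilon)) as.numeric(cfg$epsilon) else epsilon)
}
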