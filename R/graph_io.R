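# Graph container and edge-list I/O.
#
# All matrices in the package use a stable internal 1-based index; every
# user-facing result is keyed by the original node labels.  The adjacency
# matrix is always simple (0/1, zero diagonal): self-loops are a conceptual
# device of the walk and are never stored.

#' Construct a network from an edge matrix of node labels
#'
#' Internal constructor shared by all ingestion paths.  Duplicate edges
#' (in either orientation) and self-loops are dropped.
#'
#' @param edge_labels two-column character matrix, one edge per row; may have
#'   zero rows.
#' @param labels optional character vector fixing the label universe and its
#'   order; defaults to first-appearance order in `edge_labels`.
#' @return An object of class `ioqw_graph`: a list with elements `labels`,
#'   `N`, `M`, `adj` (dense 0/1 adjacency with label dimnames), `deg`
#'   (named integer degrees) and `ig` (the underlying [igraph] graph).
#' @keywords internal
new_ioqw_graph <- function(edge_labels, labels = NULL) {
  stopifnot(is.matrix(edge_labels) || nrow0(edge_labels))
  edge_labels <- matrix(as.character(edge_labels), ncol = 2)
  if (is.null(labels)) {
    labels <- unique(as.vector(t(edge_labels)))
  }
  n <- length(labels)
  if (n == 0L) stop("graph has no nodes")
  idx <- stats::setNames(seq_len(n), labels)
  ei <- matrix(idx[as.vector(edge_labels)], ncol = 2)
  # drop self-loops and duplicates (unordered)
  keep <- ei[, 1] != ei[, 2]
  ei <- ei[keep, , drop = FALSE]
  key <- paste(pmin(ei[, 1], ei[, 2]), pmax(ei[, 1], ei[, 2]))
  ei <- ei[!duplicated(key), , drop = FALSE]
  ig <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(ig)$name <- labels
  if (nrow(ei) > 0) ig <- igraph::add_edges(ig, t(ei))
  adj <- matrix(0, n, n, dimnames = list(labels, labels))
  if (nrow(ei) > 0) {
    adj[ei] <- 1
    adj[ei[, c(2, 1), drop = FALSE]] <- 1
  }
  structure(
    list(labels = labels, N = n, M = nrow(ei), adj = adj,
         deg = stats::setNames(as.integer(rowSums(adj)), labels), ig = ig),
    class = "ioqw_graph"
  )
}

nrow0 <- function(x) is.matrix(x) && nrow(x) == 0

#' @export
print.ioqw_graph <- function(x, ...) {
  cat(sprintf("ioqw_graph: %d nodes, %d edges\n", x$N, x$M))
  invisible(x)
}

#' Read an undirected graph from an edge-list
#'
#' Each non-comment, non-blank line must contain exactly two node labels.
#' The delimiter is auto-detected (comma if present, otherwise any
#' whitespace) unless given.  Edge `(a,b)` and `(b,a)` are the same edge;
#' duplicates and self-loops are dropped with a warning.
#'
#' @param source path to a file, or a character vector of lines (a string
#'   containing newlines is split into lines).
#' @param delimiter single delimiter character, or `NULL` to auto-detect.
#' @param comment_prefixes lines starting with any of these are ignored.
#' @return An `ioqw_graph` with labels in first-appearance order.
#' @examples
#' g <- read_edge_list(c("1 2", "2 3"))
#' g$M  # 2
#' @export
read_edge_list <- function(source, delimiter = NULL,
                           comment_prefixes = c("#", "%")) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(as.character(source), "\n", fixed = TRUE))
  }
  lines <- trimws(lines)
  is_comment <- rep(FALSE, length(lines))
  for (p in comment_prefixes) {
    is_comment <- is_comment | startsWith(lines, p)
  }
  keep <- which(!is_comment & nzchar(lines))
  if (length(keep) == 0) stop("empty edge-list input")
  pairs <- matrix(NA_character_, length(keep), 2)
  for (i in seq_along(keep)) {
    ln <- lines[keep[i]]
    sep <- delimiter
    if (is.null(sep)) sep <- if (grepl(",", ln, fixed = TRUE)) "," else "[[:space:]]+"
    toks <- strsplit(ln, sep)[[1]]
    toks <- trimws(toks[nzchar(trimws(toks))])
    if (length(toks) != 2) {
      stop(sprintf("malformed edge-list line %d: %s", keep[i], ln))
    }
    pairs[i, ] <- toks
  }
  n_loops <- sum(pairs[, 1] == pairs[, 2])
  key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  n_dup <- sum(duplicated(key) & pairs[, 1] != pairs[, 2])
  if (n_loops > 0) warning(sprintf("dropped %d self-loop edge(s)", n_loops))
  if (n_dup > 0) warning(sprintf("dropped %d duplicate edge(s)", n_dup))
  new_ioqw_graph(pairs)
}

#' Write a graph as a canonical tab-separated edge list
#'
#' One edge per line as `label1<TAB>label2`, pairs oriented and sorted
#' lexicographically so the output is canonical.
#'
#' @param g an `ioqw_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "ioqw_graph"))
  el <- igraph::as_edgelist(g$ig)
  a <- pmin(el[, 1], el[, 2])
  b <- pmax(el[, 1], el[, 2])
  lines <- paste(a, b, sep = "\t")
  writeLines(sort(lines), path)
  invisible(path)
}

#' All-pairs shortest-path lengths
#'
#' Breadth-first search from every node (via igraph), `O(N * M)` total.
#' Pairs in different components get `Inf`.
#'
#' @param g an `ioqw_graph`.
#' @return An `N x N` numeric matrix with label dimnames; `d[j, j] = 0`,
#'   `d[j, k] = 1` iff `(j, k)` is an edge, `Inf` for unreachable pairs.
#' @export
all_pairs_shortest_path <- function(g) {
  stopifnot(inherits(g, "ioqw_graph"))
  d <- igraph::distances(g$ig, algorithm = "unweighted")
  dimnames(d) <- list(g$labels, g$labels)
  d
}

#' Summary statistics of a network
#'
#' Mean degree `<k> = 2M/N`, second moment `<k^2> = mean(deg^2)`, maximum
#' degree, and the diameter of the largest connected component.
#'
#' @param g an `ioqw_graph`.
#' @return A list of class `graph_stats` with elements `N`, `M`,
#'   `mean_degree`, `second_moment`, `max_degree`, `diameter`.
#' @examples
#' s <- graph_stats(load_fixture("star", n = 10))
#' s$mean_degree   # 1.8
#' s$second_moment # 9
#' @export
graph_stats <- function(g) {
  stopifnot(inherits(g, "ioqw_graph"))
  if (g$N == 0) stop("graph has no nodes")
  comp <- igraph::components(g$ig)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g$ig, which(comp$membership == big))
  structure(
    list(N = g$N, M = g$M,
         mean_degree = 2 * g$M / g$N,
         second_moment = mean(as.numeric(g$deg)^2),
         max_degree = max(as.integer(g$deg), 0L),
         diameter = igraph::diameter(sub, unconnected = FALSE)),
    class = "graph_stats"
  )
}

#' @export
print.graph_stats <- function(x, ...) {
  cat(sprintf(
    "N=%d M=%d <k>=%.3f <k^2>=%.3f dmax=%d D=%g\n",
    x$N, x$M, x$mean_degree, x$second_moment, x$max_degree, x$diameter))
  invisible(x)
}

#' Generate a random graph
#'
#' Erdos-Renyi `G(n, p)` or Barabasi-Albert preferential attachment with
#' `m` edges per new vertex (always connected).  Reproducible for a fixed
#' seed; the global RNG state is restored on exit.
#'
#' @param model `"er"` or `"ba"`.
#' @param n number of nodes (>= 2).
#' @param p edge probability for `"er"` (in `[0, 1]`).
#' @param m edges added per step for `"ba"`.
#' @param seed integer seed.
#' @return An `ioqw_graph` with labels `"1" ... "n"`.
#' @export
generate_random <- function(model = c("er", "ba"), n, p = NULL, m = NULL,
                            seed = 1L) {
  model <- match.arg(model)
  if (n < 2) stop("n must be at least 2")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  if (model == "er") {
    if (is.null(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
    ig <- igraph::sample_gnp(n, p)
  } else {
    if (is.null(m) || m < 1) stop("m must be a positive integer")
    ig <- igraph::sample_pa(n, m = m, directed = FALSE)
  }
  el <- igraph::as_edgelist(ig)
  new_ioqw_graph(matrix(as.character(el), ncol = 2),
                 labels = as.character(seq_len(n)))
}
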