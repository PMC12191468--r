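# Classical centrality baselines.

#' Degree centrality
#'
#' @param g an `ioqw_graph`.
#' @return An `ioqw_scores` object with `score(j) = deg(j)`.
#' @export
degree_centrality <- function(g) {
  stopifnot(inherits(g, "ioqw_graph"))
  new_scores(stats::setNames(as.numeric(g$deg), g$labels), method = "degree")
}

#' Betweenness centrality
#'
#' Unnormalised shortest-path betweenness for undirected graphs (each
#' unordered pair counted once), computed with igraph's Brandes
#' implementation.
#'
#' @param g an `ioqw_graph`.
#' @return An `ioqw_scores` object.
#' @export
betweenness_centrality <- function(g) {
  stopifnot(inherits(g, "ioqw_graph"))
  b <- igraph::betweenness(g$ig, directed = FALSE, normalized = FALSE)
  new_scores(stats::setNames(as.numeric(b), g$labels), method = "betweenness")
}

#' PageRank by power iteration
#'
#' Power iteration on the column-stochastic transition matrix of the
#' undirected graph with uniform teleportation.  Isolated (dangling) nodes
#' redistribute their mass uniformly.  Convergence is declared when the L1
#' change of the score vector drops below `tol`.
#'
#' @param g an `ioqw_graph`.
#' @param damping damping factor in `(0, 1)`; default 0.85 (pinned: this
#'   value reproduces the standard karate-club baseline ranking).
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap; exceeding it is an error.
#' @return An `ioqw_scores` object; scores sum to 1.
#' @examples
#' pr <- pagerank(load_fixture("karate"))
#' pr$ranking[1:2]  # "34" "1"
#' @export
pagerank <- function(g, damping = 0.85, tol = 1e-10, max_iter = 1000) {
  stopifnot(inherits(g, "ioqw_graph"))
  if (damping <= 0 || damping >= 1) stop("damping must lie in (0, 1)")
  n <- g$N
  deg <- as.numeric(g$deg)
  dangling <- deg == 0
  # column-stochastic transition: column j spreads to j's neighbours
  P <- t(g$adj / ifelse(deg > 0, deg, 1))
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    x_new <- damping * (as.vector(P %*% x) + sum(x[dangling]) / n) +
      (1 - damping) / n
    if (sum(abs(x_new - x)) < tol) {
      return(new_scores(stats::setNames(x_new, g$labels),
                        method = "pagerank", damping = damping))
    }
    x <- x_new
  }
  stop(sprintf("pagerank did not converge in %d iterations", max_iter))
}
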