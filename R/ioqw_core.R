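# The IOQW score: coin, shift, evolution, measurement, ranking.
#
# State vectors have length 2N in coin-major order: entries 1..N are the
# "stay" (f) sector, entries N+1..2N the "move" (b) sector.  The shift
# operator is the direct sum S = I_N (+) Ahat with Ahat the row-normalised
# adjacency, so the evolution operator U = S . blockdiag(C, C) is itself
# block-diagonal: U^t = blockdiag(C^t, (Ahat C)^t).  S is not unitary and
# total "probability" is not conserved; only the relative magnitudes of the
# measured scores matter, and the ranking is invariant to any positive
# rescaling of the initial state.

#' Build the IOQW coin operator
#'
#' The coin entry for nodes `j`, `k` combines adjacency with the shortest-path
#' length `Pa(j, k)`.  Two algebraic readings are provided:
#' * `"additive"` (default): `C[j,k] = -A[j,k] + 2 / (Pa(j,k) + 2)`, a
#'   Grover-diffusion-like form; the diagonal (`Pa = 0`, `A = 0`) is 1, every
#'   edge entry is exactly `-1/3`, connected non-adjacent pairs lie in
#'   `(0, 1/2]`.
#' * `"ratio"`: `C[j,k] = (2 - A[j,k]) / (Pa(j,k) + 2)`.
#'
#' In both readings disconnected pairs take the `Pa -> Inf` limit, 0.  The
#' additive reading is the shipped default; see the methods vignette for the
#' benchmark evidence behind that choice.
#'
#' @param g an `ioqw_graph`.
#' @param d optional precomputed distance matrix from
#'   [all_pairs_shortest_path()].
#' @param variant `"additive"` or `"ratio"`.
#' @param max_distance distances beyond this are treated as infinite
#'   (truncates the path term to cap the cost of the all-pairs computation);
#'   default `Inf` uses the full distance matrix.
#' @return An object of class `ioqw_coin`: list with the symmetric `N x N`
#'   matrix `C` and the `variant` tag.
#' @export
build_coin <- function(g, d = NULL, variant = c("additive", "ratio"),
                       max_distance = Inf) {
  stopifnot(inherits(g, "ioqw_graph"))
  variant <- match.arg(variant)
  if (is.null(d)) d <- all_pairs_shortest_path(g)
  stopifnot(identical(dim(d), dim(g$adj)))
  d[d > max_distance] <- Inf
  C <- if (variant == "additive") -g$adj + 2 / (d + 2) else (2 - g$adj) / (d + 2)
  dimnames(C) <- dimnames(g$adj)
  structure(list(C = C, variant = variant), class = "ioqw_coin")
}

#' Build the IOQW shift operator
#'
#' `S = I_N (+) Ahat` where `Ahat[j, k] = A[j, k] / deg(j)` (zero row for an
#' isolated node).  Only `Ahat` is stored; [as_shift_matrix()] materialises
#' the full `2N x 2N` direct sum.  Cost `O(N + M)`.
#'
#' @param g an `ioqw_graph`.
#' @return An object of class `ioqw_shift`: list with `Ahat` and `N`.
#' @export
build_shift <- function(g) {
  stopifnot(inherits(g, "ioqw_graph"))
  deg <- as.numeric(g$deg)
  Ahat <- g$adj / ifelse(deg > 0, deg, 1)  # zero rows stay zero
  structure(list(Ahat = Ahat, N = g$N), class = "ioqw_shift")
}

#' Materialise the full 2N x 2N shift matrix
#' @param s an `ioqw_shift`.
#' @return The dense direct sum `blockdiag(I, Ahat)`.
#' @export
as_shift_matrix <- function(s) {
  stopifnot(inherits(s, "ioqw_shift"))
  n <- s$N
  S <- matrix(0, 2 * n, 2 * n)
  S[seq_len(n), seq_len(n)] <- diag(n)
  S[n + seq_len(n), n + seq_len(n)] <- s$Ahat
  S
}

#' Build the t-step evolution operator
#'
#' `U(t) = (S . blockdiag(C, C))^t`, stored in its block form
#' `blockdiag(C^t, (Ahat C)^t)`.
#'
#' @param s an `ioqw_shift`.
#' @param coin an `ioqw_coin`.
#' @param t non-negative integer step count (default 2).
#' @return An object of class `ioqw_evolution`: list with blocks `top`
#'   (`C^t`), `bottom` (`(Ahat C)^t`) and `t`.
#' @export
build_evolution <- function(s, coin, t = 2) {
  stopifnot(inherits(s, "ioqw_shift"), inherits(coin, "ioqw_coin"))
  if (t < 0 || t != round(t)) stop("t must be a non-negative integer")
  structure(
    list(top = mat_power(coin$C, t),
         bottom = mat_power(s$Ahat %*% coin$C, t),
         t = t),
    class = "ioqw_evolution"
  )
}

#' Materialise the full 2N x 2N evolution matrix
#' @param u an `ioqw_evolution`.
#' @return The dense block-diagonal matrix.
#' @export
as_evolution_matrix <- function(u) {
  stopifnot(inherits(u, "ioqw_evolution"))
  n <- nrow(u$top)
  U <- matrix(0, 2 * n, 2 * n)
  U[seq_len(n), seq_len(n)] <- u$top
  U[n + seq_len(n), n + seq_len(n)] <- u$bottom
  U
}

#' Uniform initial walker state
#'
#' All `2N` amplitudes equal, unit Euclidean norm (`1 / sqrt(2N)` each).
#' The final ranking is invariant to this global scale.
#'
#' @param g an `ioqw_graph`.
#' @return Numeric vector of length `2N`.
#' @export
initial_state <- function(g) {
  stopifnot(inherits(g, "ioqw_graph"), g$N >= 1)
  rep(1 / sqrt(2 * g$N), 2 * g$N)
}

#' Degree-weighted measurement vector for one node
#'
#' The projection used to read node `j`'s influence: weight `deg(k) / M` on
#' every neighbour `k` of `j`, identically in both coin sectors; zero
#' elsewhere (an isolated node gets the zero vector).
#'
#' @param g an `ioqw_graph`.
#' @param node a node label.
#' @return Numeric vector of length `2N`.
#' @export
measurement_vector <- function(g, node) {
  stopifnot(inherits(g, "ioqw_graph"))
  node <- as.character(node)
  if (!node %in% g$labels) stop(sprintf("unknown node '%s'", node))
  n <- g$N
  m <- numeric(2 * n)
  if (g$M == 0) return(m)
  nbr <- which(g$adj[node, ] > 0)
  w <- as.numeric(g$deg)[nbr] / g$M
  m[nbr] <- w
  m[n + nbr] <- w
  m
}

#' Measure per-node influence scores
#'
#' `P(j) = (m_j' U(t) psi0)^2` for every node `j`; all scores are squares of
#' real numbers and hence non-negative.  Note that the total score is not 1
#' in general: the walk is not unitary.
#'
#' @param u an `ioqw_evolution`.
#' @param psi0 initial state of length `2N` (see [initial_state()]).
#' @param g the `ioqw_graph` the operators were built from.
#' @return An object of class `ioqw_scores`: list with `scores` (named,
#'   label-keyed), `ranking` (labels by descending score, ties by ascending
#'   label), `t` and `method = "ioqw"`.
#' @export
observe <- function(u, psi0, g) {
  stopifnot(inherits(u, "ioqw_evolution"), inherits(g, "ioqw_graph"))
  n <- g$N
  stopifnot(length(psi0) == 2 * n)
  v <- as.vector(u$top %*% psi0[seq_len(n)]) +
       as.vector(u$bottom %*% psi0[n + seq_len(n)])
  scores <- ioqw_measure(g, v)
  new_scores(scores, method = "ioqw", t = u$t)
}

# Shared measurement: P(j) = (sum_{k in N(j)} deg(k)/M * v_k)^2.
ioqw_measure <- function(g, v) {
  w <- if (g$M > 0) as.numeric(g$deg) / g$M else numeric(g$N)
  inner <- as.vector(g$adj %*% (w * v))
  stats::setNames(inner^2, g$labels)
}

new_scores <- function(scores, method, ...) {
  structure(list(scores = scores, ranking = rank_labels(scores),
                 method = method, ...),
            class = "ioqw_scores")
}

#' @export
print.ioqw_scores <- function(x, n = 10, ...) {
  cat(sprintf("%s scores for %d nodes; top %d:\n",
              x$method, length(x$scores), min(n, length(x$scores))))
  top <- x$ranking[seq_len(min(n, length(x$ranking)))]
  print(data.frame(rank = seq_along(top), node = top,
                   score = as.numeric(x$scores[top])), row.names = FALSE)
  invisible(x)
}

#' Convert scores to a node/score/rank data frame
#' @param x an `ioqw_scores`.
#' @param ... unused.
#' @return data.frame with columns `node`, `score`, `rank`, sorted by rank.
#' @export
as.data.frame.ioqw_scores <- function(x, ...) {
  data.frame(node = x$ranking,
             score = as.numeric(x$scores[x$ranking]),
             rank = seq_along(x$ranking),
             stringsAsFactors = FALSE)
}

#' Rank nodes by IOQW influence
#'
#' The full pipeline: all-pairs shortest paths, coin, shift, `t`-step
#' evolution of the uniform initial state, degree-weighted measurement.
#' Deterministic.  Internally only matrix-vector products with the coin are
#' used, so no `2N x 2N` (or `N x N` power) matrix is ever formed.
#'
#' @param g an `ioqw_graph` (a warning is issued if disconnected).
#' @param t walk step count, default 2.
#' @param variant coin variant, see [build_coin()].
#' @param max_distance see [build_coin()].
#' @return An `ioqw_scores` object.
#' @examples
#' r <- rank_nodes(load_fixture("karate"))
#' head(r$ranking, 3)  # "1" "34" "3"
#' @export
rank_nodes <- function(g, t = 2, variant = c("additive", "ratio"),
                       max_distance = Inf) {
  stopifnot(inherits(g, "ioqw_graph"))
  if (g$N == 0) stop("empty graph")
  variant <- match.arg(variant)
  if (t < 0 || t != round(t)) stop("t must be a non-negative integer")
  if (igraph::components(g$ig)$no > 1) {
    warning("graph is disconnected; cross-component coin entries are 0")
  }
  coin <- build_coin(g, variant = variant, max_distance = max_distance)
  s <- build_shift(g)
  n <- g$N
  psi0 <- initial_state(g)
  top <- psi0[seq_len(n)]
  bot <- psi0[n + seq_len(n)]
  for (i in seq_len(t)) {
    top <- as.vector(coin$C %*% top)
    bot <- as.vector(s$Ahat %*% as.vector(coin$C %*% bot))
  }
  scores <- ioqw_measure(g, top + bot)
  new_scores(scores, method = "ioqw", t = t, variant = variant)
}
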