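# Ranking-agreement statistics.

#' Kendall rank correlation (tau-a)
#'
#' Counts strictly concordant (`Nc`) and strictly discordant (`Nd`)
#' unordered pairs of items; pairs tied in either vector count in neither.
#' `tau = (Nc - Nd) / (n (n - 1) / 2)`.  Note this is tau-a: it differs
#' from the tie-corrected tau-b of [stats::cor.test()] on tied data, and
#' heavily tied score vectors cannot reach `|tau| = 1`.
#'
#' @param x,y numeric score vectors over the same items.  If both are named
#'   the names must coincide as sets and `y` is aligned to `x`'s order;
#'   otherwise equal length and a shared item order are assumed.
#' @return A list of class `kendall_result` with `tau`, `Nc`, `Nd`, `n`.
#' @examples
#' kendall_tau(c(1, 2, 3), c(1, 3, 2))$tau  # 1/3
#' @export
kendall_tau <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    if (!setequal(names(x), names(y))) stop("x and y cover different items")
    y <- y[names(x)]
  } else if (length(x) != length(y)) {
    stop("x and y must have the same length")
  }
  n <- length(x)
  if (n < 2) stop("need at least 2 items")
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  prod_sign <- (dx * dy)[upper.tri(dx)]
  Nc <- sum(prod_sign > 0)
  Nd <- sum(prod_sign < 0)
  structure(list(tau = (Nc - Nd) / (n * (n - 1) / 2),
                 Nc = Nc, Nd = Nd, n = n),
            class = "kendall_result")
}

#' @export
print.kendall_result <- function(x, ...) {
  cat(sprintf("Kendall tau-a = %.4f (Nc = %d, Nd = %d, n = %d)\n",
              x$tau, x$Nc, x$Nd, x$n))
  invisible(x)
}

#' Mean of Kendall coefficients
#'
#' Arithmetic mean of a set of tau values, reported with half-up decimal
#' rounding (the convention of printed tables).
#'
#' @param taus non-empty numeric vector.
#' @param digits decimal places to round to (default 3); `NULL` for the raw
#'   mean.
#' @return The (rounded) mean.
#' @examples
#' average_tau(c(0.310, 0.493, 0.569, 0.377, 0.439, 0.641))  # 0.472
#' @export
average_tau <- function(taus, digits = 3) {
  if (length(taus) == 0) stop("empty tau list")
  m <- mean(taus)
  if (is.null(digits)) m else round_half_up(m, digits)
}

#' Overlap of two top-k lists
#'
#' @param rank_a,rank_b ordered label vectors (best first).
#' @param k list depth, `1 <= k <= length` of both rankings.
#' @return Integer size of the intersection of the two top-k sets.
#' @export
top_k_overlap <- function(rank_a, rank_b, k) {
  if (k <= 0) stop("k must be positive")
  if (k > length(rank_a) || k > length(rank_b)) {
    stop("k exceeds ranking length")
  }
  length(intersect(rank_a[seq_len(k)], rank_b[seq_len(k)]))
}

#' Paired per-node scores for scatter export
#'
#' @param scores_a,scores_b named numeric vectors over the same node set.
#' @return data.frame with columns `node`, `a`, `b`, in the label order of
#'   `scores_a`.
#' @export
correlation_pairs <- function(scores_a, scores_b) {
  if (is.null(names(scores_a)) || is.null(names(scores_b))) {
    stop("scores must be named by node")
  }
  if (!setequal(names(scores_a), names(scores_b))) {
    stop("score vectors cover different node sets")
  }
  data.frame(node = names(scores_a),
             a = as.numeric(scores_a),
             b = as.numeric(scores_b[names(scores_a)]),
             stringsAsFactors = FALSE)
}
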