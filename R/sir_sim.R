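# Discrete-time SIR spreading simulator: the influence ground truth.
#
# Dynamics are synchronous: within one step every infected node first
# attempts to infect each susceptible neighbour independently with
# probability p, then recovers with probability gamma.  A run seeded at node
# j terminates when no infected nodes remain; its outcome F is the number of
# ever-infected nodes (infected + recovered).

#' SIR simulation configuration
#'
#' @param p per-contact infection probability in `[0, 1]`, or `NULL` for the
#'   automatic choice `min(1, 1.5 * epidemic_threshold(g))` resolved when the
#'   simulation runs.
#' @param gamma per-step recovery probability in `(0, 1]`; default 1
#'   (infected nodes recover after exactly one step, the standard convention
#'   in influence benchmarking).
#' @param runs independent repetitions per seed node (default 1000).
#' @param seed master RNG seed; every (node, repetition) pair gets its own
#'   derived substream so results are order-independent.
#' @return A list of class `sir_config`.
#' @export
sir_config <- function(p = NULL, gamma = 1, runs = 1000, seed = 1L) {
  if (!is.null(p) && (p < 0 || p > 1)) stop("p must lie in [0, 1]")
  if (gamma <= 0 || gamma > 1) stop("gamma must lie in (0, 1]")
  if (runs < 1) stop("runs must be at least 1")
  structure(list(p = p, gamma = gamma, runs = as.integer(runs),
                 seed = as.integer(seed)),
            class = "sir_config")
}

#' Epidemic outbreak threshold
#'
#' `<k> / (<k^2> - <k>)` from the degree distribution: the minimum
#' per-contact infection probability sustaining an outbreak on the network.
#'
#' @param g an `ioqw_graph`.
#' @return The threshold probability.
#' @examples
#' epidemic_threshold(load_fixture("star", n = 10))  # 0.25
#' @export
epidemic_threshold <- function(g) {
  s <- graph_stats(g)
  if (s$second_moment <= s$mean_degree) {
    stop("degenerate degree distribution: <k^2> <= <k>")
  }
  s$mean_degree / (s$second_moment - s$mean_degree)
}

#' One SIR run from a single seed node
#'
#' Uses the current RNG state; callers wanting reproducibility seed the RNG
#' first (as [sir_influence()] does per repetition).
#'
#' @param g an `ioqw_graph`.
#' @param seed_node label of the initially infected node.
#' @param p per-contact infection probability.
#' @param gamma per-step recovery probability.
#' @return Integer final size: the count of ever-infected nodes.
#' @export
sir_run <- function(g, seed_node, p, gamma = 1) {
  stopifnot(inherits(g, "ioqw_graph"))
  seed_node <- as.character(seed_node)
  if (!seed_node %in% g$labels) stop(sprintf("unknown node '%s'", seed_node))
  status <- integer(g$N)  # 0 susceptible, 1 infected, 2 recovered
  status[match(seed_node, g$labels)] <- 1L
  while (any(status == 1L)) {
    inf <- status == 1L
    m <- as.vector(g$adj %*% inf)           # infected-neighbour counts
    cand <- which(status == 0L & m > 0)
    new_inf <- cand[stats::runif(length(cand)) < 1 - (1 - p)^m[cand]]
    rec <- which(inf)[stats::runif(sum(inf)) < gamma]
    status[rec] <- 2L
    status[new_inf] <- 1L
  }
  sum(status != 0L)
}

#' Mean SIR final size for every seed node
#'
#' For every node, averages [sir_run()] over `cfg$runs` repetitions, each on
#' its own RNG substream derived from `cfg$seed`, so the result is
#' reproducible bit-for-bit and independent of evaluation order.
#'
#' @param g an `ioqw_graph`.
#' @param cfg a [sir_config()].
#' @return A data.frame of class `sir_result` with columns `node`, `F_mean`,
#'   `runs`, `p`, `gamma`.
#' @export
sir_influence <- function(g, cfg = sir_config()) {
  stopifnot(inherits(g, "ioqw_graph"), inherits(cfg, "sir_config"))
  p <- cfg$p
  if (is.null(p)) p <- min(1, 1.5 * epidemic_threshold(g))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  f_mean <- numeric(g$N)
  for (j in seq_len(g$N)) {
    tot <- 0
    for (r in seq_len(cfg$runs)) {
      set.seed(substream_seed(cfg$seed, j, r))
      tot <- tot + sir_run(g, g$labels[j], p, cfg$gamma)
    }
    f_mean[j] <- tot / cfg$runs
  }
  structure(
    data.frame(node = g$labels, F_mean = f_mean, runs = cfg$runs,
               p = p, gamma = cfg$gamma, stringsAsFactors = FALSE),
    class = c("sir_result", "data.frame")
  )
}
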