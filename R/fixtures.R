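# Built-in fixture graphs.

# Zachary's karate club: the standard 34-node, 78-edge friendship network,
# nodes labelled 1..34 (1 and 34 are the two club leaders).
karate_edges <- c(
  "1 2", "1 3", "1 4", "1 5", "1 6", "1 7", "1 8", "1 9", "1 11", "1 12",
  "1 13", "1 14", "1 18", "1 20", "1 22", "1 32", "2 3", "2 4", "2 8",
  "2 14", "2 18", "2 20", "2 22", "2 31", "3 4", "3 8", "3 28", "3 29",
  "3 33", "3 10", "3 9", "3 14", "4 8", "4 13", "4 14", "5 7", "5 11",
  "6 7", "6 11", "6 17", "7 17", "9 31", "9 33", "9 34", "10 34", "14 34",
  "15 33", "15 34", "16 33", "16 34", "19 33", "19 34", "20 34", "21 33",
  "21 34", "23 33", "23 34", "24 26", "24 28", "24 33", "24 34", "24 30",
  "25 26", "25 28", "25 32", "26 32", "27 30", "27 34", "28 34", "29 32",
  "29 34", "30 33", "30 34", "31 33", "31 34", "32 33", "32 34", "33 34")

#' Load a built-in fixture graph
#'
#' Deterministic small graphs used throughout examples and tests:
#' * `"karate"` — Zachary's karate club (34 nodes, 78 edges, labels 1..34);
#' * `"triangle"` — complete graph on 3 nodes;
#' * `"path3"` — the path 1-2-3;
#' * `"star"` — a star on `n` nodes (node 1 is the centre);
#' * `"cycle"` — a cycle on `n` nodes.
#'
#' `"star(10)"`-style strings are also accepted (convenient on the command
#' line).
#'
#' @param name fixture name.
#' @param n node count for the parameterised fixtures.
#' @return An `ioqw_graph`.
#' @examples
#' load_fixture("karate")$M  # 78
#' @export
load_fixture <- function(name, n = NULL) {
  name <- as.character(name)
  m <- regmatches(name, regexec("^([a-z0-9]+)\\(([0-9]+)\\)$", name))[[1]]
  if (length(m) == 3) {
    name <- m[2]
    n <- as.integer(m[3])
  }
  known <- c("karate", "triangle", "path3", "star", "cycle")
  if (!name %in% known) {
    stop(sprintf("unknown fixture '%s'; available: %s",
                 name, paste(known, collapse = ", ")))
  }
  if (name %in% c("star", "cycle")) {
    if (is.null(n) || n < 3) stop(sprintf("fixture '%s' needs n >= 3", name))
  }
  edges <- switch(name,
    karate   = do.call(rbind, strsplit(karate_edges, " ")),
    triangle = cbind(c("1", "2", "3"), c("2", "3", "1")),
    path3    = cbind(c("1", "2"), c("2", "3")),
    star     = cbind(rep("1", n - 1), as.character(2:n)),
    cycle    = cbind(as.character(seq_len(n)),
                     as.character(c(2:n, 1)))
  )
  labels <- switch(name,
    karate = as.character(1:34),
    star   = as.character(seq_len(n)),
    cycle  = as.character(seq_len(n)),
    NULL)
  new_ioqw_graph(edges, labels = labels)
}
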