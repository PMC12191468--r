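# Independent brute-force oracles used across the suite.

# Floyd-Warshall all-pairs shortest paths on a 0/1 adjacency matrix.
oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Unnormalised betweenness by explicit shortest-path enumeration (each
# unordered pair once; endpoints excluded).
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_floyd_warshall(adj)
  enum_paths <- function(s, t) {
    if (s == t) return(list(s))
    out <- list()
    for (u in which(adj[s, ] > 0)) {
      if (is.finite(d[u, t]) && d[u, t] == d[s, t] - 1) {
        for (p in enum_paths(u, t)) out <- c(out, list(c(s, p)))
      }
    }
    out
  }
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t])) next
      paths <- enum_paths(s, t)
      inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(inner) > 0) {
        tab <- table(inner)
        idx <- as.integer(names(tab))
        b[idx] <- b[idx] + as.numeric(tab) / length(paths)
      }
    }
  }
  b
}

# Kendall tau-a by double loop over pairs.
oracle_kendall <- function(x, y) {
  n <- length(x)
  nc <- 0; nd <- 0
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      s <- sign(x[j] - x[k]) * sign(y[j] - y[k])
      if (s > 0) nc <- nc + 1
      if (s < 0) nd <- nd + 1
    }
  }
  list(tau = (nc - nd) / (n * (n - 1) / 2), Nc = nc, Nd = nd)
}

# Random 2x2 unitary via QR of a complex Gaussian matrix.
rand_unitary2 <- function() {
  z <- matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 2, 2)
  qr.Q(qr(z))
}

# Random connected-ish test graph with string labels.
rand_graph <- function(n, p = 0.3, seed = 1) {
  generate_random("er", n = n, p = p, seed = seed)
}
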