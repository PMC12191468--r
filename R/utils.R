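# Shared helpers.

# Natural ascending order of node labels: numeric if every label parses as a
# number (the common case for benchmark networks), lexicographic otherwise.
# Used as the deterministic tie-break in every ranking.
label_order_key <- function(labels) {
  num <- suppressWarnings(as.numeric(labels))
  if (!anyNA(num)) num else rank(labels, ties.method = "first")
}

# Ranking by descending score, ties broken by ascending label.
rank_labels <- function(scores) {
  labels <- names(scores)
  labels[order(-as.numeric(scores), label_order_key(labels))]
}

# Integer matrix power by repeated multiplication (exponents are tiny here).
mat_power <- function(m, t) {
  stopifnot(t >= 0, t == round(t))
  out <- diag(nrow(m))
  dimnames(out) <- dimnames(m)
  for (i in seq_len(t)) out <- out %*% m
  out
}

# Half-up decimal rounding (what tables in print use), as opposed to R's
# round-half-even on binary doubles.
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic per-(node, repetition) RNG substream seed below 2^31.
substream_seed <- function(master, j, r) {
  as.integer((as.numeric(master) * 7 + j * 1e5 + r) %% 2147483629)
}
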