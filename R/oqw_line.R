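# Reference one-dimensional coined quantum walk on a ring.
#
# This is the genuinely unitary walk the IOQW score is derived from; it is
# used to validate the coin/shift machinery (probability conservation,
# permutation structure).  States are complex vectors of length 2n in
# coin-major order: entries 1..n are the |f> (forward) sector, n+1..2n the
# |b> (backward) sector.  Boundary condition is cyclic so the shift is an
# exact permutation (unitary) for finite n.

#' Build a coin card (2x2 unitary coin)
#'
#' Validates unitarity to 1e-12.
#'
#' @param U2 a 2x2 complex (or real) matrix.
#' @return An object of class `coin_card`.
#' @export
coin_card <- function(U2) {
  U2 <- matrix(as.complex(U2), 2, 2)
  if (max(abs(U2 %*% Conj(t(U2)) - diag(2))) > 1e-12) {
    stop("coin must be unitary (to 1e-12)")
  }
  structure(list(U2 = U2), class = "coin_card")
}

#' The Hadamard coin
#' @return A `coin_card` for `H = 1/sqrt(2) * [[1, 1], [1, -1]]`.
#' @export
hadamard_coin <- function() coin_card(matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2))

#' The identity coin
#' @return A `coin_card` for the 2x2 identity.
#' @export
identity_coin <- function() coin_card(diag(2))

#' Shift operator of the walk on a cyclic line
#'
#' The |f> component moves position `j -> j + 1 (mod n)`, the |b> component
#' `j -> j - 1 (mod n)`.  The result is a `2n x 2n` permutation matrix.
#'
#' @param n_sites number of sites (>= 2).
#' @return A dense `2n x 2n` 0/1 matrix.
#' @export
line_shift <- function(n_sites) {
  if (n_sites < 2) stop("n_sites must be at least 2")
  n <- n_sites
  fwd <- matrix(0, n, n)
  fwd[cbind(c(2:n, 1), 1:n)] <- 1  # column j has its 1 in row j+1
  S <- matrix(0, 2 * n, 2 * n)
  S[seq_len(n), seq_len(n)] <- fwd
  S[n + seq_len(n), n + seq_len(n)] <- t(fwd)
  S
}

#' A walker state localised at one position
#'
#' @param n_sites number of sites.
#' @param position 1-based site index.
#' @param coin length-2 complex coin amplitudes `(f, b)`; default `(1, 0)`.
#' @return Complex amplitude vector of length `2n`, normalised.
#' @export
line_state <- function(n_sites, position, coin = c(1, 0)) {
  stopifnot(position >= 1, position <= n_sites)
  coin <- as.complex(coin)
  coin <- coin / sqrt(sum(Mod(coin)^2))
  amp <- complex(2 * n_sites)
  amp[position] <- coin[1]
  amp[n_sites + position] <- coin[2]
  amp
}

#' Evolve a line-walk state
#'
#' Applies `(S . (coin x I_pos))^t` to the initial state; the coin lift in
#' coin-major order is the Kronecker product `U2 x I_n`.  The norm is
#' preserved exactly up to round-off.
#'
#' @param initial complex amplitude vector of length `2n`, unit norm
#'   (checked to 1e-8).
#' @param coin a `coin_card`.
#' @param t non-negative integer step count.
#' @return The evolved amplitude vector.
#' @export
line_evolve <- function(initial, coin, t) {
  stopifnot(inherits(coin, "coin_card"), t >= 0, t == round(t))
  if (abs(sqrt(sum(Mod(initial)^2)) - 1) > 1e-8) {
    stop("initial state must be normalised")
  }
  n <- length(initial) / 2
  stopifnot(n == round(n), n >= 2)
  S <- line_shift(n)
  L <- kronecker(coin$U2, diag(n))
  U <- S %*% L
  amp <- initial
  for (i in seq_len(t)) amp <- as.vector(U %*% amp)
  amp
}

#' Per-position occupation probabilities
#'
#' `P(j) = |amp(f, j)|^2 + |amp(b, j)|^2`; sums to 1 for a normalised state.
#'
#' @param amplitudes complex amplitude vector of length `2n`.
#' @return Numeric probability vector of length `n`.
#' @export
line_observe <- function(amplitudes) {
  n <- length(amplitudes) / 2
  stopifnot(n == round(n))
  Mod(amplitudes[seq_len(n)])^2 + Mod(amplitudes[n + seq_len(n)])^2
}
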