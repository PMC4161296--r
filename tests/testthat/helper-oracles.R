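# Independent oracles used across tests: brute-force enumeration and direct
# absorbing-chain solves, deliberately naive.

# count sequences within Hamming distance w of a center by full enumeration
brute_ball_count <- function(L, w, A) {
  sp <- seq_space(L, A)
  seqs <- all_sequences(sp)
  center <- seqs[1]
  sum(hamming_distance(seqs, rep(center, length(seqs))) <= w)
}

# fixation probability of a single mutant (fitness r) in a Moran population of
# size N, by solving the absorbing linear system over mutant counts 0..N
moran_absorb_solve <- function(r, N) {
  if (N == 1) return(1)
  states <- 1:(N - 1)
  up <- function(i) (r * i / (r * i + N - i)) * ((N - i) / N)
  dn <- function(i) ((N - i) / (r * i + N - i)) * (i / N)
  n <- length(states)
  M <- diag(n)
  b <- numeric(n)
  for (j in seq_len(n)) {
    i <- states[j]
    u <- up(i); d <- dn(i)
    M[j, j] <- u + d
    if (j > 1) M[j, j - 1] <- -d
    if (j < n) M[j, j + 1] <- -u
    if (i == N - 1) b[j] <- u
  }
  solve(M, b)[1]
}

# probability of hitting `low` before `high` by absorbing linear solve
ruin_absorb_solve <- function(chain, start, low, high) {
  states <- (low + 1):(high - 1)
  n <- length(states)
  M <- diag(n)
  b <- numeric(n)
  for (j in seq_len(n)) {
    k <- states[j]
    pd <- chain$p_down[k + 1]; pu <- chain$p_up[k + 1]
    M[j, j] <- pd + pu
    if (j > 1) M[j, j - 1] <- -pd
    if (j < n) M[j, j + 1] <- -pu
    if (k == low + 1) b[j] <- b[j] + pd
  }
  solve(M, b)[match(start, states)]
}

# tiny two-state-per-position binary landscape used in several tests
toy_land_2x2 <- function() {
  sp <- seq_space(2, alphabet = c("0", "1"))
  tabulated_landscape(sp, c("00" = 5, "01" = 1, "10" = 2, "11" = 3))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
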