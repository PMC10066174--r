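# small fixture networks built in code

# birth-death chain on {0..bound}: 0 <-> 1 <-> ... with birth rate a, death b*x
birth_death <- function(a = 1, b = 1) {
  reaction_network("Z", list(
    reaction(integer(0), c(Z = 1), mass_action(a)),
    reaction(c(Z = 1), integer(0), mass_action(b))))
}

# irreversible conversion S -> P with rate kappa
conversion <- function(kappa = 1) {
  reaction_network(c("S", "P"),
                   list(reaction(c(S = 1), c(P = 1), mass_action(kappa))))
}

# exhaustive-enumeration oracle for the closed enzyme network state count:
# states (nS, nP, nSE) with nS + nP + nSE = S_tot, nSE <= E_tot, all >= 0
ek1_state_count_oracle <- function(S_tot, E_tot) {
  cnt <- 0L
  for (nS in 0:S_tot) for (nP in 0:(S_tot - nS)) {
    nSE <- S_tot - nS - nP
    if (nSE <= E_tot) cnt <- cnt + 1L
  }
  cnt
}

# brute-force up-set filter over all subsets (independent of the package's
# bitmask path)
upsets_bruteforce <- function(A, space) {
  N <- nrow(space$states)
  rel <- matrix(FALSE, N, N)
  for (i in seq_len(N)) for (j in seq_len(N))
    rel[i, j] <- leq_A(A, space$states[i, ], space$states[j, ])
  out <- list()
  for (mask in 0:(2^N - 1)) {
    members <- which(bitwAnd(mask, bitwShiftL(1L, 0:(N - 1))) != 0L)
    ok <- TRUE
    for (i in members) {
      succ <- which(rel[i, ])
      if (!all(succ %in% members)) { ok <- FALSE; break }
    }
    if (ok) out[[length(out) + 1L]] <- members
  }
  out
}

expect_ordered_states <- function(A, x, y) {
  expect_true(leq_A(A, x, y))
}
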