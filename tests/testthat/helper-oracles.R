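# Independent brute-force oracles for the pair-count statistics.
# Deliberately written as naive double loops, sharing no code with the
# package internals.

oracle_kendall_s <- function(x) {
  s <- 0L
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + sign(x[j] - x[i])
    }
  }
  as.integer(s)
}

oracle_s_between <- function(a, b) {
  s <- 0L
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      s <- s + sign(b[j] - a[i])
    }
  }
  as.integer(s)
}

oracle_tau_u <- function(a, b) {
  (oracle_s_between(a, b) - oracle_kendall_s(a)) / (length(a) * length(b))
}

# exact two-sided permutation p by exhaustive enumeration of all
# choose(n, n_a) phase reassignments, pooled order preserved
oracle_perm_p <- function(a, b) {
  v <- c(a, b)
  n <- length(v)
  obs <- abs(oracle_tau_u(a, b))
  sets <- combn(n, length(a))
  hits <- 0L
  for (k in seq_len(ncol(sets))) {
    ai <- sets[, k]
    bi <- setdiff(seq_len(n), ai)
    t_k <- oracle_tau_u(v[ai], v[bi])
    if (abs(t_k) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / ncol(sets)
}

# a small well-behaved A-B-A series builder used across tests
make_series <- function(a1, a2, b = numeric(0), outcome = "grip_strength",
                        participant = "P1") {
  n <- length(a1) + length(b) + length(a2)
  assessment_series(participant, outcome, seq_len(n),
                    rep(c("A1", "B", "A2"),
                        c(length(a1), length(b), length(a2))),
                    c(a1, b, a2))
}

# slow impaired-style trial on which injected submovements express as
# distinct speed peaks (low main-profile slope)
slow_durations <- c(reach = 2, forward = 2.5, drink = 2, back = 2.5,
                    return_ = 2)
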