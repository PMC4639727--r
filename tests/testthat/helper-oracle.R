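# Small-scale helpers shared across tests.

# Quick parameter sets with tiny budgets.
tiny_params <- function(N = 10, S = 5, R = 0.5, seed = 1, ...) {
  crowd_params(N = N, S = S, R = R, seed = seed, ...)
}

# Brute-force enumeration of one iteration of a single group: sums over the
# full outcome space (role of every player, collectivist solve indicator,
# individualist gain value and solve indicator) and returns the exact
# expectations of the capacity-increment indicator, the shared gain per
# member and each player's private gain. Independent of the engine and of
# the closed forms in the package: it knows only the scoring rule.
enumerate_iteration <- function(p, R, capacity, G_min, G_max) {
  S <- length(p)
  gvals <- seq.int(G_min, G_max)
  ng <- length(gvals)
  states <- lapply(seq_len(S), function(i) {
    st <- list(
      list(pr = p[i] * R,       coll = TRUE, solved = TRUE,  gain = 0),
      list(pr = p[i] * (1 - R), coll = TRUE, solved = FALSE, gain = 0))
    for (g in gvals) {
      st <- c(st, list(
        list(pr = (1 - p[i]) / ng * R^g,       coll = FALSE, solved = TRUE,
             gain = g),
        list(pr = (1 - p[i]) / ng * (1 - R^g), coll = FALSE, solved = FALSE,
             gain = g)))
    }
    st
  })
  counts <- vapply(states, length, integer(1))
  idx <- rep(1L, S)
  inc_p <- 0; shared <- 0; own <- numeric(S)
  repeat {
    combo <- lapply(seq_len(S), function(i) states[[i]][[idx[i]]])
    pr <- prod(vapply(combo, function(x) x$pr, numeric(1)))
    if (pr > 0) {
      s <- sum(vapply(combo, function(x) x$coll && x$solved, logical(1)))
      if (s >= 1) {
        inc_p <- inc_p + pr
        shared <- shared + pr * s * (capacity + 1) / S
      }
      for (i in seq_len(S))
        if (!combo[[i]]$coll && combo[[i]]$solved)
          own[i] <- own[i] + pr * combo[[i]]$gain
    }
    j <- 1L
    repeat {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= counts[j]) break
      idx[j] <- 1L
      j <- j + 1L
      if (j > S)
        return(list(increment_prob = inc_p, shared_gain = shared,
                    own_gain = own))
    }
  }
}

# A population with hand-set collaboration probabilities (group-contiguous).
fixed_population <- function(p, S) {
  n <- length(p) / S
  structure(list(
    p = p, fitness = numeric(length(p)),
    group = rep(seq_len(n), each = S),
    capacity = integer(n),
    N = length(p), S = S, n_groups = as.integer(n)
  ), class = "crowd_population")
}
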