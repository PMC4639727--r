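#' Simulate a block of iterations for one group
#'
#' Low-level vectorized engine core. For a group of `S = length(p)` players
#' it realizes `n_iter` iterations in one pass: role draws (collectivist with
#' probability `p`), collectivist solve attempts (probability `R`), per-
#' individualist gain draws `G ~ U{G_min..G_max}` and solve attempts
#' (probability `R^G`), capacity updates and fitness updates.
#'
#' Scoring per iteration: let `s` be the number of collectivists who solved.
#' If `s >= 1` the group's capacity increments by one first, and every group
#' member — collectivist or individualist, winner or loser — then gains
#' `s * capacity_new / S`. Each individualist who solved additionally pockets
#' their private `G`, credited whether or not any collectivist solved.
#'
#' With `cumulative = TRUE` (production mode) capacity accumulates across
#' the block, as within a round. With `cumulative = FALSE` the `n_iter`
#' iterations are independent replicates all starting from `capacity0`,
#' which is what the closed-form validation oracles compare against.
#'
#' @param p Collaboration probabilities of the group's players.
#' @param n_iter Number of iterations to realize.
#' @param R Task simplicity in \[0, 1\].
#' @param G_min,G_max Integer gain range for individualists.
#' @param capacity0 Capacity at block start.
#' @param cumulative Accumulate capacity across iterations (see above)?
#' @param detail Also return per-iteration outcome matrices?
#' @return A list with `fitness_gain` (per player, summed over the block),
#'   `capacity` (final capacity if cumulative, else per-iteration vector),
#'   `shared` (per-iteration shared gain per member), `solver_count`,
#'   `incremented`, and with `detail = TRUE` the `S x n_iter` matrices
#'   `collectivist`, `solved_collective`, `gain`, `solved_individual`.
#' @keywords internal
#' @export
group_iterations <- function(p, n_iter, R, G_min = 1L, G_max = 10L,
                             capacity0 = 0L, cumulative = TRUE,
                             detail = FALSE) {
  S <- length(p)
  M <- as.integer(n_iter)
  coll <- stats::runif(S * M) < p           # column-major: column = iteration
  idx_c <- which(coll)
  solveC <- logical(S * M)
  solveC[idx_c] <- stats::runif(length(idx_c)) < R
  dim(solveC) <- c(S, M)
  s <- colSums(solveC)
  inc <- s >= 1
  Sig <- if (cumulative) capacity0 + cumsum(inc) else capacity0 + as.numeric(inc)
  shared <- s * Sig / S                     # zero whenever s = 0
  idx_i <- which(!coll)
  G <- sample.int(G_max - G_min + 1L, length(idx_i), replace = TRUE) +
    G_min - 1L
  solvedI <- stats::runif(length(idx_i)) < R^G
  payout <- G * solvedI
  player_i <- (idx_i - 1L) %% S + 1L        # row (player) index of each cell
  own <- as.vector(rowsum(c(payout, numeric(S)),
                          c(player_i, seq_len(S)), reorder = TRUE))
  out <- list(
    fitness_gain = sum(shared) + own,
    capacity = if (cumulative) {
      if (M > 0) as.integer(Sig[M]) else as.integer(capacity0)
    } else as.integer(Sig),
    shared = shared,
    solver_count = as.integer(s),
    incremented = inc
  )
  if (detail) {
    dim(coll) <- c(S, M)
    gain <- matrix(0, S, M)
    gain[idx_i] <- G
    solveI <- matrix(FALSE, S, M)
    solveI[idx_i] <- solvedI
    own_gain <- matrix(0, S, M)
    own_gain[idx_i] <- payout
    out$collectivist <- coll
    out$solved_collective <- solveC
    out$gain <- gain
    out$solved_individual <- solveI
    out$own_gain <- own_gain
  }
  out
}

#' Run a single iteration for every group
#'
#' One time-step of the model: each group independently samples roles, draws
#' gains for its individualists, realizes solve attempts and applies the
#' scores. Groups never interact within an iteration.
#'
#' @param pop A `crowd_population`.
#' @param params A [crowd_params] object.
#' @return A list with the updated `population` and `outcomes`, a list with
#'   one record per group: a data frame (`role`, `gain`, `solved` per player)
#'   plus `solver_count` and `capacity_incremented`.
#' @export
run_iteration <- function(pop, params) {
  stopifnot(inherits(pop, "crowd_population"))
  outcomes <- vector("list", pop$n_groups)
  for (j in seq_len(pop$n_groups)) {
    idx <- which(pop$group == j)
    res <- group_iterations(pop$p[idx], 1L, params$R,
                            params$G_min, params$G_max,
                            capacity0 = pop$capacity[j],
                            cumulative = TRUE, detail = TRUE)
    pop$fitness[idx] <- pop$fitness[idx] + res$fitness_gain
    pop$capacity[j] <- res$capacity
    coll <- res$collectivist[, 1]
    outcomes[[j]] <- list(
      players = data.frame(
        role = ifelse(coll, "collectivist", "individualist"),
        gain = ifelse(coll, NA_integer_, as.integer(res$gain[, 1])),
        solved = ifelse(coll, res$solved_collective[, 1],
                        res$solved_individual[, 1])
      ),
      solver_count = res$solver_count[1],
      capacity_incremented = res$incremented[1]
    )
  }
  list(population = pop, outcomes = outcomes)
}

#' Apply one iteration's scores to a group
#'
#' Pure scoring rule, usable independently of the sampling: given the
#' realized roles, gains and solve outcomes of one iteration, update the
#' group's capacity and every member's fitness. If at least one collectivist
#' solved (`solver_count >= 1`), capacity increments first and every member
#' gains `solver_count * capacity_new / S`; each individualist that solved
#' additionally gains their drawn `G`, whether or not the capacity moved.
#'
#' @param group A list with `p`, `fitness` (per player) and scalar
#'   `capacity`.
#' @param outcome One group record as produced by [run_iteration()]:
#'   `players` data frame (`role`, `gain`, `solved`), `solver_count`,
#'   `capacity_incremented`.
#' @return The updated group list.
#' @export
apply_iteration_scores <- function(group, outcome) {
  pl <- outcome$players
  S <- length(group$fitness)
  if (nrow(pl) != S)
    stop("outcome does not match group size", call. = FALSE)
  s <- sum(pl$role == "collectivist" & pl$solved)
  if (s != outcome$solver_count)
    stop(sprintf("inconsistent outcome: solver_count %d but %d solving collectivists recorded",
                 outcome$solver_count, s), call. = FALSE)
  if (s >= 1) {
    group$capacity <- group$capacity + 1L
    group$fitness <- group$fitness + s * group$capacity / S
  }
  solo <- pl$role == "individualist" & pl$solved
  group$fitness[solo] <- group$fitness[solo] + pl$gain[solo]
  group
}

#' Run one round
#'
#' Executes `iterations_per_round` iterations for every group (capacity and
#' fitness accumulating from their current values, normally zero at round
#' start) and records the round summary. Selection between rounds is the
#' caller's job ([run_game()] applies it at the start of every round after
#' the first).
#'
#' @param pop A `crowd_population` (fitness/capacity at round-start values).
#' @param params A [crowd_params] object.
#' @return A list with `population` (after the round), `mean_fitness` (mean
#'   over all `N` players at round end) and `per_group_capacity`.
#' @export
run_round <- function(pop, params) {
  stopifnot(inherits(pop, "crowd_population"))
  for (j in seq_len(pop$n_groups)) {
    idx <- which(pop$group == j)
    res <- group_iterations(pop$p[idx], params$iterations_per_round,
                            params$R, params$G_min, params$G_max,
                            capacity0 = pop$capacity[j], cumulative = TRUE)
    pop$fitness[idx] <- pop$fitness[idx] + res$fitness_gain
    pop$capacity[j] <- res$capacity
  }
  list(population = pop,
       mean_fitness = mean(pop$fitness),
       per_group_capacity = pop$capacity)
}

#' Evolutionary replacement between rounds
#'
#' Computes the global mean fitness over all `N` players, takes the set `B`
#' of players strictly below it, removes `k = min(floor(replacement_fraction
#' * N), |B|)` players drawn uniformly without replacement from `B`, and
#' replaces each — in the same group slot — by a fresh player with
#' `p ~ U[0, 1]`. Afterwards every fitness and every capacity is reset to 0;
#' group sizes never change. When all players have equal fitness (e.g.
#' nothing was ever solved) `B` is empty and nobody is replaced, so the `p`
#' distribution drifts only through sampling noise.
#'
#' @param pop A `crowd_population` at round end.
#' @param params A [crowd_params] object.
#' @return The post-selection `crowd_population`.
#' @export
apply_selection <- function(pop, params) {
  stopifnot(inherits(pop, "crowd_population"))
  pbar <- mean(pop$fitness)
  below <- which(pop$fitness < pbar)
  k <- min(floor(params$replacement_fraction * pop$N), length(below))
  if (k > 0) {
    victims <- below[sample.int(length(below), k)]
    pop$p[victims] <- stats::runif(k)
  }
  pop$fitness[] <- 0
  pop$capacity[] <- 0L
  pop
}

#' Run a full game
#'
#' A game is `rounds_per_game` rounds; evolutionary selection (and the reset
#' of fitness and capacity) is applied at the beginning of every round after
#' the first. The game's product is the surviving distribution of
#' collaboration probabilities together with the last round's mean fitness
#' and final capacities (capacity resets each round, so the last round's
#' final value is the reached capacity, often written as the maximal
#' capacity of the evolved group).
#'
#' Randomness is fully determined by `seed`: the population draw and each
#' round use child streams derived via [derive_seed()], so games are
#' reproducible and independent cells of a grid never share streams.
#'
#' @param params A [crowd_params] object.
#' @param seed Root seed for this game; defaults to `params$seed`.
#' @return An object of class `crowd_game`: list with `final_mean_p`,
#'   `final_mean_fitness`, `final_capacity` (per group), `capacity_mean`,
#'   `p` (surviving values), `params`, `seed`.
#' @export
run_game <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "crowd_params"))
  set.seed(derive_seed(seed, 0L))
  pop <- init_population(params)
  rr <- NULL
  for (r in seq_len(params$rounds_per_game)) {
    set.seed(derive_seed(seed, r))
    if (r > 1) pop <- apply_selection(pop, params)
    rr <- run_round(pop, params)
    pop <- rr$population
  }
  if (is.null(rr))    # rounds_per_game >= 1 enforced by crowd_params
    rr <- list(mean_fitness = 0, per_group_capacity = pop$capacity)
  structure(list(
    final_mean_p = mean(pop$p),
    final_mean_fitness = rr$mean_fitness,
    final_capacity = rr$per_group_capacity,
    capacity_mean = mean(rr$per_group_capacity),
    p = pop$p,
    params = params,
    seed = seed
  ), class = "crowd_game")
}

#' @export
print.crowd_game <- function(x, ...) {
  cat(sprintf("crowd_game (S=%d, R=%g, seed=%d)\n",
              x$params$S, x$params$R, x$seed))
  cat(sprintf("  final mean p       : %.4f\n", x$final_mean_p))
  cat(sprintf("  final mean fitness : %.4f\n", x$final_mean_fitness))
  cat(sprintf("  final capacity     : %s (mean %.1f)\n",
              paste(utils::head(x$final_capacity, 8), collapse = " "),
              x$capacity_mean))
  invisible(x)
}
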