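test_that("scoring matches worked examples of the payoff rule", {
  # no collectivist solves; a lone individualist wins G = 6 privately
  g <- list(p = rep(0.5, 4), fitness = numeric(4), capacity = 0L)
  out <- list(players = data.frame(
    role = c("collectivist", "individualist", "individualist", "individualist"),
    gain = c(NA, 6L, 2L, 9L),
    solved = c(FALSE, TRUE, FALSE, FALSE)),
    solver_count = 0L, capacity_incremented = FALSE)
  res <- apply_iteration_scores(g, out)
  expect_equal(res$capacity, 0L)
  expect_equal(res$fitness, c(0, 6, 0, 0))

  # one collectivist solves in a pair: capacity 1, both gain 1 * 1/2
  g <- list(p = rep(0.5, 2), fitness = numeric(2), capacity = 0L)
  out <- list(players = data.frame(
    role = c("collectivist", "collectivist"),
    gain = c(NA_integer_, NA_integer_),
    solved = c(TRUE, FALSE)),
    solver_count = 1L, capacity_incremented = TRUE)
  res <- apply_iteration_scores(g, out)
  expect_equal(res$capacity, 1L)
  expect_equal(res$fitness, c(0.5, 0.5))

  # s = 2 solvers at capacity 4: everyone gets 2 * 5/4; the winning
  # individualist adds their G = 9 on top
  g <- list(p = rep(0.5, 4), fitness = numeric(4), capacity = 4L)
  out <- list(players = data.frame(
    role = c("collectivist", "collectivist", "collectivist", "individualist"),
    gain = c(NA, NA, NA, 9L),
    solved = c(TRUE, TRUE, FALSE, TRUE)),
    solver_count = 2L, capacity_incremented = TRUE)
  res <- apply_iteration_scores(g, out)
  expect_equal(res$capacity, 5L)
  expect_equal(res$fitness, c(2.5, 2.5, 2.5, 11.5))

  # a corrupted outcome record is refused
  out$solver_count <- 3L
  expect_error(apply_iteration_scores(g, out), "inconsistent")
})

test_that("one engine iteration agrees with the pure scoring rule", {
  params <- tiny_params(N = 12, S = 4, R = 0.6, seed = 8)
  for (k in 1:20) {
    set.seed(derive_seed(8, k))
    pop <- init_population(params)
    pop$capacity <- c(3L, 0L, 11L)
    set.seed(derive_seed(8, k, 1))
    stepped <- run_iteration(pop, params)
    for (j in 1:3) {
      idx <- which(pop$group == j)
      ref <- apply_iteration_scores(
        list(p = pop$p[idx], fitness = pop$fitness[idx],
             capacity = pop$capacity[j]),
        stepped$outcomes[[j]])
      expect_equal(stepped$population$fitness[idx], ref$fitness)
      expect_equal(stepped$population$capacity[j], ref$capacity)
    }
    counts <- vapply(stepped$outcomes, function(o)
      sum(o$players$role == "collectivist" & o$players$solved), integer(1))
    expect_equal(counts, vapply(stepped$outcomes, `[[`, integer(1),
                                "solver_count"))
    expect_equal(vapply(stepped$outcomes, `[[`, logical(1),
                        "capacity_incremented"), counts >= 1)
  }
})

test_that("nothing is ever solved in the zero-simplicity limit", {
  pop <- fixed_population(runif(10), S = 5)
  res <- group_iterations(pop$p[1:5], 500, R = 0, capacity0 = 0L)
  expect_equal(res$fitness_gain, numeric(5))
  expect_equal(res$capacity, 0L)
})

test_that("the all-collectivist certainty case accrues triangular fitness", {
  # p = 1, R = 1, S = 5: capacity ticks every iteration and each player
  # gains 5 * k/5 = k at iteration k
  res <- group_iterations(rep(1, 5), 40, R = 1)
  expect_equal(res$capacity, 40L)
  expect_equal(res$fitness_gain, rep(sum(1:40), 5))
})

test_that("capacity equals the recount of solving iterations", {
  params <- tiny_params(N = 8, S = 4, R = 0.4, seed = 13)
  set.seed(13)
  pop <- init_population(params)
  incs <- matrix(FALSE, 2, 100)
  prev <- pop$fitness
  for (t in 1:100) {
    stepped <- run_iteration(pop, params)
    incs[, t] <- vapply(stepped$outcomes, `[[`, logical(1),
                        "capacity_incremented")
    # fitness never decreases within a round
    expect_true(all(stepped$population$fitness >= prev))
    prev <- stepped$population$fitness
    pop <- stepped$population
  }
  expect_equal(pop$capacity, as.integer(rowSums(incs)))
})

test_that("selection replaces only below-average players and keeps shape", {
  params <- crowd_params(N = 10, S = 5, R = 0.5, seed = 5,
                         replacement_fraction = 0.2)
  pop <- fixed_population(seq(0.05, 0.95, length.out = 10), S = 5)
  pop$fitness <- c(0, 0, 0, 0, 0, 10, 10, 10, 10, 10)  # |B| = 5, k = 2
  pop$capacity <- c(7L, 3L)
  set.seed(1)
  sel <- apply_selection(pop, params)
  expect_equal(sum(sel$p != pop$p), 2)              # exactly k replaced
  expect_equal(sel$p[6:10], pop$p[6:10])            # fit players untouched
  expect_equal(tabulate(sel$group), c(5L, 5L))
  expect_equal(sel$fitness, numeric(10))            # scores reset
  expect_equal(sel$capacity, c(0L, 0L))

  # equal fitness everywhere: the below-mean pool is empty, nobody moves
  pop$fitness <- rep(4, 10)
  sel <- apply_selection(pop, params)
  expect_identical(sel$p, pop$p)
})

test_that("selection never removes a player at or above the mean", {
  params <- crowd_params(N = 20, S = 5, R = 0.5, seed = 6,
                         replacement_fraction = 0.5)
  for (k in 1:30) {
    set.seed(k)
    pop <- fixed_population(runif(20), S = 5)
    pop$fitness <- rpois(20, 3)
    keep <- pop$fitness >= mean(pop$fitness)
    sel <- apply_selection(pop, params)
    expect_identical(sel$p[keep], pop$p[keep])
    expect_lte(sum(sel$p != pop$p), floor(0.5 * 20))
  }
})

test_that("seeded games reproduce bit-identically", {
  params <- crowd_params(N = 20, S = 5, R = 0.7, seed = 21,
                         iterations_per_round = 50, rounds_per_game = 10,
                         games = 1)
  g1 <- run_game(params)
  g2 <- run_game(params)
  expect_identical(g1, g2)
  g3 <- run_game(params, seed = 22)
  expect_false(identical(g1$p, g3$p))
})

test_that("round summaries satisfy their definitions", {
  params <- crowd_params(N = 10, S = 5, R = 0.9, seed = 3,
                         iterations_per_round = 0)
  set.seed(3)
  pop <- init_population(params)
  rr <- run_round(pop, params)   # empty round
  expect_equal(rr$mean_fitness, 0)
  expect_equal(rr$per_group_capacity, c(0L, 0L))

  params <- crowd_params(N = 10, S = 5, R = 1, seed = 3,
                         iterations_per_round = 25)
  pop <- fixed_population(rep(1, 10), S = 5)
  rr <- run_round(pop, params)
  expect_equal(rr$per_group_capacity, c(25L, 25L))  # certain solving
  expect_equal(rr$mean_fitness, mean(rr$population$fitness))
})

test_that("a one-round game applies no selection pressure on p", {
  params <- crowd_params(N = 100, S = 10, R = 0.5, seed = 77,
                         iterations_per_round = 20, rounds_per_game = 1,
                         games = 1)
  ps <- vapply(1:20, function(k) run_game(params, seed = k)$final_mean_p,
               numeric(1))
  se <- sqrt(1 / 12 / (100 * 20))
  expect_lt(abs(mean(ps) - 0.5), 3 * se)
})

test_that("block simulation and stepwise iteration agree in distribution", {
  # same engine core, different slicing of the random stream: compare mean
  # round-end fitness and capacity across replicates
  params <- tiny_params(N = 4, S = 4, R = 0.5, seed = 17,
                        iterations_per_round = 30)
  p_fix <- c(0.9, 0.6, 0.3, 0.1)
  nrep <- 150
  block <- step <- matrix(NA_real_, nrep, 2)
  for (k in seq_len(nrep)) {
    pop <- fixed_population(p_fix, S = 4)
    set.seed(derive_seed(100, k))
    rr <- run_round(pop, params)
    block[k, ] <- c(mean(rr$population$fitness), rr$per_group_capacity)

    pop <- fixed_population(p_fix, S = 4)
    set.seed(derive_seed(200, k))
    for (t in 1:30) pop <- run_iteration(pop, params)$population
    step[k, ] <- c(mean(pop$fitness), pop$capacity)
  }
  for (col in 1:2) {
    se <- sqrt(var(block[, col]) / nrep + var(step[, col]) / nrep)
    z <- (mean(block[, col]) - mean(step[, col])) / se
    expect_lt(abs(z), 4)
  }
})

test_that("evolved groups of equal size are statistically exchangeable", {
  params <- crowd_params(N = 20, S = 10, R = 0.8, seed = 41,
                         iterations_per_round = 50, rounds_per_game = 30,
                         games = 1)
  caps <- t(vapply(1:12, function(k) run_game(params, seed = k)$final_capacity,
                   numeric(2)))
  se <- sqrt(var(caps[, 1]) / nrow(caps) + var(caps[, 2]) / nrow(caps))
  z <- (mean(caps[, 1]) - mean(caps[, 2])) / max(se, 1e-12)
  expect_lt(abs(z), 4)
})
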