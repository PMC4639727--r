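#' Closed-form expectations for one iteration
#'
#' Exact per-iteration expectations for a group with fixed collaboration
#' probabilities `p` and capacity, under the engine's scoring rule:
#' * capacity increments with probability `1 - prod(1 - p_i * R)`;
#' * the expected shared gain per member is `(capacity + 1) / S * R *
#'   sum(p)` — valid because the shared gain is `s * capacity_new / S` and
#'   `capacity_new = capacity + 1` exactly on the event `s >= 1`;
#' * player `i`'s expected private gain is `(1 - p_i) *
#'   expected_individual_gain(R)`.
#'
#' @param p Collaboration probabilities of the group's players.
#' @param R Task simplicity.
#' @param capacity Group capacity at the start of the iteration.
#' @param G_min,G_max Integer gain range.
#' @return List with `increment_prob`, `shared_gain`, `own_gain` (per
#'   player), and `expected_solvers = R * sum(p)`.
#' @export
exact_iteration_expectations <- function(p, R, capacity = 0,
                                         G_min = 1L, G_max = 10L) {
  S <- length(p)
  stopifnot(S >= 1, R >= 0, R <= 1)
  list(
    increment_prob = 1 - prod(1 - p * R),
    shared_gain = (capacity + 1) / S * R * sum(p),
    own_gain = (1 - p) * expected_individual_gain(R, G_min, G_max),
    expected_solvers = R * sum(p)
  )
}

#' Monte-Carlo certification of the engine against closed forms
#'
#' Freezes a random group configuration (`p ~ U[0,1]`, a fixed starting
#' capacity), pushes `n_samples` independent single iterations through the
#' engine core, and compares the Monte-Carlo means against
#' [exact_iteration_expectations()]: capacity-increment frequency, shared
#' gain per member, mean private gain per player, solver count (role
#' sampling times solving), and the mean of the drawn gains. Each
#' comparison is summarized as a z-score; `pass` is `|z| <= z_threshold`.
#' With `n_samples = 0` the estimates are undefined and `pass` is `NA`.
#'
#' @param params A [crowd_params] object; `S <= 10` keeps the closed forms
#'   cheap and the Monte-Carlo error small.
#' @param n_samples Independent iterations to realize.
#' @param capacity0 Frozen capacity during the replicated iterations.
#' @param z_threshold Pass threshold on `|z|`.
#' @param seed Seed for both the frozen configuration and the replicates.
#' @return A data frame of class `oracle_report` with columns `quantity`,
#'   `analytic`, `estimate`, `std_error`, `z`, `pass`.
#' @export
oracle_suite <- function(params, n_samples = 1e5, capacity0 = 7L,
                         z_threshold = 3, seed = params$seed) {
  stopifnot(inherits(params, "crowd_params"))
  set.seed(derive_seed(seed, 104729L))
  p <- stats::runif(params$S)
  ex <- exact_iteration_expectations(p, params$R, capacity0,
                                     params$G_min, params$G_max)
  n <- as.integer(n_samples)
  if (n > 0) {
    res <- group_iterations(p, n, params$R, params$G_min, params$G_max,
                            capacity0 = capacity0, cumulative = FALSE,
                            detail = TRUE)
    shared <- res$solver_count * res$capacity / params$S
    own_per_sample <- colMeans(res$own_gain)    # mean over players
    n_coll <- colSums(res$collectivist)
    drawn <- res$gain[!res$collectivist]
    mc <- list(
      increment_prob = as.numeric(res$incremented),
      shared_gain = shared,
      own_gain = own_per_sample,
      solver_count = as.numeric(res$solver_count),
      collectivist_count = n_coll
    )
  }
  specs <- list(
    list("capacity increment probability", ex$increment_prob,
         "increment_prob"),
    list("shared gain per member", ex$shared_gain, "shared_gain"),
    list("mean private gain per player", mean(ex$own_gain), "own_gain"),
    list("solving collectivists per iteration", ex$expected_solvers,
         "solver_count"),
    list("collectivist count per iteration", sum(p), "collectivist_count")
  )
  rows <- lapply(specs, function(sp) {
    if (n == 0)
      return(data.frame(quantity = sp[[1]], analytic = sp[[2]],
                        estimate = NA_real_, std_error = NA_real_,
                        z = NA_real_, pass = NA))
    x <- mc[[sp[[3]]]]
    se <- stats::sd(x) / sqrt(n)
    est <- mean(x)
    z <- if (se == 0) ifelse(est == sp[[2]], 0, Inf) else (est - sp[[2]]) / se
    data.frame(quantity = sp[[1]], analytic = sp[[2]], estimate = est,
               std_error = se, z = z, pass = abs(z) <= z_threshold)
  })
  gain_row <- if (n > 0 && length(drawn) > 1) {
    se <- stats::sd(drawn) / sqrt(length(drawn))
    est <- mean(drawn)
    target <- (params$G_min + params$G_max) / 2
    z <- if (se == 0) ifelse(est == target, 0, Inf) else (est - target) / se
    data.frame(quantity = "mean drawn gain G", analytic = target,
               estimate = est, std_error = se, z = z,
               pass = abs(z) <= z_threshold)
  } else {
    data.frame(quantity = "mean drawn gain G",
               analytic = (params$G_min + params$G_max) / 2,
               estimate = NA_real_, std_error = NA_real_, z = NA_real_,
               pass = NA)
  }
  out <- rbind(do.call(rbind, rows), gain_row)
  attr(out, "p") <- p
  attr(out, "n_samples") <- n
  class(out) <- c("oracle_report", "data.frame")
  out
}

#' @export
print.oracle_report <- function(x, ...) {
  cat(sprintf("oracle report (%s samples, S = %d)\n",
              format(attr(x, "n_samples"), big.mark = ","),
              length(attr(x, "p"))))
  df <- as.data.frame(x)
  df$analytic <- signif(df$analytic, 5)
  df$estimate <- signif(df$estimate, 5)
  df$std_error <- signif(df$std_error, 3)
  df$z <- round(df$z, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Run the oracle suite over several random configurations
#'
#' Configurations draw `S ~ U{1..S_max}` and `R ~ U[0.05, 1]`; the lower
#' bound on `R` keeps the capacity-increment event frequent enough that a
#' normal z-test at `n_samples` draws is valid (the near-zero corner is
#' covered deterministically by the engine unit tests).
#'
#' @param n_configs Number of random (S, R) configurations.
#' @param n_samples Samples per configuration.
#' @param S_max Maximal group size tried.
#' @param seed Root seed.
#' @return A data frame stacking the individual reports, with a `config`
#'   column.
#' @export
oracle_sweep <- function(n_configs = 10, n_samples = 1e5, S_max = 10,
                         seed = 0L) {
  rows <- lapply(seq_len(n_configs), function(k) {
    set.seed(derive_seed(seed, 7919L, k))
    S <- sample.int(S_max, 1)
    R <- stats::runif(1, 0.05, 1)
    pr <- crowd_params(N = S, S = S, R = R, seed = derive_seed(seed, k))
    rep <- oracle_suite(pr, n_samples = n_samples,
                        capacity0 = sample.int(20, 1),
                        seed = derive_seed(seed, k, 2L))
    cbind(config = k, S = S, R = R, as.data.frame(rep))
  })
  do.call(rbind, rows)
}
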