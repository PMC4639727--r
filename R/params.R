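#' Simulation parameters
#'
#' Construct and validate the full parameter set of a crowdsourcing
#' simulation: a population of `N` players split into `N/S` groups of equal
#' size `S`, facing tasks of simplicity `R`. Defaults follow the reference
#' protocol: private gains `G` drawn uniformly from 1..10, rounds of 1000
#' iterations, games of 2000 rounds, 20 games per condition, and replacement
#' of 20% of the below-average players between rounds.
#'
#' @param N Total number of players (positive integer).
#' @param S Group size; must divide `N` exactly.
#' @param R Task simplicity, a probability in (0, 1]. A collectivist solves
#'   the common task with probability `R`; an individualist who drew gain `G`
#'   solves a `G`-times-harder task, with probability `R^G`.
#' @param G_min,G_max Inclusive bounds of the uniform integer gain drawn by
#'   each individualist every iteration.
#' @param iterations_per_round Iterations in one round (scoring horizon
#'   between two selection events).
#' @param rounds_per_game Rounds in one game; selection is applied at the
#'   start of every round after the first.
#' @param games Number of independent games averaged per condition by the
#'   grid experiments.
#' @param replacement_fraction Fraction of `N` replaced between rounds
#'   (capped by the number of players strictly below the mean fitness).
#' @param seed Non-negative integer root seed; all randomness in a run is
#'   derived deterministically from it.
#'
#' @return An object of class `crowd_params`: a validated list with the above
#'   fields plus `n_groups = N/S`.
#' @examples
#' p <- crowd_params(N = 100, S = 25, R = 0.5, seed = 1)
#' p$n_groups  # 4
#' @export
crowd_params <- function(N, S, R,
                         G_min = 1L, G_max = 10L,
                         iterations_per_round = 1000L,
                         rounds_per_game = 2000L,
                         games = 20L,
                         replacement_fraction = 0.2,
                         seed = 0L) {
  check_count <- function(x, name, min = 1) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min ||
        x != floor(x))
      stop(sprintf("'%s' must be a single integer >= %s (got %s)",
                   name, min, deparse(x)), call. = FALSE)
    as.integer(x)
  }
  N <- check_count(N, "N")
  S <- check_count(S, "S")
  G_min <- check_count(G_min, "G_min")
  G_max <- check_count(G_max, "G_max")
  iterations_per_round <- check_count(iterations_per_round,
                                      "iterations_per_round", min = 0)
  rounds_per_game <- check_count(rounds_per_game, "rounds_per_game")
  games <- check_count(games, "games")
  seed <- check_count(seed, "seed", min = 0)
  if (N %% S != 0)
    stop(sprintf("group size S = %d does not divide N = %d: %d %%%% %d = %d",
                 S, N, N, S, N %% S), call. = FALSE)
  if (length(R) != 1 || !is.numeric(R) || is.na(R) || R <= 0 || R > 1)
    stop(sprintf("task simplicity R must lie in (0, 1], got %s",
                 deparse(R)), call. = FALSE)
  if (G_min > G_max)
    stop(sprintf("G_min (%d) must not exceed G_max (%d)", G_min, G_max),
         call. = FALSE)
  if (length(replacement_fraction) != 1 || !is.numeric(replacement_fraction) ||
      is.na(replacement_fraction) ||
      replacement_fraction < 0 || replacement_fraction > 1)
    stop("replacement_fraction must lie in [0, 1]", call. = FALSE)
  structure(list(
    N = N, S = S, R = as.numeric(R),
    G_min = G_min, G_max = G_max,
    iterations_per_round = iterations_per_round,
    rounds_per_game = rounds_per_game,
    games = games,
    replacement_fraction = as.numeric(replacement_fraction),
    seed = seed,
    n_groups = N %/% S
  ), class = "crowd_params")
}

#' @export
print.crowd_params <- function(x, ...) {
  cat(sprintf(
    "crowd_params: N=%d players in %d group(s) of S=%d, R=%g\n",
    x$N, x$n_groups, x$S, x$R))
  cat(sprintf("  gains G ~ U{%d..%d}; %d iterations/round, %d rounds/game, %d game(s)\n",
              x$G_min, x$G_max, x$iterations_per_round, x$rounds_per_game,
              x$games))
  cat(sprintf("  replacement fraction %g, seed %d\n",
              x$replacement_fraction, x$seed))
  invisible(x)
}

.param_keys <- c("N", "S", "R", "G_min", "G_max", "iterations_per_round",
                 "rounds_per_game", "games", "replacement_fraction", "seed")

#' Build parameters from a raw configuration mapping
#'
#' Accepts a named list (e.g. parsed from a YAML or JSON config file) with
#' keys among `N, S, R, G_min, G_max, iterations_per_round, rounds_per_game,
#' games, replacement_fraction, seed`. `N`, `S`, `R` and `seed` are required;
#' everything else takes the protocol default. Unknown keys are an error.
#'
#' @param raw Named list of configuration values.
#' @return A [crowd_params] object.
#' @export
make_params <- function(raw) {
  if (!is.list(raw) || (length(raw) > 0 && is.null(names(raw))))
    stop("configuration must be a named list", call. = FALSE)
  unknown <- setdiff(names(raw), .param_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  required <- c("N", "S", "R", "seed")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing required configuration key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  do.call(crowd_params, raw)
}

#' Read a simulation configuration file
#'
#' Parses a YAML (`.yml`/`.yaml`) or JSON (`.json`) file into validated
#' parameters via [make_params()].
#'
#' @param path Path to the configuration file.
#' @return A [crowd_params] object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    "yml"  = ,
    "yaml" = yaml::read_yaml(path),
    stop("unsupported config extension '", ext, "' (use yaml or json)",
         call. = FALSE))
  make_params(as.list(raw))
}

#' Apply a budget preset
#'
#' `"paper"` restores the full protocol budgets (1000 iterations, 2000
#' rounds, 20 games); `"desk"` is the scaled-down budget used for fast,
#' qualitative reproduction (200 iterations, 200 rounds, 5 games).
#'
#' @param params A [crowd_params] object.
#' @param preset `"desk"` or `"paper"`.
#' @return A [crowd_params] object with the budget fields replaced.
#' @export
apply_preset <- function(params, preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  budgets <- switch(preset,
    desk  = list(iterations_per_round = 200L, rounds_per_game = 200L,
                 games = 5L),
    paper = list(iterations_per_round = 1000L, rounds_per_game = 2000L,
                 games = 20L))
  p <- unclass(params)[.param_keys]
  p[names(budgets)] <- budgets
  do.call(crowd_params, p)
}

#' Derive a child seed from a root seed
#'
#' Deterministically mixes a root seed with any number of integer labels
#' (game index, group size, scaled R, ...) into a seed in
#' `[0, 2^31 - 2]`, so that independent simulation cells get independent,
#' reproducible random streams. The fold is a Lehmer-style multiply-add
#' modulo the Mersenne prime 2^31 - 1, exact in double precision.
#'
#' @param seed Non-negative integer root seed.
#' @param ... Integer-valued labels identifying the child stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  labs <- c(seed, ...)
  m <- 2147483647
  h <- 17
  for (x in labs) {
    x <- as.numeric(x) %% m
    h <- (h * 69069 + x + 1) %% m
  }
  as.integer(h)
}
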