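#' Initialize a population
#'
#' Creates `N/S` groups of `S` players. Every player gets a collaboration
#' probability `p` drawn independently and uniformly on \[0, 1\]; `p` is fixed
#' for the player's lifetime and only replacement introduces new values. All
#' fitness values and group capacities start at 0. Randomness is taken from
#' R's global stream; seed it (or let [run_game()] do so) for reproducibility.
#'
#' @param params A [crowd_params] object.
#' @return An object of class `crowd_population`: a list with per-player
#'   vectors `p`, `fitness`, `group` (group index, players stored
#'   group-contiguously) and the per-group integer vector `capacity`.
#' @export
init_population <- function(params) {
  stopifnot(inherits(params, "crowd_params"))
  n <- params$n_groups
  structure(list(
    p = stats::runif(params$N),
    fitness = numeric(params$N),
    group = rep(seq_len(n), each = params$S),
    capacity = integer(n),
    N = params$N, S = params$S, n_groups = n
  ), class = "crowd_population")
}

#' @export
print.crowd_population <- function(x, ...) {
  cat(sprintf("crowd_population: %d players, %d group(s) of %d\n",
              x$N, x$n_groups, x$S))
  cat(sprintf("  mean p = %.4f, mean fitness = %.4f, capacities: %s\n",
              mean(x$p), mean(x$fitness),
              paste(utils::head(x$capacity, 8), collapse = " ")))
  invisible(x)
}

#' Draw individualist gains
#'
#' Draws `n` desired gains, each an integer uniform on
#' `G_min..G_max`. An individualist who drew gain `G` attempts a `G`-times
#' harder task (success probability `R^G`) for a private payoff of `G`.
#'
#' @param n Number of draws.
#' @param params A [crowd_params] object (supplies `G_min`, `G_max`).
#' @return Integer vector of length `n`.
#' @export
draw_gain <- function(n, params) {
  stopifnot(inherits(params, "crowd_params"))
  if (n == 0) return(integer(0))
  sample.int(params$G_max - params$G_min + 1L, n, replace = TRUE) +
    params$G_min - 1L
}

#' Sample collectivist/individualist roles for one group
#'
#' Each player independently joins the collectivists with their own
#' probability `p`, otherwise plays the iteration alone as an individualist.
#'
#' @param p Vector of collaboration probabilities of the group's players.
#' @return Logical vector, `TRUE` for collectivists.
#' @export
sample_roles <- function(p) {
  if (length(p) == 0) stop("group is empty", call. = FALSE)
  stats::runif(length(p)) < p
}

#' Probability of solving the task
#'
#' A collectivist solves the common task with probability `R`. An
#' individualist who drew gain `G` faces a `G`-times harder task, modelled
#' as `G` independent sub-tasks of simplicity `R`, hence success probability
#' `R^G` (larger `G` means a smaller chance of solving).
#'
#' @param role `"collectivist"` or `"individualist"`.
#' @param R Task simplicity in (0, 1].
#' @param G Drawn gain (required for individualists; integer >= 1).
#' @return Success probability in \[0, 1\].
#' @export
solve_probability <- function(role = c("collectivist", "individualist"),
                              R, G = NULL) {
  role <- match.arg(role)
  if (role == "collectivist") return(R)
  if (is.null(G)) stop("individualist requires a drawn gain G", call. = FALSE)
  if (any(G < 1)) stop("G must be >= 1", call. = FALSE)
  R^G
}
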