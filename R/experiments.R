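#' Default grids of group size and task simplicity
#'
#' The protocol grid for `N = 100`: seven group sizes dividing 100 and
#' thirteen task simplicities (exponential spacing at the hard end, linear
#' at the easy end).
#' @name default_grid
NULL

#' @rdname default_grid
#' @export
default_S_values <- function() c(1L, 2L, 5L, 10L, 25L, 50L, 100L)

#' @rdname default_grid
#' @export
default_R_values <- function()
  c(0.0001, 0.001, 0.01, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1)

#' Run the (S, R) grid experiment
#'
#' For every combination of group size and task simplicity, runs
#' `params$games` independent games and averages the game-end summaries:
#' mean collaboration probability, last-round mean fitness, and the reached
#' capacity (averaged over the game's groups — evolved groups of a given
#' size are statistically equivalent — then over games). Per-game seeds are
#' hashed from the base seed, the cell's `S`, its `R` and the game index, so
#' every cell's stream is independent of which other cells are requested.
#'
#' @param params Base [crowd_params]; its `S` and `R` are overridden cell by
#'   cell, its `seed` is the root of all per-game seeds.
#' @param S_values Group sizes to sweep; each must divide `params$N`.
#' @param R_values Task simplicities to sweep.
#' @param verbose Print one progress line per cell to standard error?
#' @return A data frame (class `crowd_surface`) with one row per (S, R):
#'   columns `S, R, mean_p, mean_fitness, capacity_max, games, seed`.
#' @export
run_grid <- function(params,
                     S_values = default_S_values(),
                     R_values = default_R_values(),
                     verbose = FALSE) {
  stopifnot(inherits(params, "crowd_params"))
  bad <- S_values[params$N %% S_values != 0]
  if (length(bad))
    stop("group size(s) not dividing N = ", params$N, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  rows <- vector("list", length(S_values) * length(R_values))
  i <- 0L
  for (S in S_values) {
    for (R in R_values) {
      cell <- crowd_params(N = params$N, S = S, R = R,
                           G_min = params$G_min, G_max = params$G_max,
                           iterations_per_round = params$iterations_per_round,
                           rounds_per_game = params$rounds_per_game,
                           games = params$games,
                           replacement_fraction = params$replacement_fraction,
                           seed = params$seed)
      mp <- mf <- cm <- numeric(params$games)
      for (g in seq_len(params$games)) {
        gs <- derive_seed(params$seed, S, round(R * 1e6), g)
        res <- run_game(cell, seed = gs)
        mp[g] <- res$final_mean_p
        mf[g] <- res$final_mean_fitness
        cm[g] <- res$capacity_mean
      }
      i <- i + 1L
      rows[[i]] <- data.frame(S = S, R = R,
                              mean_p = mean(mp),
                              mean_fitness = mean(mf),
                              capacity_max = mean(cm),
                              games = params$games,
                              seed = params$seed)
      if (verbose)
        message(sprintf("cell S=%3d R=%.4f: mean_p=%.3f mean_fitness=%.2f capacity=%.1f",
                        S, R, mean(mp), mean(mf), mean(cm)))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("crowd_surface", "data.frame")
  out
}

#' Optimal group size at a given task simplicity
#'
#' Returns the group size maximizing the chosen criterion along the `S`
#' profile at task simplicity `R`; ties break toward the smaller size.
#'
#' @param surface A surface table from [run_grid()].
#' @param R Task simplicity of the profile (matched within 1e-9).
#' @param criterion `"mean_fitness"` or `"capacity_max"`.
#' @return The optimal group size (integer).
#' @export
find_optimal_size <- function(surface, R,
                              criterion = c("mean_fitness", "capacity_max")) {
  criterion <- match.arg(criterion)
  all_S <- sort(unique(surface$S))
  prof <- surface[abs(surface$R - R) < 1e-9, , drop = FALSE]
  missing <- setdiff(all_S, prof$S)
  if (length(missing))
    stop("surface is missing cells at R = ", R, " for S = ",
         paste(missing, collapse = ", "), call. = FALSE)
  prof <- prof[order(prof$S), , drop = FALSE]
  prof$S[which.max(prof[[criterion]])]
}

#' Scan the optimal group size across population sizes
#'
#' For each population size `N`, sweeps the divisors of `N` (or a supplied
#' candidate set) at fixed task simplicity `R` and reports the optimal group
#' size and its ratio to `N`. The evolved optimum sits near `N/2` across
#' population sizes.
#'
#' @param N_values Population sizes to scan.
#' @param R Task simplicity (high values make the optimum sharp).
#' @param params Base [crowd_params] providing budgets and seed.
#' @param criterion Passed to [find_optimal_size()].
#' @param S_candidates Optional list (parallel to `N_values`) of candidate
#'   group sizes; default: all divisors of each `N`.
#' @return Data frame with columns `N`, `S_opt`, `ratio`.
#' @export
robustness_scan <- function(N_values, R, params,
                            criterion = c("mean_fitness", "capacity_max"),
                            S_candidates = NULL) {
  criterion <- match.arg(criterion)
  rows <- lapply(seq_along(N_values), function(i) {
    N <- N_values[i]
    cand <- if (is.null(S_candidates)) {
      d <- seq_len(N)
      d[N %% d == 0]
    } else S_candidates[[i]]
    base <- crowd_params(N = N, S = cand[1], R = R,
                         G_min = params$G_min, G_max = params$G_max,
                         iterations_per_round = params$iterations_per_round,
                         rounds_per_game = params$rounds_per_game,
                         games = params$games,
                         replacement_fraction = params$replacement_fraction,
                         seed = derive_seed(params$seed, N))
    surf <- run_grid(base, S_values = cand, R_values = R)
    s_opt <- find_optimal_size(surf, R, criterion)
    data.frame(N = N, S_opt = s_opt, ratio = s_opt / N)
  })
  do.call(rbind, rows)
}

#' Monotonic-trend summary of the collaboration surface
#'
#' For each profile of the surface along the requested axis (holding the
#' other axis fixed), computes the Spearman rank correlation of `mean_p`
#' with the axis variable and its sign. Profiles with fewer than three
#' points, are reported as `NA` (undefined); perfectly flat profiles get
#' correlation and sign 0.
#'
#' @param surface A surface table from [run_grid()].
#' @param axis `"R"` (trend in task simplicity, one row per `S`) or `"S"`.
#' @return Data frame with the fixed-axis value, `rho`, `sign` and
#'   `n_points`.
#' @export
trend_summary <- function(surface, axis = c("R", "S")) {
  axis <- match.arg(axis)
  fixed <- setdiff(c("S", "R"), axis)
  rows <- lapply(sort(unique(surface[[fixed]])), function(v) {
    prof <- surface[surface[[fixed]] == v, , drop = FALSE]
    n <- nrow(prof)
    if (n < 3) {
      rho <- NA_real_
    } else if (stats::sd(prof$mean_p) == 0) {
      rho <- 0
    } else {
      rho <- stats::cor(prof[[axis]], prof$mean_p, method = "spearman")
    }
    out <- data.frame(v, rho = rho, sign = sign(rho), n_points = n)
    names(out)[1] <- fixed
    out
  })
  do.call(rbind, rows)
}
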