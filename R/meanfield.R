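#' Expected private gain of a lone individualist
#'
#' An individualist draws an integer gain `G` uniformly on `G_min..G_max`
#' and solves with probability `R^G`, so the per-iteration expected own gain
#' is `mean(g * R^g)` over the range. Zero at `R = 0`; equal to the plain
#' mean of the range at `R = 1`; monotone non-decreasing in `R`.
#'
#' @param R Task simplicity in \[0, 1\].
#' @param G_min,G_max Integer gain range.
#' @return Expected gain per iteration.
#' @export
expected_individual_gain <- function(R, G_min = 1L, G_max = 10L) {
  if (G_min > G_max) stop("G_min must not exceed G_max", call. = FALSE)
  g <- seq.int(G_min, G_max)
  vapply(R, function(r) mean(g * r^g), numeric(1))
}

#' Mean-field fitness of a collectivist
#'
#' Treating the group's capacity as quasi-static and the collectivist
#' density as `alpha`, a collectivist's expected per-iteration gain is the
#' expected number of solving collectivists (`alpha * S * R`) times the
#' per-solver share (`capacity / S`), i.e. `alpha * R * capacity`.
#'
#' @param alpha Collectivist density in \[0, 1\].
#' @param R Task simplicity.
#' @param S Group size.
#' @param capacity Current group capacity (continuous in the mean field).
#' @return Expected gain per iteration.
#' @export
expected_collectivist_fitness <- function(alpha, R, S, capacity) {
  alpha * R * capacity
}

#' Mean-field fitness of an individualist (free-rider)
#'
#' A defector still receives the shared gains generated by the `alpha *
#' (S - 1)` collectivists among the other players — `(capacity / S) * alpha
#' * (S - 1) * R` per iteration — and adds the expected private gain of
#' working alone, [expected_individual_gain()].
#'
#' @inheritParams expected_collectivist_fitness
#' @param G_min,G_max Integer gain range.
#' @return Expected gain per iteration.
#' @export
expected_defector_fitness <- function(alpha, R, S, capacity,
                                      G_min = 1L, G_max = 10L) {
  (capacity / S) * alpha * (S - 1) * R +
    expected_individual_gain(R, G_min, G_max)
}

#' Capacity advantage needed for cooperation to win
#'
#' Minimal capacity lead `delta = capacity_l - capacity_j` at which an
#' all-collectivist group `l` out-earns the single free-rider of a group `j`
#' that is otherwise all-collectivist. In the large-group regime the
#' defector's shared receipts approach a full share, leaving `delta =
#' expected_individual_gain(R) / R`. For single-player groups (`S = 1`) the
#' defector earns only its private gain, so the threshold is the smallest
#' integer capacity with `R * capacity > expected_individual_gain(R)`.
#' Both thresholds are monotone non-decreasing in `R`.
#'
#' @param R Task simplicity in (0, 1]; `R = 0` leaves the threshold
#'   undefined and is an error.
#' @param regime `"large_S"` (continuous threshold) or `"unit_S"` (integer
#'   capacity threshold for S = 1).
#' @param G_min,G_max Integer gain range.
#' @return The capacity gap threshold.
#' @export
capacity_gap_threshold <- function(R, regime = c("large_S", "unit_S"),
                                   G_min = 1L, G_max = 10L) {
  regime <- match.arg(regime)
  if (any(R <= 0))
    stop("capacity gap threshold is undefined at R = 0 (no task is ever solved)",
         call. = FALSE)
  ratio <- expected_individual_gain(R, G_min, G_max) / R
  switch(regime,
         large_S = ratio,
         unit_S  = floor(ratio) + 1)
}

#' Mean-field threshold table over an R grid
#'
#' @param R_values Task simplicities (each in (0, 1]).
#' @param G_min,G_max Integer gain range.
#' @return Data frame with columns `R`, `delta_large_S`, `delta_unit_S`.
#' @export
mean_field_table <- function(R_values, G_min = 1L, G_max = 10L) {
  data.frame(
    R = R_values,
    delta_large_S = capacity_gap_threshold(R_values, "large_S", G_min, G_max),
    delta_unit_S = capacity_gap_threshold(R_values, "unit_S", G_min, G_max)
  )
}
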