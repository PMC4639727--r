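#' Write a surface table as CSV
#'
#' Columns exactly `S,R,mean_p,mean_fitness,capacity_max,games,seed`, header
#' row, '.' decimal separator, UTF-8, no row names.
#'
#' @param surface A surface table from [run_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surface_csv <- function(surface, path) {
  cols <- c("S", "R", "mean_p", "mean_fitness", "capacity_max", "games",
            "seed")
  stopifnot(all(cols %in% names(surface)))
  utils::write.csv(as.data.frame(surface)[cols], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a surface table written by [write_surface_csv()]
#'
#' @param path CSV path.
#' @return A `crowd_surface` data frame.
#' @export
read_surface_csv <- function(path) {
  out <- utils::read.csv(path, fileEncoding = "UTF-8")
  class(out) <- c("crowd_surface", "data.frame")
  out
}

#' Write a run manifest
#'
#' Records everything needed to reproduce an output file bit-for-bit: the
#' fully resolved parameters, the derived per-game seeds, the package
#' version, timestamps and the output paths. Written as pretty JSON next to
#' the data.
#'
#' @param path Manifest path (`.json`).
#' @param params The resolved [crowd_params].
#' @param outputs Character vector of produced data files.
#' @param seeds Optional integer vector of derived per-game/cell seeds.
#' @param started,finished POSIXct timestamps.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, params, outputs, seeds = NULL,
                           started = Sys.time(), finished = Sys.time()) {
  manifest <- list(
    package = "crowdsolve",
    version = as.character(utils::packageVersion("crowdsolve")),
    params = unclass(params),
    seeds = seeds,
    outputs = outputs,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Serialize a game result as JSON
#'
#' @param game A `crowd_game` object.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_game_json <- function(game, path) {
  stopifnot(inherits(game, "crowd_game"))
  out <- list(
    final_mean_p = game$final_mean_p,
    final_mean_fitness = game$final_mean_fitness,
    final_capacity = game$final_capacity,
    capacity_mean = game$capacity_mean,
    p = game$p,
    params = unclass(game$params),
    seed = game$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
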