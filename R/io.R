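#' Serialize a world history to a directory
#'
#' Writes `points.csv` (long format), one `grid_<slice>.csv` per slice
#' (long format: `lat`, `lon`, `class`, `age`) and a `config.yaml` echo.
#'
#' @param world A `world_history`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(world$points, file.path(dir, "points.csv"),
                   row.names = FALSE)
  for (s in seq_along(world$grids)) {
    g <- world$grids[[s]]
    df <- data.frame(
      lat = rep(world$lat_centers, times = length(world$lon_centers)),
      lon = rep(world$lon_centers, each = length(world$lat_centers)),
      class = as.vector(g$class), age = as.vector(g$age))
    utils::write.csv(df, file.path(dir, sprintf("grid_%03d.csv", s)),
                     row.names = FALSE)
  }
  cfg <- world$config
  cfg_list <- unclass(cfg)
  yaml::write_yaml(cfg_list, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a world history from a directory written by [write_world()]
#'
#' @param dir Directory containing `points.csv`, `grid_*.csv`,
#'   `config.yaml`.
#' @return A `world_history`.
#' @export
read_world <- function(dir) {
  cfg_list <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg <- structure(cfg_list, class = "world_config")
  cfg$n_slices <- as.integer(cfg$n_slices)
  points <- utils::read.csv(file.path(dir, "points.csv"),
                            stringsAsFactors = FALSE)
  res <- cfg$grid_resolution
  nlat <- as.integer(round(180 / res))
  nlon <- as.integer(round(360 / res))
  grids <- vector("list", cfg$n_slices)
  for (s in seq_len(cfg$n_slices)) {
    df <- utils::read.csv(file.path(dir, sprintf("grid_%03d.csv", s)),
                          stringsAsFactors = FALSE)
    grids[[s]] <- list(class = matrix(df$class, nlat, nlon),
                       age = matrix(df$age, nlat, nlon))
  }
  ages <- cfg$start_age - (seq_len(cfg$n_slices) - 1) * cfg$slice_spacing
  structure(list(config = cfg, slice_ages = ages, points = points,
                 grids = grids,
                 lat_centers = row_to_lat(seq_len(nlat), res),
                 lon_centers = col_to_lon(seq_len(nlon), res)),
            class = "world_history")
}

#' Read or write an extinction schedule as CSV
#'
#' The file has columns `start_ma`, `duration_myr`, `loss_fraction`.
#'
#' @param file Path to the CSV file.
#' @return [read_extinctions()] returns an `extinction_schedule`.
#' @export
read_extinctions <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  make_extinction_schedule(data.frame(start_age = df$start_ma,
                                      duration = df$duration_myr,
                                      loss_fraction = df$loss_fraction))
}

#' @rdname read_extinctions
#' @param schedule An `extinction_schedule`.
#' @export
write_extinctions <- function(schedule, file) {
  utils::write.csv(data.frame(start_ma = schedule$start_age,
                              duration_myr = schedule$duration,
                              loss_fraction = schedule$loss_fraction),
                   file, row.names = FALSE)
  invisible(file)
}

#' Read or write model parameters as YAML
#'
#' Keys: `rho_min`, `rho_max`, `q10`, `k_food`, `k_min`, `k_max`,
#' `ode_step_myr`, `model` (`logistic` or `exponential`).
#'
#' @param file Path to the YAML file.
#' @return [read_params()] returns a [model_params()] object.
#' @export
read_params <- function(file) {
  y <- yaml::read_yaml(file)
  model_params(rho_min = y$rho_min, rho_max = y$rho_max, q10 = y$q10,
               k_food = y$k_food, k_min = y$k_min, k_max = y$k_max,
               ode_step = if (is.null(y$ode_step_myr)) 1 else y$ode_step_myr,
               model_kind = if (is.null(y$model)) "logistic" else y$model)
}

#' @rdname read_params
#' @param params A [model_params()] object.
#' @export
write_params <- function(params, file) {
  yaml::write_yaml(list(rho_min = params$rho_min, rho_max = params$rho_max,
                        q10 = params$q10, k_food = params$k_food,
                        k_min = params$k_min, k_max = params$k_max,
                        ode_step_myr = params$ode_step,
                        model = params$model_kind), file)
  invisible(file)
}

#' Write a diversity history as CSV
#'
#' Columns `point_id`, `slice`, `age_ma`, `D`, `k_eff`, `rho`.
#'
#' @param history A `diversity_history`.
#' @param file Output path.
#' @export
write_diversity <- function(history, file) {
  utils::write.csv(history[, c("point_id", "slice", "age_ma", "D",
                               "k_eff", "rho")], file, row.names = FALSE)
  invisible(file)
}

#' Write a global diversity curve as CSV
#'
#' Columns `age_ma`, `gamma_total`, `n_transects`.
#'
#' @param curve A `global_curve`.
#' @param file Output path.
#' @export
write_global_curve <- function(curve, file) {
  utils::write.csv(curve[, c("age_ma", "gamma_total", "n_transects")],
                   file, row.names = FALSE)
  invisible(file)
}

#' Read a reference diversity curve
#'
#' @param file CSV file with columns `age_ma` and `diversity`.
#' @return Data frame with `age_ma`, `diversity`.
#' @export
read_fossil_curve <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("age_ma", "diversity") %in% names(df)))
    stop("reference curve needs columns age_ma and diversity", call. = FALSE)
  df
}
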