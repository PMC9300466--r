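# Shared fixtures, all built in code.

# Small drifting world for pipeline-level tests.
tiny_config <- function(...) {
  defaults <- list(n_slices = 16, slice_spacing = 5, start_age = 75,
                   grid_resolution = 10, n_continental_points = 30,
                   n_ocean_points = 60, temp_noise_sd = 0.5,
                   poc_noise_sd = 0.2, drift_speed = 1,
                   ridge_birth_rate = 0.05, subduction_rate = 0.05,
                   seed = 7)
  do.call(world_config, utils::modifyList(defaults, list(...)))
}

# Hand-built world with permanently flooded continental points and a
# spatially and temporally constant environment: the ODE oracle substrate.
constant_world <- function(n_slices = 21, spacing = 5, temp = 20, poc = 2,
                           n_points = 1, res = 10) {
  cfg <- world_config(n_slices = n_slices, slice_spacing = spacing,
                      start_age = (n_slices - 1) * spacing,
                      grid_resolution = res,
                      n_continental_points = n_points, n_ocean_points = 0,
                      temp_noise_sd = 0, poc_noise_sd = 0, seed = 1)
  ages <- cfg$start_age - (seq_len(n_slices) - 1) * spacing
  lat <- rep(0, n_points)
  lon <- if (n_points == 1) 5 else seq(-170, 170, length.out = n_points)
  grd <- expand.grid(slice = seq_len(n_slices), point_id = seq_len(n_points))
  pts <- data.frame(point_id = grd$point_id, point_type = "continental",
                    slice = grd$slice, lat = lat[grd$point_id],
                    lon = lon[grd$point_id], class = "flooded_shelf",
                    age = (grd$slice - 1) * spacing, temp = temp, poc = poc,
                    stringsAsFactors = FALSE)
  nlat <- as.integer(180 / res); nlon <- as.integer(360 / res)
  cls <- matrix("ocean", nlat, nlon)
  cls[cbind(phanerodiv:::lat_to_row(lat, res),
            phanerodiv:::lon_to_col(lon, res))] <- "flooded_shelf"
  grids <- rep(list(list(class = cls, age = matrix(NA_real_, nlat, nlon))),
               n_slices)
  structure(list(config = cfg, slice_ages = ages, points = pts,
                 grids = grids,
                 lat_centers = phanerodiv:::row_to_lat(seq_len(nlat), res),
                 lon_centers = phanerodiv:::col_to_lon(seq_len(nlon), res)),
            class = "world_history")
}

# Parameters pinning the rate and carrying capacity to single values, so a
# constant-environment run has a known analytic solution.
pinned_params <- function(rho = 0.035, k = 123, model = "logistic",
                          ode_step = 1) {
  model_params(rho_min = rho, rho_max = rho, k_min = k, k_max = k,
               ode_step = ode_step, model_kind = model)
}

# Analytic solutions.
logistic_closed_form <- function(t, rho, k, d0 = 1) {
  k / (1 + (k / d0 - 1) * exp(-rho * t))
}
exponential_closed_form <- function(t, rho, d0 = 1) d0 * exp(rho * t)

# Assemble a diversity_grid from matrices (full-globe lattice).
make_grid <- function(div, res, class = NULL, age = NULL, age_ma = 0) {
  nlat <- nrow(div); nlon <- ncol(div)
  stopifnot(abs(nlat * res - 180) < 1e-9, abs(nlon * res - 360) < 1e-9)
  if (is.null(class)) class <- matrix("ocean", nlat, nlon)
  if (is.null(age)) age <- matrix(NA_real_, nlat, nlon)
  structure(list(div = div, class = class, age = age,
                 lat_centers = phanerodiv:::row_to_lat(seq_len(nlat), res),
                 lon_centers = phanerodiv:::col_to_lon(seq_len(nlon), res),
                 age_ma = age_ma, slice = 1L),
            class = "diversity_grid")
}

# A minimal integrated transect stub for zigzag tests.
stub_transect <- function(gamma, lat, lon, row = 1L, col = 1L) {
  structure(list(cells = data.frame(row = row, col = col, lat = lat,
                                    lon = lon, alpha = gamma),
                 step_km = numeric(0), length_km = 0, gamma = gamma,
                 peak = list(row = row, col = col, lat = lat, lon = lon)),
            class = "transect")
}
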