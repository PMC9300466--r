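#' Configuration for a synthetic world history
#'
#' Defines the conditions under which [build_world()] generates a synthetic
#' paleogeography: a set of Lagrangian seafloor points (drifting ocean points
#' born at a mid-ocean ridge and lost to subduction; fixed continental points
#' alternating flooded and emergent stints) tracked over evenly spaced time
#' slices, with per-slice seawater temperature and particulate organic carbon
#' (POC) export fields attached to every active point.
#'
#' Defaults emulate a Phanerozoic-type run: 82 slices spanning 541 Myr,
#' a 0.5-degree annotated grid, an equator-to-pole sea-surface temperature
#' gradient of 28 to -2 degrees C, and shelf POC export well above the deep-sea
#' value so that food limitation separates the two habitat classes.
#'
#' @param n_slices Number of time slices (>= 2).
#' @param slice_spacing Spacing between slices in Myr. If `NULL`, computed as
#'   `start_age / (n_slices - 1)` so the run ends at 0 Ma.
#' @param start_age Age of the first (oldest) slice in Ma.
#' @param grid_resolution Cell size of the annotated grid in degrees; must
#'   divide 180 exactly.
#' @param n_continental_points,n_ocean_points Point counts per class.
#' @param temp_equator,temp_pole Sea-surface temperature anchors in degrees C;
#'   the zonal profile is `temp_pole + (temp_equator - temp_pole) * cos(lat)`.
#' @param shelf_poc_mean,ocean_poc_mean Mean POC export flux
#'   (mol C m^-2 yr^-1) for flooded-shelf and open-ocean cells.
#' @param temp_noise_sd Additive per-cell temperature noise (degrees C).
#' @param poc_noise_sd Lognormal sigma of the multiplicative per-cell POC
#'   noise; 0 gives exactly the class mean everywhere.
#' @param drift_speed Ocean-point drift away from the ridge, degrees
#'   longitude per Myr.
#' @param flood_cycle_params List with `mean_flooded` and `mean_emergent`:
#'   mean stint lengths, in slices, of the alternating flooded/emergent
#'   process of continental points (geometric stint lengths).
#' @param ridge_birth_rate Fraction of `n_ocean_points` newly created at the
#'   ridge every slice (at least one point per slice).
#' @param subduction_rate Per-slice probability that an ocean point is
#'   destroyed at a subduction zone.
#' @param ridge_lon Longitude of the mid-ocean ridge meridian, degrees.
#' @param sea_level_band Latitude (degrees) below which empty grid cells are
#'   annotated as ocean; empty cells poleward of it are annotated
#'   continental. The default 90 annotates all empty cells as ocean.
#' @param seed Integer seed; equal configurations with equal seeds yield
#'   field-for-field identical worlds.
#' @return An object of class `world_config`.
#' @seealso [build_world()]
#' @export
world_config <- function(n_slices = 82,
                         slice_spacing = NULL,
                         start_age = 541,
                         grid_resolution = 0.5,
                         n_continental_points = 6000,
                         n_ocean_points = 44000,
                         temp_equator = 28,
                         temp_pole = -2,
                         shelf_poc_mean = 2,
                         ocean_poc_mean = 0.1,
                         temp_noise_sd = 1,
                         poc_noise_sd = 0.3,
                         drift_speed = 0.5,
                         flood_cycle_params = list(mean_flooded = 6,
                                                   mean_emergent = 4),
                         ridge_birth_rate = 0.03,
                         subduction_rate = 0.03,
                         ridge_lon = 0,
                         sea_level_band = 90,
                         seed = 1L) {
  if (is.null(slice_spacing)) slice_spacing <- start_age / (n_slices - 1)
  cfg <- structure(
    list(n_slices = as.integer(n_slices),
         slice_spacing = slice_spacing,
         start_age = start_age,
         grid_resolution = grid_resolution,
         n_continental_points = as.integer(n_continental_points),
         n_ocean_points = as.integer(n_ocean_points),
         temp_equator = temp_equator,
         temp_pole = temp_pole,
         shelf_poc_mean = shelf_poc_mean,
         ocean_poc_mean = ocean_poc_mean,
         temp_noise_sd = temp_noise_sd,
         poc_noise_sd = poc_noise_sd,
         drift_speed = drift_speed,
         flood_cycle_params = flood_cycle_params,
         ridge_birth_rate = ridge_birth_rate,
         subduction_rate = subduction_rate,
         ridge_lon = ridge_lon,
         sea_level_band = sea_level_band,
         seed = as.integer(seed)),
    class = "world_config")
  validate_world_config(cfg)
  cfg
}

validate_world_config <- function(cfg) {
  if (!is.numeric(cfg$n_slices) || cfg$n_slices < 2)
    stop_field("n_slices", "need at least 2 time slices")
  if (cfg$slice_spacing <= 0)
    stop_field("slice_spacing", "must be > 0")
  if (cfg$temp_equator < cfg$temp_pole)
    stop_field("temp_equator", "must be >= temp_pole")
  res <- cfg$grid_resolution
  if (res <= 0 || abs(180 / res - round(180 / res)) > 1e-9)
    stop_field("grid_resolution", "must divide 180 exactly")
  for (f in c("ridge_birth_rate", "subduction_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop_field(f, "must lie in [0, 1]")
  }
  if (cfg$n_continental_points < 0)
    stop_field("n_continental_points", "must be >= 0")
  if (cfg$n_ocean_points < 0)
    stop_field("n_ocean_points", "must be >= 0")
  if (cfg$shelf_poc_mean < 0 || cfg$ocean_poc_mean < 0)
    stop_field("shelf_poc_mean", "POC means must be >= 0")
  fc <- cfg$flood_cycle_params
  if (!is.list(fc) || is.null(fc$mean_flooded) || is.null(fc$mean_emergent) ||
      fc$mean_flooded < 1 || fc$mean_emergent < 1)
    stop_field("flood_cycle_params",
               "need mean_flooded >= 1 and mean_emergent >= 1 (slices)")
  invisible(cfg)
}

## Zonal temperature profile (deg C) at latitude `lat`.
temp_profile <- function(lat, cfg) {
  cfg$temp_pole + (cfg$temp_equator - cfg$temp_pole) * cos(lat * pi / 180)
}

#' Build a synthetic world history
#'
#' Generates the full Lagrangian substrate for the diversification model:
#' point trajectories, flooding histories, seafloor ages, per-slice
#' environments and annotated grids. Deterministic for a fixed
#' `config$seed`; the random stream is consumed in a fixed order
#' (continental placement, continental flood cycles, initial ocean cohort,
#' then per slice: subduction draws followed by ridge-birth placement, and
#' finally per-slice environment noise).
#'
#' Ocean points are born at the ridge meridian with seafloor age 0 and drift
#' away at `drift_speed`; the initial cohort carries the pre-run age implied
#' by its distance from the ridge. Continental points never move; their
#' seafloor age restarts at 0 whenever a flooded stint begins, emulating the
#' age reset of newly flooded shelves. Grid cells are annotated
#' `flooded_shelf` if they contain any flooded continental point, else
#' `ocean` if they contain any ocean point, else `continental` if they
#' contain an emergent point; empty cells default to ocean equatorward of
#' `sea_level_band` and continental poleward of it. The cell age layer is
#' the minimum seafloor age of the points of matching class in the cell, so
#' ridge cells with a newborn point carry age 0.
#'
#' @param config A [world_config()] object.
#' @return An object of class `world_history`: a list with elements
#'   `config`, `slice_ages` (Ma, strictly decreasing), `points` (long
#'   data frame: `point_id`, `point_type`, `slice`, `lat`, `lon`, `class`,
#'   `age`, `temp`, `poc`), `grids` (per-slice list with `class` and `age`
#'   matrices, rows from +90 to -90), and cell centre coordinates
#'   `lat_centers`, `lon_centers`.
#' @export
build_world <- function(config) {
  validate_world_config(config)
  cfg <- config
  with_seed(cfg$seed, build_world_impl(cfg))
}

build_world_impl <- function(cfg) {
  n <- cfg$n_slices
  ages <- cfg$start_age - (seq_len(n) - 1) * cfg$slice_spacing
  res <- cfg$grid_resolution
  nlat <- as.integer(round(180 / res))
  nlon <- as.integer(round(360 / res))

  ## --- continental points -------------------------------------------------
  ncont <- cfg$n_continental_points
  cont <- NULL
  if (ncont > 0) {
    lat_c <- runif(ncont, -70, 70)
    lon_c <- runif(ncont, -180, 180)
    fc <- cfg$flood_cycle_params
    p_start_flooded <- fc$mean_flooded / (fc$mean_flooded + fc$mean_emergent)
    flooded <- matrix(FALSE, ncont, n)
    for (i in seq_len(ncont)) {
      state <- runif(1) < p_start_flooded
      s <- 1L
      while (s <= n) {
        m <- if (state) fc$mean_flooded else fc$mean_emergent
        len <- rgeom(1L, 1 / m) + 1L
        flooded[i, s:min(n, s + len - 1L)] <- state
        s <- s + len
        state <- !state
      }
    }
    ## seafloor age: (position within the current flooded stint - 1) * spacing
    age_c <- matrix(NA_real_, ncont, n)
    for (i in seq_len(ncont)) {
      run <- 0
      for (s in seq_len(n)) {
        if (flooded[i, s]) {
          age_c[i, s] <- run * cfg$slice_spacing
          run <- run + 1
        } else {
          run <- 0
        }
      }
    }
    cont <- data.frame(
      point_id = rep(seq_len(ncont), each = n),
      point_type = "continental",
      slice = rep(seq_len(n), ncont),
      lat = rep(lat_c, each = n),
      lon = rep(wrap_lon(lon_c), each = n),
      class = ifelse(as.vector(t(flooded)), "flooded_shelf", "emergent_land"),
      age = as.vector(t(age_c)),
      stringsAsFactors = FALSE)
  }

  ## --- ocean points -------------------------------------------------------
  noc <- cfg$n_ocean_points
  ocean <- NULL
  if (noc > 0) {
    ## initial cohort: pre-run ages, positions implied by drift from ridge
    lat_o <- runif(noc, -85, 85)
    sign_o <- sample(c(-1, 1), noc, replace = TRUE)
    age0 <- runif(noc, 0, 100)
    birth_slice <- rep(1L, noc)
    n_birth <- max(1L, as.integer(round(cfg$ridge_birth_rate * noc)))
    ## ridge cohort of the first slice: age-0 seafloor exists from the start
    lat_o <- c(lat_o, runif(n_birth, -85, 85))
    sign_o <- c(sign_o, sample(c(-1, 1), n_birth, replace = TRUE))
    age0 <- c(age0, rep(0, n_birth))
    birth_slice <- c(birth_slice, rep(1L, n_birth))
    noc_init <- length(lat_o)
    ## per-slice tectonics: subduction draws, then ridge births
    death_slice <- rep(NA_integer_, noc_init)  # grown as points are added
    for (s in 2:n) {
      alive <- which(birth_slice < s & is.na(death_slice))
      if (length(alive)) {
        u <- runif(length(alive))
        gone <- u < cfg$subduction_rate
        ## forced subduction once a point has drifted 170 degrees from ridge
        offs <- cfg$drift_speed *
          (age0[alive] + (ages[birth_slice[alive]] - ages[s]))
        gone <- gone | offs > 170
        death_slice[alive[gone]] <- s
      }
      new_lat <- runif(n_birth, -85, 85)
      new_sign <- sample(c(-1, 1), n_birth, replace = TRUE)
      lat_o <- c(lat_o, new_lat)
      sign_o <- c(sign_o, new_sign)
      age0 <- c(age0, rep(0, n_birth))
      birth_slice <- c(birth_slice, rep(s, n_birth))
      death_slice <- c(death_slice, rep(NA_integer_, n_birth))
    }
    n_oc_total <- length(lat_o)
    rows <- vector("list", n_oc_total)
    for (i in seq_len(n_oc_total)) {
      b <- birth_slice[i]
      sl <- b:n
      elapsed <- ages[b] - ages[sl]
      a <- age0[i] + elapsed
      lon_i <- wrap_lon(cfg$ridge_lon + sign_o[i] * cfg$drift_speed * a)
      cls <- rep("ocean", length(sl))
      if (!is.na(death_slice[i])) {
        dead <- sl >= death_slice[i]
        cls[dead] <- "destroyed"
        a[dead] <- NA_real_
        lon_i[dead] <- lon_i[which(dead)[1] - 1L]  # frozen at last position
      }
      rows[[i]] <- data.frame(
        point_id = ncont + i, point_type = "ocean", slice = sl,
        lat = lat_o[i], lon = lon_i, class = cls, age = a,
        stringsAsFactors = FALSE)
    }
    ocean <- do.call(rbind, rows)
  }

  points <- rbind(cont, ocean)
  if (is.null(points)) {
    points <- data.frame(point_id = integer(), point_type = character(),
                         slice = integer(), lat = numeric(), lon = numeric(),
                         class = character(), age = numeric(),
                         stringsAsFactors = FALSE)
  }
  points$temp <- rep(NA_real_, nrow(points))
  points$poc <- rep(NA_real_, nrow(points))

  ## --- per-slice environment fields (cell-level, seeded) ------------------
  active <- points$class %in% c("flooded_shelf", "ocean")
  points$row <- lat_to_row(points$lat, res)
  points$col <- lon_to_col(points$lon, res)
  points$cell <- cell_index(points$row, points$col, nlat)
  for (s in seq_len(n)) {
    idx <- which(active & points$slice == s)
    if (!length(idx)) next
    cells <- sort(unique(points$cell[idx]))
    cell_lat <- row_to_lat((cells - 1L) %% nlat + 1L, res)
    t_noise <- if (cfg$temp_noise_sd > 0) rnorm(length(cells), 0, cfg$temp_noise_sd) else 0
    t_cell <- temp_profile(cell_lat, cfg) + t_noise
    points$temp[idx] <- t_cell[match(points$cell[idx], cells)]
    for (cls in c("flooded_shelf", "ocean")) {
      jdx <- idx[points$class[idx] == cls]
      if (!length(jdx)) next
      ccells <- sort(unique(points$cell[jdx]))
      mu <- if (cls == "flooded_shelf") cfg$shelf_poc_mean else cfg$ocean_poc_mean
      fac <- if (cfg$poc_noise_sd > 0) {
        exp(rnorm(length(ccells), 0, cfg$poc_noise_sd))
      } else {
        rep(1, length(ccells))
      }
      p_cell <- mu * fac
      points$poc[jdx] <- p_cell[match(points$cell[jdx], ccells)]
    }
  }

  ## --- annotated grids ----------------------------------------------------
  grids <- vector("list", n)
  lat_centers <- row_to_lat(seq_len(nlat), res)
  lon_centers <- col_to_lon(seq_len(nlon), res)
  empty_class <- matrix(ifelse(abs(lat_centers) <= cfg$sea_level_band,
                               "ocean", "continental"), nlat, nlon)
  for (s in seq_len(n)) {
    cls_mat <- empty_class
    age_mat <- matrix(NA_real_, nlat, nlon)
    ps <- points[points$slice == s, , drop = FALSE]
    if (nrow(ps)) {
      ## priority annotation: flooded shelf > ocean > continental
      em <- ps[ps$class == "emergent_land", , drop = FALSE]
      cls_mat[cbind(em$row, em$col)] <- "continental"
      oc <- ps[ps$class == "ocean", , drop = FALSE]
      cls_mat[cbind(oc$row, oc$col)] <- "ocean"
      sh <- ps[ps$class == "flooded_shelf", , drop = FALSE]
      cls_mat[cbind(sh$row, sh$col)] <- "flooded_shelf"
      for (cls in c("ocean", "flooded_shelf")) {
        pc <- ps[ps$class == cls, , drop = FALSE]
        if (!nrow(pc)) next
        keep <- cls_mat[cbind(pc$row, pc$col)] == cls
        pc <- pc[keep, , drop = FALSE]
        if (!nrow(pc)) next
        amin <- tapply(pc$age, pc$cell, min)
        cells <- as.integer(names(amin))
        age_mat[cbind((cells - 1L) %% nlat + 1L,
                      (cells - 1L) %/% nlat + 1L)] <- as.numeric(amin)
      }
    }
    grids[[s]] <- list(class = cls_mat, age = age_mat)
  }

  points$row <- points$col <- points$cell <- NULL
  structure(list(config = cfg, slice_ages = ages, points = points,
                 grids = grids, lat_centers = lat_centers,
                 lon_centers = lon_centers),
            class = "world_history")
}

#' @export
print.world_history <- function(x, ...) {
  cat("Synthetic world history\n")
  cat(sprintf("  slices: %d (%.1f to %.1f Ma, spacing %.3g Myr)\n",
              x$config$n_slices, x$slice_ages[1],
              x$slice_ages[length(x$slice_ages)], x$config$slice_spacing))
  cat(sprintf("  points: %d continental, %d ocean trajectories\n",
              x$config$n_continental_points,
              length(unique(x$points$point_id[x$points$point_type == "ocean"]))))
  cat(sprintf("  grid:   %g deg (%d x %d cells)\n", x$config$grid_resolution,
              length(x$lat_centers), length(x$lon_centers)))
  invisible(x)
}

#' Per-point environment at a time slice
#'
#' Returns the seawater temperature and POC export flux attached to every
#' active (flooded-shelf or ocean) point at one slice. Values are cell-level
#' field samples: two points in the same cell and habitat class carry
#' identical values.
#'
#' @param world A `world_history`.
#' @param slice_index Slice number (1-based).
#' @return Data frame with `point_id`, `class`, `temperature`, `poc_flux`.
#' @export
sample_environment <- function(world, slice_index) {
  n <- world$config$n_slices
  if (slice_index < 1 || slice_index > n)
    stop(sprintf("slice_index %d out of range [1, %d]", slice_index, n),
         call. = FALSE)
  p <- world$points
  p <- p[p$slice == slice_index & p$class %in% c("flooded_shelf", "ocean"), ]
  data.frame(point_id = p$point_id, class = p$class,
             temperature = p$temp, poc_flux = p$poc,
             stringsAsFactors = FALSE)
}

#' Seafloor-age series of every tracked point
#'
#' Extracts the per-point seafloor-age trajectories. Age accumulates by the
#' slice spacing only within an uninterrupted active stint and restarts at 0
#' on re-flooding (continental points) or creation (ocean points); emergent
#' and destroyed slices carry `NA`.
#'
#' @param world A `world_history`.
#' @return Long data frame `point_id`, `slice`, `age`.
#' @export
age_points <- function(world) {
  world$points[, c("point_id", "slice", "age")]
}

#' Build a mass-extinction schedule
#'
#' Validates and orders a table of mass-extinction events and imputes the
#' constant negative per-capita net diversification rate that removes
#' exactly the scheduled diversity fraction over the event duration (see
#' [extinction_rate_from_loss()]).
#'
#' @param events Data frame with columns `start_age` (Ma), `duration` (Myr),
#'   `loss_fraction` (in (0,1)). May have zero rows (no forcing).
#' @return An object of class `extinction_schedule`: the events sorted
#'   oldest first, with columns `event_id`, `end_age` and `imputed_rate`
#'   (Myr^-1, negative) added.
#' @export
make_extinction_schedule <- function(events) {
  if (is.null(events) || nrow(events) == 0) {
    out <- data.frame(event_id = integer(), start_age = numeric(),
                      duration = numeric(), loss_fraction = numeric(),
                      end_age = numeric(), imputed_rate = numeric())
    return(structure(out, class = c("extinction_schedule", "data.frame")))
  }
  need <- c("start_age", "duration", "loss_fraction")
  if (!all(need %in% names(events)))
    stop("events must have columns start_age, duration, loss_fraction",
         call. = FALSE)
  if (any(events$duration <= 0))
    stop("event durations must be > 0", call. = FALSE)
  if (any(events$loss_fraction <= 0 | events$loss_fraction >= 1))
    stop("loss_fraction must lie strictly in (0, 1)", call. = FALSE)
  ev <- events[order(-events$start_age), need, drop = FALSE]
  ev$end_age <- ev$start_age - ev$duration
  if (nrow(ev) > 1) {
    overlap <- ev$start_age[-1] > ev$end_age[-nrow(ev)] + 1e-12
    if (any(overlap))
      stop("extinction events overlap in time", call. = FALSE)
  }
  ev$imputed_rate <- extinction_rate_from_loss(ev$loss_fraction, ev$duration)
  ev <- cbind(event_id = seq_len(nrow(ev)), ev)
  rownames(ev) <- NULL
  structure(ev, class = c("extinction_schedule", "data.frame"))
}
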