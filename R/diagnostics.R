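#' Saturation ratio map (diversity over carrying capacity)
#'
#' Rasterizes the per-point ratio `D / K_eff` of a logistic run at one time
#' slice onto the annotated grid (mean per cell, ocean and shelf cells
#' filled independently from points of matching class). The ratio measures
#' how close a regional biota is to ecological saturation: values near 0
#' indicate dynamics deep inside the exponential regime of the logistic,
#' values near 1 indicate saturation. Cell weights proportional to
#' `cos(latitude)` give equal-area statistics downstream.
#'
#' @param history A `diversity_history` from a logistic run (errors on an
#'   exponential run, which records no carrying capacity).
#' @param world The `world_history` the simulation ran on.
#' @param slice Slice number.
#' @return An object of class `saturation_map`: data frame with `row`,
#'   `col`, `lat`, `lon`, `class`, `ratio`, `weight`.
#' @export
saturation_ratio_map <- function(history, world, slice) {
  params <- attr(history, "params")
  if (is.null(params) || params$model_kind != "logistic")
    stop("saturation ratios require a logistic run with recorded K_eff",
         call. = FALSE)
  res <- world$config$grid_resolution
  nlat <- length(world$lat_centers)
  g <- world$grids[[slice]]
  h <- history[history$slice == slice &
                 history$class %in% c("flooded_shelf", "ocean"), , drop = FALSE]
  out <- data.frame(row = integer(), col = integer(), lat = numeric(),
                    lon = numeric(), class = character(), ratio = numeric(),
                    weight = numeric(), stringsAsFactors = FALSE)
  if (nrow(h)) {
    h$ratio <- h$D / h$k_eff
    h$row <- lat_to_row(h$lat, res)
    h$col <- lon_to_col(h$lon, res)
    for (cls in c("flooded_shelf", "ocean")) {
      hc <- h[h$class == cls & g$class[cbind(h$row, h$col)] == cls, ,
              drop = FALSE]
      if (!nrow(hc)) next
      cell <- cell_index(hc$row, hc$col, nlat)
      m <- tapply(hc$ratio, cell, mean)
      cells <- as.integer(names(m))
      rr <- (cells - 1L) %% nlat + 1L
      cc <- (cells - 1L) %/% nlat + 1L
      out <- rbind(out, data.frame(
        row = rr, col = cc,
        lat = world$lat_centers[rr], lon = world$lon_centers[cc],
        class = cls, ratio = as.numeric(m),
        weight = cos(world$lat_centers[rr] * pi / 180),
        stringsAsFactors = FALSE))
    }
  }
  structure(out, class = c("saturation_map", "data.frame"),
            age_ma = world$slice_ages[slice], slice = slice)
}

#' Area-weighted histogram of saturation ratios
#'
#' Cos-latitude-weighted frequency distribution (in percent of area) of the
#' saturation ratio, optionally restricted to one habitat class. Default
#' bins split at the 0.25 and 0.5 saturation thresholds.
#'
#' @param map A `saturation_map`.
#' @param breaks Bin boundaries covering the data (default
#'   `c(0, 0.25, 0.5, 1)`).
#' @param class Optional habitat class filter (`"flooded_shelf"` or
#'   `"ocean"`).
#' @return Data frame with `bin_lo`, `bin_hi`, `pct`; percentages sum to
#'   100.
#' @export
area_weighted_histogram <- function(map, breaks = c(0, 0.25, 0.5, 1),
                                    class = NULL) {
  m <- map
  if (!is.null(class)) m <- m[m$class == class, , drop = FALSE]
  if (nrow(m) == 0) stop("no cells selected", call. = FALSE)
  bins <- cut(m$ratio, breaks = breaks, include.lowest = TRUE, right = TRUE)
  w <- tapply(m$weight, bins, sum, default = 0)
  w[is.na(w)] <- 0
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             pct = 100 * as.numeric(w) / sum(m$weight))
}

#' Zonal mean diversity profile
#'
#' Cos-latitude area-weighted mean diversity of the populated cells in
#' latitudinal bands (default 20-degree bands, giving nine bands).
#'
#' @param grid A `diversity_grid`.
#' @param band_width Band width in degrees; must divide 180.
#' @return Data frame with `band_lo`, `band_hi`, `mean_diversity`,
#'   `n_cells` (NA mean for empty bands).
#' @export
zonal_mean_profile <- function(grid, band_width = 20) {
  if (abs(180 / band_width - round(180 / band_width)) > 1e-9)
    stop_field("band_width", "must divide 180 exactly")
  lo <- seq(-90, 90 - band_width, by = band_width)
  hi <- lo + band_width
  pop <- which(!is.na(grid$div), arr.ind = TRUE)
  lat <- grid$lat_centers[pop[, 1]]
  val <- grid$div[pop]
  w <- cos(lat * pi / 180)
  band <- findInterval(lat, c(lo, 90), rightmost.closed = TRUE)
  ms <- ns <- rep(NA_real_, length(lo))
  for (b in seq_along(lo)) {
    i <- band == b
    ns[b] <- sum(i)
    if (any(i)) ms[b] <- sum(w[i] * val[i]) / sum(w[i])
  }
  data.frame(band_lo = lo, band_hi = hi, mean_diversity = ms,
             n_cells = as.integer(ns))
}

#' Quantile-bounded normalization of a diversity map
#'
#' Maps the `[lower, upper]` empirical quantile range of the populated
#' cells affinely onto \[0, 1\], clamping values outside it; used to compare
#' maps while limiting the influence of outliers.
#'
#' @param grid A `diversity_grid`.
#' @param lower,upper Quantile bounds (defaults 0.05 and 0.95).
#' @return The grid with `div` replaced by its normalized values.
#' @export
quantile_normalize_map <- function(grid, lower = 0.05, upper = 0.95) {
  v <- grid$div[!is.na(grid$div)]
  if (length(unique(v)) < 2)
    stop("cannot normalize a constant or empty map", call. = FALSE)
  q <- stats::quantile(v, c(lower, upper), names = FALSE)
  if (q[1] == q[2]) stop("degenerate quantile range", call. = FALSE)
  grid$div <- pmin(pmax((grid$div - q[1]) / (q[2] - q[1]), 0), 1)
  grid
}

#' Freeze a world history at one slice
#'
#' Returns a world in which every slice carries the chosen slice's points,
#' classes, environments and grid: geography and environment become
#' time-invariant while diversity still accumulates through the slice
#' sequence. This is the "static mode" substrate of
#' [static_geography_experiment()].
#'
#' @param world A `world_history`.
#' @param freeze_slice Slice whose state is replicated.
#' @return A `world_history` with time-invariant geography.
#' @export
freeze_world <- function(world, freeze_slice) {
  n <- world$config$n_slices
  if (freeze_slice < 1 || freeze_slice > n)
    stop("freeze_slice out of range", call. = FALSE)
  snap <- world$points[world$points$slice == freeze_slice, , drop = FALSE]
  pts <- do.call(rbind, lapply(seq_len(n), function(s) {
    p <- snap
    p$slice <- s
    p
  }))
  rownames(pts) <- NULL
  frozen <- world
  frozen$points <- pts
  frozen$grids <- rep(world$grids[freeze_slice], n)
  frozen
}

#' Static-geography (null) experiment
#'
#' Freezes geography and environment at one slice, reruns the full
#' simulation for the whole duration, and compares the resulting regional
#' diversity maps with the default moving-geography run: per populated
#' cell, the difference of `log10` of the min-max-normalized diversities
#' (small floor of 1e-6 before the log; cells empty in either run are
#' reported as missing). Positive values mean the static world
#' over-accumulates diversity relative to the drifting world.
#'
#' @param world A `world_history`.
#' @param params A [model_params()] object.
#' @param schedule An `extinction_schedule` (or `NULL`).
#' @param freeze_slice Slice at which geography is frozen.
#' @param decay A [decay_params()] object (rasterization settings).
#' @param compare_slices Slices at which maps are compared (default: the
#'   final slice).
#' @return An object of class `experiment_report`: list with `cells` (long
#'   data frame `slice`, `row`, `col`, `lat`, `lon`, `log10_diff`),
#'   `summary` (per-slice mean/sd), and both runs' histories
#'   (`history_static`, `history_default`).
#' @export
static_geography_experiment <- function(world, params, schedule = NULL,
                                        freeze_slice = 1,
                                        decay = decay_params(),
                                        compare_slices = world$config$n_slices) {
  frozen <- freeze_world(world, freeze_slice)
  h_def <- simulate_diversity(world, params, schedule)
  h_sta <- simulate_diversity(frozen, params, schedule)
  floor_ <- 1e-6
  cells <- NULL
  for (s in compare_slices) {
    g_def <- rasterize_points(h_def, world, s, decay)
    g_sta <- rasterize_points(h_sta, frozen, s, decay)
    both <- !is.na(g_def$div) & !is.na(g_sta$div)
    if (!any(both)) next
    nd <- matrix(NA_real_, nrow(g_def$div), ncol(g_def$div))
    ns <- nd
    nd[both] <- norm01_safe(g_def$div[both])
    ns[both] <- norm01_safe(g_sta$div[both])
    idx <- which(both, arr.ind = TRUE)
    cells <- rbind(cells, data.frame(
      slice = s, row = idx[, 1], col = idx[, 2],
      lat = world$lat_centers[idx[, 1]], lon = world$lon_centers[idx[, 2]],
      log10_diff = log10(pmax(ns[both], floor_)) -
        log10(pmax(nd[both], floor_))))
  }
  summ <- NULL
  if (!is.null(cells)) {
    summ <- do.call(rbind, lapply(split(cells, cells$slice), function(d) {
      data.frame(slice = d$slice[1], mean_log10_diff = mean(d$log10_diff),
                 sd_log10_diff = stats::sd(d$log10_diff), n = nrow(d))
    }))
    rownames(summ) <- NULL
  }
  structure(list(cells = cells, summary = summ, freeze_slice = freeze_slice,
                 history_static = h_sta, history_default = h_def),
            class = "experiment_report")
}

## min-max normalize, tolerating a constant vector (maps to 1).
norm01_safe <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(1, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Mass-extinction toggling experiment
#'
#' Reruns the pipeline with a subset of the scheduled mass extinctions
#' deactivated and compares the resulting global diversity curve with the
#' fully forced one.
#'
#' @param world A `world_history`.
#' @param params A [model_params()] object.
#' @param schedule An `extinction_schedule`.
#' @param disabled_event_ids Integer `event_id`s to deactivate (may be
#'   empty, in which case both runs are identical).
#' @param decay A [decay_params()] object.
#' @return An object of class `toggle_report`: list with `curves` (data
#'   frame `slice`, `age_ma`, `gamma_default`, `gamma_toggled`, `ratio`)
#'   and both histories (`history_default`, `history_toggled`).
#' @export
extinction_toggle_experiment <- function(world, params, schedule,
                                         disabled_event_ids = integer(),
                                         decay = decay_params()) {
  if (length(disabled_event_ids) &&
      !all(disabled_event_ids %in% schedule$event_id))
    stop("unknown extinction event id", call. = FALSE)
  reduced <- schedule[!schedule$event_id %in% disabled_event_ids, ,
                      drop = FALSE]
  h_def <- simulate_diversity(world, params, schedule)
  h_tog <- simulate_diversity(world, params, reduced)
  c_def <- global_diversity_curve(h_def, world, decay)
  c_tog <- global_diversity_curve(h_tog, world, decay)
  curves <- data.frame(slice = c_def$slice, age_ma = c_def$age_ma,
                       gamma_default = c_def$gamma_total,
                       gamma_toggled = c_tog$gamma_total,
                       ratio = c_tog$gamma_total / c_def$gamma_total)
  structure(list(curves = curves, disabled_event_ids = disabled_event_ids,
                 history_default = h_def, history_toggled = h_tog),
            class = "toggle_report")
}
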