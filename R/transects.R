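#' Distance-decay and transect parameters
#'
#' Parameters of the genus-level distance decay of taxonomic similarity and
#' of the peak-to-trough transect tracing. Defaults are the fitted
#' Phanerozoic values: offset 0.06, maximum 1.0 and decay rate 0.0024 km^-1
#' for the Jaccard decay curve; transects are cut at 555 km (5 degrees at
#' the equator), rejected when more than 20% of their path cells are
#' continental, and peaks are local maxima above the 0.75 quantile of all
#' local-maximum diversities.
#'
#' @param j_off Jaccard similarity offset at infinite distance.
#' @param j_max Jaccard similarity at zero distance.
#' @param lambda Distance-decay rate, km^-1.
#' @param truncation_km Maximum transect length (peak-side prefix kept), km.
#' @param land_fraction_max Maximum tolerated fraction of continental cells
#'   along a transect path.
#' @param peak_quantile Quantile of local-maximum diversities above which a
#'   local maximum is retained as a peak.
#' @param fill_radius_km Radius of the nearest-neighbour same-class fill
#'   used when rasterizing point diversities (0 = populate only the cells
#'   that contain points).
#' @return An object of class `decay_params`.
#' @export
decay_params <- function(j_off = 0.06, j_max = 1.0, lambda = 0.0024,
                         truncation_km = 555, land_fraction_max = 0.2,
                         peak_quantile = 0.75, fill_radius_km = 0) {
  if (j_off < 0 || j_off >= j_max || j_max > 1)
    stop_field("j_off", "need 0 <= j_off < j_max <= 1")
  if (lambda <= 0) stop_field("lambda", "must be > 0")
  if (truncation_km <= 0) stop_field("truncation_km", "must be > 0")
  structure(list(j_off = j_off, j_max = j_max, lambda = lambda,
                 truncation_km = truncation_km,
                 land_fraction_max = land_fraction_max,
                 peak_quantile = peak_quantile,
                 fill_radius_km = fill_radius_km),
            class = "decay_params")
}

#' Jaccard similarity as a function of geographical distance
#'
#' Exponential distance decay of the genus-level Jaccard index:
#' `J = j_off + (j_max - j_off) * exp(-lambda * distance)`.
#'
#' @param distance Great-circle distance(s) in km, >= 0.
#' @param params A [decay_params()] object.
#' @return Jaccard similarity in `[j_off, j_max]`, vectorized.
#' @export
distance_decay_similarity <- function(distance, params = decay_params()) {
  if (any(distance < 0)) stop("distance must be >= 0", call. = FALSE)
  params$j_off + (params$j_max - params$j_off) * exp(-params$lambda * distance)
}

#' Convert a Jaccard similarity to a Simpson overlap coefficient
#'
#' `V = (1 + R) * J / (1 + J)` with `R = max(alpha) / min(alpha)`, the ratio
#' of the two community richnesses. When the conversion exceeds 1 (the
#' Jaccard value implies more shared genera than the poorer community
#' holds), it is recomputed with `R = 1`, i.e. `V = 2J / (1 + J)`, keeping
#' the overlap coefficient in `[0, 1]`.
#'
#' @param j Jaccard similarity in \[0, 1\].
#' @param alpha_a,alpha_b Richness of the two communities (>= 1).
#' @return Simpson overlap coefficient(s) in \[0, 1\], vectorized.
#' @export
jaccard_to_simpson <- function(j, alpha_a, alpha_b) {
  r <- pmax(alpha_a, alpha_b) / pmin(alpha_a, alpha_b)
  v <- (1 + r) * j / (1 + j)
  over <- v > 1
  v[over] <- 2 * j[over] / (1 + j[over])
  v
}

#' Rasterize point diversities onto the annotated grid
#'
#' Builds a per-slice regional diversity map by interpolating ocean-point
#' and flooded-shelf-point diversities independently: a shelf cell is never
#' filled from ocean points and vice versa. Cells containing several points
#' of the matching class take their mean diversity; with
#' `fill_radius_km > 0`, empty cells of a class are filled from the nearest
#' point of that class within the radius.
#'
#' @param history A `diversity_history` from [simulate_diversity()].
#' @param world The `world_history` the simulation ran on.
#' @param slice Slice number.
#' @param params A [decay_params()] object (supplies `fill_radius_km`).
#' @return An object of class `diversity_grid`: list with matrices `div`
#'   (NA where unpopulated), `class`, `age`, the cell centres and the slice
#'   age.
#' @export
rasterize_points <- function(history, world, slice, params = decay_params()) {
  res <- world$config$grid_resolution
  nlat <- length(world$lat_centers)
  g <- world$grids[[slice]]
  h <- history[history$slice == slice &
                 history$class %in% c("flooded_shelf", "ocean"), , drop = FALSE]
  div <- matrix(NA_real_, nlat, length(world$lon_centers))
  cls_map <- c(flooded_shelf = "flooded_shelf", ocean = "ocean")
  if (nrow(h)) {
    h$row <- lat_to_row(h$lat, res)
    h$col <- lon_to_col(h$lon, res)
    for (cls in names(cls_map)) {
      hc <- h[h$class == cls & g$class[cbind(h$row, h$col)] == cls_map[cls], ,
              drop = FALSE]
      if (!nrow(hc)) next
      cell <- cell_index(hc$row, hc$col, nlat)
      m <- tapply(hc$D, cell, mean)
      cells <- as.integer(names(m))
      div[cbind((cells - 1L) %% nlat + 1L,
                (cells - 1L) %/% nlat + 1L)] <- as.numeric(m)
      if (params$fill_radius_km > 0) {
        empty <- which(g$class == cls_map[cls] & is.na(div), arr.ind = TRUE)
        if (nrow(empty)) {
          elat <- world$lat_centers[empty[, 1]]
          elon <- world$lon_centers[empty[, 2]]
          for (i in seq_len(nrow(empty))) {
            dd <- gc_distance_km(elat[i], elon[i], hc$lat, hc$lon)
            jmin <- which.min(dd)
            if (dd[jmin] <= params$fill_radius_km)
              div[empty[i, 1], empty[i, 2]] <- hc$D[jmin]
          }
        }
      }
    }
  }
  structure(list(div = div, class = g$class, age = g$age,
                 lat_centers = world$lat_centers,
                 lon_centers = world$lon_centers,
                 age_ma = world$slice_ages[slice], slice = slice),
            class = "diversity_grid")
}

## 8-neighbourhood shifts of a matrix with longitude (column) wraparound;
## rows beyond the poles are dropped (padded with NA).
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  cols <- ((seq_len(nc) - 1 - dc) %% nc) + 1
  out <- m[, cols, drop = FALSE]
  if (dr > 0) {
    out <- rbind(matrix(NA, dr, nc), out[seq_len(nr - dr), , drop = FALSE])
  } else if (dr < 0) {
    out <- rbind(out[(1 - dr):nr, , drop = FALSE], matrix(NA, -dr, nc))
  }
  out
}

#' Locate diversity peaks on a regional diversity map
#'
#' Peaks are local maxima over the 8-neighbourhood (with longitude
#' wraparound) whose diversity exceeds the `peak_quantile` of all
#' local-maximum diversities on the map. Flat plateaus (connected runs of
#' equal-valued local maxima) contribute a single peak: the middle cell of
#' the run in (row, column) order.
#'
#' @param grid A `diversity_grid`.
#' @param params A [decay_params()] object.
#' @return Data frame with `row`, `col`, `lat`, `lon`, `value`; zero rows
#'   when the map has no populated cells.
#' @export
find_peaks <- function(grid, params = decay_params()) {
  div <- grid$div
  empty_out <- data.frame(row = integer(), col = integer(), lat = numeric(),
                          lon = numeric(), value = numeric())
  if (!any(!is.na(div))) return(empty_out)
  nlat <- nrow(div)
  is_max <- !is.na(div)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- shift_mat(div, dr, dc)
    cmp <- !is.na(div) & !is.na(nb) & nb > div
    is_max <- is_max & !cmp
  }
  cand <- which(is_max, arr.ind = TRUE)
  if (!nrow(cand)) return(empty_out)
  ## collapse equal-valued adjacent candidates (plateaus) to their middle cell
  key <- cell_index(cand[, 1], cand[, 2], nlat)
  comp <- seq_len(nrow(cand))          # union-find over candidate cells
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  nlon <- ncol(div)
  lookup <- new.env(hash = TRUE)
  for (i in seq_len(nrow(cand))) assign(as.character(key[i]), i, envir = lookup)
  for (i in seq_len(nrow(cand))) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- cand[i, 1] + dr
      if (r2 < 1 || r2 > nlat) next
      c2 <- ((cand[i, 2] - 1 + dc) %% nlon) + 1
      j <- mget(as.character(cell_index(r2, c2, nlat)), envir = lookup,
                ifnotfound = list(NULL))[[1]]
      if (!is.null(j) && div[cand[i, 1], cand[i, 2]] == div[cand[j, 1], cand[j, 2]]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(nrow(cand)), find, integer(1))
  reps <- vapply(split(seq_len(nrow(cand)), roots), function(members) {
    ord <- order(cand[members, 1], cand[members, 2])
    members[ord][ceiling(length(members) / 2)]
  }, integer(1))
  vals <- div[cand[reps, , drop = FALSE]]
  thr <- stats::quantile(vals, params$peak_quantile, names = FALSE)
  keep <- reps[vals > thr]
  if (!length(keep)) {
    ## degenerate map (e.g. a single local maximum): keep the global argmax
    keep <- reps[which.max(vals)]
  }
  data.frame(row = cand[keep, 1], col = cand[keep, 2],
             lat = grid$lat_centers[cand[keep, 1]],
             lon = grid$lon_centers[cand[keep, 2]],
             value = div[cand[keep, , drop = FALSE]])
}

#' Locate diversity troughs on a regional diversity map
#'
#' Troughs are newly formed ocean cells: cells annotated `ocean` whose
#' seafloor age is 0 (mid-ocean ridge cells). Their diversity is one genus
#' by construction.
#'
#' @param grid A `diversity_grid`.
#' @return Data frame with `row`, `col`, `lat`, `lon`; zero rows when the
#'   map has no age-0 ocean cell (the slice is then skipped by the transect
#'   stage).
#' @export
find_troughs <- function(grid) {
  hit <- which(grid$class == "ocean" & !is.na(grid$age) & grid$age == 0,
               arr.ind = TRUE)
  data.frame(row = as.integer(hit[, 1]), col = as.integer(hit[, 2]),
             lat = grid$lat_centers[hit[, 1]], lon = grid$lon_centers[hit[, 2]])
}

## Bresenham line in grid-index space from (r1,c1) to (r2,c2), columns
## wrapping along the shorter longitudinal direction.
bresenham_cells <- function(r1, c1, r2, c2, nlon) {
  half <- nlon / 2
  dc_raw <- as.integer(round(((c2 - c1 + half) %% nlon) - half))
  ct <- c1 + dc_raw  # unwrapped target column along the shorter arc
  x <- r1; y <- c1
  dx <- abs(r2 - r1); sx <- if (r1 <= r2) 1L else -1L
  dy <- -abs(ct - c1); sy <- if (c1 <= ct) 1L else -1L
  err <- dx + dy
  rows <- integer(dx - dy + 1L); cols <- integer(dx - dy + 1L)
  k <- 0L
  repeat {
    k <- k + 1L
    rows[k] <- x; cols[k] <- y
    if (x == r2 && y == ct) break
    e2 <- 2 * err
    if (e2 >= dy) { err <- err + dy; x <- x + sx }
    if (e2 <= dx) { err <- err + dx; y <- y + sy }
  }
  cbind(row = rows[seq_len(k)], col = ((cols[seq_len(k)] - 1L) %% nlon) + 1L)
}

#' Trace a peak-to-trough transect
#'
#' Selects the trough nearest (great-circle) to the peak, enumerates the
#' grid cells between them with Bresenham's line algorithm in index space
#' (taking the shorter longitudinal direction across the antimeridian),
#' rejects the transect when continental cells exceed `land_fraction_max`
#' of the path, and truncates the accepted path to the peak-side prefix
#' whose cumulative great-circle length does not exceed `truncation_km`.
#' Unpopulated cells along the path contribute a trough-level background
#' richness of one genus.
#'
#' @param peak One-row data frame (or list) with `row`, `col`.
#' @param troughs Data frame of trough cells from [find_troughs()].
#' @param grid A `diversity_grid`.
#' @param params A [decay_params()] object.
#' @return An object of class `transect` (list with `cells` data frame
#'   `row`, `col`, `lat`, `lon`, `alpha`, per-step distances `step_km`,
#'   `length_km`, and `peak` coordinates), or `NULL` when the transect is
#'   rejected by the land rule.
#' @export
trace_transect <- function(peak, troughs, grid, params = decay_params()) {
  if (is.null(troughs) || nrow(troughs) == 0)
    stop("no troughs available", call. = FALSE)
  nlat <- nrow(grid$div); nlon <- ncol(grid$div)
  plat <- grid$lat_centers[peak$row]; plon <- grid$lon_centers[peak$col]
  dd <- gc_distance_km(plat, plon, troughs$lat, troughs$lon)
  ord <- order(dd, cell_index(troughs$row, troughs$col, nlat))
  tr <- troughs[ord[1], ]
  path <- bresenham_cells(peak$row, peak$col, tr$row, tr$col, nlon)
  cls <- grid$class[path]
  if (mean(cls == "continental") > params$land_fraction_max) return(NULL)
  lat <- grid$lat_centers[path[, "row"]]
  lon <- grid$lon_centers[path[, "col"]]
  n <- nrow(path)
  step <- if (n > 1) gc_distance_km(lat[-n], lon[-n], lat[-1], lon[-1]) else numeric(0)
  keep <- c(TRUE, cumsum(step) <= params$truncation_km)
  n_keep <- max(1L, sum(keep))
  path <- path[seq_len(n_keep), , drop = FALSE]
  lat <- lat[seq_len(n_keep)]; lon <- lon[seq_len(n_keep)]
  step <- step[seq_len(max(0L, n_keep - 1L))]
  alpha <- grid$div[path]
  alpha[is.na(alpha)] <- 1
  structure(list(cells = data.frame(row = path[, "row"], col = path[, "col"],
                                    lat = lat, lon = lon, alpha = alpha),
                 step_km = step, length_km = sum(step),
                 peak = list(row = peak$row, col = peak$col,
                             lat = plat, lon = plon)),
            class = "transect")
}

#' Integrate diversity along a transect
#'
#' Core accumulation rule: given per-cell richness `alpha` (peak first) and
#' the Simpson overlap `v` between each pair of consecutive cells, the
#' transect diversity is `alpha[1] + sum((1 - v) * alpha[-1])` - each cell
#' adds only the fraction of its richness not shared with its predecessor.
#'
#' @param alpha Numeric vector of per-cell richness (>= 1), peak first.
#' @param v Simpson overlap coefficients between consecutive cells
#'   (`length(alpha) - 1` values in \[0, 1\]).
#' @return The integrated transect diversity (genera).
#' @export
transect_gamma <- function(alpha, v) {
  if (length(alpha) < 1) stop("empty transect", call. = FALSE)
  if (length(v) != length(alpha) - 1)
    stop("need one overlap per consecutive cell pair", call. = FALSE)
  alpha[1] + sum((1 - v) * alpha[-1])
}

#' Integrated diversity of a traced transect
#'
#' Converts each per-step great-circle distance to a Jaccard similarity via
#' the distance-decay curve, then to a Simpson overlap using the two cells'
#' richnesses, and accumulates with [transect_gamma()].
#'
#' @param transect A `transect` from [trace_transect()].
#' @param params A [decay_params()] object.
#' @return The transect, with elements `gamma` and `v` filled in.
#' @export
integrate_transect <- function(transect, params = decay_params()) {
  a <- transect$cells$alpha
  n <- length(a)
  if (n == 0) stop("empty transect", call. = FALSE)
  v <- if (n > 1) {
    j <- distance_decay_similarity(transect$step_km, params)
    jaccard_to_simpson(j, a[-n], a[-1])
  } else numeric(0)
  transect$v <- v
  transect$gamma <- transect_gamma(a, v)
  transect
}

#' Zigzag integration of transects into a global diversity estimate
#'
#' Sorts the integrated transects by descending diversity (ties by peak
#' cell index) and accumulates them down-gradient: the first (richest)
#' transect enters whole, and each further transect contributes
#' `(1 - V) * gamma`, where `V` is the Simpson overlap implied by the
#' great-circle distance between its peak and the nearest already
#' integrated peak, with the richness ratio of the two transects.
#' Transects with coincident peaks are fully absorbed (V = 1).
#'
#' @param transects List of integrated transects (with `gamma` and `peak`).
#' @param params A [decay_params()] object.
#' @param nlat Number of grid rows (for deterministic tie-breaking); taken
#'   from the first transect's peak row bound if omitted.
#' @return List with `gamma_total`, `n_transects` and a `contributions`
#'   data frame (`gamma`, `nn_dist_km`, `v_nn`, `added`).
#' @export
integrate_global <- function(transects, params = decay_params(),
                             nlat = 1000L) {
  if (length(transects) == 0) stop("no transects to integrate", call. = FALSE)
  g <- vapply(transects, function(t) t$gamma, numeric(1))
  prow <- vapply(transects, function(t) t$peak$row, numeric(1))
  pcol <- vapply(transects, function(t) t$peak$col, numeric(1))
  plat <- vapply(transects, function(t) t$peak$lat, numeric(1))
  plon <- vapply(transects, function(t) t$peak$lon, numeric(1))
  ord <- order(-g, cell_index(prow, pcol, nlat))
  g <- g[ord]; plat <- plat[ord]; plon <- plon[ord]
  n <- length(g)
  nn_dist <- v_nn <- added <- numeric(n)
  nn_dist[1] <- NA; v_nn[1] <- NA; added[1] <- g[1]
  total <- g[1]
  for (i in seq_len(n)[-1]) {
    dd <- gc_distance_km(plat[i], plon[i], plat[seq_len(i - 1)],
                         plon[seq_len(i - 1)])
    k <- which.min(dd)
    j <- distance_decay_similarity(dd[k], params)
    v <- jaccard_to_simpson(j, g[i], g[k])
    nn_dist[i] <- dd[k]; v_nn[i] <- v
    added[i] <- (1 - v) * g[i]
    total <- total + added[i]
  }
  list(gamma_total = total, n_transects = n,
       contributions = data.frame(gamma = g, nn_dist_km = nn_dist,
                                  v_nn = v_nn, added = added))
}

#' Global diversity curve from a simulated diversity history
#'
#' Runs the whole per-slice estimation pipeline - rasterize, find peaks and
#' troughs, trace and integrate peak-to-trough transects, zigzag-integrate
#' them - and assembles the global diversity time series. Slices with no
#' populated cells, no troughs or no accepted transect carry `NA` and are
#' flagged.
#'
#' @param history A `diversity_history`.
#' @param world The `world_history` the simulation ran on.
#' @param params A [decay_params()] object.
#' @return An object of class `global_curve`: data frame with `slice`,
#'   `age_ma`, `gamma_total`, `n_transects`, `skipped`.
#' @export
global_diversity_curve <- function(history, world, params = decay_params()) {
  n <- world$config$n_slices
  out <- data.frame(slice = seq_len(n), age_ma = world$slice_ages,
                    gamma_total = NA_real_, n_transects = 0L,
                    skipped = TRUE)
  for (s in seq_len(n)) {
    grid <- rasterize_points(history, world, s, params)
    if (!any(!is.na(grid$div))) next
    troughs <- find_troughs(grid)
    if (nrow(troughs) == 0) next
    peaks <- find_peaks(grid, params)
    if (nrow(peaks) == 0) next
    transects <- list()
    for (i in seq_len(nrow(peaks))) {
      tr <- trace_transect(peaks[i, ], troughs, grid, params)
      if (!is.null(tr)) transects <- c(transects, list(integrate_transect(tr, params)))
    }
    if (!length(transects)) next
    gi <- integrate_global(transects, params, nlat = nrow(grid$div))
    out$gamma_total[s] <- gi$gamma_total
    out$n_transects[s] <- gi$n_transects
    out$skipped[s] <- FALSE
  }
  structure(out, class = c("global_curve", "data.frame"))
}
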