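#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorized over
#' coordinate pairs (recycled as usual).
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Numeric vector of distances in km.
#' @export
gc_distance_km <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = 6371)
}

## Run `expr` under a temporary RNG state seeded with `seed`; the caller's
## .Random.seed is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

## Wrap longitudes into [-180, 180)
wrap_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

## Cell index helpers for a lat/lon grid with `res`-degree cells.
## Rows run from +90 (row 1) to -90; columns from -180 (col 1) to +180.
lat_to_row <- function(lat, res) {
  r <- floor((90 - lat) / res) + 1L
  nlat <- as.integer(round(180 / res))
  pmin(pmax(as.integer(r), 1L), nlat)
}

lon_to_col <- function(lon, res) {
  cc <- floor((wrap_lon(lon) + 180) / res) + 1L
  nlon <- as.integer(round(360 / res))
  pmin(pmax(as.integer(cc), 1L), nlon)
}

row_to_lat <- function(row, res) 90 - (row - 0.5) * res
col_to_lon <- function(col, res) -180 + (col - 0.5) * res

## Single linear index used for deterministic tie-breaking on grids.
cell_index <- function(row, col, nlat) (col - 1L) * nlat + row
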