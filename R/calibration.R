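#' Min-max normalization of a series
#'
#' Rescales a series to \[0, 1\] by its own minimum and maximum.
#'
#' @param x Numeric vector with at least two values, not all equal.
#' @return `(x - min(x)) / (max(x) - min(x))`.
#' @export
minmax_normalize <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least two values", call. = FALSE)
  rng <- range(x, na.rm = TRUE)
  if (rng[1] == rng[2]) stop("cannot normalize a constant series", call. = FALSE)
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 * s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` using
#' population (n-divisor) moments, Lin's original formulation. It combines
#' precision (correlation) with accuracy (departure of the means and scales
#' from the 1:1 line), so `lin_ccc(x, x) = 1` and a scale or location shift
#' lowers it below the Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length >= 2, finite values.
#' @return Concordance in \[-1, 1\].
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2) stop("need at least two paired values", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxy <- mean((x - mx) * (y - my))
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) stop("zero variance with equal means: CCC undefined", call. = FALSE)
  2 * sxy / denom
}

#' Inter-extinction rising segments of a diversity curve
#'
#' Splits the time axis of a curve (ages in Ma, oldest first) at the
#' scheduled mass-extinction windows: one segment from the start of the
#' series to the beginning of the first event, one between the end of each
#' event and the beginning of the next, and one from the end of the last
#' event to the end of the series. Segment boundaries are closed (a slice
#' age equal to an event's start or end belongs to the adjacent segment);
#' ages strictly inside an event window belong to no segment. Empty
#' segments are dropped. Concordance is then computed on the concatenation
#' of these segments, excluding the forced extinction drops themselves.
#'
#' @param ages Numeric vector of ages in Ma, strictly decreasing.
#' @param schedule An `extinction_schedule` (may have zero events).
#' @return List of integer index vectors into `ages`.
#' @export
rising_segments <- function(ages, schedule) {
  if (is.null(schedule) || nrow(schedule) == 0) return(list(seq_along(ages)))
  upper <- c(Inf, schedule$end_age)    # older bound of each segment
  lower <- c(schedule$start_age, -Inf) # younger bound
  out <- lapply(seq_along(upper), function(j)
    which(ages <= upper[j] & ages >= lower[j]))
  out[vapply(out, length, integer(1)) > 0]
}

## CCC between a model curve and a reference curve on rising segments.
## Both series are min-max normalized over their full (non-NA) span first;
## the reference is linearly interpolated onto the model ages beforehand.
ccc_on_rising <- function(model_ages, model_vals, ref_ages, ref_vals,
                          schedule) {
  ref_interp <- stats::approx(ref_ages, ref_vals, xout = model_ages,
                              rule = 2)$y
  ok <- is.finite(model_vals) & is.finite(ref_interp)
  mnorm <- rep(NA_real_, length(model_vals))
  rnorm_ <- rep(NA_real_, length(ref_interp))
  mnorm[ok] <- minmax_normalize(model_vals[ok])
  rnorm_[ok] <- minmax_normalize(ref_interp[ok])
  idx <- unlist(rising_segments(model_ages, schedule))
  idx <- idx[ok[idx]]
  lin_ccc(mnorm[idx], rnorm_[idx])
}

#' Compare a model global curve against a reference curve
#'
#' Aligns the reference curve to the model's slice ages by linear
#' interpolation, min-max normalizes both series, and computes Lin's CCC on
#' the concatenated inter-extinction rising segments.
#'
#' @param curve A `global_curve` from [global_diversity_curve()].
#' @param reference Data frame with columns `age_ma` and `diversity`.
#' @param schedule The `extinction_schedule` used in the run (or `NULL`).
#' @return Lin's CCC (scalar).
#' @export
compare_to_reference <- function(curve, reference, schedule = NULL) {
  ccc_on_rising(curve$age_ma, curve$gamma_total,
                reference$age_ma, reference$diversity, schedule)
}

#' Grid search over carrying-capacity bounds
#'
#' Enumerates all pairs `k_min < k_max` from a base-2 geometric sequence
#' (default 2, 4, ..., 256: 28 pairs), runs the full logistic pipeline
#' (simulation plus transect-based global integration) for each pair, and
#' tabulates Lin's CCC against the reference curve on rising segments.
#' Pipeline failures are recorded as `NA`, not fatal.
#'
#' @param world A `world_history`.
#' @param params_template A [model_params()] object supplying every
#'   parameter except the carrying-capacity bounds; forced to the logistic
#'   model.
#' @param schedule An `extinction_schedule` (or `NULL`).
#' @param reference Data frame with `age_ma`, `diversity`.
#' @param decay A [decay_params()] object.
#' @param k_values Carrying-capacity grid (default `2^(1:8)`).
#' @param threshold CCC selection threshold for [calibrate_bounds()]
#'   (default 0.70).
#' @return An object of class `calibration_result`: list with the results
#'   `table` (`k_min`, `k_max`, `ccc`) and `threshold`.
#' @export
k_bounds_grid_search <- function(world, params_template, schedule, reference,
                                 decay = decay_params(),
                                 k_values = 2^(1:8), threshold = 0.70) {
  pairs <- t(utils::combn(sort(k_values), 2))
  tab <- data.frame(k_min = pairs[, 1], k_max = pairs[, 2], ccc = NA_real_)
  for (i in seq_len(nrow(tab))) {
    tab$ccc[i] <- tryCatch({
      p <- params_template
      p$k_min <- tab$k_min[i]
      p$k_max <- tab$k_max[i]
      p$model_kind <- "logistic"
      validate_model_params(p)
      hist_i <- simulate_diversity(world, p, schedule)
      curve <- global_diversity_curve(hist_i, world, decay)
      compare_to_reference(curve, reference, schedule)
    }, error = function(e) NA_real_)
  }
  structure(list(table = tab, threshold = threshold),
            class = "calibration_result")
}

#' Average the carrying-capacity bounds of well-fitting pairs
#'
#' Arithmetic mean of `k_min` and of `k_max` over all grid-search rows with
#' CCC above the threshold.
#'
#' @param result A `calibration_result` from [k_bounds_grid_search()].
#' @param threshold CCC selection threshold; defaults to the one stored in
#'   `result`.
#' @return Named numeric vector `c(k_min = ..., k_max = ...)`.
#' @export
calibrate_bounds <- function(result, threshold = result$threshold) {
  tab <- result$table
  sel <- tab[!is.na(tab$ccc) & tab$ccc > threshold, , drop = FALSE]
  if (nrow(sel) == 0)
    stop(sprintf(paste0("no parameter pair reaches CCC > %.2f; ",
                        "consider lowering the threshold"), threshold),
         call. = FALSE)
  c(k_min = mean(sel$k_min), k_max = mean(sel$k_max))
}

#' Sweep diversification parameters against a reference curve
#'
#' Runs the full pipeline for every row of a parameter grid (columns among
#' `q10`, `k_food`, `rho_min`, `rho_max`, `k_min`, `k_max`, `model_kind`)
#' and ranks the combinations by Lin's CCC against the reference; the
#' `top_n` best are flagged as selected. Fully deterministic given the
#' world.
#'
#' @param grid Data frame of parameter combinations.
#' @param world A `world_history`.
#' @param schedule An `extinction_schedule` (or `NULL`).
#' @param reference Data frame with `age_ma`, `diversity`.
#' @param params_template A [model_params()] supplying unswept parameters.
#' @param decay A [decay_params()] object.
#' @param top_n Number of combinations to flag (default 15).
#' @return The grid with columns `ccc`, `rank` and logical `selected`.
#' @export
parameter_sweep <- function(grid, world, schedule, reference,
                            params_template = model_params(),
                            decay = decay_params(), top_n = 15) {
  if (nrow(grid) == 0) stop("empty parameter grid", call. = FALSE)
  grid$ccc <- NA_real_
  settable <- intersect(names(grid),
                        c("q10", "k_food", "rho_min", "rho_max",
                          "k_min", "k_max", "model_kind"))
  for (i in seq_len(nrow(grid))) {
    grid$ccc[i] <- tryCatch({
      p <- params_template
      for (f in settable) p[[f]] <- grid[[f]][i]
      validate_model_params(p)
      hist_i <- simulate_diversity(world, p, schedule)
      curve <- global_diversity_curve(hist_i, world, decay)
      compare_to_reference(curve, reference, schedule)
    }, error = function(e) NA_real_)
  }
  grid$rank <- rank(-grid$ccc, ties.method = "first", na.last = "keep")
  grid$selected <- !is.na(grid$rank) & grid$rank <= top_n
  grid
}
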