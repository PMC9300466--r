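test_that("distance decay of Jaccard similarity follows the fitted curve", {
  dp <- decay_params()  # J_off 0.06, J_max 1.0, lambda 0.0024 /km
  expect_equal(distance_decay_similarity(0, dp), 1.0)
  expect_equal(distance_decay_similarity(1000, dp),
               0.06 + 0.94 * exp(-2.4))
  expect_equal(distance_decay_similarity(1000, dp), 0.14527,
               tolerance = 1e-4)
  expect_equal(distance_decay_similarity(2e4, dp), 0.06, tolerance = 1e-12)
  d <- seq(0, 5000, by = 100)
  expect_true(all(diff(distance_decay_similarity(d, dp)) < 0))
  expect_error(distance_decay_similarity(-5, dp), ">= 0")
})

test_that("Jaccard-to-Simpson conversion clamps ecologically absurd overlap", {
  expect_equal(jaccard_to_simpson(0, 10, 3), 0)
  expect_equal(jaccard_to_simpson(0.5, 10, 5), 1.0)   # (1+2)*0.5/1.5
  expect_equal(jaccard_to_simpson(0.9, 30, 10), 2 * 0.9 / 1.9)  # clamped
  expect_equal(jaccard_to_simpson(0.9, 30, 10), 0.9474, tolerance = 1e-4)
  # overlap never implies more shared genera than the poorer community
  set.seed(1)
  j <- runif(200); a <- sample(1:50, 200, TRUE); b <- sample(1:50, 200, TRUE)
  v <- jaccard_to_simpson(j, a, b)
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(v * pmin(a, b) <= pmin(a, b) + 1e-9))
})

test_that("transect integration matches hand-worked accumulations", {
  expect_equal(transect_gamma(c(10, 6, 3), c(0.8, 0.5)), 12.7)
  expect_equal(transect_gamma(c(7, 5, 4, 2), c(1, 1, 1)), 7)   # full overlap
  expect_equal(transect_gamma(c(7, 5, 4, 2), c(0, 0, 0)), 18)  # disjoint
  expect_error(transect_gamma(numeric(0), numeric(0)), "empty")
  expect_error(transect_gamma(c(3, 2), 0.5 * c(1, 1)), "pair")
})

test_that("transect diversity equals the cardinality of explicit genus sets", {
  # Construct communities realizing given Simpson overlaps under the
  # nesting assumption (genera shared by cells n and n+2 occur in n+1):
  # community n+1 takes s_n genera from community n plus brand-new ones.
  set.seed(42)
  for (rep in 1:250) {
    len <- sample(2:8, 1)
    alpha <- sort(sample(1:40, len, replace = TRUE), decreasing = TRUE)
    shared <- integer(len - 1)
    comms <- vector("list", len)
    comms[[1]] <- seq_len(alpha[1])
    next_id <- alpha[1] + 1
    for (n in seq_len(len - 1)) {
      shared[n] <- sample(0:min(alpha[n], alpha[n + 1]), 1)
      keep <- sample(comms[[n]], shared[n])
      fresh <- seq.int(next_id, length.out = alpha[n + 1] - shared[n])
      next_id <- next_id + length(fresh)
      comms[[n + 1]] <- c(keep, fresh)
    }
    v <- shared / alpha[-1]  # Simpson overlap: shared / min = alpha[n+1]
    union_size <- length(unique(unlist(comms)))
    expect_equal(transect_gamma(alpha, v), union_size)
  }
})

test_that("peaks are retained local maxima with plateau middles", {
  res <- 10
  base <- matrix(NA_real_, 18, 36)

  # a single smooth bump: exactly the argmax cell
  bump <- base
  bump[7:11, 10:14] <- outer(-(7:11 - 9)^2, -(10:14 - 12)^2, "+") + 30
  pk <- find_peaks(make_grid(bump, res))
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$row, pk$col), c(9, 12))

  # three equal collinear cells above their neighbours: middle cell only
  plat <- base
  plat[9, 10:16] <- 1
  plat[9, 12:14] <- 5
  pk <- find_peaks(make_grid(plat, res))
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$row, pk$col), c(9, 13))

  # eight isolated maxima valued 1..8: the 0.75-quantile rule keeps {7, 8}
  iso <- base
  cols <- seq(2, 30, by = 4)
  for (i in 1:8) iso[4, cols[i]] <- i
  pk <- find_peaks(make_grid(iso, res))
  expect_equal(sort(pk$value), c(7, 8))

  # empty map
  expect_equal(nrow(find_peaks(make_grid(base, res))), 0)
})

test_that("peak detection wraps across the antimeridian", {
  res <- 10
  div <- matrix(NA_real_, 18, 36)
  div[9, 36] <- 5   # would be a local max without wraparound
  div[9, 1] <- 9
  pk <- find_peaks(make_grid(div, res))
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$row, pk$col), c(9, 1))
})

test_that("troughs are newly formed ocean cells", {
  res <- 10
  age <- matrix(NA_real_, 18, 36)
  cls <- matrix("ocean", 18, 36)
  age[5, 3] <- 0; age[9, 18] <- 0; age[12, 30] <- 0
  age[6, 6] <- 40
  age[2, 2] <- 0; cls[2, 2] <- "flooded_shelf"  # young but not ocean
  g <- make_grid(matrix(1, 18, 36), res, class = cls, age = age)
  tr <- find_troughs(g)
  expect_equal(nrow(tr), 3)
  expect_setequal(paste(tr$row, tr$col),
                  c("5 3", "9 18", "12 30"))
})

test_that("transect tracing follows the line, rejects land, truncates", {
  res <- 10
  div <- matrix(2, 18, 36)
  age <- matrix(NA_real_, 18, 36)
  age[9, 19] <- 0
  g <- make_grid(div, res, age = age)
  troughs <- find_troughs(g)

  # orthogonal adjacency: a two-cell transect (high latitude, so the step
  # stays inside the length cut)
  age2 <- matrix(NA_real_, 18, 36)
  age2[2, 19] <- 0
  ga <- make_grid(div, res, age = age2)
  tr <- trace_transect(list(row = 2, col = 18), find_troughs(ga), ga,
                       decay_params())
  expect_s3_class(tr, "transect")
  expect_equal(nrow(tr$cells), 2)
  expect_equal(tr$cells$alpha, c(2, 2))

  # land rule: 3 continental cells on a 10-cell path is 30% > 20%
  cls <- matrix("ocean", 18, 36)
  cls[9, c(12, 14, 16)] <- "continental"
  gl <- make_grid(div, res, class = cls, age = age)
  expect_null(trace_transect(list(row = 9, col = 10),
                             find_troughs(gl), gl, decay_params()))
  # and 1 of 10 (10%) passes
  cls2 <- matrix("ocean", 18, 36)
  cls2[9, 14] <- "continental"
  g2 <- make_grid(div, res, class = cls2, age = age)
  expect_s3_class(trace_transect(list(row = 9, col = 10),
                                 find_troughs(g2), g2, decay_params()),
                  "transect")
  expect_error(trace_transect(list(row = 9, col = 10),
                              troughs[0, ], g, decay_params()), "trough")
})

test_that("transects keep the peak-side prefix within the length cut", {
  # fine grid: 0.5-degree equatorial cells are ~55.6 km apart, so a
  # 20-cell path spans ~1,060 km and is cut near 555 km
  res <- 0.5
  div <- matrix(NA_real_, 360, 720)
  row0 <- 181  # latitude -0.25
  div[row0, 100:119] <- seq(20, 1, length.out = 20)
  age <- matrix(NA_real_, 360, 720)
  age[row0, 119] <- 0
  g <- make_grid(div, res, age = age)
  tr <- trace_transect(list(row = row0, col = 100), find_troughs(g), g,
                       decay_params())
  expect_lte(tr$length_km, 555)
  expect_gt(tr$length_km, 555 - 2 * 56)
  expect_equal(nrow(tr$cells), 10)
  # doubling the cut keeps strictly more of the path and never lowers gamma
  tr2 <- trace_transect(list(row = row0, col = 100), find_troughs(g), g,
                        decay_params(truncation_km = 1110))
  expect_gt(nrow(tr2$cells), nrow(tr$cells))
  g1 <- integrate_transect(tr, decay_params())$gamma
  g2 <- integrate_transect(tr2, decay_params(truncation_km = 1110))$gamma
  expect_gte(g2, g1)
})

test_that("rasterization separates habitat classes and averages cells", {
  w <- constant_world(n_slices = 3, n_points = 2, res = 10)
  # two shelf points in the same cell with D 4 and 6: cell mean 5
  w$points$lat <- 2; w$points$lon <- 5
  w$config$n_continental_points <- 2
  nlat <- 18
  cls <- matrix("ocean", 18, 36)
  cls[phanerodiv:::lat_to_row(2, 10), phanerodiv:::lon_to_col(5, 10)] <-
    "flooded_shelf"
  for (s in 1:3) w$grids[[s]]$class <- cls
  h <- simulate_diversity(w, pinned_params())
  h$D[h$slice == 2] <- c(4, 6)
  g <- rasterize_points(h, w, 2)
  expect_equal(sum(!is.na(g$div)), 1)
  expect_equal(g$div[phanerodiv:::lat_to_row(2, 10),
                     phanerodiv:::lon_to_col(5, 10)], 5)

  # an ocean point in a shelf-annotated cell never fills it, and vice versa
  w2 <- build_world(tiny_config(seed = 17))
  h2 <- simulate_diversity(w2, model_params())
  for (s in c(4, 10)) {
    g2 <- rasterize_points(h2, w2, s)
    filled <- !is.na(g2$div)
    expect_true(all(g2$class[filled] %in% c("flooded_shelf", "ocean")))
  }
})

test_that("zigzag integration absorbs duplicates and respects bounds", {
  dp <- decay_params()
  t1 <- stub_transect(20, lat = 0, lon = 0, row = 9, col = 18)
  t2 <- stub_transect(10, lat = 30, lon = 60, row = 6, col = 24)

  # single transect: the base case
  expect_equal(integrate_global(list(t1), dp)$gamma_total, 20)

  # two distant transects: hand evaluation of the zigzag rule
  d <- gc_distance_km(0, 0, 30, 60)
  v <- jaccard_to_simpson(distance_decay_similarity(d, dp), 10, 20)
  expect_equal(integrate_global(list(t1, t2), dp)$gamma_total,
               20 + (1 - v) * 10)

  # coincident peaks: the poorer duplicate is fully absorbed
  t3 <- stub_transect(12, lat = 0, lon = 0, row = 9, col = 18)
  expect_equal(integrate_global(list(t1, t3), dp)$gamma_total, 20)
  # duplicate-transect invariance
  expect_equal(integrate_global(list(t1, t2, t1), dp)$gamma_total,
               integrate_global(list(t1, t2), dp)$gamma_total)

  # bounds over random transect sets
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    ts <- lapply(seq_len(n), function(i)
      stub_transect(runif(1, 1, 50), lat = runif(1, -80, 80),
                    lon = runif(1, -180, 180), row = i, col = i))
    gs <- vapply(ts, function(t) t$gamma, numeric(1))
    tot <- integrate_global(ts, dp)$gamma_total
    expect_gte(tot, max(gs) - 1e-9)
    expect_lte(tot, sum(gs) + 1e-9)
  }
})

test_that("per-transect bounds hold on simulated worlds", {
  w <- build_world(tiny_config(seed = 23, grid_resolution = 5,
                               n_ocean_points = 100))
  h <- simulate_diversity(w, model_params())
  dp <- decay_params()
  checked <- 0
  for (s in c(5, 10, 16)) {
    g <- rasterize_points(h, w, s, dp)
    if (!any(!is.na(g$div))) next
    troughs <- find_troughs(g)
    if (!nrow(troughs)) next
    peaks <- find_peaks(g, dp)
    for (i in seq_len(nrow(peaks))) {
      tr <- trace_transect(peaks[i, ], troughs, g, dp)
      if (is.null(tr)) next
      it <- integrate_transect(tr, dp)
      a <- it$cells$alpha
      expect_gte(it$gamma, a[1] - 1e-9)
      expect_lte(it$gamma, sum(a) + 1e-9)
      expect_true(all(it$v >= 0 & it$v <= 1))
      checked <- checked + 1
    }
  }
  expect_gt(checked, 3)
})

test_that("the global curve drops at a forced extinction and flags gaps", {
  w <- build_world(tiny_config(seed = 19, grid_resolution = 5,
                               n_ocean_points = 100, n_slices = 14,
                               start_age = 65))
  sch <- make_extinction_schedule(data.frame(start_age = 30, duration = 5,
                                             loss_fraction = 0.9))
  h <- simulate_diversity(w, model_params(), sch)
  cv <- global_diversity_curve(h, w)
  expect_s3_class(cv, "global_curve")
  i_before <- which(cv$age_ma == 30)
  i_after <- which(cv$age_ma == 25)
  expect_false(cv$skipped[i_before] || cv$skipped[i_after])
  expect_lt(cv$gamma_total[i_after], cv$gamma_total[i_before])
  expect_true(all(is.na(cv$gamma_total[cv$skipped])))
})
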