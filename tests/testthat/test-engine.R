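test_that("limitation terms evaluate to their closed forms", {
  # Q10 scaling, normalized to the warm end of the envelope
  expect_equal(temperature_limitation(30, 0, 30, 1.75), 1)
  expect_equal(temperature_limitation(0, 0, 30, 1.75), 1.75^-3)
  expect_equal(temperature_limitation(0, 0, 30, 1.75), 0.18659,
               tolerance = 1e-4)
  expect_equal(temperature_limitation(c(-10, 50), 0, 30, 1.75),
               c(1.75^-3, 1))  # clamped to the envelope
  expect_equal(temperature_limitation(12, 0, 30, 1), 1)
  expect_equal(temperature_limitation(5, 5, 5, 1.75), 1)  # degenerate

  # Michaelis-Menten food limitation
  expect_equal(food_limitation(0.5, 0.5), 0.5)
  expect_equal(food_limitation(0, 0.5), 0)
  expect_equal(food_limitation(1.5, 0.5), 0.75)
  expect_error(food_limitation(-1, 0.5), ">= 0")
})

test_that("net diversification rate interpolates between its limits", {
  p <- model_params()  # calibrated run: 0.001 - 0.035 Myr^-1
  expect_equal(net_diversification_rate(1, 1, p), 0.035)
  expect_equal(net_diversification_rate(0, 1, p), 0.001)
  expect_equal(net_diversification_rate(1, 0.5, p), 0.018)
  # monotone in the product of the limitation terms
  q <- seq(0, 1, by = 0.05)
  expect_true(all(diff(net_diversification_rate(q, 1, p)) > 0))
  r <- net_diversification_rate(runif(50), runif(50), p)
  expect_true(all(r >= p$rho_min & r <= p$rho_max))
})

test_that("effective carrying capacity maps the POC envelope linearly", {
  p <- model_params()  # calibrated bounds 12 - 123 genera
  expect_equal(effective_carrying_capacity(3, 0.1, 3, p), 123)
  expect_equal(effective_carrying_capacity(0.1, 0.1, 3, p), 12)
  expect_equal(effective_carrying_capacity(1.55, 0.1, 3, p), 67.5)
  # clamped outside the envelope, monotone inside
  expect_equal(effective_carrying_capacity(c(0, 10), 0.1, 3, p), c(12, 123))
  poc <- seq(0.1, 3, length.out = 30)
  expect_true(all(diff(effective_carrying_capacity(poc, 0.1, 3, p)) > 0))
  # degenerate envelope
  expect_equal(effective_carrying_capacity(1, 1, 1, p), 123)
})

test_that("elementary Euler steps match their worked forms", {
  expect_equal(step_logistic(123, 0.035, 123, 1), 123)  # fixed point
  expect_equal(step_logistic(1, 0.035, 123, 1), 1 + 0.035 * (1 - 1 / 123))
  expect_equal(step_logistic(1, 0.035, 123, 1), 1.034715, tolerance = 1e-6)
  expect_equal(step_logistic(200, 0.01, 123, 1), 123)  # arrival reset
  expect_equal(step_exponential(0, 0.035, 1), 0)
  expect_equal(step_exponential(1, 0.035, 1), 1.035)
  expect_equal(step_exponential(5, 0, 1), 5)
})

test_that("Euler stepping converges to the analytic solutions", {
  rho <- 0.035; k <- 123; t_end <- 100
  errs <- vapply(c(1, 0.25, 0.0625), function(dt) {
    d <- 1
    for (i in seq_len(round(t_end / dt))) d <- step_logistic(d, rho, k, dt)
    abs(d - logistic_closed_form(t_end, rho, k)) /
      logistic_closed_form(t_end, rho, k)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))  # first-order convergence
  expect_lt(errs[3], 0.005)
})

test_that("imputed extinction rates remove exactly the scheduled loss", {
  expect_equal(extinction_rate_from_loss(0.9, 5), log(0.1) / 5)
  expect_equal(extinction_rate_from_loss(0.9, 5), -0.46052, tolerance = 1e-4)
  expect_lt(extinction_rate_from_loss(1e-9, 5), 0)
  expect_gt(extinction_rate_from_loss(1e-9, 5), -1e-9)
  # by construction: exponential decay over the duration leaves 1 - loss
  for (loss in c(0.2, 0.55, 0.96)) {
    r <- extinction_rate_from_loss(loss, 7)
    expect_equal(100 * exp(r * 7), 100 * (1 - loss), tolerance = 1e-12)
  }
  expect_error(extinction_rate_from_loss(1, 5), "loss_fraction")
  expect_error(extinction_rate_from_loss(0.5, 0), "duration")
})

test_that("environmental envelopes use per-slice and whole-run quantiles", {
  w <- constant_world(n_slices = 3, n_points = 101)
  w$points$temp <- rep(0:100, each = 3)
  w$points$poc <- rep(seq(0.1, 3, length.out = 101), each = 3)
  env <- env_percentiles(w, model_params())
  expect_equal(env$t_min, rep(1, 3))
  expect_equal(env$t_max, rep(99, 3))
  expect_false(any(env$degenerate))
  # POC envelope is one whole-run pair, shared by all slices
  expect_length(env$poc_min, 1)
  expect_equal(env$poc_min, unname(quantile(w$points$poc, 0.01)))

  # degenerate (all equal) temperatures leave the limitation at 1
  wc <- constant_world(n_slices = 3, n_points = 4)
  envc <- env_percentiles(wc, model_params())
  expect_equal(envc$t_min, envc$t_max)
  expect_equal(temperature_limitation(20, envc$t_min[1], envc$t_max[1], 1.75),
               1)
})

test_that("constant-environment runs track the analytic solutions", {
  w <- constant_world(n_slices = 21, spacing = 5)  # 100 Myr
  for (model in c("logistic", "exponential")) {
    h <- simulate_diversity(w, pinned_params(model = model))
    d_end <- h$D[h$slice == 21]
    exact <- if (model == "logistic") {
      logistic_closed_form(100, 0.035, 123)
    } else {
      exponential_closed_form(100, 0.035)
    }
    expect_equal(d_end, exact, tolerance = 1e-10)
  }
  # the spec-level targets of those oracles
  expect_equal(logistic_closed_form(100, 0.035, 123), 26.3, tolerance = 2e-3)
  expect_equal(exponential_closed_form(100, 0.035), 33.115, tolerance = 1e-4)
})

test_that("simulation respects rate and capacity ranges and logistic bounds", {
  w <- build_world(tiny_config(seed = 4))
  p <- model_params(k_min = 4, k_max = 40)
  h <- simulate_diversity(w, p)
  expect_true(all(h$rho[h$D > 0] >= p$rho_min - 1e-12))
  expect_true(all(h$rho[h$D > 0] <= p$rho_max + 1e-12))
  expect_true(all(h$k_eff[h$D > 0] >= p$k_min & h$k_eff[h$D > 0] <= p$k_max))
  expect_true(all(h$D[h$D > 0] <= h$k_eff[h$D > 0] + 1e-9))
  # all active points start from a single genus
  expect_true(all(h$D[h$slice == 1] == 1))
})

test_that("emergence zeroes diversity and re-flooding seeds from neighbours", {
  w <- build_world(tiny_config(seed = 8, n_continental_points = 40))
  h <- simulate_diversity(w, model_params())
  pts <- w$points
  for (pid in unique(pts$point_id[pts$point_type == "continental"])) {
    cls <- pts$class[pts$point_id == pid][order(pts$slice[pts$point_id == pid])]
    for (s in which(cls[-1] == "emergent_land" &
                      cls[-length(cls)] == "flooded_shelf") + 1) {
      expect_equal(h$D[h$point_id == pid & h$slice == s], 0)
    }
  }
  # re-flooded points: recorded D equals the nearest donor's recorded D
  reflooded <- 0
  for (s in 2:w$config$n_slices) {
    prev <- pts[pts$slice == s - 1, ]; cur <- pts[pts$slice == s, ]
    ids <- cur$point_id[cur$class == "flooded_shelf" &
                          prev$class[match(cur$point_id, prev$point_id)] ==
                          "emergent_land"]
    donors <- intersect(
      prev$point_id[prev$class == "flooded_shelf" &
                      prev$point_type == "continental"],
      cur$point_id[cur$class == "flooded_shelf" &
                     cur$point_type == "continental"])
    hd <- h[h$slice == s, ]
    dvals <- hd$D[match(donors, hd$point_id)]
    donors <- donors[dvals > 1]; dvals <- dvals[dvals > 1]
    for (pid in ids) {
      got <- hd$D[hd$point_id == pid]
      if (!length(donors)) {
        expect_equal(got, 1)
      } else {
        pc <- cur[cur$point_id == pid, ]
        dn <- cur[match(donors, cur$point_id), ]
        dd <- gc_distance_km(pc$lat, pc$lon, dn$lat, dn$lon)
        expect_equal(got, min(dvals[which.min(dd)],
                              hd$k_eff[hd$point_id == pid]))
        reflooded <- reflooded + 1
      }
    }
  }
  expect_gt(reflooded, 0)  # the fixture actually exercises recolonization
})

test_that("logistic with enormous capacity reproduces the exponential run", {
  w <- build_world(tiny_config(n_slices = 20, start_age = 95,
                               n_continental_points = 60,
                               n_ocean_points = 140, seed = 31))
  base <- model_params(rho_min = 0.005, rho_max = 0.035)
  p_log <- base; p_log$k_min <- p_log$k_max <- 1e9
  p_exp <- base; p_exp$model_kind <- "exponential"
  h1 <- simulate_diversity(w, p_log)
  h2 <- simulate_diversity(w, p_exp)
  expect_equal(nrow(h1), nrow(h2))
  expect_true(all(abs(h1$D - h2$D) <= 1e-6 * pmax(h2$D, 1)))
})

test_that("scheduled losses are applied exactly and floored at one genus", {
  w <- constant_world(n_slices = 21, spacing = 5)  # ages 100..0
  sch <- make_extinction_schedule(data.frame(start_age = 20, duration = 5,
                                             loss_fraction = 0.9))
  h0 <- simulate_diversity(w, pinned_params())
  h1 <- simulate_diversity(w, pinned_params(), sch)
  d_before <- h1$D[h1$age_ma == 20]
  d_after <- h1$D[h1$age_ma == 15]
  expect_gt(0.1 * d_before, 1)
  expect_equal(d_after, 0.1 * d_before, tolerance = 1e-12)
  # identical to the unforced run before the event
  expect_equal(h1$D[h1$age_ma > 20], h0$D[h0$age_ma > 20])
  # a deep early loss is floored at one genus
  sch2 <- make_extinction_schedule(data.frame(start_age = 95, duration = 5,
                                              loss_fraction = 0.95))
  h2 <- simulate_diversity(w, pinned_params(), sch2)
  expect_equal(h2$D[h2$age_ma == 90], 1)
  # an empty schedule is identical to no forcing
  h3 <- simulate_diversity(w, pinned_params(),
                           make_extinction_schedule(NULL))
  expect_identical(h3$D, h0$D)
})

test_that("missing environment on an active point is reported", {
  w <- constant_world(n_slices = 4, n_points = 2)
  w$points$temp[w$points$slice == 3 & w$points$point_id == 2] <- NA
  expect_error(simulate_diversity(w, pinned_params()),
               "point 2 at slice 3")
})
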