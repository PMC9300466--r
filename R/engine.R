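#' Diversification model parameters
#'
#' Collects every tunable of the regional diversification model: the net
#' diversification rate limits, the temperature sensitivity (Q10), the food
#' half-saturation constant, the carrying-capacity bounds and the envelope
#' quantiles. Defaults are the calibrated run of the full-scale analysis:
#' rho in 0.001-0.035 Myr^-1 per capita, Q10 = 1.75, K_food = 0.5
#' mol C m^-2 yr^-1 and carrying-capacity bounds of 12-123 genera per cell.
#'
#' @param rho_min,rho_max Lower and upper net diversification rate limits
#'   (Myr^-1 per capita), 0 < rho_min <= rho_max.
#' @param q10 Temperature sensitivity of the origination rate (>= 1).
#' @param k_food Half-saturation POC flux (mol C m^-2 yr^-1): the flux at
#'   which food limitation halves the diversification rate.
#' @param k_min,k_max Carrying-capacity bounds (genera per cell).
#' @param temp_quantiles,poc_quantiles Quantile pair defining the
#'   temperature envelope (per slice) and the POC envelope (whole run).
#' @param ode_step Integration substep in Myr (default 1): the lag at which
#'   the environment is refreshed during simulation.
#' @param model_kind `"logistic"` (diversity-dependent) or `"exponential"`.
#' @return An object of class `model_params`.
#' @export
model_params <- function(rho_min = 0.001, rho_max = 0.035,
                         q10 = 1.75, k_food = 0.5,
                         k_min = 12, k_max = 123,
                         temp_quantiles = c(0.01, 0.99),
                         poc_quantiles = c(0.01, 0.99),
                         ode_step = 1,
                         model_kind = c("logistic", "exponential")) {
  model_kind <- match.arg(model_kind)
  p <- structure(
    list(rho_min = rho_min, rho_max = rho_max, q10 = q10, k_food = k_food,
         k_min = k_min, k_max = k_max, temp_quantiles = temp_quantiles,
         poc_quantiles = poc_quantiles, ode_step = ode_step,
         model_kind = model_kind),
    class = "model_params")
  validate_model_params(p)
  p
}

validate_model_params <- function(p) {
  if (p$rho_min <= 0 || p$rho_min > p$rho_max)
    stop_field("rho_min", "need 0 < rho_min <= rho_max")
  if (p$q10 < 1) stop_field("q10", "must be >= 1")
  if (p$k_food <= 0) stop_field("k_food", "must be > 0")
  if (p$k_min <= 0 || p$k_min > p$k_max)
    stop_field("k_min", "need 0 < k_min <= k_max")
  if (p$ode_step <= 0) stop_field("ode_step", "must be > 0")
  invisible(p)
}

#' Temperature limitation of the net diversification rate
#'
#' Q10-type scaling normalized to the warm end of the per-slice temperature
#' envelope: `q10^((T - t_min)/10) / q10^((t_max - t_min)/10)`. Temperatures
#' outside the envelope are clamped to it, so the value lies in (0, 1] and
#' equals 1 at `t_max`. A degenerate envelope (`t_min == t_max`) yields 1.
#'
#' @param temp Seawater temperature(s), degrees C.
#' @param t_min,t_max Envelope bounds (typically the 0.01 and 0.99 empirical
#'   percentiles of the slice's temperature distribution).
#' @param q10 Temperature sensitivity (>= 1).
#' @return Numeric in (0, 1], vectorized over `temp`.
#' @export
temperature_limitation <- function(temp, t_min, t_max, q10) {
  if (any(t_max < t_min)) stop("t_max must be >= t_min", call. = FALSE)
  tt <- pmin(pmax(temp, t_min), t_max)
  out <- q10^((tt - t_min) / 10) / q10^((t_max - t_min) / 10)
  out[t_min == t_max] <- 1
  out
}

#' Food limitation of the net diversification rate
#'
#' Michaelis-Menten saturation of the POC export flux:
#' `poc / (k_food + poc)`, so the limitation equals 0.5 when the flux equals
#' the half-saturation constant.
#'
#' @param poc POC export flux (mol C m^-2 yr^-1), >= 0.
#' @param k_food Half-saturation constant (> 0).
#' @return Numeric in \[0, 1), vectorized.
#' @export
food_limitation <- function(poc, k_food) {
  if (any(poc < 0)) stop("poc must be >= 0", call. = FALSE)
  poc / (k_food + poc)
}

#' Net diversification rate from limitation terms
#'
#' `rho = rho_max - (rho_max - rho_min) * (1 - q_temp * q_food)`: the rate
#' interpolates linearly between its bounds as the product of the
#' temperature and food limitation terms goes from 0 to 1.
#'
#' @param q_temp,q_food Limitation terms in \[0, 1\].
#' @param params A [model_params()] object.
#' @return Rate(s) in Myr^-1, within `[rho_min, rho_max]`.
#' @export
net_diversification_rate <- function(q_temp, q_food, params) {
  params$rho_max - (params$rho_max - params$rho_min) * (1 - q_temp * q_food)
}

#' Effective carrying capacity from POC flux
#'
#' Linear map sending the POC envelope `[poc_min, poc_max]` to the
#' carrying-capacity bounds `[k_min, k_max]`, clamped to the bounds outside
#' the envelope. A degenerate envelope (`poc_min == poc_max`) returns
#' `k_max`.
#'
#' @param poc POC export flux (mol C m^-2 yr^-1).
#' @param poc_min,poc_max Whole-run POC envelope (typically the 0.01 and
#'   0.99 empirical quantiles over all slices and points).
#' @param params A [model_params()] object.
#' @return Carrying capacity in genera per cell, vectorized over `poc`.
#' @export
effective_carrying_capacity <- function(poc, poc_min, poc_max, params) {
  if (poc_max < poc_min) stop("poc_max must be >= poc_min", call. = FALSE)
  if (poc_max == poc_min) return(rep(params$k_max, length(poc)))
  k <- params$k_max - (params$k_max - params$k_min) *
    (poc_max - poc) / (poc_max - poc_min)
  pmin(pmax(k, params$k_min), params$k_max)
}

#' One Euler step of the logistic model
#'
#' Explicit forward step of `dD/dt = rho * D * (1 - D / k_eff)`. An incoming
#' diversity above the carrying capacity is first reset to `k_eff`,
#' emulating local extinction when a point arrives in an environment poorer
#' than the diversity it accumulated.
#'
#' @param d Standing diversity (genera, >= 0), vectorized.
#' @param rho Net diversification rate (Myr^-1).
#' @param k_eff Effective carrying capacity (> 0).
#' @param dt Step length (Myr).
#' @return Updated diversity.
#' @export
step_logistic <- function(d, rho, k_eff, dt) {
  d <- pmin(d, k_eff)
  d + dt * rho * d * (1 - d / k_eff)
}

#' One Euler step of the exponential model
#'
#' Explicit forward step of `dD/dt = rho * D`.
#'
#' @inheritParams step_logistic
#' @return Updated diversity.
#' @export
step_exponential <- function(d, rho, dt) {
  d + dt * rho * d
}

#' Imputed extinction rate from a fractional diversity loss
#'
#' The constant per-capita rate `log(1 - loss_fraction) / duration` whose
#' exponential decay over `duration` removes exactly `loss_fraction` of the
#' standing diversity.
#'
#' @param loss_fraction Fraction of diversity lost, strictly in (0, 1).
#' @param duration Event duration in Myr (> 0).
#' @return Negative rate(s) in Myr^-1.
#' @export
extinction_rate_from_loss <- function(loss_fraction, duration) {
  if (any(loss_fraction <= 0 | loss_fraction >= 1))
    stop("loss_fraction must lie strictly in (0, 1)", call. = FALSE)
  if (any(duration <= 0)) stop("duration must be > 0", call. = FALSE)
  log(1 - loss_fraction) / duration
}

#' Environmental envelopes of a world history
#'
#' Computes the per-slice temperature envelope (quantiles of the active
#' points' temperatures, recomputed every slice to emulate thermal
#' adaptation) and the single whole-run POC envelope (quantiles over all
#' slices and active points). Empirical quantiles use R's default (type 7)
#' interpolation.
#'
#' @param world A `world_history`.
#' @param params A [model_params()] object (supplies the quantile pairs).
#' @return An object of class `env_envelope`: list with per-slice vectors
#'   `t_min`, `t_max`, logical `degenerate` (slices with no active points),
#'   and scalars `poc_min`, `poc_max`.
#' @export
env_percentiles <- function(world, params = model_params()) {
  n <- world$config$n_slices
  p <- world$points
  act <- p[p$class %in% c("flooded_shelf", "ocean"), ]
  t_min <- t_max <- rep(NA_real_, n)
  degenerate <- rep(TRUE, n)
  for (s in seq_len(n)) {
    tt <- act$temp[act$slice == s]
    tt <- tt[!is.na(tt)]  # missing env is caught per point during stepping
    if (length(tt)) {
      qq <- stats::quantile(tt, params$temp_quantiles, names = FALSE)
      t_min[s] <- qq[1]; t_max[s] <- qq[2]
      degenerate[s] <- FALSE
    }
  }
  poc_all <- act$poc[!is.na(act$poc)]
  if (length(poc_all)) {
    pq <- stats::quantile(poc_all, params$poc_quantiles, names = FALSE)
  } else {
    pq <- c(NA_real_, NA_real_)
  }
  structure(list(t_min = t_min, t_max = t_max, degenerate = degenerate,
                 poc_min = pq[1], poc_max = pq[2]),
            class = "env_envelope")
}

## Closed-form advance of the frozen-coefficient ODEs over one substep.
## Holding rho and k_eff constant, the logistic and exponential equations
## have exact solutions; advancing with them (an exponential-integrator
## scheme) keeps the 1 Myr environmental lag while adding no truncation
## error of its own. Incoming D above k_eff is still reset to k_eff.
advance_logistic <- function(d, rho, k_eff, dt) {
  d <- pmin(d, k_eff)
  g <- exp(rho * dt)
  k_eff * d * g / (k_eff + d * (g - 1))
}

advance_exponential <- function(d, rho, dt) {
  d * exp(rho * dt)
}

## Is time `t_ma` (Ma) inside any scheduled event window? Returns the
## imputed rate of the covering event, or NA if none.
event_rate_at <- function(t_ma, schedule) {
  if (is.null(schedule) || nrow(schedule) == 0) return(rep(NA_real_, length(t_ma)))
  out <- rep(NA_real_, length(t_ma))
  for (i in seq_len(nrow(schedule))) {
    inside <- t_ma <= schedule$start_age[i] & t_ma > schedule$end_age[i]
    out[inside] <- schedule$imputed_rate[i]
  }
  out
}

#' Simulate diversification over a world history
#'
#' Runs the full Lagrangian simulation: every active point starts with a
#' single genus at the oldest slice and accumulates diversity under the
#' environment-dependent net diversification rate. Time advances in
#' substeps of `params$ode_step` Myr with the environment (and hence rho
#' and K_eff) held constant within each slice interval; each substep
#' applies the closed-form solution of the frozen-coefficient logistic or
#' exponential equation, so the only discretization is the environmental
#' lag itself. Mass-extinction windows replace the
#' environmental dynamics with pure exponential decay at the event's imputed
#' rate (non-selective, "field of bullets"), and surviving active points are
#' floored at one genus. Continental points that emerge have their diversity
#' set to 0; re-flooded points are seeded with the diversity of the nearest
#' (great-circle) flooded continental point with more than one genus (ties
#' by lowest `point_id`), or 1 if none exists; subducted points are removed
#' and their diversity is lost; newly created ocean points start at 1. Under
#' the logistic model the recorded diversity is clipped to the effective
#' carrying capacity at every substep and at every recording.
#'
#' @param world A `world_history`.
#' @param params A [model_params()] object.
#' @param schedule An [make_extinction_schedule()] object, or `NULL` for an
#'   unforced run.
#' @return An object of class `diversity_history`: a long data frame with
#'   `point_id`, `slice`, `age_ma`, `class`, `lat`, `lon`, `D`, `k_eff`,
#'   `rho`, carrying the `model_params` and the [env_percentiles()] envelope
#'   as attributes. Inactive slices (emergent/destroyed) record `D = 0` on
#'   emergence; destroyed points are dropped.
#' @export
simulate_diversity <- function(world, params = model_params(),
                               schedule = NULL) {
  validate_model_params(params)
  env <- env_percentiles(world, params)
  n <- world$config$n_slices
  ages <- world$slice_ages
  logistic <- params$model_kind == "logistic"
  pts <- world$points
  by_slice <- split(pts, pts$slice)

  point_env <- function(s) {
    ps <- by_slice[[as.character(s)]]
    if (is.null(ps)) ps <- pts[0, , drop = FALSE]
    ps[ps$class %in% c("flooded_shelf", "ocean"), , drop = FALSE]
  }
  rates_for <- function(ps, s) {
    bad <- is.na(ps$temp) | is.na(ps$poc)
    if (any(bad))
      stop(sprintf("missing environment for point %d at slice %d",
                   ps$point_id[which(bad)[1]], s), call. = FALSE)
    qt <- temperature_limitation(ps$temp, env$t_min[s], env$t_max[s],
                                 params$q10)
    qf <- food_limitation(ps$poc, params$k_food)
    rho <- net_diversification_rate(qt, qf, params)
    keff <- effective_carrying_capacity(ps$poc, env$poc_min, env$poc_max,
                                        params)
    list(rho = rho, k_eff = keff)
  }

  records <- vector("list", n)
  ps1 <- point_env(1)
  D <- rep(1, nrow(ps1))
  names(D) <- as.character(ps1$point_id)
  r1 <- if (nrow(ps1)) rates_for(ps1, 1) else list(rho = numeric(), k_eff = numeric())
  records[[1]] <- data.frame(point_id = ps1$point_id, slice = 1L,
                             age_ma = ages[1], class = ps1$class,
                             lat = ps1$lat, lon = ps1$lon, D = D,
                             k_eff = r1$k_eff, rho = r1$rho,
                             stringsAsFactors = FALSE)

  for (s in seq_len(n - 1)) {
    ps <- point_env(s)
    nxt <- point_env(s + 1)
    dt_total <- ages[s] - ages[s + 1]
    n_sub <- max(1L, as.integer(round(dt_total / params$ode_step)))
    dt <- dt_total / n_sub

    ## integrate points active at both s and s+1
    cont_ids <- intersect(ps$point_id, nxt$point_id)
    Dc <- D[as.character(cont_ids)]
    Dc[is.na(Dc)] <- 1  # safety: active point with no prior state
    if (length(cont_ids)) {
      psc <- ps[match(cont_ids, ps$point_id), , drop = FALSE]
      rr <- rates_for(psc, s)
      for (k in seq_len(n_sub)) {
        t_mid <- ages[s] - (k - 0.5) * dt
        rext <- event_rate_at(t_mid, schedule)[1]
        if (!is.na(rext)) {
          Dc <- pmax(advance_exponential(Dc, rext, dt), 1)
        } else if (logistic) {
          Dc <- advance_logistic(Dc, rr$rho, rr$k_eff, dt)
        } else {
          Dc <- advance_exponential(Dc, rr$rho, dt)
        }
      }
    }

    ## assemble the state at slice s+1; arrival clipping happens before
    ## recolonization seeding so donors hand over their recorded diversity
    rr2 <- if (nrow(nxt)) rates_for(nxt, s + 1) else list(rho = numeric(), k_eff = numeric())
    newD <- rep(NA_real_, nrow(nxt))
    names(newD) <- as.character(nxt$point_id)
    newD[as.character(cont_ids)] <- Dc
    if (logistic && nrow(nxt)) newD <- pmin(newD, rr2$k_eff)
    newcomer <- is.na(newD)
    if (any(newcomer)) {
      nc <- nxt[newcomer, , drop = FALSE]
      seeded <- rep(1, nrow(nc))
      ## re-flooded continental points: seed from the nearest flooded
      ## continental point that stayed flooded across the transition
      reflood <- nc$point_type == "continental"
      if (any(reflood)) {
        donors_idx <- which(nxt$point_id %in% cont_ids &
                              nxt$point_type == "continental" &
                              nxt$class == "flooded_shelf")
        if (length(donors_idx)) {
          dvals <- newD[as.character(nxt$point_id[donors_idx])]
          ok <- !is.na(dvals) & dvals > 1
          donors_idx <- donors_idx[ok]
          dvals <- dvals[ok]
          if (length(donors_idx)) {
            ord <- order(nxt$point_id[donors_idx])
            donors_idx <- donors_idx[ord]; dvals <- dvals[ord]
            for (j in which(reflood)) {
              dd <- gc_distance_km(nc$lat[j], nc$lon[j],
                                   nxt$lat[donors_idx], nxt$lon[donors_idx])
              seeded[j] <- dvals[which.min(dd)]  # ties: lowest point_id
            }
          }
        }
      }
      newD[newcomer] <- seeded
      if (logistic) newD[newcomer] <- pmin(newD[newcomer], rr2$k_eff[newcomer])
    }
    D <- newD

    ## record: active points, plus emergence events (D = 0)
    rec <- data.frame(point_id = nxt$point_id, slice = s + 1L,
                      age_ma = ages[s + 1], class = nxt$class,
                      lat = nxt$lat, lon = nxt$lon, D = as.numeric(D),
                      k_eff = rr2$k_eff, rho = rr2$rho,
                      stringsAsFactors = FALSE)
    all_next <- by_slice[[as.character(s + 1)]]
    if (is.null(all_next)) all_next <- pts[0, , drop = FALSE]
    emerged <- all_next[all_next$class == "emergent_land" &
                          all_next$point_id %in% ps$point_id, , drop = FALSE]
    if (nrow(emerged)) {
      rec <- rbind(rec, data.frame(point_id = emerged$point_id,
                                   slice = s + 1L, age_ma = ages[s + 1],
                                   class = emerged$class, lat = emerged$lat,
                                   lon = emerged$lon, D = 0,
                                   k_eff = NA_real_, rho = NA_real_,
                                   stringsAsFactors = FALSE))
    }
    records[[s + 1]] <- rec
  }

  out <- do.call(rbind, records)
  rownames(out) <- NULL
  structure(out, class = c("diversity_history", "data.frame"),
            params = params, envelope = env, slice_ages = ages)
}
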