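#' Reconstruct kinematics from a metabolic power series
#'
#' Inverts the power-velocity relationship step by step. Starting from
#' rest, each step finds the next velocity `v[i+1] >= 0` whose implied
#' acceleration `a = (v[i+1] - v[i]) / dt` and metabolic power (cost of
#' accelerated running while `a > 0`, flat running cost while
#' `a <= 0`, plus the air-resistance term) match the target power at
#' that step. Candidate accelerations are bounded by `a_max` in
#' magnitude; when no admissible velocity matches the target (power
#' infeasibly high or low for one step) the bound is taken and the step
#' index is flagged.
#'
#' Two discretizations are available. `"midpoint"` (default) matches
#' the average of the target power over the step using the mid-step
#' velocity, which is second-order accurate and reproduces
#' forward-generated power series to well within 0.01% in distance.
#' `"endpoint"` matches the target at the end of the step using the
#' end-step velocity.
#'
#' Near the phase transition, one power value can be matched either by
#' a low-acceleration step (the accelerated-running cost tends to about
#' 3.6 J kg^-1 m^-1 as acceleration vanishes) or by a flat-cost
#' deceleration (3.8 J kg^-1 m^-1). When the power series records the
#' time of its cost-model discontinuity (as series produced by
#' [metabolic_power()] do), the inversion mirrors the forward
#' convention exactly, switching cost branches at that time.
#' Model-generated series carry no discontinuity; for them branch
#' selection uses the step acceleration alone, preferring the
#' deceleration branch whenever it can match the target within the
#' acceleration bound.
#'
#' @param power A `power_series` on a uniform grid whose first sample
#'   is at `t = 0` with zero power (start from rest).
#' @param config A [cost_model_config()].
#' @param a_max Acceleration bound (m/s^2).
#' @param scheme `"midpoint"` or `"endpoint"` step discretization.
#' @param t_switch Time (s) of the accelerated-to-flat cost switch;
#'   defaults to the series' recorded `discontinuity_at`. `NA` selects
#'   branches from the sign of the step acceleration alone.
#' @return A `reconstruction` object: list with `time`, `velocity`,
#'   `acceleration`, `distance` (trapezoidal, m) and `flagged_steps`
#'   (indices where the target power was infeasible within `a_max`).
#' @examples
#' pr <- sprint_velocity_profile(12.34, 1.27, duration = 9.43,
#'                               distance = 100)
#' ps <- metabolic_power(pr)
#' rec <- reconstruct_kinematics(ps)
#' c(forward = integrate_distance(pr), reconstructed = rec$distance)
#' @export
reconstruct_kinematics <- function(power, config = cost_model_config(),
                                   a_max = 12,
                                   scheme = c("midpoint", "endpoint"),
                                   t_switch = power$discontinuity_at) {
  stopifnot(inherits(power, "power_series"),
            inherits(config, "cost_model_config"))
  scheme <- match.arg(scheme)
  t <- power$time
  if (abs(t[1]) > 1e-9) {
    stop("power series must start at t = 0 (start from rest)")
  }
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-9) stop("power series grid must be uniform")
  dt <- dt[1]
  n_accel <- if (is.null(t_switch) || is.na(t_switch)) -1L
             else as.integer(floor(t_switch / dt + 1e-9))
  res <- cpp_reconstruct(power$power, dt, .variant_code(config),
                         config$es_linear_limit, config$flat_cost,
                         config$air_coeff, a_max,
                         if (scheme == "midpoint") 2L else 1L, n_accel)
  v <- res$velocity
  structure(
    list(
      time = t,
      velocity = v,
      acceleration = c(NA_real_, diff(v) / dt),
      distance = res$distance,
      flagged_steps = res$flagged_steps,
      scheme = scheme
    ),
    class = "reconstruction"
  )
}

#' @export
print.reconstruction <- function(x, ...) {
  cat("Kinematics reconstructed from metabolic power\n")
  cat(sprintf("  duration  %.2f s, distance %.2f m\n",
              max(x$time), x$distance))
  cat(sprintf("  peak velocity %.2f m/s\n", max(x$velocity)))
  if (length(x$flagged_steps)) {
    cat(sprintf("  %d step(s) could not match the target power exactly\n",
                length(x$flagged_steps)))
  }
  invisible(x)
}

#' Athlete capacity set
#'
#' Bundles the three capacity parameters that characterize an athlete
#' in the race engine: maximal aerobic power and the two maximal
#' anaerobic capacities.
#'
#' @param MAP Maximal aerobic power (W kg^-1).
#' @param E_al_max Maximal alactic capacity (J kg^-1).
#' @param E_la_max Maximal lactic capacity (J kg^-1).
#' @return An `athlete_capacities` list.
#' @export
athlete_capacities <- function(MAP, E_al_max, E_la_max) {
  stopifnot(MAP > 0, E_al_max > 0, E_la_max > 0)
  structure(list(MAP = MAP, E_al_max = E_al_max, E_la_max = E_la_max),
            class = "athlete_capacities")
}

#' @export
print.athlete_capacities <- function(x, ...) {
  cat("Athlete capacities\n")
  cat(sprintf("  MAP      %.1f W/kg\n", x$MAP))
  cat(sprintf("  alactic  %.0f J/kg\n", x$E_al_max))
  cat(sprintf("  lactic   %.0f J/kg\n", x$E_la_max))
  invisible(x)
}

#' Model power series implied by capacities for a race duration
#'
#' Chains the duration-availability models with the pathway shapes:
#' the alactic and lactic energies available for a race of duration
#' `T` are computed from the capacity models, converted to pathway
#' amplitudes via [amplitude_from_energy()], and combined with the
#' aerobic rise into a total modelled power series on a uniform grid.
#'
#' @param capacities An [athlete_capacities()].
#' @param T Race duration (s), net of reaction time.
#' @param params A [pathway_params()]; its `MAP` is overridden by the
#'   capacity set.
#' @param dt Grid step (s).
#' @param alactic_shape An [alactic_capacity_model()] shape (capacity
#'   field ignored); defaults to the standard constants.
#' @param lactic_shape A [lactic_capacity_model()] shape (capacity
#'   field ignored); defaults to the standard constants.
#' @return A `power_series` with `source = "from_model"`.
#' @export
capacity_power_series <- function(capacities, T,
                                  params = pathway_params(),
                                  dt = 0.01,
                                  alactic_shape = NULL,
                                  lactic_shape = NULL) {
  stopifnot(inherits(capacities, "athlete_capacities"), T > 0)
  params <- pathway_params(MAP = capacities$MAP, BMR = params$BMR,
                           k_aer = params$k_aer, k1 = params$k1,
                           k2 = params$k2, mu_al = params$mu_al,
                           sigma_al = params$sigma_al)
  am <- if (is.null(alactic_shape)) alactic_capacity_model(capacities$E_al_max)
        else alactic_capacity_model(capacities$E_al_max,
                                    mu = alactic_shape$mu,
                                    sigma = alactic_shape$sigma)
  lm <- if (is.null(lactic_shape)) lactic_capacity_model(capacities$E_la_max)
        else lactic_capacity_model(capacities$E_la_max,
                                   k_rise = lactic_shape$k_rise,
                                   k_decay = lactic_shape$k_decay,
                                   onset = lactic_shape$onset)
  # resolve the duration to the grid so the series stays uniform
  n_steps <- max(2, round(T / dt))
  T_grid <- n_steps * dt
  E_al <- alactic_energy(T_grid, am)
  E_la <- lactic_energy(T_grid, lm)
  P_al <- amplitude_from_energy(E_al, T_grid, "alactic", params, dt)
  P_la <- if (E_la > 0)
            amplitude_from_energy(E_la, T_grid, "lactic", params, dt)
          else 0
  t <- seq(0, by = dt, length.out = n_steps + 1)
  power_series(t, total_power(t, P_al, P_la, params),
               source = "from_model")
}

#' Estimate maximal anaerobic capacities from performances
#'
#' Given two or more sprint performances (distance and finish time),
#' finds the maximal alactic and lactic capacities whose model power
#' series, inverted back to kinematics, reproduce each race distance.
#' The objective is the sum over events of squared relative distance
#' errors; it is minimized by a derivative-free simplex over the
#' log-capacities (positivity by construction), restarted from
#' `n_starts` starting points to guard against local minima. Maximal
#' aerobic power is fixed.
#'
#' @param distances Race distances (m).
#' @param finish_times Official finish times (s), including reaction
#'   time.
#' @param MAP Maximal aerobic power (W kg^-1), fixed.
#' @param reaction_time Reaction time (s), subtracted from each finish
#'   time to obtain the running duration.
#' @param params A [pathway_params()] supplying the pathway shape
#'   constants.
#' @param config A [cost_model_config()].
#' @param dt Grid step (s).
#' @param start Starting capacities, `c(E_al_max, E_la_max)` (J kg^-1).
#' @param n_starts Number of simplex restarts (the first uses `start`,
#'   the rest perturb it geometrically).
#' @param warn_ranges Warn when the solution leaves the theoretical
#'   capacity ranges (see [check_capacity_ranges()]); `NULL` disables.
#' @return An [athlete_capacities()] with extra fields `objective`
#'   (sum of squared relative errors) and `convergence`.
#' @examples
#' \donttest{
#' optimize_capacities(c(100, 200, 400), c(9.58, 19.19, 44.06),
#'                     MAP = 24.5)
#' }
#' @export
optimize_capacities <- function(distances, finish_times, MAP,
                                reaction_time = 0.15,
                                params = pathway_params(MAP = MAP),
                                config = cost_model_config(),
                                dt = 0.01,
                                start = c(350, 1100),
                                n_starts = 3,
                                warn_ranges = NULL) {
  stopifnot(length(distances) == length(finish_times))
  if (length(distances) < 2) {
    stop("at least 2 performances are required to identify 2 capacities")
  }
  durations <- finish_times - reaction_time
  if (any(durations <= 0)) stop("finish times must exceed the reaction time")

  objective <- function(logcap) {
    caps <- athlete_capacities(MAP, exp(logcap[1]), exp(logcap[2]))
    err2 <- vapply(seq_along(distances), function(k) {
      ps <- capacity_power_series(caps, durations[k], params, dt)
      rec <- reconstruct_kinematics(ps, config)
      ((rec$distance - distances[k]) / distances[k])^2
    }, numeric(1))
    sum(err2)
  }

  starts <- list(log(start))
  if (n_starts > 1) {
    mults <- list(c(0.7, 1.3), c(1.3, 0.8), c(0.85, 0.85), c(1.2, 1.2))
    for (i in seq_len(n_starts - 1)) {
      starts[[i + 1]] <- log(start * mults[[((i - 1) %% length(mults)) + 1]])
    }
  }
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, objective, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  out <- athlete_capacities(MAP, exp(best$par[1]), exp(best$par[2]))
  out$objective <- best$value
  out$convergence <- best$convergence
  if (!is.null(warn_ranges)) {
    check_capacity_ranges(out$E_al_max, out$E_la_max, sex = warn_ranges)
  }
  out
}

#' Per-event distance errors of a capacity set
#'
#' For each performance, generates the model power series implied by
#' the capacities, reconstructs the distance covered and reports the
#' signed percentage error against the nominal distance, together with
#' the mean absolute percentage error.
#'
#' @inheritParams optimize_capacities
#' @param capacities An [athlete_capacities()].
#' @return A `distance_error_report`: list with a per-event data.frame
#'   (`distance_m`, `finish_time_s`, `reconstructed_m`,
#'   `error_percent`) and `mean_abs_error_percent`.
#' @export
distance_error_report <- function(capacities, distances, finish_times,
                                  reaction_time = 0.15,
                                  params = pathway_params(MAP = capacities$MAP),
                                  config = cost_model_config(),
                                  dt = 0.01) {
  stopifnot(inherits(capacities, "athlete_capacities"),
            length(distances) == length(finish_times))
  durations <- finish_times - reaction_time
  rec_d <- vapply(seq_along(distances), function(k) {
    ps <- capacity_power_series(capacities, durations[k], params, dt)
    reconstruct_kinematics(ps, config)$distance
  }, numeric(1))
  err <- (rec_d - distances) / distances * 100
  structure(
    list(
      events = data.frame(
        distance_m = distances,
        finish_time_s = finish_times,
        reconstructed_m = rec_d,
        error_percent = err
      ),
      mean_abs_error_percent = mean(abs(err))
    ),
    class = "distance_error_report"
  )
}

#' @export
print.distance_error_report <- function(x, ...) {
  cat("Distance reconstruction errors\n")
  print(x$events, row.names = FALSE, digits = 5)
  cat(sprintf("mean absolute error: %.2f%%\n", x$mean_abs_error_percent))
  invisible(x)
}

#' Simulate the minimal race time for a distance
#'
#' Finds, by bisection, the smallest running duration `T` such that the
#' model power series implied by the athlete's capacities, inverted to
#' kinematics, covers the target distance. The returned time includes
#' the reaction time.
#'
#' @param distance Race distance (m), positive.
#' @param capacities An [athlete_capacities()].
#' @param reaction_time Reaction time added to the running duration (s).
#' @param params A [pathway_params()].
#' @param config A [cost_model_config()].
#' @param dt Grid step (s).
#' @param tol Bisection tolerance on the running duration (s).
#' @param T_max Upper bound on the running duration (s); distances not
#'   reachable within it raise an error.
#' @return Simulated finish time (s).
#' @examples
#' \donttest{
#' caps <- athlete_capacities(MAP = 24.5, E_al_max = 328,
#'                            E_la_max = 1460)
#' simulate_race_time(60, caps)   # ~6.3 s
#' }
#' @export
simulate_race_time <- function(distance, capacities,
                               reaction_time = 0.15,
                               params = pathway_params(MAP = capacities$MAP),
                               config = cost_model_config(),
                               dt = 0.01, tol = 0.005, T_max = 600) {
  stopifnot(distance > 0, inherits(capacities, "athlete_capacities"))
  dist_at <- function(T) {
    ps <- capacity_power_series(capacities, T, params, dt)
    reconstruct_kinematics(ps, config)$distance
  }
  lo <- max(distance / 13, 2 * dt)
  hi <- lo
  while (dist_at(hi) < distance) {
    hi <- hi * 1.5
    if (hi > T_max) {
      stop(sprintf("distance %.0f m not reachable within %.0f s", distance,
                   T_max))
    }
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (dist_at(mid) < distance) lo <- mid else hi <- mid
  }
  (lo + hi) / 2 + reaction_time
}
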