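#' Specification for a synthetic split table
#'
#' Describes the race that [make_split_table()] generates: an
#' exponential acceleration phase with the given `tau` and `v_f`,
#' followed by a linear deceleration chosen so that the forward model
#' covers exactly `total_distance` in `finish_time - reaction_time`
#' seconds of running. Optional Gaussian noise perturbs the interval
#' average velocities, emulating timing error in real split data.
#'
#' @param tau Acceleration time constant (s).
#' @param v_f Peak velocity (m/s).
#' @param total_distance Race distance (m).
#' @param finish_time Official finish time (s), including reaction
#'   time. `NULL` generates a pure-acceleration race: the run ends
#'   when the exponential-rise model has covered `total_distance`,
#'   with no deceleration phase.
#' @param split_interval Distance between timing marks (m).
#' @param reaction_time Reaction time (s).
#' @param noise_sd Standard deviation of Gaussian noise applied to
#'   interval average velocities (m/s); 0 for an exact table.
#' @param seed Integer seed making noisy tables reproducible; ignored
#'   when `noise_sd = 0`.
#' @param peak_fraction Fraction of `v_f` at which the acceleration
#'   phase ends (see [sprint_velocity_profile()]).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(tau, v_f, total_distance, finish_time = NULL,
                         split_interval = 10, reaction_time = 0.15,
                         noise_sd = 0, seed = 1L,
                         peak_fraction = 0.995) {
  stopifnot(tau > 0, v_f > 0, total_distance > 0, split_interval > 0,
            noise_sd >= 0)
  if (!is.null(finish_time)) stopifnot(finish_time > reaction_time)
  if (total_distance / split_interval < 3) {
    stop("`split_interval` must allow at least 3 splits")
  }
  structure(
    list(tau = tau, v_f = v_f, total_distance = total_distance,
         finish_time = finish_time, split_interval = split_interval,
         reaction_time = reaction_time, noise_sd = noise_sd,
         seed = as.integer(seed), peak_fraction = peak_fraction),
    class = "fixture_spec"
  )
}

#' Generate a synthetic split table
#'
#' Builds the forward velocity profile implied by a [fixture_spec()],
#' computes the cumulative time at each split mark, and (optionally)
#' perturbs the interval average velocities with Gaussian noise before
#' recomputing the cumulative times. Equal seeds give identical
#' tables.
#'
#' Two timing conventions are available. `"path"` (default, the
#' physical one) inverts the distance-time relation of the forward
#' profile, so cumulative times are the true passage times. With
#' `"midpoint_consistent"` (pure-acceleration fixtures only) the times
#' are constructed so that each interval's average velocity equals the
#' model velocity at the interval's time midpoint — the exact data
#' model assumed by [fit_acceleration()], under which the noiseless
#' fit recovers the generating parameters to solver precision.
#' Path-timed tables carry a small, interval-width-dependent
#' discrepancy between chord-average and midpoint velocity, so
#' parameter recovery is close but not exact.
#'
#' @param spec A [fixture_spec()].
#' @param times `"path"` or `"midpoint_consistent"`.
#' @return A [split_table()]. The generating profile is attached as
#'   attribute `"profile"`.
#' @examples
#' spec <- fixture_spec(tau = 1.27, v_f = 12.34, total_distance = 100,
#'                      finish_time = 9.58)
#' st <- make_split_table(spec)
#' fit_acceleration(st)
#' @export
make_split_table <- function(spec, times = c("path", "midpoint_consistent")) {
  stopifnot(inherits(spec, "fixture_spec"))
  times <- match.arg(times)
  marks <- seq(spec$split_interval, spec$total_distance,
               by = spec$split_interval)
  if (abs(marks[length(marks)] - spec$total_distance) > 1e-9) {
    marks <- c(marks, spec$total_distance)
  }

  if (is.null(spec$finish_time)) {
    # pure acceleration: run ends when the exponential-rise model has
    # covered the race distance
    dist_accel <- function(t) {
      spec$v_f * (t - spec$tau * (1 - exp(-t / spec$tau)))
    }
    duration <- stats::uniroot(function(t) dist_accel(t) - spec$total_distance,
                               lower = spec$total_distance / spec$v_f,
                               upper = 2 * spec$total_distance / spec$v_f + 10,
                               tol = 1e-12)$root
    profile <- sprint_velocity_profile(
      v_f = spec$v_f, tau = spec$tau, duration = duration,
      distance = NULL, dt = 0.001, reaction_time = spec$reaction_time
    )
    if (times == "midpoint_consistent") {
      # interval average velocity == model velocity at the interval
      # time midpoint, the regression's data model
      t_net <- numeric(length(marks))
      t_prev <- 0
      d_prev <- 0
      for (i in seq_along(marks)) {
        dd <- marks[i] - d_prev
        f <- function(ti) {
          dd / (ti - t_prev) -
            model_velocity((ti + t_prev) / 2, spec$v_f, spec$tau)
        }
        t_net[i] <- stats::uniroot(f, lower = t_prev + dd / spec$v_f / 2,
                                   upper = t_prev + 100 * dd / spec$v_f,
                                   tol = 1e-13)$root
        t_prev <- t_net[i]
        d_prev <- marks[i]
      }
    } else {
      t_net <- vapply(marks, function(d) {
        stats::uniroot(function(t) dist_accel(t) - d,
                       lower = d / spec$v_f,
                       upper = 2 * d / spec$v_f + 10, tol = 1e-12)$root
      }, numeric(1))
    }
  } else {
    if (times == "midpoint_consistent") {
      stop("`midpoint_consistent` timing requires a pure-acceleration ",
           "fixture (finish_time = NULL)")
    }
    duration <- spec$finish_time - spec$reaction_time
    profile <- sprint_velocity_profile(
      v_f = spec$v_f, tau = spec$tau, duration = duration,
      distance = spec$total_distance, peak_fraction = spec$peak_fraction,
      dt = 0.001, reaction_time = spec$reaction_time
    )
    # cumulative distance on the profile grid; invert by monotone
    # interpolation of t(d)
    d_grid <- cumsum(c(0, (profile$velocity[-1] +
                           profile$velocity[-length(profile$velocity)]) / 2 *
                          diff(profile$time)))
    t_net <- stats::approx(d_grid, profile$time, xout = marks)$y
    t_net[length(t_net)] <- duration  # guard against interpolation rounding
  }

  if (spec$noise_sd > 0) {
    seg_d <- diff(c(0, marks))
    seg_t <- diff(c(0, t_net))
    v_avg <- seg_d / seg_t
    noisy <- withr_seed(spec$seed, v_avg + stats::rnorm(length(v_avg),
                                                        0, spec$noise_sd))
    if (any(noisy <= 0)) stop("noise produced a non-positive velocity")
    t_net <- cumsum(seg_d / noisy)
  }
  st <- split_table(marks, t_net + spec$reaction_time,
                    reaction_time = spec$reaction_time,
                    total_distance = spec$total_distance)
  attr(st, "profile") <- profile
  st
}

# evaluate `expr` under a local RNG seed without disturbing the
# caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Bundled sprint model parameters
#'
#' The reference constants used throughout the package, collected from
#' analyses of the 2009 Berlin World Championships 100/200/400 m
#' finals: fitted acceleration-model parameters and finish times per
#' event (`table1`), per-race pathway energies from the bioenergetic
#' decomposition (`table3`), optimized athlete capacities (`table4`),
#' simulated race times (`table5`), and the default maximal aerobic
#' powers and reaction time.
#'
#' @return A nested list. `table1[[sex]][[event]]` has `tau`, `v_f`
#'   and `finish_time`; `table3[[sex]][[event]]` has `alactic`,
#'   `lactic`, `aerobic` energies (J kg^-1); `table4[[sex]]` has
#'   `E_al_max`, `E_la_max`, `MAP`; `table5[[sex]]` is a named vector
#'   of simulated times (s) by distance.
#' @export
sprint_parameters <- function() {
  list(
    table1 = list(
      male = list(
        `100` = list(tau = 1.27, v_f = 12.34, finish_time = 9.58),
        `200` = list(tau = 1.59, v_f = 11.57, finish_time = 19.19),
        `400` = list(tau = 1.54, v_f = 9.88, finish_time = 44.06)
      ),
      female = list(
        `100` = list(tau = 1.34, v_f = 10.58, finish_time = 10.73),
        `200` = list(tau = 1.59, v_f = 10.18, finish_time = 22.02),
        `400` = list(tau = 1.52, v_f = 9.12, finish_time = 49.32)
      )
    ),
    table3 = list(
      male = list(
        `100` = list(alactic = 362, lactic = 364, aerobic = 40),
        `200` = list(alactic = 239, lactic = 790, aerobic = 142),
        `400` = list(alactic = 170, lactic = 1189, aerobic = 566)
      ),
      female = list(
        `100` = list(alactic = 237, lactic = 357, aerobic = 42),
        `200` = list(alactic = 179, lactic = 743, aerobic = 153),
        `400` = list(alactic = 144, lactic = 1155, aerobic = 571)
      )
    ),
    table4 = list(
      male = list(E_al_max = 328, E_la_max = 1460, MAP = 24.5),
      female = list(E_al_max = 218, E_la_max = 1295, MAP = 21.0)
    ),
    table5 = list(
      male = c(`60` = 6.29, `100` = 9.58, `200` = 19.01, `300` = 30.44,
               `400` = 44.05),
      female = c(`60` = 7.04, `100` = 10.73, `200` = 21.39,
                 `300` = 34.66, `400` = 50.85)
    ),
    MAP = c(male = 24.5, female = 21.0),
    reaction_time = 0.15
  )
}
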