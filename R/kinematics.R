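#' Exponential sprint acceleration model
#'
#' During the acceleration phase of a sprint, velocity rises
#' exponentially towards the peak velocity `v_f` with time constant
#' `tau`:
#' \deqn{v(t) = v_f (1 - e^{-t/\tau})}
#' and the corresponding instantaneous acceleration is
#' \deqn{a(t) = (v_f/\tau) e^{-t/\tau}.}
#' Times are net of the reaction time.
#'
#' @param t Time in seconds (net of reaction time), non-negative.
#' @param v_f Peak velocity (m/s).
#' @param tau Time constant of the velocity rise (s).
#' @param fit Alternatively, an `accel_fit` object from
#'   [fit_acceleration()]; its `v_f` and `tau` are used.
#' @return Velocity (m/s) or acceleration (m/s^2) at `t`.
#' @examples
#' model_velocity(1.27, v_f = 12.34, tau = 1.27)  # one time constant
#' model_acceleration(0, v_f = 12.34, tau = 1.27) # v_f / tau
#' @export
model_velocity <- function(t, v_f = NULL, tau = NULL, fit = NULL) {
  p <- .accel_pars(v_f, tau, fit)
  if (any(t < 0)) stop("`t` must be non-negative")
  p$v_f * (1 - exp(-t / p$tau))
}

#' @rdname model_velocity
#' @export
model_acceleration <- function(t, v_f = NULL, tau = NULL, fit = NULL) {
  p <- .accel_pars(v_f, tau, fit)
  if (any(t < 0)) stop("`t` must be non-negative")
  (p$v_f / p$tau) * exp(-t / p$tau)
}

.accel_pars <- function(v_f, tau, fit) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "accel_fit"))
    v_f <- fit$v_f
    tau <- fit$tau
  }
  if (is.null(v_f) || is.null(tau)) {
    stop("supply either `v_f` and `tau` or a fitted `accel_fit`")
  }
  if (v_f <= 0 || tau <= 0) stop("`v_f` and `tau` must be positive")
  list(v_f = v_f, tau = tau)
}

#' Fit the exponential acceleration model to split data
#'
#' Fits \eqn{v(t) = v_f (1 - e^{-t/\tau})} to the interval-average
#' velocities of a split table by damped (Levenberg-Marquardt)
#' non-linear least squares. Average velocities are assigned to the
#' time-midpoints of their intervals, with the reaction time subtracted
#' beforehand. For races with a pronounced deceleration tail (200 m,
#' 400 m) the fit can be restricted to the first `fit_range_m` metres,
#' where the exponential rise model holds.
#'
#' @param splits A [split_table()].
#' @param fit_range_m Only intervals ending at or before this distance
#'   enter the fit (default: the whole race; 200 is a sensible value
#'   for 200/400 m races).
#' @param start Optional named list with starting values `tau` and
#'   `v_f`. Defaults to `tau = 1.5` s and `v_f` = the maximum interval
#'   average velocity.
#' @return An object of class `accel_fit` with fields `v_f`, `tau`,
#'   `rse` (residual standard error, m/s), `rmse` (root mean square
#'   error, m/s), `n` (intervals used), `residuals` and `data`.
#' @examples
#' st <- make_split_table(fixture_spec(tau = 1.5, v_f = 10,
#'                                     total_distance = 100,
#'                                     finish_time = 11.3))
#' fit_acceleration(st)
#' @export
fit_acceleration <- function(splits, fit_range_m = Inf, start = NULL) {
  stopifnot(inherits(splits, "split_table"))
  iv <- split_intervals(splits)
  iv <- iv[iv$d_to <= fit_range_m + 1e-9, , drop = FALSE]
  if (nrow(iv) < 3) stop("need at least 3 intervals within `fit_range_m`")
  if (is.null(start)) {
    start <- list(tau = 1.5, v_f = max(iv$v_avg))
  }
  fit <- minpack.lm::nlsLM(
    v_avg ~ v_f * (1 - exp(-t_mid / tau)),
    data = iv,
    start = start,
    lower = c(tau = 1e-3, v_f = 1e-3),
    control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                         maxiter = 200)
  )
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  structure(
    list(
      v_f = unname(cf["v_f"]),
      tau = unname(cf["tau"]),
      rse = sqrt(sum(res^2) / (nrow(iv) - 2)),
      rmse = sqrt(mean(res^2)),
      n = nrow(iv),
      residuals = as.numeric(res),
      data = iv
    ),
    class = "accel_fit"
  )
}

#' @export
print.accel_fit <- function(x, ...) {
  cat("Exponential acceleration fit (v(t) = v_f (1 - exp(-t/tau)))\n")
  cat(sprintf("  v_f  = %.3f m/s\n  tau  = %.3f s\n", x$v_f, x$tau))
  cat(sprintf("  RSE  = %.3f m/s, RMSE = %.3f m/s (n = %d intervals)\n",
              x$rse, x$rmse, x$n))
  invisible(x)
}

#' Adjust fitted peak velocity with observed maxima
#'
#' Including deceleration-phase intervals in the least-squares fit
#' biases the fitted `v_f` downwards. This correction replaces `v_f`
#' by the highest measured instantaneous velocity when the split table
#' carries one, or otherwise by the highest interval average velocity,
#' whichever exceeds the fitted value. `v_f` is never lowered: the bias
#' being corrected is an underestimate. `tau` is unchanged.
#'
#' @param fit An `accel_fit` from [fit_acceleration()].
#' @param splits The [split_table()] the fit came from.
#' @return An updated `accel_fit`.
#' @export
adjust_peak_velocity <- function(fit, splits) {
  stopifnot(inherits(fit, "accel_fit"), inherits(splits, "split_table"))
  iv <- split_intervals(splits)
  candidate <- if (!is.null(splits$max_velocity)) {
    splits$max_velocity
  } else {
    max(iv$v_avg)
  }
  fit$v_f <- max(fit$v_f, candidate)
  fit
}

#' Build a full-race velocity profile
#'
#' Combines the fitted exponential acceleration phase with a linear
#' deceleration tail. The acceleration phase ends at `t_peak`, taken as
#' the net time-midpoint of the interval with the highest average
#' velocity. The final velocity is obtained by linear interpolation of
#' the average velocity over the last timing interval: if velocity
#' decays linearly from `v_f` at `t_peak` to `v_final` at the finish,
#' the average over the last interval fixes `v_final` in closed form.
#'
#' @param fit An `accel_fit` (after [adjust_peak_velocity()] if
#'   desired).
#' @param splits The [split_table()].
#' @param dt Time step of the profile grid (s), default 0.01.
#' @return A `velocity_profile` object: a list with `time` (s, net of
#'   reaction), `velocity` (m/s), `acceleration` (m/s^2), `t_peak`,
#'   `v_final`, `duration`, `dt` and `reaction_time`.
#' @export
build_velocity_profile <- function(fit, splits, dt = 0.01) {
  stopifnot(inherits(fit, "accel_fit"), inherits(splits, "split_table"))
  if (dt <= 0) stop("`dt` must be positive")
  iv <- split_intervals(splits)
  duration <- splits$finish_time - splits$reaction_time
  t_peak <- iv$t_mid[which.max(iv$v_avg)]

  n <- nrow(iv)
  v_avg_last <- iv$v_avg[n]
  t_last_start <- iv$t_from[n]
  if (t_peak >= duration - dt) {
    t_peak <- duration
    v_final <- model_velocity(duration, fit = fit)
  } else {
    # average of a linear segment over the last interval fixes v_final;
    # v at the interval start lies on the same line, so solve linearly
    r <- (t_last_start - t_peak) / (duration - t_peak)
    r <- min(max(r, 0), 1 - 1e-9)
    v_peak <- model_velocity(t_peak, fit = fit)
    v_final <- (2 * v_avg_last - v_peak * (1 - r)) / (1 + r)
  }
  v_peak <- model_velocity(t_peak, fit = fit)
  if (v_final > fit$v_f + 1e-9) {
    warning("derived final velocity exceeds peak velocity; ",
            "deceleration model is inconsistent with the last split")
  }
  .velocity_profile(fit$v_f, fit$tau, duration, t_peak, v_final, dt,
                    reaction_time = splits$reaction_time)
}

#' Velocity profile from model parameters
#'
#' Builds a sprint velocity profile directly from acceleration-model
#' parameters, without split data: exponential rise until the velocity
#' reaches `peak_fraction` of `v_f` (default 99.5%), then linear
#' deceleration chosen so that the integrated distance equals
#' `distance` at `duration`. With `distance = NULL` the profile is pure
#' acceleration for the whole duration.
#'
#' @param v_f Peak velocity (m/s).
#' @param tau Time constant (s).
#' @param duration Net running time (s), reaction time excluded.
#' @param distance Target race distance (m), or `NULL` for a
#'   pure-acceleration profile.
#' @param peak_fraction Fraction of `v_f` at which the acceleration
#'   phase ends when `distance` is given.
#' @param dt Grid step (s).
#' @param reaction_time Stored as metadata only (s).
#' @return A `velocity_profile`.
#' @examples
#' pr <- sprint_velocity_profile(v_f = 12.34, tau = 1.27,
#'                               duration = 9.43, distance = 100)
#' integrate_distance(pr)
#' @export
sprint_velocity_profile <- function(v_f, tau, duration, distance = NULL,
                                    peak_fraction = 0.995, dt = 0.01,
                                    reaction_time = 0.15) {
  if (v_f <= 0 || tau <= 0 || duration <= 0) {
    stop("`v_f`, `tau` and `duration` must be positive")
  }
  if (is.null(distance)) {
    return(.velocity_profile(v_f, tau, duration, t_peak = duration,
                             v_final = v_f * (1 - exp(-duration / tau)),
                             dt = dt, reaction_time = reaction_time))
  }
  t_peak <- -tau * log(1 - peak_fraction)
  if (t_peak >= duration) {
    stop("acceleration phase exceeds `duration`; increase `duration` ",
         "or lower `peak_fraction`")
  }
  d_accel <- v_f * (t_peak - tau * (1 - exp(-t_peak / tau)))
  v_peak <- v_f * (1 - exp(-t_peak / tau))
  v_final <- 2 * (distance - d_accel) / (duration - t_peak) - v_peak
  if (v_final < 0) {
    stop("infeasible profile: `distance` too short for `duration`")
  }
  if (v_final > v_f) {
    stop("infeasible profile: `distance` requires exceeding peak velocity")
  }
  .velocity_profile(v_f, tau, duration, t_peak, v_final, dt,
                    reaction_time = reaction_time)
}

# assemble the piecewise (exponential rise + linear tail) profile on a
# uniform grid
.velocity_profile <- function(v_f, tau, duration, t_peak, v_final, dt,
                              reaction_time) {
  time <- seq(0, duration, by = dt)
  if (time[length(time)] < duration - 1e-9) time <- c(time, duration)
  v_peak <- v_f * (1 - exp(-t_peak / tau))
  accel_phase <- time <= t_peak + 1e-12
  velocity <- numeric(length(time))
  acceleration <- numeric(length(time))
  velocity[accel_phase] <- v_f * (1 - exp(-time[accel_phase] / tau))
  acceleration[accel_phase] <- (v_f / tau) * exp(-time[accel_phase] / tau)
  if (any(!accel_phase)) {
    slope <- if (duration > t_peak) (v_final - v_peak) / (duration - t_peak) else 0
    velocity[!accel_phase] <- v_peak + slope * (time[!accel_phase] - t_peak)
    acceleration[!accel_phase] <- slope
  }
  velocity <- pmax(velocity, 0)
  structure(
    list(
      time = time,
      velocity = velocity,
      acceleration = acceleration,
      t_peak = t_peak,
      v_peak = v_peak,
      v_final = v_final,
      v_f = v_f,
      tau = tau,
      duration = duration,
      dt = dt,
      reaction_time = reaction_time
    ),
    class = "velocity_profile"
  )
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat("Sprint velocity profile\n")
  cat(sprintf("  duration    %.2f s (net of reaction time)\n", x$duration))
  cat(sprintf("  t_peak      %.2f s, v_peak %.2f m/s\n", x$t_peak, x$v_peak))
  cat(sprintf("  v_final     %.2f m/s\n", x$v_final))
  cat(sprintf("  distance    %.2f m (trapezoidal integral, dt = %g s)\n",
              integrate_distance(x), x$dt))
  invisible(x)
}

#' Integrate a velocity profile to distance
#'
#' Trapezoidal integral of velocity over the profile's time grid.
#'
#' @param profile A `velocity_profile`.
#' @return Distance in metres.
#' @export
integrate_distance <- function(profile) {
  stopifnot(inherits(profile, "velocity_profile"))
  trapz(profile$time, profile$velocity)
}

# trapezoidal rule on a (possibly non-uniform) grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' @export
as.data.frame.velocity_profile <- function(x, ...) {
  data.frame(time_s = x$time, velocity_ms = x$velocity,
             acceleration_ms2 = x$acceleration)
}
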