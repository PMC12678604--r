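#' Cost-model configuration
#'
#' Fixed constants of the equivalent-slope energy cost model of
#' accelerated running and of the air-resistance correction.
#'
#' Two cost variants are available:
#' \describe{
#'   \item{`"minetti2002_em"` (default)}{The gradient energy-cost
#'     polynomial of running,
#'     \eqn{C(ES) = 155.4 ES^5 - 30.4 ES^4 - 43.3 ES^3 + 46.3 ES^2 +
#'     19.5 ES + 3.6} (J kg^-1 m^-1), evaluated at the equivalent slope
#'     \eqn{ES = a/g} and multiplied by the equivalent mass
#'     \eqn{EM = \sqrt{ES^2 + 1}}. The polynomial is only calibrated on
#'     moderate gradients, so beyond `|ES| > es_linear_limit` it is
#'     continued linearly with matched slope.}
#'   \item{`"minetti_pavei"`}{A closed-form cost of accelerated running
#'     fitted directly on sprint accelerations up to about 8 m s^-2:
#'     \eqn{C_{AR} = 0.102 \sqrt{a^2 + 96.2}\,(4.03 a + 3.6 e^{-0.408 a})}.}
#' }
#' Both reduce to approximately 3.6 J kg^-1 m^-1 at `a = 0`.
#'
#' @param variant `"minetti2002_em"` or `"minetti_pavei"`.
#' @param gravity Gravitational acceleration (m/s^2).
#' @param air_coeff Air-resistance coefficient: `air_coeff * v^2` is
#'   added to the per-metre cost (J s^2 kg^-1 m^-3).
#' @param flat_cost Energy cost of flat running at constant speed,
#'   applied after the acceleration phase (J kg^-1 m^-1).
#' @param es_linear_limit Equivalent slope beyond which the gradient
#'   polynomial is linearly extrapolated (dimensionless).
#' @return A `cost_model_config` list.
#' @export
cost_model_config <- function(variant = c("minetti2002_em", "minetti_pavei"),
                              gravity = 9.81,
                              air_coeff = 0.01,
                              flat_cost = 3.8,
                              es_linear_limit = 0.45) {
  variant <- match.arg(variant)
  stopifnot(gravity > 0, air_coeff > 0, flat_cost > 0, es_linear_limit > 0)
  structure(
    list(variant = variant, gravity = gravity, air_coeff = air_coeff,
         flat_cost = flat_cost, es_linear_limit = es_linear_limit),
    class = "cost_model_config"
  )
}

.variant_code <- function(config) {
  switch(config$variant, minetti2002_em = 1L, minetti_pavei = 2L)
}

#' Equivalent slope of accelerated running
#'
#' The forward acceleration divided by gravitational acceleration:
#' running on the flat while accelerating at `a` costs as much per
#' metre as running at constant speed up a slope `a / g`.
#'
#' @param a Forward acceleration (m/s^2).
#' @param gravity Gravitational acceleration (m/s^2).
#' @return Dimensionless slope.
#' @export
equivalent_slope <- function(a, gravity = 9.81) {
  a / gravity
}

#' Energy cost of accelerated running
#'
#' Per-metre metabolic cost (J kg^-1 m^-1) as a function of forward
#' acceleration, excluding air resistance. See [cost_model_config()]
#' for the two variants.
#'
#' @param a Forward acceleration (m/s^2), vectorized.
#' @param config A [cost_model_config()].
#' @return Cost in J kg^-1 m^-1.
#' @examples
#' cost_accelerated(0)                     # ~3.6, flat-running cost
#' cost_accelerated(2, cost_model_config("minetti_pavei"))
#' @export
cost_accelerated <- function(a, config = cost_model_config()) {
  stopifnot(inherits(config, "cost_model_config"))
  cpp_cost_accelerated(as.numeric(a), .variant_code(config),
                       config$es_linear_limit)
}

#' Metabolic power of a sprint velocity profile
#'
#' Instantaneous metabolic power (W kg^-1) is the per-metre energy
#' cost times velocity. During the acceleration phase the cost of
#' accelerated running is used; after peak velocity the flat-running
#' cost applies, reflecting that decelerating runners keep a stable
#' posture and merely fail to sustain power. Air resistance adds
#' `air_coeff * v^2` to the per-metre cost throughout. The cost switch
#' at `t_peak` produces a genuine discontinuity in the power series;
#' it is flagged in the result, not smoothed.
#'
#' Basal metabolism is not included: the series represents power
#' expended above rest.
#'
#' @param profile A `velocity_profile`.
#' @param config A [cost_model_config()].
#' @return A `power_series` object: list with `time` (s), `power`
#'   (W kg^-1), `source = "from_kinematics"`, `peak_power`,
#'   `mean_power`, `total_energy` (J kg^-1), `dt`, and
#'   `discontinuity_at` (`t_peak`, or `NA` when the profile has no
#'   deceleration phase).
#' @examples
#' pr <- sprint_velocity_profile(12.34, 1.27, duration = 9.43,
#'                               distance = 100)
#' ps <- metabolic_power(pr)
#' ps
#' @export
metabolic_power <- function(profile, config = cost_model_config()) {
  stopifnot(inherits(profile, "velocity_profile"),
            inherits(config, "cost_model_config"))
  accel_phase <- profile$time <= profile$t_peak + 1e-12
  cost <- numeric(length(profile$time))
  cost[accel_phase] <- cost_accelerated(profile$acceleration[accel_phase],
                                        config)
  cost[!accel_phase] <- config$flat_cost
  cost <- cost + config$air_coeff * profile$velocity^2
  power <- cost * profile$velocity
  power_series(profile$time, power,
               source = "from_kinematics",
               discontinuity_at = if (any(!accel_phase)) profile$t_peak
                                  else NA_real_)
}

#' Construct a metabolic power series
#'
#' @param time Time grid (s), increasing.
#' @param power Metabolic power (W kg^-1), non-negative.
#' @param source `"from_kinematics"` (derived from a velocity profile)
#'   or `"from_model"` (generated by the bioenergetic pathway model).
#' @param discontinuity_at Time of a known discontinuity (s) or `NA`.
#' @return A `power_series` with summary statistics (`peak_power`,
#'   `mean_power`, trapezoidal `total_energy`).
#' @export
power_series <- function(time, power,
                         source = c("from_kinematics", "from_model"),
                         discontinuity_at = NA_real_) {
  source <- match.arg(source)
  stopifnot(length(time) == length(power), all(diff(time) > 0))
  if (any(power < -1e-9)) stop("`power` must be non-negative")
  power <- pmax(power, 0)
  structure(
    list(
      time = time,
      power = power,
      source = source,
      peak_power = max(power),
      mean_power = trapz(time, power) / (max(time) - min(time)),
      total_energy = trapz(time, power),
      dt = if (length(time) > 1) time[2] - time[1] else NA_real_,
      discontinuity_at = discontinuity_at
    ),
    class = "power_series"
  )
}

#' @export
print.power_series <- function(x, ...) {
  cat("Metabolic power series (", x$source, ")\n", sep = "")
  cat(sprintf("  duration     %.2f s (%d samples)\n",
              max(x$time) - min(x$time), length(x$time)))
  cat(sprintf("  peak power   %.1f W/kg\n", x$peak_power))
  cat(sprintf("  mean power   %.1f W/kg\n", x$mean_power))
  cat(sprintf("  total energy %.0f J/kg\n", x$total_energy))
  if (!is.na(x$discontinuity_at)) {
    cat(sprintf("  cost-model discontinuity at t = %.2f s\n",
                x$discontinuity_at))
  }
  invisible(x)
}

#' @export
as.data.frame.power_series <- function(x, ...) {
  data.frame(time_s = x$time, power_wkg = x$power)
}
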