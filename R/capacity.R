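#' Duration-dependent anaerobic energy availability models
#'
#' Even in maximal efforts, the anaerobic stores are not fully emptied:
#' the energy actually drawn from each store depends on race duration.
#'
#' The alactic (phosphocreatine) model expresses average alactic power
#' over a race of duration `T` as a log-normal bell scaled by the
#' maximal alactic capacity `E_al_max`:
#' \deqn{P_{al,avg}(T) = \frac{E_{al,max}}{T}
#'   \exp\!\left(-\frac{(\ln T - \mu)^2}{2\sigma^2}\right)}
#' so the alactic energy drawn is
#' \eqn{E_{al}(T) = T \cdot P_{al,avg}(T) \le E_{al,max}}, with
#' equality only at \eqn{T = e^{\mu}}. Average alactic power itself
#' peaks at \eqn{T = e^{\mu - \sigma^2}} (about 0.6 s with the
#' defaults), consistent with phosphocreatine splitting being fastest
#' at contraction onset.
#'
#' The lactic (glycolytic) model expresses lactic energy drawn as a
#' peak-normalized bi-exponential of duration, with an onset delay
#' below which glycolytic energy is negligible:
#' \deqn{E_{la}(T) = E_{la,max} k_{norm,2}
#'   \left(1 - e^{-(T - T_0)/k_{rise}}\right) e^{-(T - T_0)/k_{decay}}}
#' for `T > onset` and 0 otherwise. `k_norm2` (see [knorm()]) makes
#' the maximum over `T` equal `E_la_max`, reached at
#' `onset + k_rise * log(1 + k_decay/k_rise)` (about 90 s with the
#' defaults), matching peak blood-lactate accumulation in races of
#' 50-100 s.
#'
#' @param E_al_max Maximal alactic capacity (J kg^-1).
#' @param mu,sigma Log-normal constants of the alactic model
#'   (ln-seconds and magnitude).
#' @param E_la_max Maximal lactic capacity (J kg^-1).
#' @param k_rise,k_decay Rise and decay time constants of the lactic
#'   model (s).
#' @param onset Delay before glycolytic energy release (s).
#' @return An `alactic_capacity_model` or `lactic_capacity_model`
#'   list.
#' @name capacity_models
#' @examples
#' am <- alactic_capacity_model(328)
#' alactic_energy(9.43, am)   # ~311 J/kg
#' lm <- lactic_capacity_model(1460)
#' lactic_energy(9.43, lm)    # ~429 J/kg
NULL

#' @rdname capacity_models
#' @export
alactic_capacity_model <- function(E_al_max, mu = 1.75, sigma = 1.5) {
  stopifnot(E_al_max > 0, sigma > 0)
  structure(list(E_al_max = E_al_max, mu = mu, sigma = sigma),
            class = "alactic_capacity_model")
}

#' @rdname capacity_models
#' @export
lactic_capacity_model <- function(E_la_max, k_rise = 20, k_decay = 1500,
                                  onset = 3) {
  stopifnot(E_la_max > 0, k_rise > 0, k_decay > k_rise, onset >= 0)
  structure(
    list(E_la_max = E_la_max, k_rise = k_rise, k_decay = k_decay,
         onset = onset, k_norm2 = knorm(k_rise, k_decay)),
    class = "lactic_capacity_model"
  )
}

#' Alactic energy drawn in a race of duration T
#'
#' @param T Race duration (s), net of reaction time; vectorized.
#' @param model An [alactic_capacity_model()].
#' @return Energy in J kg^-1.
#' @export
alactic_energy <- function(T, model) {
  stopifnot(inherits(model, "alactic_capacity_model"))
  if (any(T <= 0)) stop("`T` must be positive")
  model$E_al_max * exp(-(log(T) - model$mu)^2 / (2 * model$sigma^2))
}

#' Average alactic power over a race of duration T
#'
#' @inheritParams alactic_energy
#' @return Power in W kg^-1.
#' @export
alactic_avg_power <- function(T, model) {
  alactic_energy(T, model) / T
}

#' Lactic energy drawn in a race of duration T
#'
#' Zero at or below the onset delay; bi-exponential beyond it.
#'
#' @param T Race duration (s), net of reaction time; vectorized.
#' @param model A [lactic_capacity_model()].
#' @return Energy in J kg^-1.
#' @export
lactic_energy <- function(T, model) {
  stopifnot(inherits(model, "lactic_capacity_model"))
  out <- numeric(length(T))
  past <- T > model$onset
  x <- T[past] - model$onset
  out[past] <- model$E_la_max * model$k_norm2 *
    (1 - exp(-x / model$k_rise)) * exp(-x / model$k_decay)
  out
}

#' Duration at which the lactic energy model peaks
#'
#' Analytic argmax of the bi-exponential availability model:
#' `onset + k_rise * log(1 + k_decay / k_rise)`.
#'
#' @param model A [lactic_capacity_model()].
#' @return Duration in seconds.
#' @export
lactic_energy_peak_duration <- function(model = lactic_capacity_model(1)) {
  stopifnot(inherits(model, "lactic_capacity_model"))
  model$onset + knorm_peak_time(model$k_rise, model$k_decay)
}

#' Fit the maximal alactic capacity to per-race energies
#'
#' Least-squares fit of the average-alactic-power model to observed
#' per-race average powers `E_al / T`. With the log-normal shape
#' constants fixed, the model is linear in `E_al_max` and the solution
#' is closed-form: `sum(y * m) / sum(m^2)` where `m` is the
#' unit-capacity model value.
#'
#' @param T Race durations (s), net of reaction time.
#' @param E_al Alactic energies drawn in each race (J kg^-1).
#' @param mu,sigma Shape constants, fixed during the fit.
#' @return An [alactic_capacity_model()] with the fitted capacity and
#'   an `rse` field (residual standard error of average power,
#'   W kg^-1).
#' @examples
#' # capacity from three race energies
#' fit_alactic_capacity(c(9.43, 19.04, 43.91), c(362, 239, 170))
#' @export
fit_alactic_capacity <- function(T, E_al, mu = 1.75, sigma = 1.5) {
  if (any(T <= 0)) stop("race durations must be positive")
  stopifnot(length(T) == length(E_al), length(T) >= 1)
  y <- E_al / T
  m <- exp(-(log(T) - mu)^2 / (2 * sigma^2)) / T
  cap <- sum(y * m) / sum(m^2)
  model <- alactic_capacity_model(cap, mu = mu, sigma = sigma)
  res <- y - alactic_avg_power(T, model)
  model$rse <- if (length(T) > 1) sqrt(sum(res^2) / (length(T) - 1)) else 0
  model
}

#' Fit the maximal lactic capacity to per-race energies
#'
#' Least-squares fit of the bi-exponential availability model to
#' observed per-race lactic energies, with the time constants and
#' onset fixed; linear in `E_la_max`, solved in closed form.
#'
#' @param T Race durations (s), net of reaction time; all must exceed
#'   the onset delay.
#' @param E_la Lactic energies drawn in each race (J kg^-1).
#' @param k_rise,k_decay,onset Shape constants, fixed during the fit.
#' @return A [lactic_capacity_model()] with the fitted capacity and an
#'   `rse` field (J kg^-1).
#' @examples
#' fit_lactic_capacity(c(9.43, 19.04, 43.91), c(364, 790, 1189))
#' @export
fit_lactic_capacity <- function(T, E_la, k_rise = 20, k_decay = 1500,
                                onset = 3) {
  stopifnot(length(T) == length(E_la), length(T) >= 1)
  if (any(T <= onset)) {
    stop("all race durations must exceed the lactic onset delay")
  }
  unit <- lactic_capacity_model(1, k_rise = k_rise, k_decay = k_decay,
                                onset = onset)
  m <- lactic_energy(T, unit)
  cap <- sum(E_la * m) / sum(m^2)
  model <- lactic_capacity_model(cap, k_rise = k_rise,
                                 k_decay = k_decay, onset = onset)
  res <- E_la - lactic_energy(T, model)
  model$rse <- if (length(T) > 1) sqrt(sum(res^2) / (length(T) - 1)) else 0
  model
}

#' @export
print.alactic_capacity_model <- function(x, ...) {
  cat(sprintf("Alactic capacity model: E_al_max = %.0f J/kg", x$E_al_max))
  cat(sprintf(" (mu = %.2f, sigma = %.2f)\n", x$mu, x$sigma))
  if (!is.null(x$rse)) cat(sprintf("  RSE %.3f W/kg\n", x$rse))
  invisible(x)
}

#' @export
print.lactic_capacity_model <- function(x, ...) {
  cat(sprintf("Lactic capacity model: E_la_max = %.0f J/kg", x$E_la_max))
  cat(sprintf(" (rise %.0f s, decay %.0f s, onset %.0f s)\n",
              x$k_rise, x$k_decay, x$onset))
  if (!is.null(x$rse)) cat(sprintf("  RSE %.1f J/kg\n", x$rse))
  invisible(x)
}

#' Pathway amplitude reproducing a target energy
#'
#' Given an energy to be delivered by a pathway over a race of
#' duration `T`, returns the model amplitude whose power curve
#' integrates to that energy. Because the pathway shapes are linear in
#' their amplitude, the solution is `E_target` divided by the
#' trapezoidal integral of the unit-amplitude shape over `(0, T]`.
#'
#' @param E_target Target energy (J kg^-1), non-negative.
#' @param T Race duration (s), positive.
#' @param shape `"alactic"` or `"lactic"`.
#' @param params A [pathway_params()].
#' @param dt Integration step (s).
#' @return Amplitude in W kg^-1.
#' @export
amplitude_from_energy <- function(E_target, T,
                                  shape = c("alactic", "lactic"),
                                  params = pathway_params(), dt = 0.01) {
  shape <- match.arg(shape)
  stopifnot(E_target >= 0, T > 0)
  t <- seq(0, by = dt, length.out = max(2, round(T / dt)) + 1)
  unit <- switch(shape,
                 alactic = alactic_power(t, 1, params),
                 lactic = lactic_power(t, 1, params))
  denom <- trapz(t, unit)
  if (denom <= 1e-10) stop("unit shape integral vanishes; `T` too small")
  E_target / denom
}

#' Lactate equivalence of anaerobic lactic energy
#'
#' The accumulation of 1 mmol L^-1 of blood lactate reflects an
#' anaerobic-lactic energy release equivalent to the consumption of
#' 3 mL O2 per kg body mass in men (2.7 in women). With the energy
#' equivalent of oxygen at 20.9 J mL^-1, 1 mmol L^-1 corresponds to
#' 62.7 J kg^-1 in men and 56.43 J kg^-1 in women (the product of the
#' two constants is used throughout).
#'
#' @param sex `"male"` or `"female"`.
#' @param o2_energy Energy equivalent of oxygen (J mL^-1).
#' @param o2_per_mM Oxygen equivalent of 1 mmol L^-1 blood lactate
#'   (mL O2 per kg body mass); defaults 3.0 (men) / 2.7 (women).
#' @return Energy per unit lactate accumulation
#'   (J kg^-1 per mmol L^-1).
#' @export
lactate_energy_equivalent <- function(sex = c("male", "female"),
                                      o2_energy = 20.9,
                                      o2_per_mM = NULL) {
  sex <- match.arg(sex)
  if (is.null(o2_per_mM)) o2_per_mM <- if (sex == "male") 3.0 else 2.7
  o2_energy * o2_per_mM
}

#' Blood lactate accumulation implied by a lactic energy release
#'
#' @param E_la Anaerobic lactic energy (J kg^-1), non-negative.
#' @param sex `"male"` or `"female"` (selects the energy equivalent,
#'   see [lactate_energy_equivalent()]).
#' @return Lactate accumulation above rest (mmol L^-1).
#' @examples
#' lactate_from_energy(1314)   # ~21 mmol/L
#' @export
lactate_from_energy <- function(E_la, sex = c("male", "female")) {
  if (any(E_la < 0)) stop("`E_la` must be non-negative")
  E_la / lactate_energy_equivalent(sex)
}

#' Reference ranges for anaerobic capacities
#'
#' Theoretical ranges of the maximal anaerobic capacities, derived
#' from muscle phosphocreatine content and from peak blood-lactate
#' accumulation: alactic 310-390 J kg^-1 (men) / 230-292 J kg^-1
#' (women); lactic 940-1250 J kg^-1 (15-20 mmol L^-1 in men). Used
#' for plausibility warnings only, never to constrain a fit.
#'
#' @param sex `"male"` or `"female"`.
#' @return List with `alactic` and `lactic` two-element ranges
#'   (J kg^-1).
#' @export
capacity_reference_ranges <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (sex == "male") {
    list(alactic = c(310, 390), lactic = c(940, 1250))
  } else {
    list(alactic = c(230, 292), lactic = c(850, 1130))
  }
}

#' Warn when fitted capacities fall outside reference ranges
#'
#' @param E_al_max,E_la_max Fitted capacities (J kg^-1); `NULL` values
#'   are skipped.
#' @param sex `"male"` or `"female"`.
#' @return Character vector of warning messages (empty when all values
#'   are in range), invisibly; warnings are also signalled.
#' @export
check_capacity_ranges <- function(E_al_max = NULL, E_la_max = NULL,
                                  sex = c("male", "female")) {
  sex <- match.arg(sex)
  rng <- capacity_reference_ranges(sex)
  msgs <- character(0)
  if (!is.null(E_al_max) &&
      (E_al_max < rng$alactic[1] || E_al_max > rng$alactic[2])) {
    msgs <- c(msgs, sprintf(
      "alactic capacity %.0f J/kg outside the theoretical range %.0f-%.0f J/kg",
      E_al_max, rng$alactic[1], rng$alactic[2]))
  }
  if (!is.null(E_la_max) &&
      (E_la_max < rng$lactic[1] || E_la_max > rng$lactic[2])) {
    msgs <- c(msgs, sprintf(
      "lactic capacity %.0f J/kg outside the theoretical range %.0f-%.0f J/kg",
      E_la_max, rng$lactic[1], rng$lactic[2]))
  }
  for (m in msgs) warning(m, call. = FALSE)
  invisible(msgs)
}
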