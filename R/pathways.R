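#' Pathway model parameters
#'
#' Fixed constants of the three-pathway sprint bioenergetics model.
#' Aerobic power rises exponentially to `MAP - BMR` with time constant
#' `k_aer`. Anaerobic-lactic (glycolytic) power follows a
#' peak-normalized bi-exponential with rise constant `k1` and decay
#' constant `k2`. Anaerobic-alactic (phosphocreatine) power follows a
#' log-normal bell with location `mu_al` (ln-seconds) and width
#' `sigma_al`. Only the two anaerobic amplitudes are free; everything
#' here is fixed.
#'
#' @param MAP Maximal aerobic power, W kg^-1 (24.5 for elite men, 21.0
#'   for elite women).
#' @param BMR Basal metabolic rate, W kg^-1.
#' @param k_aer Aerobic rise time constant (s).
#' @param k1,k2 Lactic rise and decay time constants (s), `k1 < k2`.
#' @param mu_al Alactic log-normal location (ln-seconds): peak alactic
#'   power occurs at `t = exp(mu_al)`.
#' @param sigma_al Alactic log-normal width (magnitude; it enters the
#'   model only squared).
#' @return A `pathway_params` list; the derived normalization constant
#'   `k_norm` (see [knorm()]) is included.
#' @export
pathway_params <- function(MAP = 24.5, BMR = 1.2, k_aer = 23,
                           k1 = 2.75, k2 = 35, mu_al = 1,
                           sigma_al = 0.4) {
  stopifnot(MAP > BMR, BMR >= 0, k_aer > 0, k1 > 0, k2 > 0, k1 < k2,
            sigma_al > 0)
  structure(
    list(MAP = MAP, BMR = BMR, k_aer = k_aer, k1 = k1, k2 = k2,
         mu_al = mu_al, sigma_al = abs(sigma_al),
         k_norm = knorm(k1, k2)),
    class = "pathway_params"
  )
}

#' Default pathway parameters by sex
#'
#' Convenience wrapper around [pathway_params()] selecting the default
#' maximal aerobic power: 24.5 W kg^-1 for men, 21.0 W kg^-1 for
#' women.
#'
#' @param sex `"male"` or `"female"`.
#' @param ... Passed on to [pathway_params()].
#' @return A `pathway_params` list.
#' @export
pathway_params_for <- function(sex = c("male", "female"), ...) {
  sex <- match.arg(sex)
  pathway_params(MAP = if (sex == "male") 24.5 else 21.0, ...)
}

#' Normalization constant of the bi-exponential power model
#'
#' The bi-exponential \eqn{f(t) = (1 - e^{-t/k_1}) e^{-t/k_2}} peaks
#' below 1. `knorm` returns the constant that rescales it so its
#' maximum equals 1, allowing the model amplitude to be read as the
#' peak power. The peak time is analytic:
#' \eqn{t^* = k_1 \ln(1 + k_2/k_1)}, and
#' \eqn{k_{norm} = 1 / f(t^*)}.
#'
#' @param k1,k2 Rise and decay time constants (s).
#' @return Named list components are not used; returns the scalar
#'   constant.
#' @examples
#' knorm(2.75, 35)    # 1.3251
#' knorm_peak_time(2.75, 35)  # 7.204 s
#' @export
knorm <- function(k1, k2) {
  stopifnot(k1 > 0, k2 > 0)
  t_star <- knorm_peak_time(k1, k2)
  1 / ((1 - exp(-t_star / k1)) * exp(-t_star / k2))
}

#' @rdname knorm
#' @export
knorm_peak_time <- function(k1, k2) {
  stopifnot(k1 > 0, k2 > 0)
  k1 * log(1 + k2 / k1)
}

#' Aerobic power and energy
#'
#' Aerobic power above basal rises exponentially towards `MAP - BMR`:
#' \deqn{P_{aer}(t) = (MAP - BMR)(1 - e^{-t/k_{aer}})}
#' Its time integral has the closed form
#' \deqn{E_{aer}(T) = (MAP - BMR)\,[T - k_{aer}(1 - e^{-T/k_{aer}})].}
#'
#' @param t,T Time / race duration (s), net of reaction time.
#' @param params A [pathway_params()].
#' @return Power in W kg^-1, or energy in J kg^-1.
#' @examples
#' aerobic_energy(9.43, pathway_params(MAP = 24.5))  # ~40 J/kg
#' @export
aerobic_power <- function(t, params = pathway_params()) {
  stopifnot(inherits(params, "pathway_params"))
  if (any(t < 0)) stop("`t` must be non-negative")
  (params$MAP - params$BMR) * (1 - exp(-t / params$k_aer))
}

#' @rdname aerobic_power
#' @export
aerobic_energy <- function(T, params = pathway_params()) {
  stopifnot(inherits(params, "pathway_params"))
  if (any(T < 0)) stop("`T` must be non-negative")
  (params$MAP - params$BMR) *
    (T - params$k_aer * (1 - exp(-T / params$k_aer)))
}

#' Anaerobic-lactic (glycolytic) power
#'
#' Peak-normalized bi-exponential:
#' \deqn{P_{la}(t) = P_{la,max} k_{norm} (1 - e^{-t/k_1}) e^{-t/k_2}}
#' By construction of `k_norm`, the maximum over `t` equals
#' `P_la_max`, attained at \eqn{t^* = k_1 \ln(1 + k_2/k_1)}.
#'
#' @param t Time (s), non-negative.
#' @param P_la_max Peak lactic power (W kg^-1).
#' @param params A [pathway_params()].
#' @return Power in W kg^-1.
#' @export
lactic_power <- function(t, P_la_max, params = pathway_params()) {
  stopifnot(inherits(params, "pathway_params"), P_la_max >= 0)
  if (any(t < 0)) stop("`t` must be non-negative")
  P_la_max * params$k_norm * (1 - exp(-t / params$k1)) *
    exp(-t / params$k2)
}

#' Anaerobic-alactic (phosphocreatine) power
#'
#' Log-normal bell:
#' \deqn{P_{al}(t) = P_{al,max} \exp\!\left(-\frac{(\ln t -
#'   \mu_{al})^2}{2\sigma_{al}^2}\right)}
#' peaking at `P_al_max` when \eqn{t = e^{\mu_{al}}}. The value at
#' `t = 0` is defined as 0 by continuity.
#'
#' @param t Time (s), non-negative.
#' @param P_al_max Peak alactic power (W kg^-1).
#' @param params A [pathway_params()].
#' @return Power in W kg^-1.
#' @export
alactic_power <- function(t, P_al_max, params = pathway_params()) {
  stopifnot(inherits(params, "pathway_params"), P_al_max >= 0)
  if (any(t < 0)) stop("`t` must be non-negative")
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- P_al_max *
    exp(-(log(t[pos]) - params$mu_al)^2 / (2 * params$sigma_al^2))
  out
}

#' Total modelled metabolic power
#'
#' Sum of the three pathway powers (the pathways are assumed to act
#' independently and additively).
#'
#' @param t Time (s).
#' @param P_al_max,P_la_max Pathway amplitudes (W kg^-1).
#' @param params A [pathway_params()].
#' @return Power in W kg^-1.
#' @export
total_power <- function(t, P_al_max, P_la_max, params = pathway_params()) {
  alactic_power(t, P_al_max, params) +
    lactic_power(t, P_la_max, params) +
    aerobic_power(t, params)
}

#' Fit pathway amplitudes to an observed power series
#'
#' With the shape constants fixed, the pathway model is linear in the
#' two anaerobic amplitudes, so the least-squares problem reduces to a
#' non-negative linear regression of the aerobic-corrected observed
#' power on the unit-amplitude alactic and lactic shapes. Negative
#' solutions are handled by clamping the offending amplitude to zero
#' and refitting the other.
#'
#' @param observed A `power_series` covering the race on a uniform
#'   grid.
#' @param params A [pathway_params()].
#' @return A `model_amplitudes` object: `P_al_max`, `P_la_max`
#'   (W kg^-1), `adjusted_r2` (against the observed series, with
#'   p = 2 free parameters) and `params`.
#' @export
fit_amplitudes <- function(observed, params = pathway_params()) {
  stopifnot(inherits(observed, "power_series"),
            inherits(params, "pathway_params"))
  if (all(observed$power == 0)) {
    stop("observed power series is identically zero; nothing to fit")
  }
  t <- observed$time
  y <- observed$power - aerobic_power(t, params)
  x_al <- alactic_power(t, 1, params)
  x_la <- lactic_power(t, 1, params)

  beta <- .nnls2(cbind(x_al, x_la), y)
  fitted <- total_power(t, beta[1], beta[2], params)
  res <- observed$power - fitted
  n <- length(t)
  p <- 2
  ss_res <- sum(res^2)
  ss_tot <- sum((observed$power - mean(observed$power))^2)
  r2 <- 1 - ss_res / ss_tot
  structure(
    list(
      P_al_max = beta[1],
      P_la_max = beta[2],
      r2 = r2,
      adjusted_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1),
      params = params
    ),
    class = "model_amplitudes"
  )
}

# non-negative least squares for two columns: try unconstrained, then
# clamp-and-refit (exact for 2 variables)
.nnls2 <- function(X, y) {
  beta <- tryCatch(unname(qr.solve(X, y)), error = function(e) c(0, 0))
  if (all(beta >= 0)) return(beta)
  b1 <- max(0, sum(X[, 1] * y) / sum(X[, 1]^2))
  b2 <- max(0, sum(X[, 2] * y) / sum(X[, 2]^2))
  rss <- function(b) sum((y - X %*% b)^2)
  c1 <- c(b1, 0)
  c2 <- c(0, b2)
  if (rss(c1) <= rss(c2)) c1 else c2
}

#' @export
print.model_amplitudes <- function(x, ...) {
  cat("Fitted pathway amplitudes\n")
  cat(sprintf("  P_al_max    %.1f W/kg (alactic peak)\n", x$P_al_max))
  cat(sprintf("  P_la_max    %.1f W/kg (lactic peak)\n", x$P_la_max))
  cat(sprintf("  adjusted R2 %.3f\n", x$adjusted_r2))
  invisible(x)
}

#' Pathway energy accounting
#'
#' Integrates each pathway power over the race duration (trapezoidal
#' rule on a uniform grid of width `dt`) and reports absolute and
#' percentage contributions. The alactic integrand is started at
#' `t = dt` (its `t = 0` value is 0 by continuity and the omitted sliver
#' is bounded by `P_al_max * dt`).
#'
#' @param amplitudes A `model_amplitudes`, or a list with `P_al_max`
#'   and `P_la_max`.
#' @param T Race duration (s), net of reaction time.
#' @param params A [pathway_params()]; defaults to the params stored in
#'   `amplitudes` if present.
#' @param dt Integration step (s).
#' @return A `pathway_energies` object: energies `alactic`, `lactic`,
#'   `aerobic`, `total` (J kg^-1) and `percent` (named vector summing
#'   to 100).
#' @export
pathway_energies <- function(amplitudes, T, params = NULL, dt = 0.01) {
  if (is.null(params)) {
    params <- amplitudes$params
  }
  stopifnot(inherits(params, "pathway_params"), T > 0, dt > 0)
  t <- seq(0, T, by = dt)
  if (t[length(t)] < T - 1e-9) t <- c(t, T)
  e_al <- trapz(t, alactic_power(t, amplitudes$P_al_max, params))
  e_la <- trapz(t, lactic_power(t, amplitudes$P_la_max, params))
  e_aer <- trapz(t, aerobic_power(t, params))
  total <- e_al + e_la + e_aer
  structure(
    list(
      alactic = e_al, lactic = e_la, aerobic = e_aer, total = total,
      percent = c(alactic = 100 * e_al / total,
                  lactic = 100 * e_la / total,
                  aerobic = 100 * e_aer / total),
      duration = T
    ),
    class = "pathway_energies"
  )
}

#' @export
print.pathway_energies <- function(x, ...) {
  cat(sprintf("Pathway energies over %.2f s\n", x$duration))
  cat(sprintf("  alactic %6.0f J/kg (%4.1f%%)\n", x$alactic,
              x$percent["alactic"]))
  cat(sprintf("  lactic  %6.0f J/kg (%4.1f%%)\n", x$lactic,
              x$percent["lactic"]))
  cat(sprintf("  aerobic %6.0f J/kg (%4.1f%%)\n", x$aerobic,
              x$percent["aerobic"]))
  cat(sprintf("  total   %6.0f J/kg\n", x$total))
  invisible(x)
}
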