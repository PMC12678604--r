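test_that("knorm matches a numeric maximization oracle", {
  # oracle: dense grid + local refinement of the raw bi-exponential
  oracle <- function(k1, k2) {
    f <- function(t) (1 - exp(-t / k1)) * exp(-t / k2)
    opt <- optimize(f, c(1e-6, 100 * k1 + k2), maximum = TRUE,
                    tol = 1e-12)
    list(t_star = opt$maximum, k_norm = 1 / opt$objective)
  }
  for (k in list(c(2.75, 35), c(20, 1500), c(1, 5), c(0.5, 60))) {
    o <- oracle(k[1], k[2])
    expect_equal(knorm_peak_time(k[1], k[2]), o$t_star, tolerance = 1e-6)
    expect_equal(knorm(k[1], k[2]), o$k_norm, tolerance = 1e-8)
  }
  expect_equal(knorm_peak_time(2.75, 35), 7.2033, tolerance = 1e-4)
  expect_equal(knorm(2.75, 35), 1.3250, tolerance = 1e-4)
  expect_equal(knorm_peak_time(20, 1500), 86.61, tolerance = 1e-3)
  expect_equal(knorm(20, 1500), 1.0736, tolerance = 1e-4)
  # equal constants: peak at k ln 2
  expect_equal(knorm_peak_time(7, 7.0000001), 7 * log(2), tolerance = 1e-6)
})

test_that("lactic power peaks exactly at its amplitude", {
  set.seed(42)
  for (i in 1:20) {
    k1 <- runif(1, 0.5, 30)
    k2 <- k1 * runif(1, 1.5, 100)
    p <- pathway_params(k1 = k1, k2 = k2)
    amp <- runif(1, 5, 150)
    peak <- optimize(function(t) lactic_power(t, amp, p),
                     c(1e-6, 10 * (k1 + k2)), maximum = TRUE,
                     tol = 1e-10)$objective
    expect_equal(peak, amp, tolerance = 1e-6)
  }
  p <- pathway_params()
  expect_equal(lactic_power(0, 47.6, p), 0)
  expect_equal(lactic_power(knorm_peak_time(2.75, 35), 47.6, p), 47.6,
               tolerance = 1e-9)
  expect_lt(lactic_power(5000, 47.6, p), 1e-10)
})

test_that("alactic power is a log-normal bell peaking at exp(mu)", {
  p <- pathway_params()
  expect_equal(alactic_power(exp(1), 137.7, p), 137.7)
  expect_equal(alactic_power(0, 137.7, p), 0)
  expect_equal(alactic_power(1, 100, p), 100 * exp(-1 / (2 * 0.16)))
  # grid-search oracle for the peak location
  tg <- seq(0.01, 20, by = 0.001)
  vals <- alactic_power(tg, 1, p)
  expect_equal(tg[which.max(vals)], exp(p$mu_al), tolerance = 1e-3)
  expect_lt(alactic_power(1e-8, 137.7, p), 1e-10)
})

test_that("total power is the sum of the three pathways", {
  p <- pathway_params()
  t <- c(0, 0.5, 2.7, 7.2, 9.4)
  expect_equal(total_power(t, 137.7, 47.6, p),
               alactic_power(t, 137.7, p) + lactic_power(t, 47.6, p) +
                 aerobic_power(t, p))
  expect_equal(total_power(0, 137.7, 47.6, p), 0)
  p0 <- pathway_params(MAP = 1.2 + 1e-12)
  expect_lt(max(total_power(t, 0, 0, p0)), 1e-10)
})

test_that("aerobic closed-form energy matches numeric integration", {
  p <- pathway_params(MAP = 24.5)
  expect_equal(aerobic_power(0, p), 0)
  expect_equal(aerobic_power(23, p), 23.3 * (1 - exp(-1)))
  expect_equal(aerobic_power(1e6, pathway_params(MAP = 21)), 19.8,
               tolerance = 1e-9)
  for (T in c(5, 9.43, 43.91, 120)) {
    tg <- seq(0, T, by = 0.001)
    num <- sum((aerobic_power(tg[-1], p) +
                aerobic_power(tg[-length(tg)], p)) / 2 * diff(tg))
    expect_equal(aerobic_energy(T, p), num, tolerance = 1e-6)
  }
  expect_equal(aerobic_energy(0, p), 0)
})

test_that("amplitude fitting recovers self-generated series exactly", {
  p <- pathway_params()
  t <- seq(0, 9.43, by = 0.01)
  obs <- power_series(t, total_power(t, 100, 40, p), source = "from_model")
  fit <- fit_amplitudes(obs, p)
  expect_equal(fit$P_al_max, 100, tolerance = 1e-9)
  expect_equal(fit$P_la_max, 40, tolerance = 1e-9)
  expect_equal(fit$adjusted_r2, 1, tolerance = 1e-12)
})

test_that("amplitude fitting is unbiased under observation noise", {
  p <- pathway_params()
  t <- seq(0, 9.43, by = 0.01)
  clean <- total_power(t, 100, 40, p)
  ests <- t(vapply(1:50, function(s) {
    set.seed(s)
    noisy <- pmax(clean + rnorm(length(t), 0, 5), 0)
    fit <- fit_amplitudes(power_series(t, noisy, source = "from_model"), p)
    c(fit$P_al_max, fit$P_la_max)
  }, numeric(2)))
  expect_lt(abs(mean(ests[, 1]) / 100 - 1), 0.01)
  expect_lt(abs(mean(ests[, 2]) / 40 - 1), 0.01)
})

test_that("degenerate amplitude fits are handled", {
  p <- pathway_params()
  t <- seq(0, 9.43, by = 0.01)
  expect_error(
    fit_amplitudes(power_series(t, rep(0, length(t)),
                                source = "from_model"), p),
    "identically zero")
  # aerobic-only series: anaerobic amplitudes shrink to ~0, never negative
  obs <- power_series(t, aerobic_power(t, p), source = "from_model")
  fit <- fit_amplitudes(obs, p)
  expect_gte(fit$P_al_max, 0)
  expect_gte(fit$P_la_max, 0)
  expect_lt(fit$P_al_max + fit$P_la_max, 1e-6)
})

test_that("pathway energies are additive and consistent with total power", {
  p <- pathway_params()
  amp <- list(P_al_max = 137.7, P_la_max = 47.6)
  pe <- pathway_energies(amp, T = 9.43, params = p)
  t <- seq(0, 9.43, by = 0.01)
  tot <- total_power(t, amp$P_al_max, amp$P_la_max, p)
  tot_int <- sum((tot[-1] + tot[-length(tot)]) / 2 * diff(t))
  expect_equal(pe$total, tot_int, tolerance = 1e-9)
  expect_equal(pe$total, pe$alactic + pe$lactic + pe$aerobic)
  expect_equal(sum(pe$percent), 100)
  # zero anaerobic amplitudes leave the aerobic integral only
  pe0 <- pathway_energies(list(P_al_max = 0, P_la_max = 0), 9.43,
                          params = p)
  expect_equal(pe0$total, pe0$aerobic)
})
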