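test_that("OD to DCW conversion applies the linear correlation", {
  expect_identical(od_to_dcw(1.0), 0.452)
  expect_identical(od_to_dcw(0), 0)
  expect_equal(od_to_dcw(2.0), 0.904)
  expect_equal(od_to_dcw(c(1, 2, 3)), 0.452 * c(1, 2, 3))
  expect_error(od_to_dcw(-0.1), "non-negative")
})

test_that("linear calibration inverts a known standard curve", {
  conc <- c(0.5, 1, 2, 4, 8)
  abs_ <- 0.12 + 0.31 * conc
  cal <- linear_calibration(conc, abs_)
  expect_equal(cal$slope, 0.31, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_equal(cal$predict(0.12 + 0.31 * 3), 3, tolerance = 1e-9)
})

test_that("exponential phase detection prefers the true growth window", {
  # pure exponential: full range, perfect fit
  t <- 0:9
  curve <- tibble::tibble(time_h = t, dcw_g_l = 0.1 * exp(0.4 * t))
  w <- detect_exponential_phase(curve)
  expect_identical(c(w$start, w$end), c(1L, 10L))
  expect_equal(w$r_squared, 1)
  # exponential then plateau: plateau points excluded, and the chosen
  # window beats the full-range fit
  curve2 <- tibble::tibble(
    time_h = 0:9,
    dcw_g_l = pmin(0.1 * exp(0.4 * (0:9)), 0.1 * exp(0.4 * 5)))
  w2 <- detect_exponential_phase(curve2)
  expect_lte(w2$end, 6L)
  expect_gte(w2$r_squared,
             kivflux:::loglinear_r2(curve2$time_h, log(curve2$dcw_g_l)))
  expect_equal(fit_mu_max(curve2, w2)$mu_max, 0.4, tolerance = 1e-9)
  # too few points
  expect_error(
    detect_exponential_phase(tibble::tibble(time_h = 0:1,
                                            dcw_g_l = c(1, 2)),
                             min_points = 4),
    "fewer than 4")
})

test_that("window choice agrees with an enumerate-all-windows oracle", {
  withr::local_seed(88)
  for (rep in 1:5) {
    t <- 0:11
    x <- pmin(0.08 * exp(0.35 * t), 0.08 * exp(0.35 * 7)) *
      exp(stats::rnorm(12, 0, 0.01))
    curve <- tibble::tibble(time_h = t, dcw_g_l = x)
    w <- detect_exponential_phase(curve, min_points = 4)
    # oracle: brute force over every window, same tie-break
    best <- NULL
    for (i in 1:9) for (j in (i + 3):12) {
      r2 <- summary(stats::lm(log(x[i:j]) ~ t[i:j]))$r.squared
      cand <- list(start = i, end = j, n = j - i + 1, r2 = r2)
      if (is.null(best) || r2 > best$r2 + 1e-9 ||
          (r2 > best$r2 - 1e-9 && (cand$n > best$n ||
                                   (cand$n == best$n && i < best$start)))) {
        best <- cand
      }
    }
    expect_identical(c(w$start, w$end), c(best$start, best$end),
                     label = sprintf("replicate %d window", rep))
  }
})

test_that("mu_max fitting is exact on clean data and scale-invariant", {
  t <- 0:5
  curve <- tibble::tibble(time_h = t, dcw_g_l = 0.1 * exp(0.5 * t))
  fit <- fit_mu_max(curve)
  expect_equal(fit$mu_max, 0.5, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  # invariance under positive rescaling of biomass
  for (k in c(0.01, 3, 250)) {
    scaled <- dplyr::mutate(curve, dcw_g_l = dcw_g_l * k)
    expect_equal(fit_mu_max(scaled)$mu_max, 0.5, tolerance = 1e-9)
  }
  # constant biomass: zero growth rate
  flat <- tibble::tibble(time_h = 0:5, dcw_g_l = rep(2, 6))
  expect_equal(fit_mu_max(flat)$mu_max, 0)
  # degenerate time axis
  expect_error(
    fit_mu_max(curve, window = structure(list(start = 1, end = 1, n = 1),
                                         class = "phase_window")),
    "zero time variance")
})

test_that("yield arithmetic matches the published endpoint ratios", {
  # glucose and lactose batches of the producer strain, to 2 decimals
  expect_equal(round(compute_yields(NA, 10.2, 2.18)$yps, 2), 0.21)
  expect_equal(round(compute_yields(NA, 9.0, 2.41)$yps, 2), 0.27)
  y <- compute_yields(0.5, 10, 2)
  expect_equal(y$yxs, 0.05)
  expect_equal(y$yps, 0.2)
  expect_equal(y$ypx, 4)
  expect_error(compute_yields(0.5, 0, 2), "delta_s must be positive")
  expect_error(compute_yields(-1, 10, 2), "delta_x must be positive")
})

test_that("yields are invariant to common unit rescaling", {
  base <- compute_yields(0.41, 9.7, 2.2)
  for (k in c(0.001, 1000)) {
    scaled <- compute_yields(0.41 * k, 9.7 * k, 2.2 * k)
    expect_equal(scaled$yxs, base$yxs, tolerance = 1e-12)
    expect_equal(scaled$yps, base$yps, tolerance = 1e-12)
    expect_equal(scaled$ypx, base$ypx, tolerance = 1e-12)
  }
})

test_that("kinetics estimates converge to the generative truth", {
  # noiseless closed loop: exact recovery
  clean <- simulate_batch_culture(mu = 0.45, yxs = 0.38, yps = 0.22,
                                  noise_sd = 0, n_replicates = 1, seed = 1)
  k <- estimate_kinetics(clean)
  expect_equal(k$mu_max, 0.45, tolerance = 1e-9)
  expect_equal(k$yxs, 0.38, tolerance = 1e-9)
  expect_equal(k$yps, 0.22, tolerance = 1e-9)
  # estimates tighten as noise shrinks
  err_at <- function(sd) {
    curves <- simulate_batch_culture(mu = 0.45, yxs = 0.38, yps = 0.22,
                                     noise_sd = sd, n_replicates = 12,
                                     seed = 42)
    est <- curves |>
      dplyr::group_by(replicate) |>
      dplyr::group_modify(~ estimate_kinetics(.x)) |>
      dplyr::ungroup()
    abs(mean(est$mu_max) - 0.45)
  }
  expect_lt(err_at(0.005), err_at(0.08) + 1e-12)
  expect_lt(err_at(0.005), 0.01)
})
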