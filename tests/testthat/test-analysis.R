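test_that("Anderson-Darling family selection matches direct pass counts", {
  withr::with_seed(101, {
    logn <- replicate(20, 10^rnorm(200, 1, 0.3), simplify = FALSE)
    norm <- replicate(20, rnorm(200, 50, 2), simplify = FALSE)
  })
  sel_log <- choose_transform_family(logn)
  expect_equal(sel_log$family, "log10")
  sel_raw <- choose_transform_family(norm)
  expect_equal(sel_raw$family, "raw")
  # oracle: recount non-rejections straight from nortest on one set
  n_raw <- sum(vapply(logn, function(v) nortest::ad.test(v)$p.value,
                      1) > 0.05)
  n_log <- sum(vapply(logn, function(v) nortest::ad.test(log10(v))$p.value,
                      1) > 0.05)
  expect_equal(unname(sel_log$non_rejections), c(n_raw, n_log))
  expect_gt(n_log, n_raw)

  expect_error(choose_transform_family(list(rep(1, 20), rep(2, 20))),
               class = "ptmr_empty_input")
  expect_error(choose_transform_family(list(rnorm(5))),
               class = "ptmr_invalid_parameter")
})

test_that("dilution-point aggregation takes medians of log10 replicates", {
  agg <- aggregate_dilution_point(eta_star = c(0.1, 1, 10),
                                  velocity = c(20, 40, 80))
  expect_equal(agg$log_eta, 0)
  expect_equal(agg$log_v, log10(40))
  one <- aggregate_dilution_point(2, 30)
  expect_equal(one$log_eta, log10(2))
  bad <- aggregate_dilution_point(c(-1, 1, 10), c(10, 20, 30))
  expect_equal(bad$n_eta, 2L)
  expect_equal(bad$n_excluded, 1L)
  expect_equal(bad$log_eta, 0.5)
  none <- aggregate_dilution_point(numeric(), 10)
  expect_true(is.na(none$log_eta))
})

test_that("Pearson correlation matches the closed form and its contracts", {
  exact <- tibble::tibble(log_eta = 1:10, log_v = -(1:10))
  res <- correlate_log_values(exact)
  expect_equal(res$r, -1)
  expect_lt(res$p, 1e-10)
  expect_equal(res$slope, -1)

  three <- tibble::tibble(log_eta = c(1, 2, 3), log_v = c(2, 1, 4))
  r3 <- correlate_log_values(three)
  expect_equal(r3$r, pearson_oracle(c(1, 2, 3), c(2, 1, 4)), tolerance = 1e-12)
  expect_equal(r3$r, 0.6547, tolerance = 1e-4)

  expect_error(correlate_log_values(exact[1:2, ]), class = "ptmr_empty_input")
  expect_error(
    correlate_log_values(tibble::tibble(log_eta = c(1, 1, 1),
                                        log_v = c(1, 2, 3))),
    class = "ptmr_degenerate")
})

test_that("Pearson r is affine-invariant and sign-flips under negation", {
  withr::with_seed(5, {
    pts <- tibble::tibble(log_eta = rnorm(30), log_v = rnorm(30))
  })
  r0 <- correlate_log_values(pts)$r
  scaled <- pts |> dplyr::mutate(log_eta = 3 * log_eta + 7,
                                 log_v = 0.5 * log_v - 2)
  expect_equal(correlate_log_values(scaled)$r, r0, tolerance = 1e-12)
  flipped <- pts |> dplyr::mutate(log_eta = -log_eta)
  expect_equal(correlate_log_values(flipped)$r, -r0, tolerance = 1e-12)
})

test_that("power-law fits recover exact and noisy exponents", {
  conc <- 1 / 2^(0:7)
  fit <- suppressWarnings(fit_power_law(conc, conc^-0.5)) # exact fit
  expect_equal(fit$slope, -0.5, tolerance = 1e-12)
  expect_equal(fit$exponent, 0.5, tolerance = 1e-12)
  flat <- suppressWarnings(fit_power_law(conc, rep(3, 8)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)

  withr::with_seed(99, {
    v <- conc^-0.5 * 10^rnorm(8, 0, 0.05)
  })
  noisy <- fit_power_law(conc, v)
  expect_lt(abs(noisy$exponent - 0.5), 2 * noisy$se + 1e-12)
  expect_error(fit_power_law(c(1, -1, 2), c(1, 2, 3)),
               class = "ptmr_invalid_parameter", regexp = "indices: 2")
})

test_that("fit objects expose broom-style tidy and glance methods", {
  fit <- suppressWarnings(fit_power_law(1 / 2^(0:4), 2^(0:4)))
  expect_s3_class(generics::tidy(fit), "tbl_df")
  expect_equal(generics::glance(fit)$exponent, 1, tolerance = 1e-12)
  res <- correlate_log_values(tibble::tibble(log_eta = 1:5,
                                             log_v = c(5, 4, 3.2, 2, 1)))
  g <- generics::glance(res)
  expect_true(all(c("r", "p.value", "n") %in% names(g)))
  expect_equal(generics::tidy(res)$estimate[2], res$slope)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})

test_that("the default simulated cohort selects the log10 family", {
  ser <- simulate_dilution_series(
    n_animals = 2, dilution_factors = 2^(0:3),
    swimmer_cfg_template = swimmer_sim_config(n_sperm = 30, duration = 1),
    bead_cfg_template = bead_sim_config(n_particles = 2, duration = 0.2),
    seed = 77)
  ensembles <- lapply(ser$sperm_truth, function(tt) {
    unique(tt[c("particle", "true_speed")])$true_speed
  })
  expect_equal(choose_transform_family(ensembles)$family, "log10")
})
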