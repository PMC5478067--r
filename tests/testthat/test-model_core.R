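test_that("log-lambda predictor evaluates the treatment/origin/area terms", {
  zero <- toy_params()[1, ]
  expect_equal(compute_log_lambda(zero, list(TRT = 1, ORI = 0, area = 2.3)), 0)

  p <- list(u1 = 0.5, u2 = 0, o1 = 0.3, o2 = 0, a1 = 0.1, a2 = 0.2,
            a3 = 0.4, a4 = 0)
  expect_equal(compute_log_lambda(p, list(TRT = 1, ORI = 1, area = 2)), 1.8)

  # untreated sites annihilate every interaction term
  p2 <- list(u1 = 9, u2 = 1, o1 = 4, o2 = -1, a1 = 0, a2 = 5, a3 = -7, a4 = 2)
  expect_equal(compute_log_lambda(p2, list(TRT = 0, ORI = 0, area = 1.7)), 0)

  # vectorized over sites, and exp() is always a valid Poisson rate
  sites <- list(TRT = c(0, 1, 1), ORI = c(0, 0, 1), area = c(-1, 0, 2))
  ll <- compute_log_lambda(p, sites)
  expect_length(ll, 3)
  expect_true(all(exp(ll) > 0))
  expect_error(compute_log_lambda(p, list(TRT = 2, ORI = 0, area = 0)), "TRT")
  expect_error(compute_log_lambda(p, list(TRT = 1, ORI = 1, area = Inf)), "finite")
})

test_that("detection probability is the inverse-logit of the date/time terms", {
  expect_equal(compute_detection_prob(toy_params()[1, ], list(DATE = 0.7, TSR = -2)), 0.5)
  p <- toy_params(v1 = 1, b1 = 0.5)[1, ]
  expect_equal(compute_detection_prob(p, list(DATE = 1, TSR = 0)),
               1 / (1 + exp(-1.5)), tolerance = 1e-12)
  # saturation stays strictly inside (0, 1)
  lo <- compute_detection_prob(toy_params(v1 = -20)[1, ], list(DATE = 0, TSR = 0))
  hi <- compute_detection_prob(toy_params(v1 = 50)[1, ], list(DATE = 0, TSR = 0))
  expect_true(lo > 0 && lo < 1e-8)
  expect_true(hi < 1 && hi > 1 - 1e-8)
})

test_that("detection probability is strictly increasing in the intercept", {
  v <- seq(-6, 6, by = 0.5)
  ps <- vapply(v, function(v1) {
    compute_detection_prob(toy_params(v1 = v1, b1 = 0.3, b3 = -0.2)[1, ],
                           list(DATE = 1.1, TSR = -0.4))
  }, numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("marginal likelihood handles the inclusion mixture edge cases", {
  expect_equal(site_species_loglik(c(0, 0, 0), 0, log(2), c(0.5, 0.5, 0.5), 100), 0)
  expect_identical(site_species_loglik(c(1, 0, 0), 0, log(2), c(0.5, 0.5, 0.5), 100), -Inf)
  expect_error(site_species_loglik(c(5, 0), 0.5, log(2), 0.5, 3), "N_max")
  expect_error(site_species_loglik(c(1, 0), 1.5, log(2), 0.5, 100), "psi")
  expect_error(site_species_loglik(c(1, 0), 0.5, log(2), 1, 100), "detection")
})

test_that("marginal likelihood matches brute-force summation over a parameter grid", {
  grid <- expand.grid(psi = c(0.2, 0.7, 1), lambda = c(0.5, 2, 8),
                      p = c(0.15, 0.5, 0.85), stringsAsFactors = FALSE)
  y_sets <- list(0L, c(0L, 0L), c(1L, 0L), c(2L, 1L, 0L), c(3L, 5L, 2L, 0L))
  for (r in seq_len(nrow(grid))) {
    for (y in y_sets) {
      got <- site_species_loglik(y, grid$psi[r], log(grid$lambda[r]),
                                 grid$p[r], 200)
      want <- oracle_loglik(y, grid$psi[r], grid$lambda[r], grid$p[r], 200)
      expect_equal(got, want, tolerance = 1e-8,
                   label = sprintf("psi=%g lambda=%g p=%g y=(%s)",
                                   grid$psi[r], grid$lambda[r], grid$p[r],
                                   paste(y, collapse = ",")))
    }
  }
})

test_that("likelihood is insensitive to the truncation point beyond the Poisson tail", {
  y <- c(2L, 0L, 1L)
  base <- site_species_loglik(y, 0.6, log(4), c(0.3, 0.6, 0.5), 120)
  for (nm in c(200, 400, 1000)) {
    expect_equal(site_species_loglik(y, 0.6, log(4), c(0.3, 0.6, 0.5), nm),
                 base, tolerance = 1e-10)
  }
})

test_that("conditional inclusion probability matches its brute-force oracle", {
  expect_equal(conditional_inclusion_prob(c(0, 2, 0), 0.3, 2, c(0.5, 0.5, 0.5)), 1)
  expect_equal(conditional_inclusion_prob(c(0, 0), 1, 2, c(0.5, 0.5)), 1)
  expect_equal(conditional_inclusion_prob(c(0, 0), 0, 2, c(0.5, 0.5)), 0)
  for (psi in c(0.1, 0.5, 0.9)) {
    for (lambda in c(0.5, 2, 6)) {
      p <- c(0.4, 0.55, 0.7)
      got <- conditional_inclusion_prob(rep(0L, 3), psi, lambda, p, N_max = 200)
      want <- oracle_inclusion_zero(psi, lambda, p, N_max = 200)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})
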