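test_that("generated designs have the blocked four-treatment structure", {
  d <- generate_design(design_spec(), seed = 7)
  expect_s3_class(d, "survey_design")
  expect_equal(nrow(d$sites), 76)           # 19 blocks x 4 site types
  expect_equal(nrow(d$visits), 228)         # x 3 visits
  tab <- table(d$sites$origin, d$sites$treated)
  expect_true(all(tab == 19))
  # every block holds all four types
  per_block <- tapply(paste(d$sites$origin, d$sites$treated),
                      d$sites$block_id, function(x) length(unique(x)))
  expect_true(all(per_block == 4))
  # weed dropout flags forest sites of exactly 3 blocks, deletes nothing
  inel <- d$sites[d$sites$weed_contrast_eligible == 0, ]
  expect_equal(nrow(inel), 6)
  expect_true(all(inel$origin == "forest"))
  expect_equal(length(unique(inel$block_id)), 3)
  # area constraints: range and within-block spread
  expect_true(all(d$sites$site_area_ha >= 0.5 & d$sites$site_area_ha <= 2.5))
  spread <- tapply(d$sites$site_area_ha, d$sites$block_id,
                   function(x) diff(range(x)))
  expect_true(all(spread <= 0.5))
  expect_true(all(d$sites$patch_area_ha >= d$sites$site_area_ha))
  # standardized covariates are centered
  expect_equal(mean(d$area), 0, tolerance = 1e-12)
  expect_equal(mean(d$DATE), 0, tolerance = 1e-12)

  d2 <- generate_design(design_spec(n_blocks = 2, n_visits = 2), seed = 1)
  expect_equal(nrow(d2$sites), 8)
  expect_equal(nrow(d2$visits), 16)
})

test_that("design and counts are bit-identical under a fixed seed", {
  s <- design_spec(n_blocks = 5)
  expect_identical(generate_design(s, seed = 42), generate_design(s, seed = 42))
  d <- generate_design(s, seed = 42)
  sp <- draw_species_params(default_class_hyperparams(), default_roster(3, 3, 3), seed = 9)
  expect_identical(sp, draw_species_params(default_class_hyperparams(),
                                           default_roster(3, 3, 3), seed = 9))
  expect_identical(simulate_counts(d, sp, seed = 5), simulate_counts(d, sp, seed = 5))
})

test_that("species draws follow their class hyperparameters", {
  hp <- default_class_hyperparams()
  # degenerate hierarchy: sigma -> 0 pins every species at the class mean
  hp0 <- class_hyperparams(hp$mu, hp$sigma * 0 + 1e-12)
  sp0 <- draw_species_params(hp0, default_roster(4, 4, 4), seed = 3)
  for (cc in c("sensitive", "adaptable", "exploitative")) {
    b <- as.matrix(sp0[sp0$urban_class == cc, colnames(hp$mu)])
    expect_true(max(abs(sweep(b, 2, hp$mu[cc, ]))) < 1e-6)
  }
  # class sizes follow the roster (the observed 29/21/24 community split)
  sp <- draw_species_params(hp, default_roster(), seed = 4)
  expect_equal(unname(table(sp$urban_class)[c("sensitive", "adaptable", "exploitative")]),
               c(29, 21, 24), ignore_attr = TRUE)
  # CLT check on one coefficient across many draws
  big <- draw_species_params(hp, default_roster(10000, 0, 0), seed = 5)
  se <- hp$sigma["sensitive", "u1"] / sqrt(10000)
  expect_lt(abs(mean(big$u1) - hp$mu["sensitive", "u1"]), 3 * se)
  expect_error(draw_species_params(hp, default_roster(0, 0, 0)), "0")
})

test_that("simulated counts follow the generative hierarchy", {
  d <- toy_design(n_sites = 30, n_visits = 3)
  # perfect detection and certain inclusion: every visit count equals N
  perf <- toy_params(psi = 1, u2 = log(3), v1 = 40)
  tb <- simulate_counts(d, perf, seed = 6)
  expect_true(all(tb$y[1, , ] == matrix(tb$N[1, ], 30, 3)))
  # hopeless detection: counts all zero while N can be positive
  blind <- toy_params(psi = 1, u2 = log(3), v1 = -40)
  tb0 <- simulate_counts(d, blind, seed = 6)
  expect_true(all(tb0$y == 0))
  expect_gt(sum(tb0$N), 0)
  # latent truth invariants
  sp <- draw_species_params(default_class_hyperparams(), default_roster(5, 5, 5), seed = 2)
  tb2 <- simulate_counts(generate_design(design_spec(n_blocks = 3), seed = 1), sp, seed = 3)
  expect_true(all(tb2$N[tb2$w == 0] == 0))
  expect_true(all(apply(tb2$y, c(1, 2), max) <= tb2$N))
})

test_that("simulated count moments match the zero-inflated thinning law", {
  # E[y] = psi * lambda * p; Var[y] from total variance decomposition:
  # Var = psi lam p [1 - p + p (1 - psi) lam] for y | N ~ Bin(N, p),
  # N ~ ZIP(psi, lam), checked against a brute-force enumeration.
  psi <- 0.6; lam <- 2.5; p <- 0.45
  d <- toy_design(n_sites = 2000, n_visits = 2)
  tb <- simulate_counts(d, toy_params(psi = psi, u2 = log(lam),
                                      v1 = qlogis(p)), seed = 8)
  ybar <- mean(tb$y)
  mu_want <- psi * lam * p
  # brute-force moments of y over the enumerable joint (w, N, y)
  pn <- sapply(0:100, function(n) (1 - psi) * (n == 0) + psi * dpois(n, lam))
  ey <- sum(sapply(0:100, function(n) pn[n + 1] * n * p))
  ey2 <- sum(sapply(0:100, function(n) pn[n + 1] * (n * p * (1 - p) + (n * p)^2)))
  expect_equal(ey, mu_want, tolerance = 1e-10)
  vy <- ey2 - ey^2
  n_eff <- length(tb$y)
  expect_lt(abs(ybar - ey), 4 * sqrt(vy / n_eff))
  expect_lt(abs(var(as.vector(tb$y)) - vy), 0.1 * vy)
})
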