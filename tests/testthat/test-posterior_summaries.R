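test_that("per-site class richness counts species with N >= 1", {
  roster <- data.frame(species_id = c("A", "B", "C"),
                       urban_class = c("sensitive", "sensitive", "exploitative"))
  N <- matrix(c(2, 0, 5,
                0, 0, 0), nrow = 3, ncol = 2,
              dimnames = list(c("A", "B", "C"), c("S1", "S2")))
  r <- richness_per_iteration(N, roster)
  expect_equal(r["S1", "sensitive"], 1)      # A present, B absent
  expect_equal(r["S1", "exploitative"], 1)   # C present
  expect_equal(r["S1", "adaptable"], 0)
  expect_true(all(r["S2", ] == 0))
  # all present: richness equals class sizes everywhere
  Nfull <- matrix(1, 3, 2, dimnames = dimnames(N))
  rfull <- richness_per_iteration(Nfull, roster)
  expect_true(all(rfull[, "sensitive"] == 2 & rfull[, "exploitative"] == 1))
})

test_that("richness benefit is the treated-minus-untreated stratum mean", {
  d <- generate_design(design_spec(n_blocks = 2, weed_block_dropout = 0), seed = 3)
  # one draw, richness set by hand: treated grass sites 3 and 5, untreated 1 and 1
  rich <- array(0, c(1, d$J, 3), dimnames = list(NULL, d$sites$site_id,
                                                 c("sensitive", "adaptable", "exploitative")))
  gt <- d$sites$site_id[d$sites$origin == "grass" & d$sites$treated == 1]
  gu <- d$sites$site_id[d$sites$origin == "grass" & d$sites$treated == 0]
  rich[1, gt, "sensitive"] <- c(3, 5)
  rich[1, gu, "sensitive"] <- c(1, 1)
  expect_equal(richness_benefit(rich, d, "sensitive", "grass"), 3.0)
  # identical strata: benefit identically zero
  rich[1, gu, "sensitive"] <- c(3, 5)
  expect_equal(richness_benefit(rich, d, "sensitive", "grass"), 0)
  # swapping treatment labels negates the benefit
  d2 <- d
  d2$sites$treated <- 1 - d2$sites$treated
  rich[1, gu, "sensitive"] <- c(1, 1)
  expect_equal(richness_benefit(rich, d2, "sensitive", "grass"),
               -richness_benefit(rich, d, "sensitive", "grass"))
})

test_that("weed-contrast-ineligible sites are excluded from forest strata", {
  d <- generate_design(design_spec(n_blocks = 4, weed_block_dropout = 2), seed = 5)
  rich <- array(0, c(1, d$J, 3), dimnames = list(NULL, d$sites$site_id,
                                                 c("sensitive", "adaptable", "exploitative")))
  s <- d$sites
  elig_ft <- s$site_id[s$origin == "forest" & s$treated == 1 & s$weed_contrast_eligible == 1]
  inel_ft <- s$site_id[s$origin == "forest" & s$treated == 1 & s$weed_contrast_eligible == 0]
  rich[1, elig_ft, "adaptable"] <- 2
  rich[1, inel_ft, "adaptable"] <- 100  # must not leak into the contrast
  expect_equal(richness_benefit(rich, d, "adaptable", "forest"), 2)
})

test_that("HDI is the shortest order-statistic window", {
  expect_equal(unname(hdi(rep(3.5, 50))), c(3.5, 3.5))
  expect_equal(unname(hdi(1:100, 0.95)), c(1, 95))  # ties -> lowest endpoint
  set.seed(11)
  for (rdist in list(function(n) rnorm(n),
                     function(n) rexp(n),
                     function(n) c(rnorm(n %/% 2), rnorm(n - n %/% 2, 6)))) {
    for (n in c(37, 200, 1000)) {
      x <- rdist(n)
      for (mass in c(0.5, 0.9, 0.95)) {
        expect_equal(unname(hdi(x, mass)), oracle_hdi(x, mass))
      }
    }
  }
  expect_error(hdi(1:5), "20")
  expect_error(hdi(1:100, 1.2), "mass")
})

test_that("HDI contains the required mass and no shorter window exists", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(25:400, 1)
    x <- rgamma(n, shape = 2)
    mass <- runif(1, 0.5, 0.99)
    ci <- hdi(x, mass)
    m <- ceiling(mass * n)
    expect_gte(sum(x >= ci[1] & x <= ci[2]), m)
    xs <- sort(x)
    widths <- xs[m:n] - xs[1:(n - m + 1)]
    expect_equal(unname(ci[2] - ci[1]), min(widths))
  }
})

test_that("posterior mode tracks the dominant density peak", {
  set.seed(4)
  tight <- rnorm(500, 2, 1e-6)
  expect_equal(posterior_mode(tight), 2, tolerance = 1e-3)
  bimix <- c(rnorm(8000, 0, 0.1), rnorm(2000, 5, 0.1))
  m <- posterior_mode(bimix)
  expect_lt(abs(m), 0.3)   # near the dominant component, not near 5
  x <- rlnorm(5000)
  expect_true(posterior_mode(x) >= min(x) && posterior_mode(x) <= max(x))
})

test_that("proportion above zero uses a strict inequality", {
  expect_equal(prop_above_zero(c(-1, 1)), 0.5)
  expect_equal(prop_above_zero(c(2, 0.1, 5)), 1)
  expect_equal(prop_above_zero(c(-2, -1, 0, 1, 2, 3)), 0.5)
  expect_error(prop_above_zero(numeric(0)), "samples")
})

test_that("summary table reproduces the mode/HDI/prop-above-zero layout", {
  set.seed(9)
  draws <- list(effect = rnorm(100000), shifted = rnorm(1000, 3, 1e-8))
  tab <- summarize_draws(draws)
  expect_equal(names(tab), c("parameter", "hdi_lower", "mode", "hdi_upper",
                             "prop_above_0"))
  expect_equal(nrow(tab), 2)
  r1 <- tab[tab$parameter == "effect", ]
  expect_equal(r1$prop_above_0, 0.5, tolerance = 0.02)
  expect_equal(r1$mode, 0, tolerance = 0.06)
  expect_equal(r1$hdi_lower, -1.96, tolerance = 0.05)
  expect_equal(r1$hdi_upper, 1.96, tolerance = 0.05)
  r2 <- tab[tab$parameter == "shifted", ]
  expect_equal(unlist(r2[, 2:5]), c(3, 3, 3, 1), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_true(all(tab$hdi_lower <= tab$mode & tab$mode <= tab$hdi_upper))
})

test_that("benefit direction probabilities are complementary", {
  set.seed(13)
  b <- rnorm(5000, 0.3)
  expect_equal(prop_above_zero(b) + prop_above_zero(-b), 1)  # no exact zeros
  b0 <- c(b, rep(0, 100))
  expect_lte(prop_above_zero(b0) + prop_above_zero(-b0), 1)
})
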