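# Independent brute-force oracles and tiny fixture builders. The
# oracles deliberately avoid the package's own code paths: plain
# linear-space summation, exhaustive window search, direct enumeration.

# Marginal likelihood of one species at one site by direct summation in
# probability space (no log-sum-exp, no shared helpers).
oracle_loglik <- function(y, psi, lambda, p, N_max = 200) {
  p <- rep_len(p, length(y))
  s <- 0
  for (n in max(y):N_max) {
    term <- dpois(n, lambda)
    for (k in seq_along(y)) term <- term * dbinom(y[k], n, p[k])
    s <- s + term
  }
  log((1 - psi) * as.numeric(all(y == 0)) + psi * s)
}

# P(w = 1 | y = 0) by the same direct summation.
oracle_inclusion_zero <- function(psi, lambda, p, N_max = 200) {
  p <- rep_len(p, length(p))
  s <- 0
  for (n in 0:N_max) s <- s + dpois(n, lambda) * prod((1 - p)^n)
  psi * s / (psi * s + (1 - psi))
}

# Shortest contiguous order-statistic window by exhaustive search,
# ties broken toward the smallest lower endpoint.
oracle_hdi <- function(x, mass = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in 1:(n - m + 1)) {
    if ((x[i + m - 1] - x[i]) < (best[2] - best[1])) {
      best <- c(x[i], x[i + m - 1])
    }
  }
  best
}

# Exact posterior over N for a single species x site cell with fixed
# (psi, lambda, p) and truncated support 0..N_max.
enum_N_posterior <- function(y, psi, lambda, p, N_max) {
  p <- rep_len(p, length(y))
  post <- sapply(0:N_max, function(n) {
    if (n == 0) {
      as.numeric(all(y == 0)) * ((1 - psi) + psi * dpois(0, lambda))
    } else {
      psi * dpois(n, lambda) * prod(dbinom(y, n, p))
    }
  })
  post / sum(post)
}

# Minimal hand-built design: n_sites sites in one block, constant
# covariates (so the standardized area/DATE/TSR are all zero and
# lambda, p reduce to the intercept terms).
toy_design <- function(n_sites = 1, n_visits = 2, treated = rep(0, n_sites),
                       origin = rep("grass", n_sites)) {
  sites <- data.frame(
    site_id = sprintf("S%02d", seq_len(n_sites)),
    block_id = "B1", origin = origin, treated = treated,
    site_area_ha = 1, patch_area_ha = 1, weed_contrast_eligible = 1)
  visits <- data.frame(
    site_id = rep(sites$site_id, each = n_visits),
    visit = rep(seq_len(n_visits), n_sites),
    date_days = 0, minutes_since_sunrise = 0)
  make_design(sites, visits)
}

# One-row species_params with all coefficients zero except as given.
toy_params <- function(species_id = "SP1", urban_class = "sensitive",
                       psi = 1, ...) {
  out <- data.frame(species_id = species_id, urban_class = urban_class,
                    psi = psi, u1 = 0, u2 = 0, o1 = 0, o2 = 0, a1 = 0,
                    a2 = 0, a3 = 0, a4 = 0, v1 = 0, b1 = 0, b2 = 0,
                    b3 = 0, b4 = 0)
  dots <- list(...)
  for (nm in names(dots)) out[[nm]] <- dots[[nm]]
  out
}

# Count array with dimnames from a matrix/vector of per-visit counts.
toy_y <- function(counts, species = "SP1", sites = "S01") {
  K <- length(counts) / (length(species) * length(sites))
  array(as.integer(counts), c(length(species), length(sites), K),
        dimnames = list(species, sites, NULL))
}
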