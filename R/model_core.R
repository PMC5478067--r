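# Probability kernel of the hierarchical community ZIP N-mixture model.
#
# A species i at site j is "included" with probability psi_i
# (w_ij ~ Bernoulli); given inclusion its latent abundance is
# N_ij ~ Poisson(lambda_ij) with log-linear covariate structure, and each
# of K repeat visits yields y_ijk ~ Binomial(N_ij, p_ijk) with logit-linear
# detection. These functions are the single source of truth for every
# density term used by both the sampler and the synthetic-data generator.

# Coefficient layout shared across the package: 8 abundance terms then 5
# detection terms, in the order they enter the linear predictors.
ABUND_COEFS <- c("u1", "u2", "o1", "o2", "a1", "a2", "a3", "a4")
DETECT_COEFS <- c("v1", "b1", "b2", "b3", "b4")
COEF_NAMES <- c(ABUND_COEFS, DETECT_COEFS)
URBAN_CLASSES <- c("sensitive", "adaptable", "exploitative")

# Detection probabilities are kept strictly inside (0,1) so log terms
# never produce -Inf through rounding of the inverse logit.
P_EPS <- 1e-12

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
}

coef_get <- function(params, name) {
  v <- params[[name]]
  if (is.null(v)) stop(sprintf("missing coefficient '%s'", name), call. = FALSE)
  as.numeric(v)
}

#' Log expected abundance for one species at one or more sites
#'
#' Evaluates the log-linear abundance predictor
#' \deqn{\log\lambda = u_1 TRT + u_2(1-TRT) + o_1 ORI + o_2(1-ORI) +
#'   a_1\,\mathrm{area} + a_2\,\mathrm{area}\cdot TRT + a_3 TRT\cdot ORI +
#'   a_4 TRT(1-ORI)}
#' where `TRT` is 1 for treated (revegetated or weed-controlled) sites,
#' `ORI` is 1 for forest-origin sites, and `area` is the standardized log
#' patch area. There is no global intercept: `u1`/`u2` act as the treated
#' and untreated intercepts.
#'
#' @param params species coefficients: a named list or one-row data frame
#'   with elements `u1, u2, o1, o2, a1, a2, a3, a4` (extra elements are
#'   ignored).
#' @param site site covariates: named list or data frame with `TRT`
#'   (0/1), `ORI` (0/1) and `area`; may contain several rows, in which
#'   case a vector is returned.
#' @return numeric vector of log expected abundances; `exp()` of it is
#'   the Poisson rate \eqn{\lambda}.
#' @examples
#' p <- list(u1 = 0.5, u2 = 0, o1 = 0.3, o2 = 0, a1 = 0.1, a2 = 0.2,
#'           a3 = 0.4, a4 = 0)
#' compute_log_lambda(p, list(TRT = 1, ORI = 1, area = 2))  # 1.8
#' @export
compute_log_lambda <- function(params, site) {
  trt <- as.numeric(site$TRT)
  ori <- as.numeric(site$ORI)
  area <- as.numeric(site$area)
  if (!all(trt %in% c(0, 1))) stop("TRT must be 0 or 1", call. = FALSE)
  if (!all(ori %in% c(0, 1))) stop("ORI must be 0 or 1", call. = FALSE)
  check_finite(area, "site area")
  b <- vapply(ABUND_COEFS, function(nm) coef_get(params, nm), numeric(1))
  check_finite(b, "abundance coefficients")
  b[["u1"]] * trt + b[["u2"]] * (1 - trt) +
    b[["o1"]] * ori + b[["o2"]] * (1 - ori) +
    b[["a1"]] * area + b[["a2"]] * area * trt +
    b[["a3"]] * trt * ori + b[["a4"]] * trt * (1 - ori)
}

#' Per-visit detection probability for one species
#'
#' Inverse-logit of `v1 + b1 DATE + b2 DATE^2 + b3 TSR + b4 TSR^2`, where
#' `DATE` is the standardized day-of-season and `TSR` the standardized
#' minutes since sunrise of the visit. The result is clamped to stay
#' strictly inside (0, 1).
#'
#' @param params species coefficients with elements `v1, b1, b2, b3, b4`.
#' @param visit visit covariates with `DATE` and `TSR`; vectorized over
#'   rows.
#' @return detection probabilities in (0, 1).
#' @export
compute_detection_prob <- function(params, visit) {
  date <- as.numeric(visit$DATE)
  tsr <- as.numeric(visit$TSR)
  check_finite(c(date, tsr), "visit covariates")
  b <- vapply(DETECT_COEFS, function(nm) coef_get(params, nm), numeric(1))
  check_finite(b, "detection coefficients")
  eta <- b[["v1"]] + b[["b1"]] * date + b[["b2"]] * date^2 +
    b[["b3"]] * tsr + b[["b4"]] * tsr^2
  pmin(pmax(stats::plogis(eta), P_EPS), 1 - P_EPS)
}

#' Marginal log-likelihood of one species at one site
#'
#' Log of
#' \deqn{(1-\psi)\,1\{\text{all } y = 0\} + \psi \sum_{N=\max y}^{N_{max}}
#'   \mathrm{Pois}(N;\lambda) \prod_k \mathrm{Bin}(y_k; N, p_k),}
#' i.e. the likelihood of the K visit counts with the inclusion indicator
#' and latent abundance summed out. The sum truncates the Poisson tail at
#' `N_max`; the invariant tests check insensitivity to the truncation
#' point once the tail mass is negligible. All accumulation is in log
#' space via log-sum-exp; pmfs come from `dpois`/`dbinom` with
#' `log = TRUE` (log-gamma based, no factorials).
#'
#' @param y_visits integer vector of counts, one per visit.
#' @param psi inclusion probability in \[0, 1\].
#' @param log_lambda log Poisson rate (finite).
#' @param p_visits per-visit detection probabilities in (0, 1); length 1
#'   is recycled.
#' @param N_max truncation bound for the latent-abundance sum; must be
#'   at least `max(y_visits)`.
#' @return the marginal log-likelihood (may be `-Inf`, e.g. a positive
#'   count with `psi = 0`).
#' @export
site_species_loglik <- function(y_visits, psi, log_lambda, p_visits, N_max) {
  y <- as.numeric(y_visits)
  if (length(y) == 0 || any(y < 0) || any(y != floor(y))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (length(psi) != 1 || !is.finite(psi) || psi < 0 || psi > 1) {
    stop("psi must be a single probability in [0, 1]", call. = FALSE)
  }
  check_finite(log_lambda, "log_lambda")
  p <- rep_len(as.numeric(p_visits), length(y))
  if (any(p <= 0) || any(p >= 1)) stop("detection probabilities must lie in (0, 1)", call. = FALSE)
  if (N_max < max(y)) stop("N_max smaller than the largest observed count", call. = FALSE)

  Ns <- seq.int(max(y), N_max)
  lw <- stats::dpois(Ns, exp(log_lambda), log = TRUE)
  for (k in seq_along(y)) {
    lw <- lw + stats::dbinom(y[k], Ns, p[k], log = TRUE)
  }
  lp_w1 <- logsumexp(lw)  # log P(y | w = 1)
  if (all(y == 0)) {
    if (psi == 0) return(0)
    if (psi == 1) return(lp_w1)
    logsumexp(c(log1p(-psi), log(psi) + lp_w1))
  } else {
    if (psi == 0) return(-Inf)
    log(psi) + lp_w1
  }
}

#' Posterior inclusion probability for one species at one site
#'
#' `P(w = 1 | y, psi, lambda, p)` under the same truncated latent-N sum as
#' [site_species_loglik()]. Any positive count proves presence, so the
#' result is exactly 1 whenever `any(y > 0)`.
#'
#' @inheritParams site_species_loglik
#' @param lambda Poisson rate (positive).
#' @param N_max truncation bound; defaults to `max(100, 10 * max(y))`.
#' @return probability in \[0, 1\].
#' @export
conditional_inclusion_prob <- function(y_visits, psi, lambda, p_visits,
                                       N_max = max(100, 10 * max(y_visits))) {
  y <- as.numeric(y_visits)
  if (length(psi) != 1 || !is.finite(psi) || psi < 0 || psi > 1) {
    stop("psi must be a single probability in [0, 1]", call. = FALSE)
  }
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be non-negative and finite", call. = FALSE)
  if (any(y > 0)) {
    if (psi == 0) stop("positive count observed but psi = 0", call. = FALSE)
    return(1)
  }
  if (psi == 0) return(0)
  if (psi == 1) return(1)
  p <- rep_len(as.numeric(p_visits), length(y))
  if (any(p <= 0) || any(p >= 1)) stop("detection probabilities must lie in (0, 1)", call. = FALSE)
  # P(all zero | w = 1) = sum_{N=0}^{Nmax} Pois(N; lambda) prod_k (1-p_k)^N
  #                     = exp(lambda (q - 1)) * ppois(Nmax, lambda q), q = prod(1-p)
  q <- prod(1 - p)
  lp_zero_w1 <- lambda * (q - 1) + stats::ppois(N_max, lambda * q, log.p = TRUE)
  lnum <- log(psi) + lp_zero_w1
  lden <- logsumexp(c(lnum, log1p(-psi)))
  exp(lnum - lden)
}
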