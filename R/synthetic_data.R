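# Synthetic survey generator. Emulates the blocked urban-restoration
# study design: blocks each holding the four site types
# (grass/untreated = open mowed turf, grass/treated = revegetated,
# forest/untreated = weedy, forest/treated = weed-controlled), three
# early-morning visits per site in one breeding season, and a subset of
# blocks whose forest pair fails the weed-cover criteria and is flagged
# out of the weed contrast. Counts are generated from exactly the model
# the sampler fits, and the latent truth is retained for recovery tests.

#' Specification of a synthetic survey design
#'
#' Defaults mirror the motivating study: 19 blocks of four site types
#' (76 sites; the realized field design had 70 because three blocks'
#' forest pairs failed the weed-cover criteria — reproduced here by the
#' `weed_block_dropout` eligibility flag rather than by deleting sites),
#' three visits per site over a 150-day season within a 210-minute
#' post-sunrise window, site areas 0.5-2.5 ha with at most 0.5 ha spread
#' within a block.
#'
#' @param n_blocks number of blocks, each contributing all four site
#'   types.
#' @param n_visits repeat visits per site (>= 2).
#' @param area_range range of site areas in hectares.
#' @param within_block_area_jitter maximum area spread among sites of
#'   one block, hectares.
#' @param weed_block_dropout number of blocks whose forest sites are
#'   flagged ineligible for the weed-control contrast.
#' @param season_days length of the survey season in days.
#' @param tsr_max survey window length in minutes after sunrise.
#' @return a `design_spec` list.
#' @export
design_spec <- function(n_blocks = 19, n_visits = 3,
                        area_range = c(0.5, 2.5),
                        within_block_area_jitter = 0.5,
                        weed_block_dropout = min(3, n_blocks),
                        season_days = 150, tsr_max = 210) {
  stopifnot(n_blocks >= 1, n_visits >= 2,
            length(area_range) == 2, area_range[1] > 0,
            diff(area_range) > within_block_area_jitter,
            weed_block_dropout >= 0, weed_block_dropout <= n_blocks,
            season_days > 0, tsr_max > 0)
  structure(list(n_blocks = n_blocks, n_visits = n_visits,
                 area_range = area_range,
                 within_block_area_jitter = within_block_area_jitter,
                 weed_block_dropout = weed_block_dropout,
                 season_days = season_days, tsr_max = tsr_max),
            class = "design_spec")
}

#' Generate a blocked four-treatment survey design
#'
#' @param spec a [design_spec()].
#' @param seed integer seed; the same seed reproduces the design
#'   bit-identically.
#' @return a [make_design()] `survey_design` with `4 * n_blocks` sites.
#' @export
generate_design <- function(spec = design_spec(), seed = 1) {
  stopifnot(inherits(spec, "design_spec"))
  set.seed(seed)
  nb <- spec$n_blocks
  half_j <- spec$within_block_area_jitter / 2
  base <- stats::runif(nb, spec$area_range[1] + half_j, spec$area_range[2] - half_j)
  types <- data.frame(code = c("GU", "GT", "FU", "FT"),
                      origin = c("grass", "grass", "forest", "forest"),
                      treated = c(0L, 1L, 0L, 1L))
  sites <- do.call(rbind, lapply(seq_len(nb), function(b) {
    data.frame(site_id = sprintf("B%02d_%s", b, types$code),
               block_id = sprintf("B%02d", b),
               origin = types$origin, treated = types$treated,
               site_area_ha = base[b] + stats::runif(4, -half_j, half_j))
  }))
  # enclosing green patch is at least the site itself
  sites$patch_area_ha <- sites$site_area_ha * stats::runif(nrow(sites), 1, 4)
  drop_blocks <- if (spec$weed_block_dropout > 0) {
    sprintf("B%02d", sort(sample.int(nb, spec$weed_block_dropout)))
  } else character(0)
  sites$weed_contrast_eligible <-
    as.integer(!(sites$origin == "forest" & sites$block_id %in% drop_blocks))
  J <- nrow(sites)
  visits <- data.frame(
    site_id = rep(sites$site_id, each = spec$n_visits),
    visit = rep(seq_len(spec$n_visits), J),
    date_days = stats::runif(J * spec$n_visits, 0, spec$season_days),
    minutes_since_sunrise = stats::runif(J * spec$n_visits, 0, spec$tsr_max))
  make_design(sites, visits)
}

#' Urban-class hyperparameter table
#'
#' Container for the class-level means and spreads from which
#' species-level coefficients are drawn: one (mu, sigma) pair per urban
#' class and per coefficient.
#'
#' @param mu,sigma numeric matrices, classes in rows (`sensitive`,
#'   `adaptable`, `exploitative`) and coefficients
#'   `u1,u2,o1,o2,a1,a2,a3,a4,v1,b1,b2,b3,b4` in columns; all sigmas
#'   strictly positive.
#' @return a `class_hyperparams` object.
#' @export
class_hyperparams <- function(mu, sigma) {
  mu <- as.matrix(mu); sigma <- as.matrix(sigma)
  stopifnot(identical(dim(mu), dim(sigma)))
  if (is.null(rownames(mu))) rownames(mu) <- URBAN_CLASSES[seq_len(nrow(mu))]
  if (is.null(colnames(mu))) colnames(mu) <- COEF_NAMES
  dimnames(sigma) <- dimnames(mu)
  stopifnot(all(COEF_NAMES %in% colnames(mu)),
            all(is.finite(mu)), all(is.finite(sigma)), all(sigma > 0))
  structure(list(mu = mu[, COEF_NAMES, drop = FALSE],
                 sigma = sigma[, COEF_NAMES, drop = FALSE]),
            class = "class_hyperparams")
}

#' Default generating hyperparameters for the synthetic community
#'
#' The reference community used throughout the package's simulations:
#' exploiters most abundant overall, sensitive species scarcer and
#' forest-associated, exploiters grass-associated; revegetation
#' (treatment on grass origin, `a4`) benefits every class, weed control
#' (treatment on forest origin, `a3`) benefits exploiters and harms
#' adaptable/sensitive species; a mild patch-area effect, no
#' area-by-treatment confounding; detection just below 0.4 at the mean
#' survey conditions with shallow date and time-of-morning curvature.
#' Between-species spread is 0.5 on every coefficient.
#'
#' @return a [class_hyperparams()] object.
#' @export
default_class_hyperparams <- function() {
  mu <- rbind(
    sensitive    = c(u1 = -0.7, u2 = -0.7, o1 = 0.5, o2 = -0.5, a1 = 0.1,
                     a2 = 0, a3 = -0.3, a4 = 0.4, v1 = -0.5, b1 = 0.1,
                     b2 = -0.1, b3 = -0.2, b4 = -0.1),
    adaptable    = c(u1 = 0.0, u2 = 0.0, o1 = 0.0, o2 = 0.0, a1 = 0.1,
                     a2 = 0, a3 = -0.2, a4 = 0.7, v1 = -0.5, b1 = 0.1,
                     b2 = -0.1, b3 = -0.2, b4 = -0.1),
    exploitative = c(u1 = 0.5, u2 = 0.5, o1 = -0.2, o2 = 0.3, a1 = 0.1,
                     a2 = 0, a3 = 0.3, a4 = 0.5, v1 = -0.5, b1 = 0.1,
                     b2 = -0.1, b3 = -0.2, b4 = -0.1))
  sigma <- matrix(0.5, nrow = 3, ncol = length(COEF_NAMES),
                  dimnames = dimnames(mu))
  class_hyperparams(mu, sigma)
}

#' Species roster with urban-class labels
#'
#' Defaults to the observed community composition: 74 species of which
#' 29 urban sensitive, 21 urban adaptable and 24 urban exploitative.
#'
#' @param n_sensitive,n_adaptable,n_exploitative class sizes.
#' @return data frame with `species_id`, `common_name`, `urban_class`.
#' @export
default_roster <- function(n_sensitive = 29, n_adaptable = 21,
                           n_exploitative = 24) {
  n <- c(sensitive = n_sensitive, adaptable = n_adaptable,
         exploitative = n_exploitative)
  stopifnot(all(n >= 0), sum(n) > 0)
  cls <- rep(names(n), n)
  ids <- sprintf("SP%03d", seq_along(cls))
  data.frame(species_id = ids,
             common_name = sprintf("synthetic species %d", seq_along(cls)),
             urban_class = cls)
}

#' Draw species-level coefficients from class hyperparameters
#'
#' Each coefficient of species i is drawn Normal(mu_c, sigma_c) for its
#' urban class c; the inclusion probability psi_i is drawn from a Beta
#' distribution (uniform by default, matching the model's psi prior).
#'
#' @param hyper a [class_hyperparams()].
#' @param roster data frame with `species_id` and `urban_class`.
#' @param seed integer seed.
#' @param psi_beta length-2 shape parameters of the Beta draw for psi.
#' @return `species_params` data frame: `species_id`, `urban_class`,
#'   `psi`, and the 13 coefficients.
#' @export
draw_species_params <- function(hyper, roster, seed = 1, psi_beta = c(1, 1)) {
  stopifnot(inherits(hyper, "class_hyperparams"))
  roster <- normalize_roster(roster)
  if (nrow(roster) == 0) stop("empty species roster", call. = FALSE)
  if (!all(roster$urban_class %in% rownames(hyper$mu))) {
    stop("roster contains classes without hyperparameters", call. = FALSE)
  }
  set.seed(seed)
  I <- nrow(roster)
  mu <- hyper$mu[roster$urban_class, , drop = FALSE]
  sg <- hyper$sigma[roster$urban_class, , drop = FALSE]
  beta <- matrix(stats::rnorm(I * length(COEF_NAMES), mu, sg),
                 nrow = I, dimnames = list(roster$species_id, COEF_NAMES))
  psi <- stats::rbeta(I, psi_beta[1], psi_beta[2])
  cbind(data.frame(species_id = roster$species_id,
                   urban_class = roster$urban_class, psi = psi),
        as.data.frame(beta))
}

#' Simulate repeated count surveys from the generative model
#'
#' Draws, per species x site, the inclusion indicator
#' `w ~ Bernoulli(psi)`, latent abundance `N ~ Poisson(w * lambda)`, and
#' per-visit counts `y ~ Binomial(N, p)`; lambda and p follow the
#' package's log-linear abundance and logit detection predictors on the
#' design's standardized covariates.
#'
#' @param design a `survey_design`.
#' @param params a `species_params` data frame from
#'   [draw_species_params()] (or built by hand).
#' @param seed integer seed; with the design and params it reproduces
#'   the counts bit-identically.
#' @return a `truth_bundle`: `design`, `params`, `roster`, the count
#'   array `y` (species x site x visit), and the latent truth `w`, `N`,
#'   `lambda`, `p`.
#' @export
simulate_counts <- function(design, params, seed = 1) {
  stopifnot(inherits(design, "survey_design"))
  params <- as.data.frame(params)
  stopifnot(all(c("species_id", "urban_class", "psi", COEF_NAMES) %in% names(params)),
            all(params$psi >= 0 & params$psi <= 1))
  set.seed(seed)
  dm <- design_matrices(design)
  I <- nrow(params); J <- dm$J; K <- dm$K
  beta_a <- as.matrix(params[, ABUND_COEFS, drop = FALSE])
  beta_d <- as.matrix(params[, DETECT_COEFS, drop = FALSE])
  loglam <- beta_a %*% t(dm$Xa)                       # I x J
  p <- stats::plogis(beta_d %*% t(dm$Xd))             # I x (J*K), visit-major
  p <- pmin(pmax(p, P_EPS), 1 - P_EPS)
  w <- matrix(stats::rbinom(I * J, 1, rep(params$psi, J)), I, J)
  N <- matrix(stats::rpois(I * J, w * exp(loglam)), I, J)
  Nrep <- N[, rep(seq_len(J), each = K), drop = FALSE]
  yflat <- matrix(stats::rbinom(I * J * K, as.vector(Nrep), as.vector(p)), I, J * K)
  # yflat columns are visit-major within site; rebuild as an (i, j, k) array
  y <- array(0L, dim = c(I, J, K),
             dimnames = list(params$species_id, design$sites$site_id, NULL))
  for (k in seq_len(K)) y[, , k] <- yflat[, (seq_len(J) - 1L) * K + k]
  dimnames(N) <- dimnames(w) <- list(params$species_id, design$sites$site_id)
  structure(list(design = design,
                 params = params,
                 roster = params[, c("species_id", "urban_class")],
                 y = y, w = w, N = N,
                 lambda = exp(loglam), p = p, seed = seed),
            class = "truth_bundle")
}

#' @export
print.truth_bundle <- function(x, ...) {
  d <- dim(x$y)
  cat(sprintf("truth_bundle: %d species x %d sites x %d visits (seed %d)\n",
              d[1], d[2], d[3], x$seed))
  cat(sprintf("  occupied species-sites: %d/%d; total count %d\n",
              sum(x$w), length(x$w), sum(x$y)))
  invisible(x)
}

normalize_roster <- function(roster) {
  roster <- as.data.frame(roster)
  stopifnot(all(c("species_id", "urban_class") %in% names(roster)))
  roster$species_id <- as.character(roster$species_id)
  roster$urban_class <- tolower(as.character(roster$urban_class))
  bad <- setdiff(unique(roster$urban_class), URBAN_CLASSES)
  if (length(bad)) {
    stop("unknown urban class label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(roster$species_id)) stop("duplicate species_id in roster", call. = FALSE)
  roster
}
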