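# Derived posterior quantities and the reporting currency used
# throughout: per-class site species richness (N_ij >= 1), stratum mean
# richness, treated-minus-untreated richness benefit, and summaries as
# mode / 95% highest-density interval / proportion of draws above zero.

#' Per-site, per-class species richness for one latent-abundance draw
#'
#' Richness of urban class c at site j is the number of species of that
#' class with `N_ij >= 1`.
#'
#' @param N species x site integer matrix of latent abundances (species
#'   in rows, named).
#' @param roster data frame mapping `species_id` to `urban_class`; must
#'   cover every row of `N`.
#' @return site x class integer matrix.
#' @export
richness_per_iteration <- function(N, roster) {
  roster <- normalize_roster(roster)
  if (!all(rownames(N) %in% roster$species_id)) {
    stop("roster does not cover all species in N", call. = FALSE)
  }
  cls <- roster$urban_class[match(rownames(N), roster$species_id)]
  out <- sapply(URBAN_CLASSES, function(cc) {
    rows <- which(cls == cc)
    if (!length(rows)) return(integer(ncol(N)))
    colSums(N[rows, , drop = FALSE] >= 1)
  })
  rownames(out) <- colnames(N)
  out
}

#' Posterior draws of per-site, per-class richness from a fit
#'
#' @param fit a `zipnmix_fit` with retained latent `N` draws.
#' @return array draws x site x class, chains stacked in order; the
#'   chain of each draw is in `attr(, "chain")`.
#' @export
richness_draws <- function(fit) {
  roster <- fit$roster
  per_chain <- lapply(fit$chains, function(ch) {
    ns <- dim(ch$N)[1]
    out <- array(0L, c(ns, dim(ch$N)[3], length(URBAN_CLASSES)),
                 dimnames = list(NULL, dimnames(ch$N)[[3]], URBAN_CLASSES))
    for (s in seq_len(ns)) {
      out[s, , ] <- richness_per_iteration(ch$N[s, , ], roster)
    }
    out
  })
  res <- do.call(abind1, per_chain)
  attr(res, "chain") <- rep(seq_along(per_chain),
                            vapply(per_chain, function(a) dim(a)[1], integer(1)))
  res
}

# rbind for 3-d arrays along the first margin
abind1 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  out <- array(0L, c(sum(vapply(xs, function(a) dim(a)[1], integer(1))), d[2], d[3]),
               dimnames = c(list(NULL), dimnames(xs[[1]])[2:3]))
  at <- 0
  for (a in xs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

# Sites entering one stratum of a richness contrast. For forest origin
# the weed-contrast-ineligible sites are omitted from both strata.
stratum_sites <- function(design, origin, treated, contrast_only = TRUE) {
  s <- design$sites
  keep <- s$origin == origin & s$treated == treated
  if (contrast_only && origin == "forest") {
    keep <- keep & s$weed_contrast_eligible == 1
  }
  s$site_id[keep]
}

#' Posterior draws of stratum mean richness
#'
#' The mean over sites of one (origin, treatment) stratum of the
#' per-site richness of one urban class, per retained draw.
#'
#' @param rich richness draws from [richness_draws()] (or any draws x
#'   site x class array).
#' @param design the `survey_design`.
#' @param class urban class.
#' @param origin `"grass"` or `"forest"`.
#' @param treated 0 or 1.
#' @return numeric vector, one value per draw.
#' @export
stratum_mean_richness <- function(rich, design, class, origin, treated) {
  ids <- stratum_sites(design, origin, treated)
  if (!length(ids)) stop("empty stratum: ", origin, "/treated=", treated, call. = FALSE)
  rowMeans(rich[, ids, class, drop = FALSE], dims = 1)
}

#' Posterior distribution of the richness benefit of treatment
#'
#' Treated-minus-untreated stratum mean richness within one origin, per
#' draw: for grass origin this is the revegetation benefit, for forest
#' origin the weed-control benefit (computed over weed-contrast-eligible
#' sites only).
#'
#' @param rich richness draws ([richness_draws()] output) or a
#'   `zipnmix_fit`.
#' @inheritParams stratum_mean_richness
#' @return numeric vector of per-draw benefits.
#' @export
richness_benefit <- function(rich, design = NULL, class, origin) {
  if (inherits(rich, "zipnmix_fit")) {
    if (is.null(design)) design <- rich$design
    rich <- richness_draws(rich)
  }
  stratum_mean_richness(rich, design, class, origin, 1) -
    stratum_mean_richness(rich, design, class, origin, 0)
}

#' Highest density interval of a posterior sample
#'
#' The shortest contiguous window of order statistics containing
#' `ceiling(mass * n)` samples; ties are broken toward the smallest
#' lower endpoint. Computed on the empirical sample directly, with no
#' distributional assumption.
#'
#' @param samples numeric vector (>= 20 values).
#' @param mass interval mass in (0, 1); default 0.95.
#' @return named vector `c(lower, upper)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  x <- sort(as.numeric(samples))
  n <- length(x)
  if (n < 20) stop("at least 20 samples are required for an HDI", call. = FALSE)
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)", call. = FALSE)
  m <- ceiling(mass * n)
  lo <- seq_len(n - m + 1)
  widths <- x[lo + m - 1] - x[lo]
  i <- which.min(widths)  # first minimum = smallest lower endpoint
  c(lower = x[i], upper = x[i + m - 1])
}

#' Posterior mode of a continuous sample
#'
#' Argmax of a Gaussian kernel density estimate (Silverman's
#' rule-of-thumb bandwidth) evaluated on a 512-point grid spanning the
#' sample range. Degenerate (near-constant) samples return their median.
#'
#' @param samples numeric vector (>= 20 values).
#' @return the estimated mode, always within `range(samples)`.
#' @export
posterior_mode <- function(samples) {
  x <- as.numeric(samples)
  if (length(x) < 20) stop("at least 20 samples are required", call. = FALSE)
  if (diff(range(x)) < .Machine$double.eps^0.5) return(stats::median(x))
  d <- stats::density(x, bw = "nrd0", n = 512, from = min(x), to = max(x))
  d$x[which.max(d$y)]
}

#' Proportion of a posterior sample strictly above zero
#'
#' Used as the posterior probability that an effect is positive; draws
#' exactly at zero count as not above.
#'
#' @param samples numeric vector (>= 1 value).
#' @return fraction in \[0, 1\].
#' @export
prop_above_zero <- function(samples) {
  x <- as.numeric(samples)
  if (!length(x)) stop("no samples", call. = FALSE)
  mean(x > 0)
}

#' Summary table in the mode / HDI / proportion-above-zero currency
#'
#' @param draws a named list of numeric draw vectors, or a matrix /
#'   data frame with one column per parameter.
#' @param mass HDI mass.
#' @return data frame with columns `parameter`, `hdi_lower`, `mode`,
#'   `hdi_upper`, `prop_above_0` — one row per parameter.
#' @export
summarize_draws <- function(draws, mass = 0.95) {
  if (is.matrix(draws) || is.data.frame(draws)) {
    draws <- as.list(as.data.frame(draws))
  }
  stopifnot(is.list(draws), length(names(draws)) == length(draws))
  rows <- lapply(names(draws), function(nm) {
    x <- as.numeric(draws[[nm]])
    ci <- hdi(x, mass)
    data.frame(parameter = nm, hdi_lower = ci[["lower"]],
               mode = posterior_mode(x), hdi_upper = ci[["upper"]],
               prop_above_0 = prop_above_zero(x))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hyperparameter summary table for a fitted model
#'
#' One row per class-level mean hyperparameter (all chains pooled), in
#' the same currency as [summarize_draws()].
#'
#' @param fit a `zipnmix_fit`.
#' @param coefs coefficients to include (default: the four
#'   area/treatment interaction terms `a1..a4`, the effects of primary
#'   ecological interest).
#' @param stat `"mu"` (class means, default) or `"sigma"`.
#' @param mass HDI mass.
#' @return data frame as from [summarize_draws()], parameters named
#'   `mu_<coef>_<class>`.
#' @export
summarize_hyperparams <- function(fit, coefs = c("a1", "a2", "a3", "a4"),
                                  stat = c("mu", "sigma"), mass = 0.95) {
  stat <- match.arg(stat)
  stopifnot(all(coefs %in% COEF_NAMES))
  draws <- list()
  for (cf in coefs) {
    for (cc in URBAN_CLASSES) {
      draws[[sprintf("%s_%s_%s", stat, cf, cc)]] <-
        as.vector(hyper_draws(fit, stat, cc, cf))
    }
  }
  summarize_draws(draws, mass)
}
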