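# Metropolis-within-Gibbs sampler for the hierarchical community ZIP
# N-mixture model. Update blocks per iteration:
#   (a) inclusion w_ij | rest: exact Bernoulli with latent N marginalized
#       (closed form for all-zero cells under the same N_max truncation
#       as the likelihood functions);
#   (b) latent N_ij | w, rest: exact draw — truncated Poisson(lambda q)
#       for all-zero cells (conjugate thinning identity), categorical on
#       max(y)..N_max via precomputed log-gamma tables and the
#       Gumbel-max trick for cells with positive counts;
#   (c) species coefficients: single-coordinate random-walk Metropolis,
#       vectorized across species, with Robbins-Monro scale adaptation
#       during burn-in only;
#   (d) class means mu: conjugate normal draw;
#   (e) class spreads sigma: random-walk Metropolis on log sigma under
#       the Gamma prior (Jacobian included);
#   (f) psi_i: conjugate Beta draw given w.

#' MCMC configuration
#'
#' @param n_chains number of chains (>= 2; convergence diagnostics need
#'   at least two).
#' @param n_iter total iterations per chain.
#' @param n_burnin burn-in iterations discarded (adaptation happens only
#'   here); must be < `n_iter`.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer master seed; per-chain streams are derived from
#'   it deterministically.
#' @param N_max truncation bound for latent abundance; default
#'   `max(100, 10 * max(y))`, resolved at fit time.
#' @param mu_prior_sd sd of the vague Normal(0, sd) prior on class means.
#' @param sigma_prior_shape,sigma_prior_rate Gamma prior on the class
#'   standard deviations.
#' @param psi_prior length-2 Beta prior on the inclusion probabilities.
#' @param update_species,update_hyper,update_psi switch individual
#'   update blocks off to sample latent states conditional on fixed
#'   parameters (used by exactness checks).
#' @param target_accept Metropolis acceptance target for adaptation.
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 10000, n_burnin = 2000,
                        thin = 5, seed = 1, N_max = NULL,
                        mu_prior_sd = 10,
                        sigma_prior_shape = 0.1, sigma_prior_rate = 0.1,
                        psi_prior = c(1, 1),
                        update_species = TRUE, update_hyper = TRUE,
                        update_psi = TRUE, target_accept = 0.44) {
  if (n_chains < 2) stop("at least 2 chains are required for convergence diagnostics", call. = FALSE)
  if (n_iter <= n_burnin) stop("n_iter must exceed n_burnin", call. = FALSE)
  stopifnot(thin >= 1, mu_prior_sd > 0, sigma_prior_shape > 0,
            sigma_prior_rate > 0, length(psi_prior) == 2, all(psi_prior > 0),
            target_accept > 0, target_accept < 1)
  structure(as.list(environment()), class = "mcmc_config")
}

# Likelihood-invariant directions of the abundance predictor (see the
# (c') block in run_chain): named coefficient weights.
RIDGE_DIRS <- list(c(u1 = 1, a3 = -1, a4 = -1),
                   c(u1 = -1, u2 = -1, o1 = 1, o2 = 1))

# Spread hyperparameters are sampled on sigma >= SIGMA_MIN: the Gamma
# shape-0.1 prior is integrable but unbounded at zero, and spreads below
# this bound are observationally identical to zero while breaking the
# conditioning of the collapsed moves.
SIGMA_MIN <- 1e-12

# Numerically stable log(1 + exp(x)), so detection log-probabilities
# log p = -softplus(-eta) and log(1-p) = -softplus(eta) never hit -Inf.
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# Closed-form conjugate moments for a class mean given its species
# coefficients: x_i ~ N(mu, sigma), mu ~ N(0, prior_sd).
conj_mu_moments <- function(sum_x, n, sigma, prior_sd) {
  prec <- n / sigma^2 + 1 / prior_sd^2
  list(mean = (sum_x / sigma^2) / prec, sd = sqrt(1 / prec))
}

#' Fit the hierarchical community model by MCMC
#'
#' @param y count array (species x site x visit) or a `truth_bundle`
#'   (in which case `design` and `roster` default to its own).
#' @param design a `survey_design`.
#' @param roster data frame assigning every species of `y` to exactly
#'   one urban class.
#' @param config an [mcmc_config()].
#' @param fixed_params optional `species_params` data frame used to
#'   initialize species coefficients and psi; with the corresponding
#'   `update_*` switches off these are held fixed, so the chain samples
#'   the latent states (w, N) conditional on them.
#' @return a `zipnmix_fit`: per-chain arrays of retained draws of the
#'   class hyperparameters (`mu`, `sigma`), species coefficients
#'   (`beta`), `psi` and latent `N`, plus the configuration, acceptance
#'   rates and data references.
#' @export
fit_model <- function(y, design = NULL, roster = NULL,
                      config = mcmc_config(), fixed_params = NULL) {
  if (inherits(y, "truth_bundle")) {
    if (is.null(design)) design <- y$design
    if (is.null(roster)) roster <- y$roster
    y <- y$y
  }
  stopifnot(inherits(design, "survey_design"), inherits(config, "mcmc_config"))
  roster <- normalize_roster(roster)
  dn <- dimnames(y)
  if (is.null(dn) || is.null(dn[[1]])) stop("y must carry species dimnames", call. = FALSE)
  if (!setequal(dn[[1]], roster$species_id)) {
    stop("every species in y must be assigned exactly one urban class", call. = FALSE)
  }
  roster <- roster[match(dn[[1]], roster$species_id), , drop = FALSE]
  I <- dim(y)[1]; J <- dim(y)[2]; K <- dim(y)[3]
  if (J != design$J || K != design$K) stop("count array does not match the design", call. = FALSE)
  if (any(y < 0) || any(y != floor(y))) stop("counts must be non-negative integers", call. = FALSE)

  N_max <- if (is.null(config$N_max)) max(100, 10 * max(y)) else config$N_max
  if (N_max < max(y)) stop("N_max smaller than the largest observed count", call. = FALSE)

  dm <- design_matrices(design)
  JK <- J * K
  ymat <- matrix(0, I, JK)            # site-major visit layout
  for (k in seq_len(K)) ymat[, (seq_len(J) - 1L) * K + k] <- y[, , k]
  site_of_col <- rep(seq_len(J), each = K)
  Ssum <- matrix(0, JK, J); Ssum[cbind(seq_len(JK), site_of_col)] <- 1
  maxy <- apply(y, c(1, 2), max)
  idx_nz <- which(maxy > 0)           # cells with a positive count: w == 1
  idx_z <- which(maxy == 0)
  cls <- factor(roster$urban_class, levels = URBAN_CLASSES)
  cls_idx <- as.integer(cls)
  n_class <- tabulate(cls_idx, length(URBAN_CLASSES))

  # log-gamma tables for the categorical N draw at positive-count cells:
  # log w(N) = N * (log lambda + sum_k log(1-p_k)) + (K-1) lgamma(N+1)
  #            - sum_k lgamma(N - y_k + 1) + const(y, p)
  Ngrid <- 0:N_max
  lgf <- lgamma(Ngrid + 1)            # lgf[n + 1] = log n!
  m_nz <- length(idx_nz)
  Cmat <- NULL
  if (m_nz > 0) {
    Cmat <- matrix(-Inf, m_nz, N_max + 1)
    ij <- arrayInd(idx_nz, dim(maxy))
    for (r in seq_len(m_nz)) {
      yk <- y[ij[r, 1], ij[r, 2], ]
      lo <- max(yk)
      Ns <- lo:N_max
      v <- (K - 1) * lgf[Ns + 1]
      for (k in seq_len(K)) v <- v - lgf[Ns - yk[k] + 1]
      Cmat[r, Ns + 1] <- v
    }
  }

  CmatT <- if (is.null(Cmat)) NULL else t(Cmat)   # support-major for the C++ draw

  chains <- vector("list", config$n_chains)
  acc_list <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    chain_seed <- (config$seed %% 1000003L) * 2017L + ch * 7919L
    res <- run_chain(chain_seed, ymat, maxy, idx_nz, idx_z, CmatT, Ngrid,
                     dm, Ssum, site_of_col, cls_idx, n_class, roster,
                     I, J, K, N_max, config, fixed_params)
    chains[[ch]] <- res$draws
    acc_list[[ch]] <- res$acceptance
  }
  structure(list(chains = chains, config = config, N_max = N_max,
                 roster = roster, design = design, y = y,
                 acceptance = acc_list),
            class = "zipnmix_fit")
}

run_chain <- function(chain_seed, ymat, maxy, idx_nz, idx_z, CmatT, Ngrid,
                      dm, Ssum, site_of_col, cls_idx, n_class, roster,
                      I, J, K, N_max, config, fixed_params) {
  set.seed(chain_seed)
  Xa <- dm$Xa; Xd <- dm$Xd
  JK <- J * K
  nC <- length(URBAN_CLASSES); nP <- length(COEF_NAMES)

  # ---- initialization (overdispersed across chains unless fixed) ----
  if (!is.null(fixed_params)) {
    fp <- as.data.frame(fixed_params)
    fp <- fp[match(roster$species_id, fp$species_id), , drop = FALSE]
    beta <- as.matrix(fp[, COEF_NAMES, drop = FALSE])
    psi <- pmin(pmax(fp$psi, 0), 1)
    mu <- matrix(0, nC, nP, dimnames = list(URBAN_CLASSES, COEF_NAMES))
    sigma <- matrix(1, nC, nP, dimnames = list(URBAN_CLASSES, COEF_NAMES))
    for (c in seq_len(nC)) {
      if (n_class[c] > 0) {
        mu[c, ] <- colMeans(beta[cls_idx == c, , drop = FALSE])
      }
    }
  } else {
    mu <- matrix(stats::rnorm(nC * nP, 0, 1), nC, nP,
                 dimnames = list(URBAN_CLASSES, COEF_NAMES))
    sigma <- matrix(stats::runif(nC * nP, 0.5, 2), nC, nP,
                    dimnames = list(URBAN_CLASSES, COEF_NAMES))
    beta <- mu[cls_idx, , drop = FALSE] +
      matrix(stats::rnorm(I * nP), I, nP) * sigma[cls_idx, , drop = FALSE]
    rownames(beta) <- roster$species_id
    psi <- stats::runif(I, 0.2, 0.9)
  }
  w <- (maxy > 0) + 0
  if (length(idx_z)) w[idx_z] <- stats::rbinom(length(idx_z), 1, 0.5)
  if (any(psi == 1)) w[psi == 1, ] <- 1
  if (any(psi == 0)) {
    r0 <- which(psi == 0)
    w[r0, ] <- (maxy[r0, , drop = FALSE] > 0) + 0
  }
  N <- w * maxy

  loglam <- beta[, ABUND_COEFS, drop = FALSE] %*% t(Xa)   # I x J
  lam <- exp(pmin(loglam, 300))
  eta <- beta[, DETECT_COEFS, drop = FALSE] %*% t(Xd)     # I x JK
  # detection enters every term through sp = softplus(eta):
  # log p = eta - sp, log(1-p) = -sp, and the binomial log-likelihood
  # row-sums reduce to sum_k (y * eta - N * sp)
  sp <- softplus(eta)

  ls_beta <- matrix(log(0.3), I, nP)      # log proposal scales
  ls_sigma <- matrix(log(0.5), nC, nP)
  ls_signc <- matrix(log(0.3), nC, nP)    # non-centered sigma interweave
  ls_ray <- rep(log(0.3), I)              # abundance-detection trade-off move
  ls_rayc <- rep(log(0.3), nC)            # same trade-off at class level
  ls_alloc <- rep(log(0.15), nC)          # collapsed allocation move scale
  acc_signc <- matrix(0, nC, nP); acc_ray <- numeric(I); acc_rayc <- numeric(nC)
  acc_alloc <- numeric(nC)
  # ray geometry for the collapsed sigma-allocation move: the six
  # abundance coefficients touched by the two invariant rays, and the
  # ray basis restricted to them
  ray_cols <- match(c("u1", "u2", "o1", "o2", "a3", "a4"), COEF_NAMES)
  Bray <- cbind(c(1, 0, 0, 0, -1, -1), c(-1, -1, 1, 1, 0, 0))
  acc_beta <- matrix(0, I, nP); acc_sigma <- matrix(0, nC, nP)
  n_kept_acc <- 0

  n_save <- floor((config$n_iter - config$n_burnin) / config$thin)
  draws <- list(
    mu = array(NA_real_, c(n_save, nC, nP),
               dimnames = list(NULL, URBAN_CLASSES, COEF_NAMES)),
    sigma = array(NA_real_, c(n_save, nC, nP),
                  dimnames = list(NULL, URBAN_CLASSES, COEF_NAMES)),
    beta = array(NA_real_, c(n_save, I, nP),
                 dimnames = list(NULL, roster$species_id, COEF_NAMES)),
    psi = matrix(NA_real_, n_save, I, dimnames = list(NULL, roster$species_id)),
    N = array(NA_integer_, c(n_save, I, J),
              dimnames = list(NULL, roster$species_id, colnames(maxy))))
  s_idx <- 0

  for (it in seq_len(config$n_iter)) {
    adapt <- it <= config$n_burnin
    gam <- min(0.25, it^-0.6)

    Qlog <- -(sp %*% Ssum)              # I x J: sum_k log(1 - p_ijk)
    lamq <- lam * exp(Qlog)

    # (a) inclusion indicators at all-zero cells
    if (length(idx_z)) {
      lp0 <- (lamq[idx_z] - lam[idx_z]) +
        stats::ppois(N_max, lamq[idx_z], log.p = TRUE)
      pz <- stats::plogis(stats::qlogis(rep(psi, J)[idx_z]) + lp0)
      w[idx_z] <- (stats::runif(length(idx_z)) < pz) + 0
      N[idx_z] <- 0L
    }

    # (b) latent abundance
    on_z <- idx_z[w[idx_z] == 1]
    if (length(on_z)) {
      lmq <- lamq[on_z]
      Ftr <- stats::ppois(N_max, lmq)
      N[on_z] <- pmin(stats::qpois(stats::runif(length(on_z)) * Ftr, lmq), N_max)
    }
    if (length(idx_nz)) {
      a <- loglam[idx_nz] + Qlog[idx_nz]
      N[idx_nz] <- .sample_N_cells(CmatT, a)
    }
    Nrep <- N[, site_of_col, drop = FALSE]

    # (c) species coefficients, one coordinate at a time across species.
    # ll_a / ll_d are the per-species Poisson and binomial log-likelihood
    # terms, maintained across all species-block moves below.
    if (config$update_species) {
      ll_a <- rowSums(w * (N * loglam - lam))
      ll_d <- rowSums(ymat * eta - Nrep * sp)   # choose-terms constant, dropped
      for (r in seq_len(nP)) {
        scl <- exp(ls_beta[, r])
        delta <- scl * stats::rnorm(I)
        prior_diff <-
          stats::dnorm(beta[, r] + delta, mu[cbind(cls_idx, r)],
                       sigma[cbind(cls_idx, r)], log = TRUE) -
          stats::dnorm(beta[, r], mu[cbind(cls_idx, r)],
                       sigma[cbind(cls_idx, r)], log = TRUE)
        if (r <= length(ABUND_COEFS)) {
          ab <- .abund_ll(loglam + tcrossprod(delta, Xa[, r]), N, w)
          loglam_p <- ab$loglam; lam_p <- ab$lam; ll_p <- ab$ll
          acc <- log(stats::runif(I)) < (ll_p - ll_a + prior_diff)
          if (any(acc)) {
            beta[acc, r] <- beta[acc, r] + delta[acc]
            loglam[acc, ] <- loglam_p[acc, , drop = FALSE]
            lam[acc, ] <- lam_p[acc, , drop = FALSE]
            ll_a[acc] <- ll_p[acc]
          }
        } else {
          rd <- r - length(ABUND_COEFS)
          eta_p <- eta + tcrossprod(delta, Xd[, rd])
          de <- .detect_ll(eta_p, ymat, Nrep)
          sp_p <- de$sp; ll_p <- de$ll
          acc <- log(stats::runif(I)) < (ll_p - ll_d + prior_diff)
          if (any(acc)) {
            beta[acc, r] <- beta[acc, r] + delta[acc]
            eta[acc, ] <- eta_p[acc, , drop = FALSE]
            sp[acc, ] <- sp_p[acc, , drop = FALSE]
            ll_d[acc] <- ll_p[acc]
          }
        }
        if (adapt) ls_beta[, r] <- ls_beta[, r] + gam * (acc - config$target_accept)
        if (!adapt) acc_beta[, r] <- acc_beta[, r] + acc
      }
    }

    # (c'') abundance-detection trade-off: lambda up, p down leaves the
    # expected count nearly unchanged, so (u1, u2, v1) mix slowly under
    # coordinate moves. The columns for u1 + u2 and for v1 are constant
    # one, so a joint shift (u1 + d, u2 + d, v1 - d) moves every
    # log lambda by +d and every logit p by -d: one cheap Metropolis
    # proposal along the soft ridge.
    if (config$update_species) {
      dlt <- exp(ls_ray) * stats::rnorm(I)
      ab <- .abund_ll(loglam + dlt, N, w)
      loglam_p <- ab$loglam; lam_p <- ab$lam; ll_ap <- ab$ll
      eta_p <- eta - dlt
      de <- .detect_ll(eta_p, ymat, Nrep)
      sp_p <- de$sp; ll_dp <- de$ll
      iu1 <- match("u1", COEF_NAMES); iu2 <- match("u2", COEF_NAMES)
      iv1 <- match("v1", COEF_NAMES)
      pr_diff <-
        stats::dnorm(beta[, iu1] + dlt, mu[cbind(cls_idx, iu1)],
                     sigma[cbind(cls_idx, iu1)], log = TRUE) -
        stats::dnorm(beta[, iu1], mu[cbind(cls_idx, iu1)],
                     sigma[cbind(cls_idx, iu1)], log = TRUE) +
        stats::dnorm(beta[, iu2] + dlt, mu[cbind(cls_idx, iu2)],
                     sigma[cbind(cls_idx, iu2)], log = TRUE) -
        stats::dnorm(beta[, iu2], mu[cbind(cls_idx, iu2)],
                     sigma[cbind(cls_idx, iu2)], log = TRUE) +
        stats::dnorm(beta[, iv1] - dlt, mu[cbind(cls_idx, iv1)],
                     sigma[cbind(cls_idx, iv1)], log = TRUE) -
        stats::dnorm(beta[, iv1], mu[cbind(cls_idx, iv1)],
                     sigma[cbind(cls_idx, iv1)], log = TRUE)
      acc <- log(stats::runif(I)) < (ll_ap - ll_a + ll_dp - ll_d + pr_diff)
      if (any(acc)) {
        beta[acc, iu1] <- beta[acc, iu1] + dlt[acc]
        beta[acc, iu2] <- beta[acc, iu2] + dlt[acc]
        beta[acc, iv1] <- beta[acc, iv1] - dlt[acc]
        loglam[acc, ] <- loglam_p[acc, , drop = FALSE]
        lam[acc, ] <- lam_p[acc, , drop = FALSE]
        eta[acc, ] <- eta_p[acc, , drop = FALSE]
        sp[acc, ] <- sp_p[acc, , drop = FALSE]
        ll_a[acc] <- ll_ap[acc]; ll_d[acc] <- ll_dp[acc]
      }
      if (adapt) ls_ray <- ls_ray + gam * (acc - config$target_accept)
      if (!adapt) acc_ray <- acc_ray + acc
    }

    # (c0) collapsed update of the ray-coordinate spreads. The species
    # prior restricted to the two invariant rays can be integrated out
    # in closed form, leaving the marginal prior of the identified
    # combinations of (u1, u2, o1, o2, a3, a4). A joint log-scale
    # proposal of those six sigmas against this marginal lets the
    # sampler hop between variance-allocation modes (e.g. intercept
    # spread vs origin spread), which single-sigma moves cannot do; the
    # ray components are redrawn from their exact conditional in (c')
    # immediately afterwards, making this a valid partially collapsed
    # step.
    if (config$update_species && config$update_hyper) {
      log_marg <- function(sg6, Rres, n_i) {
        # integral over the ray plane of prod N(r + B z; 0, diag(sg6^2))
        si2 <- 1 / sg6^2
        Q <- crossprod(Bray * si2, Bray)          # 2 x 2
        detQ <- Q[1, 1] * Q[2, 2] - Q[1, 2]^2
        if (!is.finite(detQ) || detQ <= 0) return(-Inf)
        Qi <- matrix(c(Q[2, 2], -Q[1, 2], -Q[1, 2], Q[1, 1]), 2) / detQ
        U <- -(Rres * rep(si2, each = nrow(Rres))) %*% Bray
        quad_r <- sum(Rres^2 %*% si2)
        quad_u <- sum((U %*% Qi) * U)
        out <- n_i * (-sum(log(sg6)) - 0.5 * log(detQ)) -
          0.5 * quad_r + 0.5 * quad_u
        if (!is.finite(out)) return(-Inf)
        out
      }
      for (c in seq_len(nC)) {
        if (n_class[c] == 0) next
        rows_c <- which(cls_idx == c)
        sg6 <- sigma[c, ray_cols]
        rw <- stats::runif(1) < 0.5
        if (rw) {
          # random-walk refinement on the log scale
          t1 <- log(sg6) + exp(ls_alloc[c]) * stats::rnorm(6)
          sg6p <- exp(t1)
          lq <- sum(t1) - sum(log(sg6))           # log-scale Jacobians
        } else {
          # independence proposal from the prior: crosses allocation
          # modes and the prior's many orders of magnitude in one jump
          sg6p <- stats::rgamma(6, config$sigma_prior_shape,
                                rate = config$sigma_prior_rate)
          lq <- sum(stats::dgamma(sg6, config$sigma_prior_shape,
                                  rate = config$sigma_prior_rate, log = TRUE)) -
            sum(stats::dgamma(sg6p, config$sigma_prior_shape,
                              rate = config$sigma_prior_rate, log = TRUE))
        }
        Rres <- beta[rows_c, ray_cols, drop = FALSE] -
          rep(mu[c, ray_cols], each = length(rows_c))
        lr <- if (any(sg6p < SIGMA_MIN) || any(sg6p > 1e6)) -Inf else {
          lm_p <- log_marg(sg6p, Rres, n_class[c])
          lm_c <- log_marg(sg6, Rres, n_class[c])
          if (!is.finite(lm_p)) -Inf
          else if (!is.finite(lm_c)) Inf   # escape a numerically dead state
          else lm_p - lm_c +
            sum(stats::dgamma(sg6p, config$sigma_prior_shape,
                              rate = config$sigma_prior_rate, log = TRUE)) -
            sum(stats::dgamma(sg6, config$sigma_prior_shape,
                              rate = config$sigma_prior_rate, log = TRUE)) + lq
        }
        acc1 <- log(stats::runif(1)) < lr
        if (acc1) sigma[c, ray_cols] <- sg6p
        if (adapt && rw) ls_alloc[c] <- ls_alloc[c] + gam * (acc1 - 0.25)
        if (!adapt) acc_alloc[c] <- acc_alloc[c] + acc1
      }
    }

    # (c') exact Gibbs moves along the likelihood-invariant directions.
    # The predictor leaves two linear combinations of the abundance
    # coefficients unidentified: every treated site contributes u1 + a3
    # (forest) or u1 + a4 (grass), and every site pairs an intercept
    # with an origin term. Shifting beta along
    #   d1 = (+u1, -a3, -a4)   or   d2 = (-u1, -u2, +o1, +o2)
    # changes no lambda, so the conditional posterior of the shift is
    # the (Gaussian) hierarchical prior restricted to the ray — drawn
    # exactly. Without these moves the ridge mixes pathologically.
    if (config$update_species) {
      for (dir in RIDGE_DIRS) {
        cols <- match(names(dir), COEF_NAMES)
        dvec <- unname(dir)
        mu_i <- mu[cls_idx, cols, drop = FALSE]
        sg2_i <- sigma[cls_idx, cols, drop = FALSE]^2
        prec <- rowSums(sweep(1 / sg2_i, 2, dvec^2, `*`))
        mn <- -rowSums(sweep((beta[, cols, drop = FALSE] - mu_i) / sg2_i,
                             2, dvec, `*`)) / prec
        dlt <- stats::rnorm(I, mn, 1 / sqrt(prec))
        beta[, cols] <- beta[, cols] + dlt %o% dvec
      }
      # The same rays exist at the class level: shifting a class mean
      # and every member species' coefficients together along d leaves
      # both the likelihood and the species-level prior terms unchanged,
      # so the conditional of the joint shift is the hyperprior
      # restricted to the ray — again an exact Gaussian draw. Without it
      # the class means random-walk across a prior-wide ridge.
      if (config$update_hyper) {
        for (dir in RIDGE_DIRS) {
          cols <- match(names(dir), COEF_NAMES)
          dvec <- unname(dir)
          prec0 <- sum(dvec^2) / config$mu_prior_sd^2
          mn0 <- -as.vector(mu[, cols, drop = FALSE] %*% dvec) /
            config$mu_prior_sd^2 / prec0
          dlt0 <- stats::rnorm(nC, mn0, 1 / sqrt(prec0))
          mu[, cols] <- mu[, cols] + dlt0 %o% dvec
          beta[, cols] <- beta[, cols] + dlt0[cls_idx] %o% dvec
        }
      }
      # The abundance-detection trade-off also has a class-level soft
      # ridge: shift a class's (mu_u1, mu_u2, mu_v1) and all member
      # species' (u1, u2, v1) together. Species-prior terms cancel, so
      # the Metropolis ratio is the likelihood change plus the
      # hyperprior change; classes are disjoint and update in one pass.
      if (config$update_hyper) {
        iu1 <- match("u1", COEF_NAMES); iu2 <- match("u2", COEF_NAMES)
        iv1 <- match("v1", COEF_NAMES)
        dlt0 <- exp(ls_rayc) * stats::rnorm(nC)
        dsp <- dlt0[cls_idx]
        ab <- .abund_ll(loglam + dsp, N, w)
        loglam_p <- ab$loglam; lam_p <- ab$lam; ll_ap <- ab$ll
        eta_p <- eta - dsp
        de <- .detect_ll(eta_p, ymat, Nrep)
        sp_p <- de$sp; ll_dp <- de$ll
        dll <- ll_ap - ll_a + ll_dp - ll_d
        dll_c <- numeric(nC)
        tmpc <- rowsum(dll, cls_idx)
        dll_c[as.integer(rownames(tmpc))] <- tmpc
        s0 <- config$mu_prior_sd
        pr <- stats::dnorm(mu[, iu1] + dlt0, 0, s0, log = TRUE) -
          stats::dnorm(mu[, iu1], 0, s0, log = TRUE) +
          stats::dnorm(mu[, iu2] + dlt0, 0, s0, log = TRUE) -
          stats::dnorm(mu[, iu2], 0, s0, log = TRUE) +
          stats::dnorm(mu[, iv1] - dlt0, 0, s0, log = TRUE) -
          stats::dnorm(mu[, iv1], 0, s0, log = TRUE)
        accc <- log(stats::runif(nC)) < (dll_c + pr)
        if (any(accc)) {
          mu[accc, iu1] <- mu[accc, iu1] + dlt0[accc]
          mu[accc, iu2] <- mu[accc, iu2] + dlt0[accc]
          mu[accc, iv1] <- mu[accc, iv1] - dlt0[accc]
          rows <- accc[cls_idx]
          beta[rows, iu1] <- beta[rows, iu1] + dsp[rows]
          beta[rows, iu2] <- beta[rows, iu2] + dsp[rows]
          beta[rows, iv1] <- beta[rows, iv1] - dsp[rows]
          loglam[rows, ] <- loglam_p[rows, , drop = FALSE]
          lam[rows, ] <- lam_p[rows, , drop = FALSE]
          eta[rows, ] <- eta_p[rows, , drop = FALSE]
          sp[rows, ] <- sp_p[rows, , drop = FALSE]
          ll_a[rows] <- ll_ap[rows]; ll_d[rows] <- ll_dp[rows]
        }
        if (adapt) ls_rayc <- ls_rayc + gam * (accc - config$target_accept)
        if (!adapt) acc_rayc <- acc_rayc + accc
      }
      # refresh the cached predictor (invariant in exact arithmetic)
      loglam <- beta[, ABUND_COEFS, drop = FALSE] %*% t(Xa)
      lam <- exp(pmin(loglam, 300))
    }

    # (d) class means: conjugate normal
    if (config$update_hyper) {
      Sx <- matrix(0, nC, nP)
      tmp <- rowsum(beta, cls_idx)
      Sx[as.integer(rownames(tmp)), ] <- tmp
      mom <- conj_mu_moments(Sx, n_class, sigma, config$mu_prior_sd)
      mu <- matrix(stats::rnorm(nC * nP, mom$mean, mom$sd), nC, nP,
                   dimnames = dimnames(mu))

      # (e) class sds: RW Metropolis on log sigma. The conditional given
      # the residual sum of squares costs no likelihood evaluation, so
      # several sweeps per iteration give a near-fresh draw.
      ss <- matrix(0, nC, nP)
      tmp <- rowsum((beta - mu[cls_idx, , drop = FALSE])^2, cls_idx)
      ss[as.integer(rownames(tmp)), ] <- tmp
      lp_sig <- function(tt) {
        s <- exp(tt)
        out <- -n_class * tt - ss / (2 * s^2) +
          stats::dgamma(s, config$sigma_prior_shape,
                        rate = config$sigma_prior_rate, log = TRUE) + tt
        out[s < SIGMA_MIN] <- -Inf
        out
      }
      for (sweep in 1:5) {
        t0 <- log(sigma)
        t1 <- t0 + exp(ls_sigma) * matrix(stats::rnorm(nC * nP), nC, nP)
        accs <- matrix(log(stats::runif(nC * nP)), nC, nP) < (lp_sig(t1) - lp_sig(t0))
        sigma[accs] <- exp(t1[accs])
        if (adapt) ls_sigma <- ls_sigma + gam * (accs - config$target_accept)
        if (!adapt && sweep == 1) acc_sigma <- acc_sigma + accs
      }

      # (e') non-centered interweave for (mu, sigma). Holding the
      # standardized residuals e_i = (beta_i - mu_c)/sigma_c fixed, a
      # joint (mu, sigma) proposal translates and rescales every member
      # species' coefficient, so the acceptance ratio involves the
      # likelihood and hyperpriors but no species-prior term — the
      # complementary move to (d)/(e), and the standard cure for the
      # funnel coupling of the hyperparameters with their species
      # coefficients. Classes are disjoint, so all three update in one
      # vectorized pass per coefficient.
      if (config$update_species) {
        for (sweep_nc in 1:3) {
        for (r in seq_len(nP)) {
          sig_c <- sigma[, r]; mu_c <- mu[, r]
          # per class, either a log-scale random walk on (mu, sigma) or
          # an independence draw of sigma from its prior; the latter
          # crosses the prior's orders of magnitude for spreads the
          # data barely inform
          rw_c <- stats::runif(nC) < 0.5
          t1 <- log(sig_c) + exp(ls_signc[, r]) * stats::rnorm(nC)
          # independence component: a gamma-prior / mid-scale lognormal
          # mixture, so both collapse (sigma ~ 0) and re-expansion to
          # data scale are proposed often enough to switch regimes
          comp <- stats::runif(nC) < 0.5
          sig_ind <- ifelse(comp,
                            stats::rgamma(nC, config$sigma_prior_shape,
                                          rate = config$sigma_prior_rate),
                            stats::rlnorm(nC, log(0.3), 1.2))
          sig_p <- ifelse(rw_c, exp(t1), pmax(sig_ind, SIGMA_MIN))
          mu_p <- ifelse(rw_c, mu_c + exp(ls_signc[, r]) * stats::rnorm(nC),
                         mu_c)
          ld_mix <- function(x) {
            log(0.5 * stats::dgamma(x, config$sigma_prior_shape,
                                    rate = config$sigma_prior_rate) +
                0.5 * stats::dlnorm(x, log(0.3), 1.2))
          }
          e_i <- (beta[, r] - mu_c[cls_idx]) / sig_c[cls_idx]
          beta_p <- mu_p[cls_idx] + sig_p[cls_idx] * e_i
          dbet <- beta_p - beta[, r]
          if (r <= length(ABUND_COEFS)) {
            ab <- .abund_ll(loglam + tcrossprod(dbet, Xa[, r]), N, w)
            loglam_p <- ab$loglam; lam_p <- ab$lam; ll_p <- ab$ll
            dll <- ll_p - ll_a
          } else {
            rd <- r - length(ABUND_COEFS)
            eta_p <- eta + tcrossprod(dbet, Xd[, rd])
            de <- .detect_ll(eta_p, ymat, Nrep)
            sp_p <- de$sp; ll_p <- de$ll
            dll <- ll_p - ll_d
            if (COEF_NAMES[r] == "v1") {
              # ride the abundance-detection ridge: compensate the v1
              # change with an opposite shift of u1 and u2 so lambda * p
              # is roughly preserved and regime switches of sigma_v1
              # are not vetoed by the likelihood
              ab <- .abund_ll(loglam - dbet, N, w)
              iu1 <- match("u1", COEF_NAMES); iu2 <- match("u2", COEF_NAMES)
              dll <- dll + ab$ll - ll_a +
                stats::dnorm(beta[, iu1] - dbet, mu[cbind(cls_idx, iu1)],
                             sigma[cbind(cls_idx, iu1)], log = TRUE) -
                stats::dnorm(beta[, iu1], mu[cbind(cls_idx, iu1)],
                             sigma[cbind(cls_idx, iu1)], log = TRUE) +
                stats::dnorm(beta[, iu2] - dbet, mu[cbind(cls_idx, iu2)],
                             sigma[cbind(cls_idx, iu2)], log = TRUE) -
                stats::dnorm(beta[, iu2], mu[cbind(cls_idx, iu2)],
                             sigma[cbind(cls_idx, iu2)], log = TRUE)
              loglam_v <- ab$loglam; lam_v <- ab$lam; ll_av <- ab$ll
            }
          }
          dll_c <- numeric(nC)
          tmpc <- rowsum(dll, cls_idx)
          dll_c[as.integer(rownames(tmpc))] <- tmpc
          lr_rw <- stats::dgamma(sig_p, config$sigma_prior_shape,
                                 rate = config$sigma_prior_rate, log = TRUE) -
            stats::dgamma(sig_c, config$sigma_prior_shape,
                          rate = config$sigma_prior_rate, log = TRUE) +
            stats::dnorm(mu_p, 0, config$mu_prior_sd, log = TRUE) -
            stats::dnorm(mu_c, 0, config$mu_prior_sd, log = TRUE) +
            t1 - log(sig_c)
          lr_ind <- stats::dgamma(sig_p, config$sigma_prior_shape,
                                  rate = config$sigma_prior_rate, log = TRUE) -
            stats::dgamma(sig_c, config$sigma_prior_shape,
                          rate = config$sigma_prior_rate, log = TRUE) +
            ld_mix(sig_c) - ld_mix(sig_p)
          lr <- dll_c + ifelse(rw_c, lr_rw, lr_ind)
          lr[sig_p < SIGMA_MIN] <- -Inf
          accc <- log(stats::runif(nC)) < lr
          if (any(accc)) {
            sigma[accc, r] <- sig_p[accc]
            mu[accc, r] <- mu_p[accc]
            rows <- accc[cls_idx]
            beta[rows, r] <- beta_p[rows]
            if (r <= length(ABUND_COEFS)) {
              loglam[rows, ] <- loglam_p[rows, , drop = FALSE]
              lam[rows, ] <- lam_p[rows, , drop = FALSE]
              ll_a[rows] <- ll_p[rows]
            } else {
              eta[rows, ] <- eta_p[rows, , drop = FALSE]
              sp[rows, ] <- sp_p[rows, , drop = FALSE]
              ll_d[rows] <- ll_p[rows]
              if (COEF_NAMES[r] == "v1") {
                iu1 <- match("u1", COEF_NAMES); iu2 <- match("u2", COEF_NAMES)
                beta[rows, iu1] <- beta[rows, iu1] - dbet[rows]
                beta[rows, iu2] <- beta[rows, iu2] - dbet[rows]
                loglam[rows, ] <- loglam_v[rows, , drop = FALSE]
                lam[rows, ] <- lam_v[rows, , drop = FALSE]
                ll_a[rows] <- ll_av[rows]
              }
            }
          }
          if (adapt) {
            ls_signc[rw_c, r] <- ls_signc[rw_c, r] +
              gam * (accc[rw_c] - config$target_accept)
          }
          if (!adapt && sweep_nc == 1) acc_signc[, r] <- acc_signc[, r] + accc
        }
        }
      }
    }

    # (f) inclusion probabilities: conjugate Beta
    if (config$update_psi) {
      sw <- rowSums(w)
      psi <- stats::rbeta(I, config$psi_prior[1] + sw,
                          config$psi_prior[2] + J - sw)
    }

    if (!adapt) n_kept_acc <- n_kept_acc + 1
    if (it > config$n_burnin && (it - config$n_burnin) %% config$thin == 0) {
      s_idx <- s_idx + 1
      draws$mu[s_idx, , ] <- mu
      draws$sigma[s_idx, , ] <- sigma
      draws$beta[s_idx, , ] <- beta
      draws$psi[s_idx, ] <- psi
      draws$N[s_idx, , ] <- N
    }
  }

  nk <- max(n_kept_acc, 1)
  list(draws = draws,
       acceptance = list(beta = acc_beta / nk, sigma = acc_sigma / nk,
                         sigma_nc = acc_signc / nk, ray = acc_ray / nk,
                         ray_class = acc_rayc / nk, alloc = acc_alloc / nk))
}

#' @export
print.zipnmix_fit <- function(x, ...) {
  cf <- x$config
  cat(sprintf("zipnmix_fit: %d chains x %d iterations (burn-in %d, thin %d)\n",
              cf$n_chains, cf$n_iter, cf$n_burnin, cf$thin))
  cat(sprintf("  %d species, %d sites, %d visits; N truncated at %d\n",
              dim(x$y)[1], dim(x$y)[2], dim(x$y)[3], x$N_max))
  rh <- try(rhat_table(x), silent = TRUE)
  if (!inherits(rh, "try-error")) {
    cat(sprintf("  max split R-hat over hyperparameters: %.3f\n", max(rh$rhat)))
  }
  invisible(x)
}

#' Unnormalized joint log posterior at the current state
#'
#' The full-data joint density of counts, latent states and parameters:
#' likelihood terms of every observation given (N, p), the Poisson term
#' of N given (w, lambda), the Bernoulli term of w given psi, the
#' hierarchical normal terms of the species coefficients, and the
#' hyperpriors. Nothing is marginalized. Out-of-support states (sigma
#' <= 0, psi outside \[0,1\], y > N) give `-Inf`.
#'
#' @param y count array (species x site x visit).
#' @param design a `survey_design`.
#' @param params `species_params` data frame (coefficients and psi).
#' @param hyper a [class_hyperparams()]-shaped list (`mu`, `sigma`
#'   matrices; sigma entries may be non-positive, yielding `-Inf`).
#' @param N,w latent abundance and inclusion matrices (species x site).
#' @param config an [mcmc_config()] providing the prior constants.
#' @return a single finite number or `-Inf`.
#' @export
log_posterior <- function(y, design, params, hyper, N, w,
                          config = mcmc_config()) {
  params <- as.data.frame(params)
  psi <- params$psi
  if (any(psi < 0 | psi > 1)) return(-Inf)
  sig <- hyper$sigma
  if (any(sig <= 0)) return(-Inf)
  if (any(N < 0) || any(w != 0 & w != 1)) return(-Inf)
  if (any(N[w == 0] != 0)) return(-Inf)
  dm <- design_matrices(design)
  I <- dim(y)[1]; J <- dim(y)[2]; K <- dim(y)[3]
  beta_a <- as.matrix(params[, ABUND_COEFS, drop = FALSE])
  beta_d <- as.matrix(params[, DETECT_COEFS, drop = FALSE])
  loglam <- beta_a %*% t(dm$Xa)
  p <- pmin(pmax(stats::plogis(beta_d %*% t(dm$Xd)), P_EPS), 1 - P_EPS)
  lp <- sum(stats::dbinom(w, 1, rep(psi, J), log = TRUE))
  lp <- lp + sum(stats::dpois(N, w * exp(loglam), log = TRUE))
  for (k in seq_len(K)) {
    pk <- p[, (seq_len(J) - 1L) * K + k, drop = FALSE]
    lp <- lp + sum(stats::dbinom(y[, , k], N, pk, log = TRUE))
  }
  cls <- normalize_roster(params[, c("species_id", "urban_class")])$urban_class
  mu_i <- hyper$mu[cls, COEF_NAMES, drop = FALSE]
  sig_i <- sig[cls, COEF_NAMES, drop = FALSE]
  beta <- as.matrix(params[, COEF_NAMES, drop = FALSE])
  lp <- lp + sum(stats::dnorm(beta, mu_i, sig_i, log = TRUE))
  lp <- lp + sum(stats::dnorm(hyper$mu, 0, config$mu_prior_sd, log = TRUE))
  lp <- lp + sum(stats::dgamma(sig, config$sigma_prior_shape,
                               rate = config$sigma_prior_rate, log = TRUE))
  lp <- lp + sum(stats::dbeta(psi, config$psi_prior[1], config$psi_prior[2],
                              log = TRUE))
  lp
}

#' Split-R-hat (potential scale reduction factor)
#'
#' Each chain is split in half and the classical Gelman-Rubin statistic
#' is computed over the resulting 2m half-chains; values near 1 indicate
#' convergence.
#'
#' @param x draws of one scalar parameter: an iterations x chains
#'   matrix, or a list of equal-length numeric vectors (>= 2 chains of
#'   length >= 10).
#' @return the split-R-hat; exactly 1 (with a warning) when the draws
#'   have zero total variance.
#' @export
gelman_rubin <- function(x) {
  if (is.list(x)) {
    n <- unique(lengths(x))
    if (length(n) != 1) stop("chains must have equal length", call. = FALSE)
    x <- do.call(cbind, x)
  }
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("at least 2 chains are required", call. = FALSE)
  if (nrow(x) < 10) stop("chains must have length >= 10", call. = FALSE)
  h <- floor(nrow(x) / 2)
  halves <- cbind(x[seq_len(h), , drop = FALSE],
                  x[seq_len(h) + (nrow(x) - h), , drop = FALSE])
  if (stats::var(as.vector(halves)) == 0) {
    warning("zero total variance; R-hat set to 1 by convention")
    return(1)
  }
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- h * stats::var(means)
  var_hat <- (h - 1) / h * W + B / h
  if (W == 0) return(Inf)
  sqrt(var_hat / W)
}

#' Draws of one class-level hyperparameter as an iterations x chains matrix
#'
#' @param fit a `zipnmix_fit`.
#' @param stat `"mu"` or `"sigma"`.
#' @param class urban class name.
#' @param coef coefficient name (e.g. `"a3"`).
#' @return numeric matrix, retained iterations in rows, chains in columns.
#' @export
hyper_draws <- function(fit, stat = c("mu", "sigma"), class, coef) {
  stat <- match.arg(stat)
  stopifnot(class %in% URBAN_CLASSES, coef %in% COEF_NAMES)
  sapply(fit$chains, function(ch) ch[[stat]][, class, coef])
}

#' Split-R-hat for every class-level hyperparameter
#'
#' @param fit a `zipnmix_fit`.
#' @return data frame with `parameter` (e.g. `"mu_a3_sensitive"`) and
#'   `rhat`.
#' @export
rhat_table <- function(fit) {
  rows <- expand.grid(stat = c("mu", "sigma"), class = URBAN_CLASSES,
                      coef = COEF_NAMES, stringsAsFactors = FALSE)
  rhat <- suppressWarnings(vapply(seq_len(nrow(rows)), function(i) {
    gelman_rubin(hyper_draws(fit, rows$stat[i], rows$class[i], rows$coef[i]))
  }, numeric(1)))
  data.frame(parameter = sprintf("%s_%s_%s", rows$stat, rows$coef, rows$class),
             rhat = rhat)
}
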