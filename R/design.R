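# Survey-design container: raw site and visit tables plus the
# standardized covariates that enter the model. Standardization constants
# are computed from the data at hand and kept with the object so a fitted
# model's covariate scale is reproducible.

#' Assemble a survey design from site and visit tables
#'
#' @param sites data frame with columns `site_id`, `block_id`, `origin`
#'   (`"forest"`/`"grass"`), `treated` (0/1), `site_area_ha`,
#'   `patch_area_ha`, `weed_contrast_eligible` (0/1; sites excluded from
#'   the weed-control contrast are flagged, not dropped).
#' @param visits data frame with columns `site_id`, `visit` (1..K),
#'   `date_days` (days since surveys began), `minutes_since_sunrise`.
#' @param area_source which area enters the abundance model: the
#'   enclosing vegetation `"patch"` (default) or the `"site"` itself.
#'   Areas are log-transformed then z-scored; `DATE` and `TSR` are
#'   z-scored over all visits.
#' @return a `survey_design`: the raw tables, the number of visits per
#'   site `K`, standardized covariates (`TRT`, `ORI`, `area` per site;
#'   `DATE`, `TSR` as J x K matrices) and the standardization constants.
#' @export
make_design <- function(sites, visits, area_source = c("patch", "site")) {
  area_source <- match.arg(area_source)
  req_s <- c("site_id", "block_id", "origin", "treated",
             "site_area_ha", "patch_area_ha", "weed_contrast_eligible")
  req_v <- c("site_id", "visit", "date_days", "minutes_since_sunrise")
  if (!all(req_s %in% names(sites))) {
    stop("sites table missing columns: ",
         paste(setdiff(req_s, names(sites)), collapse = ", "), call. = FALSE)
  }
  if (!all(req_v %in% names(visits))) {
    stop("visits table missing columns: ",
         paste(setdiff(req_v, names(visits)), collapse = ", "), call. = FALSE)
  }
  sites <- as.data.frame(sites)
  visits <- as.data.frame(visits)
  sites$site_id <- as.character(sites$site_id)
  visits$site_id <- as.character(visits$site_id)
  if (anyDuplicated(sites$site_id)) stop("duplicate site_id in sites table", call. = FALSE)
  sites$origin <- tolower(as.character(sites$origin))
  if (!all(sites$origin %in% c("forest", "grass"))) {
    stop("origin must be 'forest' or 'grass'", call. = FALSE)
  }
  if (!all(sites$treated %in% c(0, 1))) stop("treated must be 0/1", call. = FALSE)
  bad <- setdiff(visits$site_id, sites$site_id)
  if (length(bad)) {
    stop("visit rows reference unknown site(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(visits[c("site_id", "visit")])) {
    stop("duplicate (site_id, visit) rows in visits table", call. = FALSE)
  }
  kk <- table(visits$site_id)
  K <- unique(as.integer(kk))
  if (length(K) != 1) stop("all sites must have the same number of visits", call. = FALSE)

  J <- nrow(sites)
  zs <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) s <- 1  # constant covariate: center only
    list(mean = mean(x), sd = s, z = (x - mean(x)) / s)
  }
  area_raw <- if (area_source == "patch") sites$patch_area_ha else sites$site_area_ha
  if (any(area_raw <= 0) || !all(is.finite(area_raw))) {
    stop("areas must be positive and finite", call. = FALSE)
  }
  za <- zs(log(area_raw))
  zd <- zs(visits$date_days)
  zt <- zs(visits$minutes_since_sunrise)

  ord <- order(match(visits$site_id, sites$site_id), visits$visit)
  visits <- visits[ord, , drop = FALSE]
  rownames(visits) <- NULL
  DATE <- matrix(zd$z[ord], nrow = J, ncol = K, byrow = TRUE,
                 dimnames = list(sites$site_id, NULL))
  TSR <- matrix(zt$z[ord], nrow = J, ncol = K, byrow = TRUE,
                dimnames = list(sites$site_id, NULL))

  structure(list(
    sites = sites, visits = visits, J = J, K = K,
    TRT = as.numeric(sites$treated),
    ORI = as.numeric(sites$origin == "forest"),
    area = za$z,
    DATE = DATE, TSR = TSR,
    standardization = list(
      area_source = area_source,
      logarea_mean = za$mean, logarea_sd = za$sd,
      date_mean = zd$mean, date_sd = zd$sd,
      tsr_mean = zt$mean, tsr_sd = zt$sd)
  ), class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat(sprintf("survey_design: %d sites in %d blocks, %d visits each\n",
              x$J, length(unique(x$sites$block_id)), x$K))
  tab <- table(origin = x$sites$origin, treated = x$sites$treated)
  print(tab)
  inel <- sum(x$sites$weed_contrast_eligible == 0)
  if (inel > 0) cat(sprintf("%d sites flagged ineligible for the weed contrast\n", inel))
  invisible(x)
}

# Design matrices for the linear predictors, in COEF_NAMES order.
# Xa: J x 8 (TRT, 1-TRT, ORI, 1-ORI, area, area*TRT, TRT*ORI, TRT*(1-ORI))
# Xd: (J*K) x 5 (1, DATE, DATE^2, TSR, TSR^2), visit-major within site.
design_matrices <- function(design) {
  trt <- design$TRT; ori <- design$ORI; area <- design$area
  Xa <- cbind(u1 = trt, u2 = 1 - trt, o1 = ori, o2 = 1 - ori,
              a1 = area, a2 = area * trt, a3 = trt * ori, a4 = trt * (1 - ori))
  d <- as.vector(t(design$DATE))  # site-major: (site1 k1..K, site2 ...)
  s <- as.vector(t(design$TSR))
  Xd <- cbind(v1 = 1, b1 = d, b2 = d^2, b3 = s, b4 = s^2)
  list(Xa = Xa, Xd = Xd, J = design$J, K = design$K)
}
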