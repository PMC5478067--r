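# Plain-CSV dataset interchange. Four files describe a survey dataset:
#   sites.csv   site_id, block_id, origin, treated, site_area_ha,
#               patch_area_ha, weed_contrast_eligible
#   visits.csv  site_id, visit, date_days, minutes_since_sunrise
#   counts.csv  site_id, visit, species_id, count   (sparse: zero rows
#               may be omitted)
#   species.csv species_id, common_name, urban_class
# Standardization constants are always recomputed from the files read,
# so a written-then-read dataset reproduces the covariates exactly.

#' Write a dataset (and optional latent truth) as CSV files
#'
#' @param bundle a `truth_bundle` from [simulate_counts()], or a list
#'   with elements `design`, `y` (species x site x visit array) and
#'   `roster`.
#' @param dir output directory, created if needed.
#' @param truth if `TRUE` (default when present) the latent `N`, `w` and
#'   generating parameters are written alongside, in files prefixed
#'   `truth_`.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(bundle, dir, truth = !is.null(bundle$N)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  design <- bundle$design
  y <- bundle$y
  roster <- normalize_roster(bundle$roster)
  if (!("common_name" %in% names(roster))) roster$common_name <- roster$species_id
  paths <- c(sites = file.path(dir, "sites.csv"),
             visits = file.path(dir, "visits.csv"),
             counts = file.path(dir, "counts.csv"),
             species = file.path(dir, "species.csv"))
  utils::write.csv(design$sites, paths["sites"], row.names = FALSE, quote = FALSE)
  utils::write.csv(design$visits, paths["visits"], row.names = FALSE, quote = FALSE)
  utils::write.csv(roster[, c("species_id", "common_name", "urban_class")],
                   paths["species"], row.names = FALSE, quote = FALSE)
  idx <- which(y > 0, arr.ind = TRUE)
  counts <- data.frame(site_id = dimnames(y)[[2]][idx[, 2]],
                       visit = idx[, 3],
                       species_id = dimnames(y)[[1]][idx[, 1]],
                       count = y[idx])
  counts <- counts[order(counts$site_id, counts$visit, counts$species_id), ]
  utils::write.csv(counts, paths["counts"], row.names = FALSE, quote = FALSE)
  if (isTRUE(truth)) {
    Nlong <- data.frame(species_id = rep(rownames(bundle$N), ncol(bundle$N)),
                        site_id = rep(colnames(bundle$N), each = nrow(bundle$N)),
                        w = as.vector(bundle$w), N = as.vector(bundle$N))
    utils::write.csv(Nlong, file.path(dir, "truth_latent.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(bundle$params, file.path(dir, "truth_species_params.csv"),
                     row.names = FALSE, quote = FALSE)
    paths <- c(paths, latent = file.path(dir, "truth_latent.csv"),
               params = file.path(dir, "truth_species_params.csv"))
  }
  invisible(paths)
}

#' Read a dataset from the four CSV files
#'
#' Counts are densified: any (species, site, visit) cell absent from
#' `counts_csv` is a zero. Unknown site or species ids, duplicate count
#' rows, negative counts and unknown class labels are rejected with an
#' error naming the offender; class labels are matched
#' case-insensitively.
#'
#' @param sites_csv,visits_csv,counts_csv,species_csv file paths, or a
#'   single directory for `sites_csv` containing the four standard file
#'   names.
#' @param area_source passed to [make_design()].
#' @return list with `design` (a `survey_design`), `y` (species x site
#'   x visit integer array) and `roster`.
#' @export
read_dataset <- function(sites_csv, visits_csv = NULL, counts_csv = NULL,
                         species_csv = NULL, area_source = "patch") {
  if (is.null(visits_csv) && dir.exists(sites_csv)) {
    dir <- sites_csv
    sites_csv <- file.path(dir, "sites.csv")
    visits_csv <- file.path(dir, "visits.csv")
    counts_csv <- file.path(dir, "counts.csv")
    species_csv <- file.path(dir, "species.csv")
  }
  for (f in c(sites_csv, visits_csv, counts_csv, species_csv)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  sites <- utils::read.csv(sites_csv, stringsAsFactors = FALSE)
  visits <- utils::read.csv(visits_csv, stringsAsFactors = FALSE)
  counts <- utils::read.csv(counts_csv, stringsAsFactors = FALSE)
  species <- utils::read.csv(species_csv, stringsAsFactors = FALSE)

  design <- make_design(sites, visits, area_source = area_source)
  roster <- normalize_roster(species)

  req_c <- c("site_id", "visit", "species_id", "count")
  if (!all(req_c %in% names(counts))) {
    stop("counts file missing columns: ",
         paste(setdiff(req_c, names(counts)), collapse = ", "), call. = FALSE)
  }
  counts$site_id <- as.character(counts$site_id)
  counts$species_id <- as.character(counts$species_id)
  if (nrow(counts)) {
    bad_site <- !(counts$site_id %in% design$sites$site_id)
    if (any(bad_site)) {
      stop("counts row ", which(bad_site)[1], " references unknown site '",
           counts$site_id[which(bad_site)[1]], "'", call. = FALSE)
    }
    bad_sp <- !(counts$species_id %in% roster$species_id)
    if (any(bad_sp)) {
      stop("counts row ", which(bad_sp)[1], " references unknown species '",
           counts$species_id[which(bad_sp)[1]], "'", call. = FALSE)
    }
    if (any(counts$count < 0)) stop("negative counts in counts file", call. = FALSE)
    if (any(counts$count != floor(counts$count))) stop("non-integer counts", call. = FALSE)
    if (!all(counts$visit %in% seq_len(design$K))) {
      stop("counts reference visit indices outside 1..", design$K, call. = FALSE)
    }
    key <- paste(counts$species_id, counts$site_id, counts$visit)
    if (anyDuplicated(key)) {
      stop("duplicate (species, site, visit) rows in counts file: ",
           key[anyDuplicated(key)], call. = FALSE)
    }
  }
  I <- nrow(roster); J <- design$J; K <- design$K
  y <- array(0L, dim = c(I, J, K),
             dimnames = list(roster$species_id, design$sites$site_id, NULL))
  if (nrow(counts)) {
    y[cbind(match(counts$species_id, roster$species_id),
            match(counts$site_id, design$sites$site_id),
            counts$visit)] <- as.integer(counts$count)
  }
  list(design = design, y = y, roster = roster)
}

#' Serialize posterior draws as long-format CSV plus a JSON run manifest
#'
#' The CSV has columns `chain, iter, parameter, value` covering all
#' class hyperparameters (and optionally species coefficients and psi);
#' the manifest records the configuration, seeds, truncation bound,
#' standardization constants, acceptance-rate ranges and the split-R-hat
#' table, so a run is fully reproducible from files.
#'
#' @param fit a `zipnmix_fit`.
#' @param dir output directory, created if needed.
#' @param species include per-species coefficients and psi in the CSV
#'   (large); default `FALSE` writes hyperparameters only.
#' @return invisibly, the two paths written.
#' @export
write_posterior <- function(fit, dir, species = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (ch in seq_along(fit$chains)) {
    dr <- fit$chains[[ch]]
    ns <- dim(dr$mu)[1]
    for (stat in c("mu", "sigma")) {
      a <- dr[[stat]]
      long <- expand.grid(iter = seq_len(ns), class = URBAN_CLASSES,
                          coef = COEF_NAMES, stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        chain = ch, iter = long$iter,
        parameter = sprintf("%s_%s_%s", stat, long$coef, long$class),
        value = as.vector(a))
    }
    if (species) {
      b <- dr$beta
      long <- expand.grid(iter = seq_len(ns), sp = dimnames(b)[[2]],
                          coef = COEF_NAMES, stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        chain = ch, iter = long$iter,
        parameter = sprintf("%s_%s", long$coef, long$sp),
        value = as.vector(b))
      rows[[length(rows) + 1]] <- data.frame(
        chain = ch, iter = rep(seq_len(ns), ncol(dr$psi)),
        parameter = rep(sprintf("psi_%s", colnames(dr$psi)), each = ns),
        value = as.vector(dr$psi))
    }
  }
  draws_path <- file.path(dir, "posterior_draws.csv")
  utils::write.csv(do.call(rbind, rows), draws_path,
                   row.names = FALSE, quote = FALSE)
  rh <- rhat_table(fit)
  manifest <- list(
    package = "zipnmix",
    config = fit$config[c("n_chains", "n_iter", "n_burnin", "thin", "seed",
                          "mu_prior_sd", "sigma_prior_shape",
                          "sigma_prior_rate", "psi_prior")],
    N_max = fit$N_max,
    standardization = fit$design$standardization,
    n_species = nrow(fit$roster), n_sites = fit$design$J,
    n_visits = fit$design$K,
    acceptance = list(
      beta_range = range(unlist(lapply(fit$acceptance, `[[`, "beta"))),
      sigma_range = range(unlist(lapply(fit$acceptance, `[[`, "sigma")))),
    max_split_rhat = max(rh$rhat),
    rhat = stats::setNames(as.list(rh$rhat), rh$parameter))
  manifest_path <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(draws = draws_path, manifest = manifest_path))
}
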