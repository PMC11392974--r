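#' Generating parameters paired with their model spec
#'
#' Bundles a model spec with a full coefficient vector on the logit scale,
#' for use by the simulators. Coefficients act on *standardized*
#' covariates (per-SD effects), so generating values are directly
#' comparable with fitted coefficients.
#'
#' @param spec An [occu_spec()] naming the covariates each parameter uses.
#' @param theta Named coefficient vector in [param_names()] order.
#' @return An object of class `true_parameters`.
#' @export
true_parameters <- function(spec, theta) {
  stopifnot(inherits(spec, "occu_spec"), is.numeric(theta),
            all(is.finite(theta)))
  structure(list(spec = spec, theta = theta), class = "true_parameters")
}

#' @export
print.true_parameters <- function(x, ...) {
  cat("<true_parameters> ", x$spec$label, "\n", sep = "")
  print(x$theta)
  invisible(x)
}

# Truncated-normal draws by inverse-CDF; exact and vectorized.
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  u <- runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Default seasonal mesocarnivore survey scenario
#'
#' Generates the survey design and covariates of a two-year seasonal
#' camera-trap study in a Mediterranean agroforestry landscape: 60 sites,
#' four seasons (`W20`, `D21`, `W21`, `D22`) of 13 five-day occasions, and
#' covariates drawn to match the field study's observed moments —
#' distances to riparian vegetation and grazing-exclusion plots,
#' vegetation phenology/productivity indices, grazing pressure (livestock
#' units per area times days), forestry-intervention ratio, NDVI mean and
#' heterogeneity, shrub cover, and categorical camera-placement features.
#' Continuous covariates are Gaussian with the study's means/SDs,
#' truncated to their natural ranges (percentages to \[0, 100\], NDVI to
#' \[-1, 1\], distances and rates to non-negative values).
#'
#' Covariates are returned on their original scales; the simulators and
#' the fitting pipeline standardize them internally, so the generating
#' coefficients in the returned `true_parameters` are per-SD effects.
#'
#' @param seed Integer seed; the full draw order (site covariates in table
#'   order, then season-site covariates) is fixed, so equal seeds give
#'   identical scenarios.
#' @param n_sites Number of camera sites.
#' @param feat_freq Frequencies of the camera field-of-view feature
#'   (`none`, `trail`, `dirt road`).
#' @param alt_freq Probability the field of view was cleared of vegetation.
#' @return A list with `design` ([survey_design()]), `covs`
#'   ([covariate_set()], original scale) and `params`
#'   ([true_parameters()]: a positive per-SD effect of total vegetation
#'   productivity on first-season occupancy, grazing pressure on
#'   extinction, NDVI on colonization, and season plus feature-type
#'   effects on detection).
#' @examples
#' sc <- scenario_study_default(seed = 1)
#' sc$design
#' @export
scenario_study_default <- function(seed = 1, n_sites = 60,
                                   feat_freq = c(none = 0.4, trail = 0.35,
                                                 `dirt road` = 0.25),
                                   alt_freq = 0.3) {
  set.seed(seed)
  design <- survey_design(n_sites = n_sites)
  T <- n_seasons(design)
  n <- n_sites

  site <- tibble::tibble(
    D_Rip  = rtnorm(n, 753, 664, lo = 0),
    D_Excl = rtnorm(n, 230, 303, lo = 0),
    MINV   = rtnorm(n, 0.08, 0.03, lo = 0),
    TPROD  = rtnorm(n, 115, 18, lo = 0),
    Shrubs = rtnorm(n, 39, 31, lo = 0, hi = 100),
    Feat   = factor(sample(names(feat_freq), n, replace = TRUE,
                           prob = feat_freq),
                    levels = names(feat_freq)),
    Alt    = factor(ifelse(runif(n) < alt_freq, "cleared", "intact"),
                    levels = c("intact", "cleared"))
  )
  ss <- function(mean, sd, lo = -Inf, hi = Inf) {
    matrix(rtnorm(n * T, mean, sd, lo, hi), n, T,
           dimnames = list(NULL, design$seasons$label))
  }
  season_site <- list(
    Graz      = ss(6.27, 13.24, lo = 0),
    ForInterv = ss(0.14, 0.25, lo = 0, hi = 1),
    NDVI      = ss(0.53, 0.10, lo = -1, hi = 1),
    NDVIstdv  = ss(0.12, 0.04, lo = 0)
  )
  covs <- covariate_set(site = site, season_site = season_site)

  spec <- occu_spec(phi1 = "TPROD", eps = "Graz", gamma = NULL,
                    p = c("Season", "Feat"), species = "sim",
                    label = "generating")
  # gamma cannot carry a covariate in the same model as eps (and the
  # simulator honours the same restriction the candidate models obey)
  theta <- c(
    "phi1_(Intercept)" = 0.2, "phi1_TPROD" = 0.5,
    "gamma_(Intercept)" = -1.0,
    "eps_(Intercept)" = -1.2, "eps_Graz" = 0.25,
    "p_(Intercept)" = -0.4,
    "p_SeasonD21" = -0.5, "p_SeasonW21" = 0.1, "p_SeasonD22" = -0.6,
    "p_Feattrail" = 0.4, "p_Featdirt road" = 0.8
  )
  list(design = design, covs = covs,
       params = true_parameters(spec, theta))
}

#' Simulate latent occupancy dynamics
#'
#' Draws the latent occupancy matrix `z` (sites x seasons): first-season
#' states from `Bernoulli(phi1)`, then occupied sites persist with
#' probability `1 - eps` and unoccupied sites are colonized with
#' probability `gamma`, season by season.
#'
#' @param design A [survey_design()].
#' @param params A [true_parameters()].
#' @param covs A [covariate_set()] (any scale; standardized internally).
#' @param seed Integer seed.
#' @return Binary matrix `z`, sites x seasons.
#' @export
simulate_dynamics <- function(design, params, covs, seed = 1) {
  set.seed(seed)
  probs <- linear_predictors(params$spec, params$theta,
                             standardize_covariates(covs), design)
  n <- design$n_sites
  T <- n_seasons(design)
  z <- matrix(0L, n, T, dimnames = list(NULL, design$seasons$label))
  z[, 1] <- rbinom(n, 1, probs$phi1)
  for (t in seq_len(T - 1)) {
    pr <- ifelse(z[, t] == 1, 1 - probs$eps[, t], probs$gamma[, t])
    z[, t + 1] <- rbinom(n, 1, pr)
  }
  z
}

#' Simulate detection histories given latent occupancy
#'
#' Draws per-occasion detections `y ~ Bernoulli(p)` at occupied
#' site-seasons and 0 at unoccupied ones (no false positives). Effort per
#' occasion starts at the occasion length, loses days through a small
#' per-day failure rate, and is zeroed by occasion-level camera dropout;
#' occasions with effort < 1 day are recorded as `NA`, the convention for
#' an inactive camera.
#'
#' @param z Latent occupancy matrix from [simulate_dynamics()].
#' @param params A [true_parameters()].
#' @param covs A [covariate_set()].
#' @param design A [survey_design()].
#' @param dropout_rate Probability an occasion is lost entirely
#'   (effort 0, `y = NA`). Must be in `[0, 1)`.
#' @param day_miss_prob Per-day probability an active camera loses a day
#'   of effort (gives mean effort about 4.86 days of 5).
#' @param seed Integer seed. Draw order: effort day losses, dropout,
#'   detections.
#' @return A `detection_history` (see [detection_history()]).
#' @export
simulate_detections <- function(z, params, covs, design,
                                dropout_rate = 0.05, day_miss_prob = 0.028,
                                seed = 1) {
  stopifnot(dropout_rate >= 0, dropout_rate < 1)
  set.seed(seed)
  n <- design$n_sites
  T <- n_seasons(design)
  K <- design$n_occasions
  d <- design$occasion_days

  effort <- array(d - rbinom(n * T * K, d, day_miss_prob), c(n, T, K))
  dropped <- array(runif(n * T * K) < dropout_rate, c(n, T, K))
  effort[dropped] <- 0

  covs2 <- covs
  eff_cov <- effort
  eff_cov[eff_cov < 1] <- NA
  covs2$observation$Effort <- eff_cov
  probs <- linear_predictors(params$spec, params$theta,
                             standardize_covariates(covs2), design)
  p <- array(aperm(array(probs$p, c(n, K, T)), c(1, 3, 2)), c(n, T, K))

  y <- array(NA_integer_, c(n, T, K))
  active <- effort >= 1
  zocc <- array(rep(z == 1, times = K), c(n, T, K))
  y[active & !zocc] <- 0L
  idx <- which(active & zocc)
  y[idx] <- rbinom(length(idx), 1, p[idx])
  detection_history(y, effort, species = params$spec$species,
                    design = design)
}

#' Simulate a timestamped camera-trap event stream
#'
#' For every occupied site-season, visit times follow a homogeneous
#' Poisson process over the season at `visit_rate` events per day; each
#' visit additionally spawns a geometric number of extra camera triggers
#' within 30 minutes (cameras fire bursts per animal passage), so the
#' independent-event filter has real work to do. Unoccupied site-seasons
#' emit nothing.
#'
#' @param z Latent occupancy matrix.
#' @param design A [survey_design()].
#' @param visit_rate Expected independent visits per day (> 0).
#' @param burst_mean Mean number of extra triggers per visit.
#' @param species Species label for the output.
#' @param seed Integer seed.
#' @return A tibble with `site_id`, `species`, `timestamp` (POSIXct, UTC),
#'   sorted by site and time.
#' @export
simulate_event_stream <- function(z, design, visit_rate = 0.1,
                                  burst_mean = 1, species = "sim",
                                  seed = 1) {
  stopifnot(visit_rate > 0)
  set.seed(seed)
  T <- n_seasons(design)
  out <- vector("list", design$n_sites * T)
  m <- 0
  for (i in seq_len(design$n_sites)) {
    for (t in seq_len(T)) {
      if (z[i, t] != 1) next
      span <- as.numeric(design$seasons$end[t] - design$seasons$start[t])
      n_vis <- rpois(1, visit_rate * span)
      if (n_vis == 0) next
      t0 <- as.POSIXct(design$seasons$start[t], tz = "UTC")
      vis <- t0 + runif(n_vis, 0, span * 86400)
      extras <- lapply(seq_len(n_vis), function(v) {
        ne <- rgeom(1, 1 / (1 + burst_mean))
        if (ne == 0) return(NULL)
        vis[v] + runif(ne, 1, 29 * 60)  # within the 30-min window
      })
      ts <- sort(c(vis, do.call(c, c(extras, list(NULL)))))
      m <- m + 1
      out[[m]] <- tibble::tibble(site_id = i, species = species,
                                 timestamp = ts)
    }
  }
  if (m == 0) {
    return(tibble::tibble(site_id = integer(), species = character(),
                          timestamp = as.POSIXct(character(), tz = "UTC")))
  }
  dplyr::arrange(dplyr::bind_rows(out[seq_len(m)]), .data$site_id,
                 .data$timestamp)
}

#' Full-coverage deployment table for a design
#'
#' One deployment row per site spanning the whole survey (first season
#' start to last season end), the simplest deployment record consistent
#' with a simulated event stream.
#'
#' @param design A [survey_design()].
#' @return A tibble with `site_id`, `start`, `end` (POSIXct, UTC).
#' @export
full_deployments <- function(design) {
  tibble::tibble(
    site_id = seq_len(design$n_sites),
    start = as.POSIXct(min(design$seasons$start), tz = "UTC"),
    end = as.POSIXct(max(design$seasons$end), tz = "UTC")
  )
}

#' Write a simulated scenario to delimited text files
#'
#' Emits `events.csv` (`site_id`, `species`, `timestamp` ISO-8601),
#' `deployments.csv` (`site_id`, `start`, `end`), `covariates_site.csv`
#' and one `covariates_<name>.csv` per season-site covariate, for
#' interoperability with other occupancy tooling.
#'
#' @param dir Output directory (created if needed).
#' @param events Event tibble (e.g. from [simulate_event_stream()]).
#' @param deployments Deployment tibble.
#' @param covs A [covariate_set()].
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(dir, events, deployments, covs) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  ev <- dplyr::mutate(events, timestamp = fmt(.data$timestamp))
  write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  dp <- dplyr::mutate(deployments, start = fmt(.data$start),
                      end = fmt(.data$end))
  write.csv(dp, file.path(dir, "deployments.csv"), row.names = FALSE)
  write.csv(covs$site, file.path(dir, "covariates_site.csv"),
            row.names = FALSE)
  for (nm in names(covs$season_site)) {
    write.csv(as.data.frame(covs$season_site[[nm]]),
              file.path(dir, paste0("covariates_", nm, ".csv")),
              row.names = FALSE)
  }
  invisible(dir)
}
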