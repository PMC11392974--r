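#' Bundle site, season-site and observation covariates
#'
#' Occupancy covariates come in three flavours, distinguished by what they
#' can model: site covariates are constant across seasons (usable on any
#' parameter), season-site covariates vary by primary period (used on
#' colonization/extinction and detection), and observation covariates vary
#' by secondary occasion (detection only, e.g. survey effort).
#'
#' @param site A data frame with one row per site. Continuous covariates
#'   are numeric columns; categorical covariates are factors whose first
#'   level is the reference level.
#' @param season_site Named list of numeric matrices, each sites x seasons.
#' @param observation Named list of numeric arrays, each sites x seasons x
#'   occasions.
#' @param standardization Named list recording `(mean, sd)` per covariate on
#'   the original scale; filled by [standardize_covariates()].
#'
#' @return An object of class `covariate_set`.
#' @export
covariate_set <- function(site = tibble::tibble(),
                          season_site = list(),
                          observation = list(),
                          standardization = list()) {
  site <- tibble::as_tibble(site)
  stopifnot(is.list(season_site), is.list(observation))
  if (length(season_site) && is.null(names(season_site)))
    stop("`season_site` must be a named list", call. = FALSE)
  if (length(observation) && is.null(names(observation)))
    stop("`observation` must be a named list", call. = FALSE)
  structure(
    list(site = site, season_site = season_site, observation = observation,
         standardization = standardization),
    class = "covariate_set"
  )
}

#' @export
print.covariate_set <- function(x, ...) {
  cat("<covariate_set>\n",
      "  site:        ", paste(names(x$site), collapse = ", "), "\n",
      "  season-site: ", paste(names(x$season_site), collapse = ", "), "\n",
      "  observation: ", paste(names(x$observation), collapse = ", "), "\n",
      "  standardized: ", paste(names(x$standardization), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

covariate_names <- function(covs) {
  c(names(covs$site), names(covs$season_site), names(covs$observation))
}

covariate_kind <- function(covs, name) {
  if (name %in% names(covs$site)) return("site")
  if (name %in% names(covs$season_site)) return("season_site")
  if (name %in% names(covs$observation)) return("observation")
  stop("unknown covariate: ", name, call. = FALSE)
}

#' Standardize continuous covariates to mean 0, SD 1
#'
#' Centers and scales every continuous covariate (numeric site columns,
#' season-site matrices, observation arrays) using the sample mean and
#' sample SD over all values entering the model; for wet-season-only
#' species, call this *after* [subset_seasons()] so the scaling support
#' matches the fitted data. Categorical (factor) covariates are left
#' untouched. The original `(mean, sd)` pairs are stored so effect plots
#' can be back-transformed. Already-standardized columns pass through
#' unchanged up to floating-point tolerance, so the operation is
#' idempotent.
#'
#' @param covs A [covariate_set()].
#' @param exclude Character vector of covariate names to leave on their
#'   original scale.
#' @return A `covariate_set` with standardized continuous covariates and
#'   populated `standardization` metadata.
#' @examples
#' cs <- covariate_set(site = tibble::tibble(x = c(1, 2, 3)))
#' standardize_covariates(cs)$site$x  # -1, 0, 1
#' @export
standardize_covariates <- function(covs, exclude = character()) {
  stopifnot(inherits(covs, "covariate_set"))
  std <- covs$standardization

  scale_vec <- function(v, nm) {
    m <- mean(v, na.rm = TRUE)
    s <- sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("covariate '", nm, "' has zero variance and cannot be standardized",
           call. = FALSE)
    }
    std[[nm]] <<- c(mean = m, sd = s)
    (v - m) / s
  }

  for (nm in setdiff(names(covs$site), exclude)) {
    if (is.numeric(covs$site[[nm]])) {
      covs$site[[nm]] <- scale_vec(covs$site[[nm]], nm)
    }
  }
  for (nm in setdiff(names(covs$season_site), exclude)) {
    x <- covs$season_site[[nm]]
    covs$season_site[[nm]][] <- scale_vec(as.vector(x), nm)
  }
  for (nm in setdiff(names(covs$observation), exclude)) {
    x <- covs$observation[[nm]]
    covs$observation[[nm]][] <- scale_vec(as.vector(x), nm)
  }
  covs$standardization <- std
  covs
}
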