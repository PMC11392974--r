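#' Specify a candidate multi-season occupancy model
#'
#' A model spec names the covariates acting on each of the four model
#' parameters: first-season occupancy (`phi1`), colonization (`gamma`),
#' extinction (`eps`) and detection (`p`). State parameters follow the
#' univariate rule — at most one covariate each — and colonization and
#' extinction are never covaried in the same model (one of them stays
#' constant), reflecting the small number of sites relative to the
#' parameter count these models can otherwise accumulate.
#'
#' @param phi1,gamma,eps `NULL` (intercept only) or a single covariate name.
#' @param p Character vector of detection covariate names (may include the
#'   special term `"Season"`, a categorical effect of primary period), or
#'   `NULL` for constant detection.
#' @param species Species label the model applies to.
#' @param seasons_used Ordered labels of the seasons entering the model, or
#'   `NULL` for all seasons in the design.
#' @param label Optional model id; a compact default is derived from the
#'   terms.
#'
#' @return An object of class `occu_spec`.
#' @examples
#' occu_spec(phi1 = "TPROD", eps = "Graz", p = c("Season", "Feat"))
#' @export
occu_spec <- function(phi1 = NULL, gamma = NULL, eps = NULL, p = NULL,
                      species = "species", seasons_used = NULL,
                      label = NULL) {
  chk1 <- function(x, what) {
    if (!is.null(x) && length(x) > 1) {
      stop("univariate rule: at most one covariate on ", what, call. = FALSE)
    }
    x
  }
  phi1 <- chk1(phi1, "phi1")
  gamma <- chk1(gamma, "gamma")
  eps <- chk1(eps, "eps")
  if (!is.null(gamma) && !is.null(eps)) {
    stop("colonization and extinction must not carry covariates ",
         "simultaneously in one model", call. = FALSE)
  }
  if (is.null(label)) {
    fmt <- function(x) if (is.null(x) || !length(x)) "." else
      paste(x, collapse = "+")
    label <- paste0("phi(", fmt(phi1), ")g(", fmt(gamma), ")e(", fmt(eps),
                    ")p(", fmt(p), ")")
  }
  structure(
    list(phi1_terms = phi1, gamma_terms = gamma, eps_terms = eps,
         p_terms = p, species = species, seasons_used = seasons_used,
         label = label),
    class = "occu_spec"
  )
}

#' @export
print.occu_spec <- function(x, ...) {
  cat("<occu_spec> ", x$label, " [", x$species, "]\n", sep = "")
  invisible(x)
}

#' Named parameter vector for a model spec
#'
#' Expands a spec into the flat, named coefficient vector the likelihood
#' and samplers work with: an intercept plus reference-coded slopes for
#' each of `phi1`, `gamma`, `eps`, `p`, on the logit scale.
#'
#' @param spec An [occu_spec()].
#' @param covs A [covariate_set()] (needed to expand factor levels).
#' @param design A [survey_design()] (needed for the `Season` term).
#' @return Character vector of parameter names in likelihood order.
#' @export
param_names <- function(spec, covs, design) {
  design <- restrict_design(design, spec$seasons_used)
  unlist(lapply(c("phi1", "gamma", "eps", "p"), function(block) {
    terms <- spec[[paste0(block, "_terms")]]
    cols <- c("(Intercept)",
              unlist(lapply(terms, term_colnames, covs = covs,
                            design = design)))
    paste0(block, "_", cols)
  }), use.names = FALSE)
}

term_colnames <- function(term, covs, design) {
  if (term == "Season") {
    lab <- design$seasons$label
    if (length(lab) < 2) return(character())
    return(paste0("Season", lab[-1]))
  }
  kind <- covariate_kind(covs, term)
  v <- switch(kind,
    site = covs$site[[term]],
    season_site = covs$season_site[[term]],
    observation = covs$observation[[term]]
  )
  if (is.factor(v)) paste0(term, levels(v)[-1]) else term
}

# Restrict a design to an ordered subset of its seasons.
restrict_design <- function(design, seasons_used) {
  if (is.null(seasons_used)) return(design)
  idx <- resolve_season(design, seasons_used)
  design$seasons <- design$seasons[idx, ]
  design
}
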