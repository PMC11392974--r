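#' Build design matrices for each model parameter
#'
#' Expands a model spec against a covariate set into the four design
#' matrices the likelihood uses, with reference-coded categorical terms
#' (first factor level is the reference; season `W20`-style labels use the
#' first season as reference).
#'
#' Row ordering conventions (all with site index moving fastest):
#' * `phi1`: one row per site.
#' * `gamma`, `eps`: one row per site x transition; the season-site
#'   covariate value attached to the transition `t -> t+1` is the value
#'   measured for season `t+1`'s preceding interval, i.e. column `t+1` of
#'   the season-site matrix (forestry interventions are recorded before
#'   each trapping season and grazing pressure over the interval leading
#'   into it).
#' * `p`: one row per site x occasion x season, matching the flattened
#'   `n x (T*K)` probability matrix used by the likelihood core.
#'
#' @param spec An [occu_spec()].
#' @param covs A [covariate_set()] whose seasons already match
#'   `spec$seasons_used` (see [subset_seasons()]).
#' @param design A [survey_design()].
#' @return A list of matrices `X_phi1`, `X_gamma`, `X_eps`, `X_p`, each
#'   carrying an intercept column, plus the restricted `design`.
#' @export
build_model_matrices <- function(spec, covs, design) {
  design <- restrict_design(design, spec$seasons_used)
  n <- design$n_sites
  T <- n_seasons(design)
  K <- design$n_occasions

  X_phi1 <- block_matrix(spec$phi1_terms, covs, design, n, "phi1")
  X_gamma <- block_matrix(spec$gamma_terms, covs, design,
                          n * max(T - 1, 0), "transition")
  X_eps <- block_matrix(spec$eps_terms, covs, design,
                        n * max(T - 1, 0), "transition")
  X_p <- block_matrix(spec$p_terms, covs, design, n * K * T, "p")
  list(X_phi1 = X_phi1, X_gamma = X_gamma, X_eps = X_eps, X_p = X_p,
       design = design)
}

# One design-matrix block: intercept + expanded covariate columns.
# context: "phi1" (per site), "transition" (site x transition, site
# fastest), "p" (site x occasion x season, site fastest, then occasion).
block_matrix <- function(terms, covs, design, n_rows, context) {
  X <- matrix(1, n_rows, 1, dimnames = list(NULL, "(Intercept)"))
  for (term in terms) {
    v <- term_values(term, covs, design, context)
    if (is.factor(v)) {
      mm <- stats::model.matrix(~v)[, -1, drop = FALSE]
      colnames(mm) <- paste0(term, levels(v)[-1])
      X <- cbind(X, mm)
    } else {
      X <- cbind(X, matrix(v, ncol = 1, dimnames = list(NULL, term)))
    }
  }
  X
}

term_values <- function(term, covs, design, context) {
  n <- design$n_sites
  T <- n_seasons(design)
  K <- design$n_occasions

  if (term == "Season") {
    if (context != "p") {
      stop("'Season' is a detection-only term", call. = FALSE)
    }
    lab <- design$seasons$label
    return(factor(rep(lab, each = n * K), levels = lab))
  }

  kind <- covariate_kind(covs, term)
  if (kind == "site") {
    v <- covs$site[[term]]
    stopifnot(length(v) == n)
    switch(context,
      phi1 = v,
      transition = rep_vec(v, times = max(T - 1, 0)),
      p = rep_vec(v, times = T * K))
  } else if (kind == "season_site") {
    m <- covs$season_site[[term]]
    if (!all(dim(m) == c(n, T))) {
      stop("season-site covariate '", term, "' must be ", n, " x ", T,
           call. = FALSE)
    }
    switch(context,
      phi1 = stop("season-site covariate '", term,
                  "' cannot model first-season occupancy", call. = FALSE),
      # transition t -> t+1 carries the value for season t+1
      transition = as.vector(m[, -1, drop = FALSE]),
      p = as.vector(m[, rep(seq_len(T), each = K), drop = FALSE]))
  } else {  # observation
    a <- covs$observation[[term]]
    if (!all(dim(a) == c(n, T, K))) {
      stop("observation covariate '", term, "' must be ", n, " x ", T,
           " x ", K, call. = FALSE)
    }
    if (context != "p") {
      stop("observation covariate '", term,
           "' can only model detection", call. = FALSE)
    }
    v <- as.vector(aperm(a, c(1, 3, 2)))  # site, occasion, season order
    v[is.na(v)] <- 0  # NA effort rows pair with NA detections; inert
    v
  }
}

rep_vec <- function(v, times) {
  if (is.factor(v)) {
    factor(rep(as.character(v), times = times), levels = levels(v))
  } else {
    rep(v, times = times)
  }
}

#' Per-parameter probabilities from a coefficient vector
#'
#' Applies the inverse-logit link to each block's linear predictor.
#'
#' @param spec An [occu_spec()].
#' @param theta Coefficient vector in [param_names()] order.
#' @param covs A [covariate_set()].
#' @param design A [survey_design()].
#' @return A list with `phi1` (length n), `gamma` and `eps`
#'   (n x (T-1) matrices), and `p` (n x (T*K) matrix, column `(t-1)K + k`).
#' @examples
#' # all-zero coefficients give probability 0.5 everywhere
#' @export
linear_predictors <- function(spec, theta, covs, design) {
  Xs <- build_model_matrices(spec, covs, design)
  design <- Xs$design
  n <- design$n_sites
  T <- n_seasons(design)
  K <- design$n_occasions
  th <- split_theta(theta, Xs)
  list(
    phi1 = plogis(drop(Xs$X_phi1 %*% th$phi1)),
    gamma = matrix(plogis(drop(Xs$X_gamma %*% th$gamma)), n,
                   max(T - 1, 0)),
    eps = matrix(plogis(drop(Xs$X_eps %*% th$eps)), n, max(T - 1, 0)),
    p = matrix(plogis(drop(Xs$X_p %*% th$p)), n, T * K)
  )
}

split_theta <- function(theta, Xs) {
  d <- c(phi1 = ncol(Xs$X_phi1), gamma = ncol(Xs$X_gamma),
         eps = ncol(Xs$X_eps), p = ncol(Xs$X_p))
  if (length(theta) != sum(d)) {
    stop("theta has length ", length(theta), ", expected ", sum(d),
         call. = FALSE)
  }
  ends <- cumsum(d)
  starts <- c(1, head(ends, -1) + 1)
  list(phi1 = theta[starts[1]:ends[1]],
       gamma = theta[starts[2]:ends[2]],
       eps = theta[starts[3]:ends[3]],
       p = theta[starts[4]:ends[4]])
}

#' Marginal log-likelihood of each site's detection history
#'
#' Computes, per site, the exact likelihood of the observed multi-season
#' detection history with the latent occupancy state marginalized out by a
#' forward recursion: the state starts at `(1 - phi1, phi1)`, each season
#' multiplies in the Bernoulli emission of that season's non-missing
#' occasions (an empty season contributes factor 1), and transitions apply
#' the colonization/extinction matrix
#' `[[1 - gamma, gamma], [eps, 1 - eps]]`. Missing occasions (effort < 1
#' day) are marginalized out. A detection at a site whose every latent
#' path has probability zero yields `-Inf`, not an error.
#'
#' @param spec An [occu_spec()].
#' @param theta Coefficient vector in [param_names()] order.
#' @param history A `detection_history` (see [build_detection_history()]).
#' @param covs A [covariate_set()].
#' @return Numeric vector of per-site log-likelihood contributions; their
#'   sum is the joint log-likelihood of the independent-sites model.
#' @export
pointwise_loglik <- function(spec, theta, history, covs) {
  probs <- linear_predictors(spec, theta, covs, history$design)
  loglik_from_probs(probs, history)
}

# Shared core: evaluate the forward recursion given probability arrays.
loglik_from_probs <- function(probs, history) {
  ym <- flatten_y(history$y)
  T <- dim(history$y)[2]
  K <- dim(history$y)[3]
  forward_loglik_cpp(probs$phi1, probs$gamma, probs$eps, probs$p, ym, T, K)
}

flatten_y <- function(y) {
  n <- dim(y)[1]
  m <- matrix(as.integer(aperm(y, c(1, 3, 2))), n, dim(y)[2] * dim(y)[3])
  m
}

#' Derived seasonal occupancy from first-season occupancy and dynamics
#'
#' Under the original dynamic-occupancy parameterization only first-season
#' occupancy is a free parameter; later seasons follow the recursion
#' `phi[, t+1] = phi[, t] * (1 - eps[, t]) + (1 - phi[, t]) * gamma[, t]`.
#'
#' @param phi1 First-season occupancy probabilities, length n.
#' @param gamma,eps Colonization / extinction probabilities, n x (T-1).
#' @return A matrix n x T of per-site, per-season occupancy probabilities;
#'   the per-season mean over sites is in `attr(, "season_mean")`.
#' @examples
#' derived_occupancy(0.5, matrix(0.3), matrix(0.2))  # season 2: 0.55
#' @export
derived_occupancy <- function(phi1, gamma, eps) {
  gamma <- as.matrix(gamma)
  eps <- as.matrix(eps)
  n <- length(phi1)
  T <- ncol(gamma) + 1
  phi <- matrix(NA_real_, n, T)
  phi[, 1] <- phi1
  for (t in seq_len(T - 1)) {
    phi[, t + 1] <- phi[, t] * (1 - eps[, t]) + (1 - phi[, t]) * gamma[, t]
  }
  structure(phi, season_mean = colMeans(phi))
}

#' Log-density of the weakly informative prior
#'
#' Independent standard Logistic(0, 1) priors on every intercept and
#' regression coefficient (logit scale), the customary weakly informative
#' choice for probability-type occupancy parameters.
#'
#' @param theta Coefficient vector.
#' @return Scalar log prior density.
#' @examples
#' log_prior(0)  # log(1/4)
#' @export
log_prior <- function(theta) {
  sum(dlogis(theta, 0, 1, log = TRUE))
}

#' Log-density of the Gamma(1,1) prior for random-effect standard deviations
#'
#' The model family reserves Gamma(1,1) priors for random-effect standard
#' deviations; no candidate model in the default set includes random
#' effects, so this density is provided for completeness of the prior
#' specification.
#'
#' @param sigma Positive standard deviations.
#' @return Scalar log prior density (`-Inf` for non-positive values).
#' @export
log_prior_sd <- function(sigma) {
  sum(stats::dgamma(sigma, shape = 1, rate = 1, log = TRUE))
}
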