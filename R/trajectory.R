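#' Posterior seasonal occupancy trajectory
#'
#' Pushes each posterior (or model-averaged mixture) draw through the
#' occupancy recursion — first-season occupancy, then
#' `phi[t+1] = phi[t](1 - eps[t]) + (1 - phi[t]) gamma[t]` — averages the
#' per-site occupancy over sites within each draw, and summarizes the
#' resulting draws per season. This is the averaging order used for
#' seasonal mean-occupancy figures: sites first, then posterior
#' uncertainty.
#'
#' @param object An `occu_fit` or `averaged_posterior`.
#' @param covs The standardized [covariate_set()] the model was fitted
#'   with.
#' @param design The [survey_design()] (already restricted to the seasons
#'   used, as in `fit$design`).
#' @param max_draws Cap on the number of draws pushed through (draws are
#'   subsampled deterministically beyond it).
#' @param ... Unused.
#' @return A tibble with `season`, `estimate` (posterior mean of the
#'   across-site mean occupancy), `conf.low`, `conf.high` (95% credible
#'   interval).
#' @export
occupancy_trajectory <- function(object, covs, design, max_draws = 2000,
                                 ...) {
  UseMethod("occupancy_trajectory")
}

#' @export
occupancy_trajectory.occu_fit <- function(object, covs, design,
                                          max_draws = 2000, ...) {
  trajectory_from_draws(object$draws, object$spec, covs, design, max_draws)
}

#' @export
occupancy_trajectory.averaged_posterior <- function(object, covs, design,
                                                    max_draws = 2000, ...) {
  uspec <- union_spec(object$specs)
  trajectory_from_draws(object$draws, uspec, covs, design, max_draws)
}

# A spec carrying the union of every candidate's terms. Built without the
# univariate-rule validation: it is only ever evaluated on mixture draws
# whose absent coefficients are exactly zero, where it reproduces each
# candidate model's predictor.
union_spec <- function(specs) {
  u <- function(field) {
    unique(unlist(lapply(specs, function(s) s[[field]])))
  }
  structure(
    list(phi1_terms = u("phi1_terms"), gamma_terms = u("gamma_terms"),
         eps_terms = u("eps_terms"), p_terms = u("p_terms"),
         species = specs[[1]]$species,
         seasons_used = specs[[1]]$seasons_used,
         label = "union"),
    class = "occu_spec"
  )
}

trajectory_from_draws <- function(draws, spec, covs, design, max_draws) {
  Xs <- build_model_matrices(spec, covs, design)
  design <- Xs$design
  nms <- param_names(spec, covs, design)
  # align draw columns to the spec's parameter order; absent terms are 0
  th <- matrix(0, nrow(draws), length(nms), dimnames = list(NULL, nms))
  common <- intersect(colnames(draws), nms)
  th[, common] <- draws[, common, drop = FALSE]
  if (nrow(th) > max_draws) {
    th <- th[round(seq(1, nrow(th), length.out = max_draws)), ,
             drop = FALSE]
  }
  D <- nrow(th)
  n <- design$n_sites
  T <- n_seasons(design)
  sp <- split_theta_matrix(th, Xs)
  phi <- plogis(Xs$X_phi1 %*% t(sp$phi1))          # n x D
  occ <- matrix(NA_real_, D, T)
  occ[, 1] <- colMeans(phi)
  if (T > 1) {
    gam <- plogis(Xs$X_gamma %*% t(sp$gamma))      # n(T-1) x D
    eps <- plogis(Xs$X_eps %*% t(sp$eps))
    for (t in seq_len(T - 1)) {
      rows <- (t - 1) * n + seq_len(n)
      phi <- phi * (1 - eps[rows, , drop = FALSE]) +
        (1 - phi) * gam[rows, , drop = FALSE]
      occ[, t + 1] <- colMeans(phi)
    }
  }
  q <- apply(occ, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  tibble::tibble(
    season = design$seasons$label,
    estimate = colMeans(occ),
    conf.low = q[1, ],
    conf.high = q[2, ]
  )
}

# split a draws matrix (rows = draws) into per-block column sets
split_theta_matrix <- function(th, Xs) {
  d <- c(ncol(Xs$X_phi1), ncol(Xs$X_gamma), ncol(Xs$X_eps), ncol(Xs$X_p))
  ends <- cumsum(d)
  starts <- c(1, head(ends, -1) + 1)
  list(phi1 = th[, starts[1]:ends[1], drop = FALSE],
       gamma = th[, starts[2]:ends[2], drop = FALSE],
       eps = th[, starts[3]:ends[3], drop = FALSE],
       p = th[, starts[4]:ends[4], drop = FALSE])
}
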