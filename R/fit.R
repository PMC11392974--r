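#' Maximum a-posteriori coefficients
#'
#' Deterministically maximizes log-likelihood + log-prior by quasi-Newton
#' (BFGS) from a given start; used to initialize MCMC chains and for fast
#' tests. Same start and tolerance give the same output.
#'
#' @param spec An [occu_spec()].
#' @param history A [detection_history()].
#' @param covs A standardized [covariate_set()].
#' @param start Starting coefficient vector, or `NULL` for all zeros (the
#'   logistic prior mode).
#' @param tol Relative convergence tolerance passed to [stats::optim()].
#' @param maxit Iteration cap.
#' @return Named coefficient vector at the posterior mode, with the
#'   attained log-posterior in `attr(, "value")`.
#' @export
fit_map <- function(spec, history, covs, start = NULL, tol = 1e-10,
                    maxit = 500) {
  nms <- param_names(spec, covs, history$design)
  if (is.null(start)) start <- rep(0, length(nms))
  Xs <- build_model_matrices(spec, covs, history$design)
  ym <- flatten_y(history$y)
  T <- dim(history$y)[2]
  K <- dim(history$y)[3]
  negpost <- function(th) {
    pr <- probs_from_theta(th, Xs)
    -(sum(forward_loglik_cpp(pr$phi1, pr$gamma, pr$eps, pr$p, ym, T, K)) +
        log_prior(th))
  }
  res <- optim(start, negpost, method = "BFGS",
               control = list(maxit = maxit, reltol = tol))
  if (res$convergence != 0) {
    stop("MAP optimization did not converge (code ", res$convergence,
         "); best log-posterior ", signif(-res$value, 6), " at theta = ",
         paste(signif(res$par, 4), collapse = ", "), call. = FALSE)
  }
  structure(stats::setNames(res$par, nms), value = -res$value)
}

# Deduplicate design-matrix rows; map is 0-based into the unique rows.
compress_rows <- function(X) {
  if (nrow(X) == 0) return(list(X = X, map = integer(0)))
  key <- do.call(paste, c(as.data.frame(X), sep = "\r"))
  u <- which(!duplicated(key))
  list(X = X[u, , drop = FALSE], map = match(key, key[u]) - 1L)
}

probs_from_theta <- function(theta, Xs) {
  design <- Xs$design
  n <- design$n_sites
  T <- n_seasons(design)
  K <- design$n_occasions
  th <- split_theta(theta, Xs)
  list(phi1 = plogis(drop(Xs$X_phi1 %*% th$phi1)),
       gamma = matrix(plogis(drop(Xs$X_gamma %*% th$gamma)), n,
                      max(T - 1, 0)),
       eps = matrix(plogis(drop(Xs$X_eps %*% th$eps)), n, max(T - 1, 0)),
       p = matrix(plogis(drop(Xs$X_p %*% th$p)), n, T * K))
}

#' Sample the posterior of a multi-season occupancy model
#'
#' Componentwise adaptive random-walk Metropolis targeting
#' likelihood x Logistic(0,1) priors, with the exact marginal likelihood
#' of each site's detection history evaluated by forward recursion.
#' Chains start from the posterior mode plus Gaussian jitter; per-
#' coordinate proposal scales adapt only during burn-in and are frozen
#' afterwards. The per-draw pointwise log-likelihood matrix is retained
#' in full (no thinning) because leave-one-out model comparison needs it.
#'
#' The default run configuration is three chains of 15,000 iterations
#' with 5,000 discarded as burn-in; reduced budgets are fine for checks
#' against deterministic oracles.
#'
#' @param spec An [occu_spec()].
#' @param history A [detection_history()].
#' @param covs A standardized [covariate_set()].
#' @param n_chains,n_iter,n_burn Chain count, iterations per chain, and
#'   burn-in discarded from each chain.
#' @param seed Integer seed; the fit is bit-reproducible given it.
#' @param init Optional start vector (defaults to the MAP, or zeros if
#'   the mode search fails).
#' @param init_jitter SD of the Gaussian jitter applied per chain.
#' @param init_scale Initial proposal SD.
#' @param target_accept Acceptance rate targeted during adaptation.
#' @param adapt_every Sweeps between scale updates during burn-in.
#' @return An object of class `occu_fit`: retained draws with chain
#'   labels, pointwise log-likelihood (draws x sites), split-chain
#'   R-hat per parameter, and a summary table (posterior mean, SD, 95%
#'   credible interval, and a significance flag that is `TRUE` iff the
#'   2.5% and 97.5% percentiles share a sign).
#' @export
fit_occu <- function(spec, history, covs, n_chains = 3, n_iter = 15000,
                     n_burn = 5000, seed = 1, init = NULL,
                     init_jitter = 0.1, init_scale = 0.5,
                     target_accept = 0.44, adapt_every = 50) {
  stopifnot(n_iter > n_burn, n_chains >= 1)
  set.seed(seed)
  nms <- param_names(spec, covs, history$design)
  d <- length(nms)
  Xs <- build_model_matrices(spec, covs, history$design)
  ym <- flatten_y(history$y)
  T <- dim(history$y)[2]
  K <- dim(history$y)[3]

  theta0 <- if (is.null(init)) {
    tryCatch(unname(fit_map(spec, history, covs)),
             error = function(e) rep(0, d))
  } else {
    stopifnot(length(init) == d)
    unname(init)
  }

  n_keep <- n_iter - n_burn
  draws <- matrix(NA_real_, n_chains * n_keep, d,
                  dimnames = list(NULL, nms))
  loglik <- matrix(NA_real_, n_chains * n_keep, history$design$n_sites)
  chain <- rep(seq_len(n_chains), each = n_keep)
  acc <- matrix(NA_real_, n_chains, d)
  # design matrices usually repeat rows (categorical detection terms,
  # site covariates replicated over occasions); the sampler works on the
  # unique rows with an index map
  cmp <- lapply(Xs[c("X_phi1", "X_gamma", "X_eps", "X_p")], compress_rows)
  for (ch in seq_len(n_chains)) {
    start <- theta0 + rnorm(d, 0, init_jitter)
    res <- mcmc_chain_cpp(cmp$X_phi1$X, cmp$X_gamma$X, cmp$X_eps$X,
                          cmp$X_p$X, cmp$X_phi1$map, cmp$X_gamma$map,
                          cmp$X_eps$map, cmp$X_p$map, ym,
                          history$design$n_sites,
                          T, K, start, n_iter, n_burn, init_scale,
                          target_accept, adapt_every)
    rows <- (ch - 1) * n_keep + seq_len(n_keep)
    draws[rows, ] <- res$draws
    loglik[rows, ] <- res$loglik
    acc[ch, ] <- res$accept_rate
  }
  if (all(acc == 0)) {
    stop("all proposals were rejected in every chain; the model is ",
         "likely degenerate for these data - consider reparameterizing ",
         "or simplifying the spec", call. = FALSE)
  }

  fit <- structure(
    list(spec = spec, draws = draws, chain = chain, n_chains = n_chains,
         n_iter = n_iter, n_burn = n_burn, loglik = loglik,
         accept_rate = acc, seed = seed, map = theta0,
         design = restrict_design(history$design, spec$seasons_used)),
    class = "occu_fit"
  )
  fit$rhat <- tryCatch(rhat(fit), error = function(e) {
    stats::setNames(rep(NA_real_, d), nms)
  })
  fit$summary <- posterior_summary(draws)
  fit
}

#' @export
print.occu_fit <- function(x, ...) {
  cat("<occu_fit> ", x$spec$label, "\n",
      "  ", x$n_chains, " chains x ", x$n_iter, " iterations (",
      x$n_burn, " burn-in); max R-hat ",
      signif(max(x$rhat, na.rm = TRUE), 4), "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Split-chain potential scale reduction factor
#'
#' Gelman-Rubin R-hat computed after splitting every chain in half, so
#' within-chain drift also registers as lack of convergence. The working
#' convergence rule for these models is R-hat < 1.1 for every parameter.
#'
#' @param x An `occu_fit`, or a draws matrix.
#' @param ... Unused, or `chain` (integer vector of chain labels per row)
#'   when `x` is a matrix.
#' @return Named vector of R-hat values, one per parameter.
#' @export
rhat <- function(x, ...) UseMethod("rhat")

#' @export
rhat.occu_fit <- function(x, ...) rhat(x$draws, chain = x$chain)

#' @rdname rhat
#' @param chain Integer vector of chain labels, one per draw row.
#' @export
rhat.matrix <- function(x, chain, ...) {
  stopifnot(length(chain) == nrow(x))
  n_chains <- length(unique(chain))
  if (n_chains < 2) {
    stop("R-hat needs at least 2 chains", call. = FALSE)
  }
  m <- min(table(chain))
  if (m < 4) stop("R-hat needs at least 4 draws per chain", call. = FALSE)
  half <- m %/% 2
  # split each chain into first/second half
  groups <- unlist(lapply(unique(chain), function(ch) {
    idx <- which(chain == ch)[seq_len(2 * half)]
    split(idx, rep(1:2, each = half))
  }), recursive = FALSE)
  nms <- colnames(x)
  out <- vapply(seq_len(ncol(x)), function(j) {
    means <- vapply(groups, function(idx) mean(x[idx, j]), numeric(1))
    vars <- vapply(groups, function(idx) var(x[idx, j]), numeric(1))
    W <- mean(vars)
    if (!is.finite(W) || W == 0) {
      stop("zero within-chain variance for parameter '",
           if (is.null(nms)) j else nms[j], "'", call. = FALSE)
    }
    B <- half * var(means)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, numeric(1))
  stats::setNames(out, nms)
}

# Posterior mean, SD, central 95% interval and the no-zero-overlap
# significance flag, per column of a draws matrix.
posterior_summary <- function(draws) {
  q <- apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  tibble::tibble(
    term = colnames(draws),
    estimate = unname(colMeans(draws)),
    std.error = unname(apply(draws, 2, sd)),
    conf.low = unname(q[1, ]),
    conf.high = unname(q[2, ]),
    significant = unname(q[1, ] > 0 | q[2, ] < 0)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of an occupancy fit
#'
#' @param x An `occu_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`
#'   (posterior mean), `std.error` (posterior SD), `conf.low`/`conf.high`
#'   (95% credible interval) and `significant` (interval excludes zero).
#' @export
tidy.occu_fit <- function(x, ...) x$summary

#' One-row model-level summary of an occupancy fit
#'
#' @param x An `occu_fit`.
#' @param ... Unused.
#' @return A tibble with the model label, draw counts, max R-hat and mean
#'   total log-likelihood over draws.
#' @export
glance.occu_fit <- function(x, ...) {
  tibble::tibble(
    model = x$spec$label,
    n_chains = x$n_chains,
    n_draws = nrow(x$draws),
    n_params = ncol(x$draws),
    max_rhat = max(x$rhat, na.rm = TRUE),
    mean_loglik = mean(rowSums(x$loglik))
  )
}
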