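#' Fit a generalized Pareto distribution to importance-ratio tails
#'
#' Empirical-Bayes profile-likelihood fit (Zhang & Stephens 2009) of the
#' generalized Pareto shape `k` and scale `sigma` to a sample of tail
#' exceedances. The shape estimate is the reliability diagnostic of
#' Pareto-smoothed importance sampling: `k < 0.5` means the smoothed
#' estimate is accurate, `k > 0.7` that importance sampling cannot give a
#' useful estimate.
#'
#' @param tail_values Positive exceedances over the tail threshold
#'   (at least 5 values).
#' @return A list with `k_hat`, `sigma_hat` and `degenerate` (`TRUE`,
#'   with `k_hat = -Inf`, when all tail values are equal so no tail shape
#'   exists).
#' @export
gpd_fit_tail <- function(tail_values) {
  x <- sort(as.numeric(tail_values))
  n <- length(x)
  if (n < 5) stop("need at least 5 tail values to fit the GPD",
                  call. = FALSE)
  if (any(x <= 0) || anyNA(x)) {
    stop("tail values must be positive and non-missing", call. = FALSE)
  }
  if (diff(range(x)) < .Machine$double.eps * max(x)) {
    return(list(k_hat = -Inf, sigma_hat = 0, degenerate = TRUE))
  }
  m <- 30 + floor(sqrt(n))
  j <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (j - 0.5))) / (3 * xstar)
  # profile log-likelihood over theta = -k/sigma; shape k > 0 is a heavy
  # tail (grid values all satisfy theta < 1/max(x))
  k_j <- vapply(theta, function(th) mean(log1p(-th * x)), numeric(1))
  l_j <- n * (log(-theta / k_j) - k_j - 1)
  w <- exp(l_j - max(l_j))
  w <- w / sum(w)
  theta_hat <- sum(theta * w)
  k_hat <- mean(log1p(-theta_hat * x))
  sigma_hat <- -k_hat / theta_hat
  list(k_hat = k_hat, sigma_hat = sigma_hat, degenerate = FALSE)
}

# GPD quantile function, shape k, scale sigma (location 0).
qgpd <- function(q, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-q) else sigma * expm1(-k * log1p(-q)) / k
}

#' PSIS leave-one-out cross-validation from a pointwise log-likelihood
#'
#' Computes the expected log pointwise predictive density (elpd) by
#' Pareto-smoothed importance sampling: per site, raw importance ratios
#' are the reciprocal likelihoods of the retained draws; the largest
#' `M = min(0.2 S, 3 sqrt(S))` ratios are replaced by quantiles of a
#' generalized Pareto distribution fitted to their exceedances, weights
#' are capped at `S^(3/4)` times the mean weight, and the pointwise elpd
#' is the weighted log predictive density. The fitted Pareto shape
#' `k_hat` is recorded per site as the reliability diagnostic.
#'
#' @param loglik Matrix of pointwise log-likelihoods, draws x sites
#'   (e.g. `fit$loglik` from [fit_occu()]); at least ~100 draws.
#' @return An object of class `loo_result`: `elpd_loo` (total),
#'   `pointwise` (tibble with `site`, `elpd`, `pareto_k`), `n_bad_k`
#'   (sites with `k_hat > 0.7`) and `se` (spread of the pointwise elpd).
#' @export
psis_loo <- function(loglik) {
  loglik <- as.matrix(loglik)
  S <- nrow(loglik)
  n <- ncol(loglik)
  bad <- which(!apply(is.finite(loglik), 2, all))
  if (length(bad)) {
    stop("non-finite log-likelihood for site(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  elpd <- numeric(n)
  pareto_k <- numeric(n)
  for (i in seq_len(n)) {
    lr <- -loglik[, i]
    lr <- lr - max(lr)
    if (diff(range(lr)) < 1e-12) {
      # constant likelihood across draws: weights are irrelevant
      elpd[i] <- loglik[1, i]
      pareto_k[i] <- -Inf
      next
    }
    ord <- order(lr)
    tail_idx <- ord[(S - M + 1):S]
    cut <- lr[ord[S - M]]
    exceed <- exp(lr[tail_idx]) - exp(cut)
    fit <- gpd_fit_tail(pmax(exceed, .Machine$double.xmin))
    lw <- lr
    if (!fit$degenerate) {
      qs <- qgpd((seq_len(M) - 0.5) / M, fit$k_hat, fit$sigma_hat)
      lw[tail_idx[order(lr[tail_idx])]] <- log(exp(cut) + qs)
    }
    pareto_k[i] <- fit$k_hat
    # cap smoothed weights at S^(3/4) times the mean weight
    lw_mean <- logsumexp(lw) - log(S)
    lw <- pmin(lw, lw_mean + 0.75 * log(S))
    elpd[i] <- logsumexp(lw + loglik[, i]) - logsumexp(lw)
  }
  structure(
    list(elpd_loo = sum(elpd),
         pointwise = tibble::tibble(site = seq_len(n), elpd = elpd,
                                    pareto_k = pareto_k),
         n_bad_k = sum(pareto_k > 0.7),
         se = sqrt(n * var(elpd))),
    class = "loo_result"
  )
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @export
print.loo_result <- function(x, ...) {
  cat("<loo_result> elpd_loo = ", signif(x$elpd_loo, 6), " (se ",
      signif(x$se, 3), "), ", x$n_bad_k, " site(s) with k_hat > 0.7\n",
      sep = "")
  invisible(x)
}

#' Rank candidate models by LOO predictive accuracy
#'
#' Models with any site's Pareto `k_hat > 0.7` are discarded (their LOO
#' estimate is unusable); survivors are sorted by decreasing `elpd_loo`
#' and their difference to the top model reported. When every surviving
#' difference is below 4 the models have similar predictive performance
#' and model averaging is indicated (`attr(, "average")` and the
#' `average` column).
#'
#' @param loos List of [psis_loo()] results.
#' @param labels Model labels (defaults to list names or indices).
#' @return A tibble with one row per model: `model`, `elpd_loo`, `se`,
#'   `max_k`, `n_bad_k`, `high_accuracy` (all `k_hat < 0.5`),
#'   `discarded`, `elpd_diff` (vs the best surviving model; `NA` for
#'   discarded models) and `average`, sorted with survivors first by
#'   decreasing elpd.
#' @export
rank_models <- function(loos, labels = NULL) {
  stopifnot(length(loos) >= 1)
  if (is.null(labels)) {
    labels <- names(loos)
    if (is.null(labels)) labels <- paste0("model", seq_along(loos))
  }
  tab <- dplyr::bind_rows(lapply(seq_along(loos), function(i) {
    l <- loos[[i]]
    tibble::tibble(
      model = labels[i],
      elpd_loo = l$elpd_loo,
      se = l$se,
      max_k = max(l$pointwise$pareto_k),
      n_bad_k = l$n_bad_k,
      high_accuracy = all(l$pointwise$pareto_k < 0.5),
      discarded = l$n_bad_k > 0
    )
  }))
  if (all(tab$discarded)) {
    stop("every candidate model was discarded (Pareto k_hat > 0.7); ",
         "re-run with more posterior draws", call. = FALSE)
  }
  tab <- dplyr::arrange(tab, .data$discarded, dplyr::desc(.data$elpd_loo))
  top <- tab$elpd_loo[!tab$discarded][1]
  tab$elpd_diff <- ifelse(tab$discarded, NA_real_, top - tab$elpd_loo)
  avg <- all(tab$elpd_diff[!tab$discarded] < 4)
  tab$average <- avg
  attr(tab, "average") <- avg
  tab
}

#' Stacking weights over candidate models
#'
#' Maximizes the leave-one-out log score of the stacked predictive
#' distribution, `sum_i log sum_m w_m exp(elpd[i, m])`, over the simplex
#' (stacking of predictive distributions). Optimization uses a softmax
#' reparameterization with BFGS from five fixed starts; symmetric
#' solutions (models with identical pointwise elpd) are resolved to
#' equal weights.
#'
#' @param pointwise_elpd Matrix, sites x models, of pointwise elpd values
#'   (from `psis_loo(...)$pointwise$elpd`).
#' @param labels Optional model labels.
#' @return An object of class `stacking_weights`: `weights` (simplex
#'   vector) and `objective` (attained total log score).
#' @export
stacking_weights <- function(pointwise_elpd, labels = NULL) {
  E <- as.matrix(pointwise_elpd)
  if (anyNA(E) || any(!is.finite(E))) {
    stop("pointwise elpd matrix must be finite", call. = FALSE)
  }
  m <- ncol(E)
  if (is.null(labels)) labels <- colnames(E)
  if (is.null(labels)) labels <- paste0("model", seq_len(m))
  if (m == 1) {
    return(structure(list(weights = stats::setNames(1, labels),
                          objective = sum(E)),
                     class = "stacking_weights"))
  }
  c_i <- apply(E, 1, max)
  R <- exp(E - c_i)  # sites x models, rescaled per site
  obj <- function(v) {
    w <- softmax(c(0, v))
    -sum(log(R %*% w) + c_i)
  }
  grad <- function(v) {
    w <- softmax(c(0, v))
    denom <- drop(R %*% w)
    dw <- -colSums(R / denom)  # d(-obj)/dw
    J <- (diag(m) - matrix(w, m, m, byrow = TRUE)) * w  # softmax Jacobian
    drop(dw %*% J)[-1]
  }
  starts <- c(list(rep(0, m - 1)),
              lapply(seq_len(min(4, m)), function(j) {
                v <- rep(-2, m - 1)
                if (j > 1) v[j - 1] <- 2
                v
              }))
  best <- NULL
  for (s in starts) {
    r <- tryCatch(optim(s, obj, grad, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12)),
                  error = function(e) NULL)
    if (!is.null(r) && (is.null(best) || r$value < best$value)) best <- r
  }
  w <- softmax(c(0, best$par))
  # tie rule: identical pointwise-elpd columns share their total weight
  groups <- match(apply(round(E, 8), 2, paste, collapse = ","),
                  unique(apply(round(E, 8), 2, paste, collapse = ",")))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    w[idx] <- sum(w[idx]) / length(idx)
  }
  w <- pmax(w, 0)
  w <- w / sum(w)
  structure(list(weights = stats::setNames(w, labels),
                 objective = -best$value),
            class = "stacking_weights")
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' @export
print.stacking_weights <- function(x, ...) {
  cat("<stacking_weights> log score ", signif(x$objective, 6), "\n",
      sep = "")
  print(round(x$weights, 4))
  invisible(x)
}

#' Mix posteriors of candidate models by stacking weights
#'
#' Draws a model index with probability equal to its weight, then a
#' uniform retained draw from that model's posterior. Coefficients absent
#' from the selected model contribute exactly 0, so a covariate carried
#' only by models with total weight `w` has at least `1 - w` of its
#' mixture draws at zero — which is why averaged credible intervals can
#' have an endpoint exactly at 0.
#'
#' @param fits List of [fit_occu()] results.
#' @param weights A [stacking_weights()] (or bare numeric simplex vector)
#'   aligned with `fits`.
#' @param n_out Number of mixture draws.
#' @param seed Integer seed.
#' @return An object of class `averaged_posterior`: `draws` (n_out x
#'   union of parameters), `model` (index drawn per row), `weights`, and
#'   `summary` in the same layout as [tidy.occu_fit()].
#' @export
average_posteriors <- function(fits, weights, n_out = 4000, seed = 1) {
  w <- if (inherits(weights, "stacking_weights")) weights$weights
       else weights
  stopifnot(length(w) == length(fits), all(w >= -1e-9))
  w <- pmax(w, 0)
  w <- w / sum(w)
  for (i in seq_along(fits)) {
    if (w[i] > 0 && (is.null(fits[[i]]$draws) || !nrow(fits[[i]]$draws))) {
      stop("model ", i, " has positive weight but no stored draws",
           call. = FALSE)
    }
  }
  set.seed(seed)
  all_names <- unique(unlist(lapply(fits, function(f) colnames(f$draws))))
  draws <- matrix(0, n_out, length(all_names),
                  dimnames = list(NULL, all_names))
  model_idx <- sample.int(length(fits), n_out, replace = TRUE, prob = w)
  for (mi in unique(model_idx)) {
    rows <- which(model_idx == mi)
    src <- fits[[mi]]$draws
    pick <- sample.int(nrow(src), length(rows), replace = TRUE)
    draws[rows, colnames(src)] <- src[pick, , drop = FALSE]
  }
  structure(
    list(draws = draws, model = model_idx, weights = w,
         specs = lapply(fits, function(f) f$spec),
         summary = posterior_summary(draws)),
    class = "averaged_posterior"
  )
}

#' @export
print.averaged_posterior <- function(x, ...) {
  cat("<averaged_posterior> ", nrow(x$draws), " mixture draws over ",
      length(x$weights), " model(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.averaged_posterior <- function(x, ...) x$summary
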