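# Independent oracles and small fixture builders used across the suite.

# Brute-force site likelihood: enumerate every latent occupancy path
# z in {0,1}^T and sum P(z) * P(y | z). p and y are T x K matrices
# (y may contain NA); gamma and eps have length T - 1.
enum_site_lik <- function(phi1, gamma, eps, p, y) {
  T <- nrow(y)
  K <- ncol(y)
  total <- 0
  for (bits in 0:(2^T - 1)) {
    z <- as.integer(intToBits(bits))[seq_len(T)]
    pz <- if (z[1] == 1) phi1 else 1 - phi1
    if (T > 1) {
      for (t in seq_len(T - 1)) {
        pz <- pz * if (z[t] == 1) {
          if (z[t + 1] == 1) 1 - eps[t] else eps[t]
        } else {
          if (z[t + 1] == 1) gamma[t] else 1 - gamma[t]
        }
      }
    }
    pe <- 1
    for (t in seq_len(T)) {
      for (k in seq_len(K)) {
        if (is.na(y[t, k])) next
        pe <- pe * if (z[t] == 1) {
          if (y[t, k] == 1) p[t, k] else 1 - p[t, k]
        } else {
          if (y[t, k] == 1) 0 else 1
        }
      }
    }
    total <- total + pz * pe
  }
  total
}

# Package forward recursion for a single site, from explicit probability
# matrices (T x K for p and y).
forward_site_ll <- function(phi1, gamma, eps, p, y) {
  T <- nrow(y)
  K <- ncol(y)
  dynoccu:::forward_loglik_cpp(
    phi1,
    matrix(gamma, 1, T - 1), matrix(eps, 1, T - 1),
    matrix(as.vector(t(p)), 1, T * K),
    matrix(as.integer(as.vector(t(y))), 1, T * K),
    T, K
  )
}

# Minimal design with T seasons of K occasions (5-day occasions).
make_design <- function(n_sites, T = 2, K = 2) {
  survey_design(n_sites = n_sites,
                season_labels = paste0("S", seq_len(T)),
                season_starts = as.Date("2020-01-01") + (seq_len(T) - 1) * 100,
                occasion_days = 5, n_occasions = K)
}

# Detection history from a y array; effort 5 where observed, 0 where NA.
make_history <- function(y, design, species = "sp") {
  eff <- array(ifelse(is.na(y), 0, 5), dim(y))
  detection_history(array(as.integer(y), dim(y)), eff, species, design)
}

empty_covs <- function() covariate_set()

# 2-D log-posterior grid integrator for the constant single-season model
# (logit phi1 = a, logit p = b): returns posterior means of a, b and the
# normalizing constant, by trapezoid-free simple Riemann summation on a
# fine grid. nd = detections per site, K occasions, all sites surveyed.
grid_posterior_2d <- function(nd, K, lim = 8, n_grid = 401) {
  a <- seq(-lim, lim, length.out = n_grid)
  b <- seq(-lim, lim, length.out = n_grid)
  phi <- plogis(a)
  tab <- table(nd)
  counts <- as.integer(tab)
  vals <- as.integer(names(tab))
  lp <- matrix(0, n_grid, n_grid)
  for (gi in seq_along(vals)) {
    d <- vals[gi]
    # per site: phi * p^d (1-p)^(K-d) + (1-phi) [d == 0]
    pb <- plogis(b)
    li <- outer(phi, pb^d * (1 - pb)^(K - d)) +
      outer(1 - phi, rep(as.numeric(d == 0), n_grid))
    lp <- lp + counts[gi] * log(li)
  }
  lp <- lp + outer(dlogis(a, log = TRUE), dlogis(b, log = TRUE), "+")
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  list(mean_a = sum(rowSums(w) * a), mean_b = sum(colSums(w) * b),
       mean_phi1 = sum(rowSums(w) * phi),
       sd_a = sqrt(sum(rowSums(w) * a^2) - sum(rowSums(w) * a)^2),
       sd_b = sqrt(sum(colSums(w) * b^2) - sum(colSums(w) * b)^2))
}

# Batch-means Monte-Carlo standard error for a (possibly autocorrelated)
# draw sequence, computed per chain and pooled.
mcse_batch <- function(x, chain, batches = 30) {
  bm <- unlist(lapply(split(x, chain), function(xs) {
    nb <- max(2, min(batches, floor(length(xs) / 20)))
    size <- floor(length(xs) / nb)
    vapply(seq_len(nb), function(b) {
      mean(xs[((b - 1) * size + 1):(b * size)])
    }, numeric(1))
  }))
  sd(bm) / sqrt(length(bm))
}

# A fake loo_result with prescribed elpd and Pareto-k values.
fake_loo <- function(pointwise_elpd, pareto_k) {
  structure(
    list(elpd_loo = sum(pointwise_elpd),
         pointwise = tibble::tibble(site = seq_along(pointwise_elpd),
                                    elpd = pointwise_elpd,
                                    pareto_k = pareto_k),
         n_bad_k = sum(pareto_k > 0.7),
         se = sqrt(length(pointwise_elpd) * stats::var(pointwise_elpd))),
    class = "loo_result"
  )
}

# A fake occu_fit carrying only named draws (enough for averaging tests).
fake_fit <- function(draws, spec = NULL) {
  structure(list(draws = draws, spec = spec), class = "occu_fit")
}
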