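test_that("hand-computable site likelihoods are exact", {
  # T = 1, K = 1, phi1 = 0.4, p = 0.5, y = 0:
  # L = 0.4 * 0.5 + 0.6 = 0.8
  ll <- forward_site_ll(0.4, numeric(0), numeric(0),
                        matrix(0.5, 1, 1), matrix(0L, 1, 1))
  expect_equal(ll, log(0.8), tolerance = 1e-12)
  # perfect detection with detections observed: L = phi1 exactly
  ll <- forward_site_ll(0.37, numeric(0), numeric(0),
                        matrix(1, 1, 2), matrix(c(1L, 1L), 1, 2))
  expect_equal(ll, log(0.37), tolerance = 1e-12)
  # impossible history (detection with phi1 = 0) gives -Inf, no error
  ll <- forward_site_ll(0, numeric(0), numeric(0),
                        matrix(0.5, 1, 1), matrix(1L, 1, 1))
  expect_identical(ll, -Inf)
})

test_that("forward recursion equals latent-state enumeration (oracle)", {
  set.seed(11)
  for (r in 1:1000) {
    T <- sample(1:4, 1)
    K <- sample(1:3, 1)
    phi1 <- runif(1)
    gam <- runif(max(T - 1, 0))
    eps <- runif(max(T - 1, 0))
    p <- matrix(runif(T * K), T, K)
    y <- matrix(rbinom(T * K, 1, 0.4), T, K)
    y[runif(T * K) < 0.2] <- NA
    expect_equal(forward_site_ll(phi1, gam, eps, p, y),
                 log(enum_site_lik(phi1, gam, eps, p, y)),
                 tolerance = 1e-10)
  }
})

test_that("likelihood normalizes over all possible histories", {
  set.seed(12)
  T <- 2; K <- 2
  grid <- as.matrix(expand.grid(rep(list(0:1), T * K)))
  for (r in 1:100) {
    phi1 <- runif(1); gam <- runif(1); eps <- runif(1)
    p <- matrix(runif(T * K), T, K)
    tot <- sum(apply(grid, 1, function(yy) {
      exp(forward_site_ll(phi1, gam, eps, p, matrix(yy, T, K, byrow = TRUE)))
    }))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("an NA occasion is identical to removing the observation", {
  set.seed(13)
  for (r in 1:50) {
    T <- sample(2:3, 1); K <- 3
    phi1 <- runif(1); gam <- runif(T - 1); eps <- runif(T - 1)
    p <- matrix(runif(T * K), T, K)
    y <- matrix(rbinom(T * K, 1, 0.4), T, K)
    y_na <- y; y_na[1, 2] <- NA
    # same model with occasion (1,2) absent: emulate by p = 0.5, y = NA
    # versus a K-1 layout for season 1 and full K elsewhere; the forward
    # recursion must treat NA as emission factor 1, so dropping the cell
    # from the enumeration oracle gives the same value
    expect_equal(forward_site_ll(phi1, gam, eps, p, y_na),
                 log(enum_site_lik(phi1, gam, eps, p, y_na)),
                 tolerance = 1e-12)
    # and the NA value cannot influence the likelihood
    y_na2 <- y_na
    expect_equal(forward_site_ll(phi1, gam, eps, p, y_na),
                 forward_site_ll(phi1, gam, eps, p, y_na2),
                 tolerance = 0)
  }
  # season entirely NA keeps the site in the likelihood via other seasons
  p <- matrix(0.3, 2, 2)
  y_all <- matrix(c(1L, 0L, NA, NA), 2, 2, byrow = TRUE)
  y_one <- matrix(c(1L, 0L), 1, 2)
  # with eps = gamma = 0 the latent state persists, so marginalizing an
  # empty second season equals the single-season likelihood
  expect_equal(forward_site_ll(0.4, 0, 0, p, y_all),
               forward_site_ll(0.4, numeric(0), numeric(0),
                               matrix(0.3, 1, 2), y_one),
               tolerance = 1e-12)
})

test_that("all-zero histories have likelihood non-increasing in phi1", {
  p <- matrix(0.4, 2, 3)
  y <- matrix(0L, 2, 3)
  lls <- vapply(seq(0.01, 0.99, by = 0.01), function(phi) {
    forward_site_ll(phi, 0.2, 0.3, p, y)
  }, numeric(1))
  expect_true(all(diff(lls) <= 1e-12))
})

test_that("linear predictors apply the inverse-logit to each block", {
  design <- make_design(3, T = 2, K = 2)
  covs <- covariate_set(
    site = tibble::tibble(x = c(-1, 0, 1)),
    season_site = list(g = matrix(c(0, 0, 0, 1, 1, 1), 3, 2))
  )
  spec <- occu_spec(phi1 = "x", eps = "g", p = "Season", species = "sp")
  nms <- param_names(spec, covs, design)
  expect_equal(nms, c("phi1_(Intercept)", "phi1_x", "gamma_(Intercept)",
                      "eps_(Intercept)", "eps_g", "p_(Intercept)",
                      "p_SeasonS2"))
  # all-zero coefficients: every probability is 0.5
  pr <- linear_predictors(spec, rep(0, 7), covs, design)
  expect_true(all(unlist(pr) == 0.5))
  # a slope of 0.51 at covariate value +1, zero intercept
  th <- stats::setNames(rep(0, 7), nms)
  th["phi1_x"] <- 0.51
  pr <- linear_predictors(spec, th, covs, design)
  expect_equal(pr$phi1, plogis(0.51 * c(-1, 0, 1)))
  expect_equal(pr$phi1[3], 0.6248065, tolerance = 1e-6)
  # transition covariate uses the season-(t+1) value: eps slope 1 with
  # g[, 2] = 1 gives plogis(1) for the single transition
  th2 <- stats::setNames(rep(0, 7), nms)
  th2["eps_g"] <- 1
  pr2 <- linear_predictors(spec, th2, covs, design)
  expect_equal(unname(pr2$eps[, 1]), rep(plogis(1), 3))
  # monotone in the intercept toward 0
  lows <- vapply(c(-2, -5, -10), function(b) {
    linear_predictors(spec, c(b, 0, 0, 0, 0, 0, 0), covs, design)$phi1[1]
  }, numeric(1))
  expect_true(all(diff(lows) < 0))
  expect_error(linear_predictors(occu_spec(phi1 = "nope"), rep(0, 5),
                                 covs, design),
               "unknown covariate")
})

test_that("pointwise log-likelihood is per-site and sums to the joint", {
  design <- make_design(6, T = 2, K = 2)
  set.seed(14)
  y <- array(rbinom(24, 1, 0.3), c(6, 2, 2))
  h <- make_history(y, design)
  covs <- empty_covs()
  spec <- occu_spec(species = "sp")
  th <- c(0.3, -0.2, 0.1, -0.5)
  pw <- pointwise_loglik(spec, th, h, covs)
  expect_length(pw, 6)
  # per-site values equal the single-site enumeration oracle
  pr <- linear_predictors(spec, th, covs, design)
  for (i in 1:6) {
    expect_equal(pw[i], log(enum_site_lik(
      pr$phi1[i], pr$gamma[i, ], pr$eps[i, ],
      matrix(pr$p[i, ], 2, 2, byrow = TRUE), y[i, , ]
    )), tolerance = 1e-10)
  }
  # permuting sites permutes the vector
  y_perm <- y[6:1, , , drop = FALSE]
  pw_perm <- pointwise_loglik(spec, th, make_history(y_perm, design), covs)
  expect_equal(pw_perm, rev(pw))
})

test_that("derived occupancy follows the recursion and its fixed point", {
  # one step: 0.5 * 0.8 + 0.5 * 0.3 = 0.55
  phi <- derived_occupancy(0.5, matrix(0.3), matrix(0.2))
  expect_equal(phi[1, 2], 0.55)
  # absorbing dynamics: constant trajectory
  phi <- derived_occupancy(c(0.2, 0.9), matrix(0, 2, 3), matrix(0, 2, 3))
  expect_true(all(phi == matrix(c(0.2, 0.9), 2, 4)))
  # stationary point: gamma = eps * phi / (1 - phi) at phi = 0.4, eps = 0.3
  phi <- derived_occupancy(0.4, matrix(0.2, 1, 5), matrix(0.3, 1, 5))
  expect_equal(as.vector(phi), rep(0.4, 6), tolerance = 1e-12)
  expect_equal(attr(phi, "season_mean"), rep(0.4, 6), tolerance = 1e-12)
})

test_that("the logistic prior density is correct and symmetric", {
  expect_equal(log_prior(0), log(1 / 4), tolerance = 1e-12)
  expect_equal(log_prior(c(0, 0)), 2 * log(1 / 4), tolerance = 1e-12)
  set.seed(15)
  th <- rnorm(6, 0, 2)
  expect_equal(log_prior(th), log_prior(-th), tolerance = 1e-12)
  expect_equal(log_prior_sd(1), dgamma(1, 1, 1, log = TRUE))
  expect_identical(log_prior_sd(-1), -Inf)
})
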