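test_that("the GPD tail fit recovers known shapes", {
  set.seed(61)
  # exponential tail is GPD with shape 0
  f <- gpd_fit_tail(rexp(10000))
  expect_lt(abs(f$k_hat), 0.05)
  # Pareto with shape 1 is far in the unusable region
  f <- gpd_fit_tail(1 / runif(10000) - 1)
  expect_gt(f$k_hat, 0.7)
  expect_lt(abs(f$k_hat - 1), 0.1)
  # bounded (uniform) tails give negative shape
  expect_lt(gpd_fit_tail(runif(10000))$k_hat, 0)
  expect_error(gpd_fit_tail(c(1, 2, 3, 4)), "at least 5")
  deg <- gpd_fit_tail(rep(2, 100))
  expect_true(deg$degenerate)
})

test_that("constant pointwise log-likelihood passes through PSIS unchanged", {
  ll <- matrix(rep(c(-1.3, -0.4, -2.2), each = 500), 500, 3)
  res <- psis_loo(ll)
  expect_equal(res$pointwise$elpd, c(-1.3, -0.4, -2.2))
  expect_equal(res$elpd_loo, sum(c(-1.3, -0.4, -2.2)))
  expect_equal(res$n_bad_k, 0)
})

test_that("duplicated sites get equal pointwise elpd", {
  set.seed(62)
  base <- rnorm(800, -1, 0.3)
  ll <- cbind(base, base, rnorm(800, -2, 0.4))
  res <- psis_loo(ll)
  expect_equal(res$pointwise$elpd[1], res$pointwise$elpd[2],
               tolerance = 1e-12)
})

test_that("non-finite log-likelihoods are rejected with the site named", {
  ll <- matrix(rnorm(100), 50, 2)
  ll[3, 2] <- -Inf
  expect_error(psis_loo(ll), "site\\(s\\) 2")
})

test_that("PSIS-LOO matches exact leave-one-site-out on a small model", {
  # constant single-season model: only (logit phi1, logit p) carry data
  set.seed(63)
  n <- 10; K <- 4
  d <- make_design(n, T = 1, K = K)
  y <- array(0L, c(n, 1, K))
  det <- c(2, 0, 1, 3, 0, 0, 4, 1, 0, 2)
  for (i in seq_len(n)) if (det[i] > 0) y[i, 1, seq_len(det[i])] <- 1L
  h <- make_history(y, d)
  fit <- fit_occu(occu_spec(species = "sp"), h, empty_covs(),
                  n_chains = 3, n_iter = 6000, n_burn = 2000, seed = 64)
  res <- psis_loo(fit$loglik)

  # exact LOO by 2-D quadrature: elpd_i = log E_{post(-i)}[L_i]
  gridv <- seq(-9, 9, length.out = 351)
  L <- matrix(1, length(gridv)^2, n)  # per-site likelihood on the grid
  ab <- expand.grid(a = gridv, b = gridv)
  phi <- plogis(ab$a); p <- plogis(ab$b)
  for (i in seq_len(n)) {
    L[, i] <- phi * p^det[i] * (1 - p)^(K - det[i]) +
      (1 - phi) * (det[i] == 0)
  }
  lprior <- dlogis(ab$a, log = TRUE) + dlogis(ab$b, log = TRUE)
  ll_full <- rowSums(log(L)) + lprior
  exact <- vapply(seq_len(n), function(i) {
    lw <- ll_full - log(L[, i])   # posterior without site i, unnormalized
    lw <- lw - max(lw)
    log(sum(exp(lw) * L[, i]) / sum(exp(lw)))
  }, numeric(1))
  expect_lt(abs(res$elpd_loo - sum(exact)), 0.3)
})

test_that("LOO elpd never beats the in-sample log score on average", {
  set.seed(65)
  worse <- 0
  for (r in 1:20) {
    d <- make_design(40, T = 2, K = 3)
    params <- true_parameters(
      occu_spec(species = "sp"),
      c("phi1_(Intercept)" = 0.4, "gamma_(Intercept)" = -0.7,
        "eps_(Intercept)" = -0.7, "p_(Intercept)" = 0))
    z <- simulate_dynamics(d, params, empty_covs(), seed = 650 + r)
    h <- simulate_detections(z, params, empty_covs(), d,
                             dropout_rate = 0, day_miss_prob = 0,
                             seed = 680 + r)
    fit <- fit_occu(occu_spec(species = "sp"), h, empty_covs(),
                    n_chains = 2, n_iter = 700, n_burn = 300,
                    seed = 700 + r)
    # in-sample pointwise log predictive density
    insample <- sum(vapply(seq_len(40), function(i) {
      m <- max(fit$loglik[, i])
      m + log(mean(exp(fit$loglik[, i] - m)))
    }, numeric(1)))
    if (psis_loo(fit$loglik)$elpd_loo > insample) worse <- worse + 1
  }
  expect_lte(worse, 2)  # optimism correction is non-positive in expectation
})

test_that("ranking applies the discard and averaging threshold rules", {
  mk <- function(elpd_total, kmax, n = 10) {
    fake_loo(rep(elpd_total / n, n), c(rep(0.1, n - 1), kmax))
  }
  # discard on any k > 0.7 (0.71 discarded, 0.69 kept)
  r <- rank_models(list(a = mk(-100, 0.69), b = mk(-90, 0.71)))
  expect_identical(r$discarded[r$model == "b"], TRUE)
  expect_identical(r$discarded[r$model == "a"], FALSE)
  expect_equal(r$model[1], "a")
  # high-accuracy annotation at k < 0.5
  expect_true(rank_models(list(x = mk(-10, 0.49)))$high_accuracy)
  expect_false(rank_models(list(x = mk(-10, 0.51)))$high_accuracy)
  expect_false(rank_models(list(x = mk(-10, 0.51)))$discarded)
  # averaging flag: all surviving differences < 4
  r2 <- rank_models(list(a = mk(-100, 0.1), b = mk(-102, 0.1)))
  expect_true(attr(r2, "average"))
  expect_equal(sort(r2$elpd_diff), c(0, 2))
  r3 <- rank_models(list(a = mk(-100, 0.1), b = mk(-110, 0.1)))
  expect_false(attr(r3, "average"))
  # boundary: a difference of exactly 4 does not average
  r4 <- rank_models(list(a = mk(-100, 0.1), b = mk(-104, 0.1)))
  expect_false(attr(r4, "average"))
  r5 <- rank_models(list(a = mk(-100, 0.1), b = mk(-103.99, 0.1)))
  expect_true(attr(r5, "average"))
  # discarded models do not affect the averaging decision
  r6 <- rank_models(list(a = mk(-100, 0.1), b = mk(-90, 0.9),
                         c = mk(-101, 0.2)))
  expect_true(attr(r6, "average"))
  expect_error(rank_models(list(a = mk(-10, 0.9))), "discarded")
})

test_that("stacking weights solve the simplex log-score problem", {
  # single model shortcut
  w <- stacking_weights(matrix(-1, 5, 1))
  expect_equal(unname(w$weights), 1)
  # dominant model: better at every site by 2 nats
  E <- cbind(a = rep(-1, 20), b = rep(-3, 20))
  w <- stacking_weights(E)
  expect_gt(w$weights[["a"]], 0.99)
  # tie: identical columns get equal weights
  E2 <- cbind(a = rnorm(15, -2), b = 0)
  E2[, 2] <- E2[, 1]
  w2 <- stacking_weights(E2)
  expect_equal(unname(w2$weights), c(0.5, 0.5), tolerance = 1e-8)
  # never worse than the best vertex
  set.seed(66)
  E3 <- matrix(rnorm(60, -2, 1), 20, 3)
  w3 <- stacking_weights(E3)
  vertex_best <- max(colSums(E3))
  expect_gte(w3$objective, vertex_best - 1e-6)
  expect_equal(sum(w3$weights), 1, tolerance = 1e-12)
  expect_true(all(w3$weights >= 0))
  expect_error(stacking_weights(cbind(c(1, NA))), "finite")
})

test_that("averaging zero-fills absent coefficients", {
  set.seed(67)
  fa <- fake_fit(cbind("phi1_(Intercept)" = rnorm(1000, 0.5, 0.1),
                       "phi1_x" = rnorm(1000, 1, 0.05) + 0.5))
  fb <- fake_fit(cbind("phi1_(Intercept)" = rnorm(1000, 0.4, 0.1)))
  avg <- average_posteriors(list(fa, fb), c(0.4, 0.6), n_out = 5000,
                            seed = 68)
  x <- avg$draws[, "phi1_x"]
  # at least 60% of mixture draws are exactly zero
  expect_gte(mean(x == 0), 0.55)
  s <- avg$summary
  expect_identical(s$conf.low[s$term == "phi1_x"], 0)
  expect_false(s$significant[s$term == "phi1_x"])
  # intercept present in both models mixes both posteriors
  expect_equal(mean(avg$draws[, "phi1_(Intercept)"]),
               0.4 * 0.5 + 0.6 * 0.4, tolerance = 0.02)
  # single model with weight 1 reproduces that model's posterior
  one <- average_posteriors(list(fa, fb), c(1, 0), n_out = 5000, seed = 69)
  expect_equal(mean(one$draws[, "phi1_x"]), 1.5, tolerance = 0.02)
  # equal weights over identical fits match the single-fit summary
  twin <- average_posteriors(list(fa, fa), c(0.5, 0.5), n_out = 5000,
                             seed = 70)
  expect_equal(mean(twin$draws[, "phi1_(Intercept)"]), 0.5,
               tolerance = 0.02)
  # positive weight without draws errors
  expect_error(average_posteriors(list(fa, fake_fit(NULL)), c(0.5, 0.5)),
               "no stored draws")
})
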