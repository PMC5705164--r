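make_toy_model <- function(n_per = 20, seed = 17, sigma_u = 1) {
  set.seed(seed)
  x <- runif(2 * n_per, -1.5, 1.5)
  u <- rnorm(2, 0, sigma_u)
  g <- rep(1:2, each = n_per)
  z <- rbinom(2 * n_per, 1, plogis(0.3 + 0.8 * x + u[g]))
  d <- tibble::tibble(ptt = sprintf("g%d", g), x = x, z = z)
  hbm_model(d, covariates = "x")
}

test_that("configuration objects validate their inputs", {
  expect_error(prior_spec(beta_var = -1), "> 0")
  expect_error(mcmc_config(n_iter = 15, thin = 10), "multiple")
  pp <- mcmc_config("paper")
  expect_equal(pp$n_chains, 4L)
  expect_equal(pp$n_adapt, 100000L)
  expect_equal(pp$n_iter %/% pp$thin, 50000L)
})

test_that("log posterior matches a term-by-term summation oracle", {
  mod <- make_toy_model(n_per = 5)
  beta <- c(0.2, -0.4); u <- c(0.5, -1.2); tau <- 0.7
  pr <- prior_spec()
  # independent oracle: plain dbinom / dnorm / dgamma sums, no shared code
  eta <- beta[1] + beta[2] * mod$X[, 2] + u[mod$g]
  oracle <- sum(dbinom(mod$z, 1, 1 / (1 + exp(-eta)), log = TRUE)) +
    sum(dnorm(beta, 0, sqrt(10), log = TRUE)) +
    sum(dnorm(u, 0, 1 / sqrt(tau), log = TRUE)) +
    dgamma(tau, 0.1, 0.01, log = TRUE)
  expect_equal(log_unnorm_posterior(mod, beta, u, tau, pr), oracle,
               tolerance = 1e-10)
  # beta = 0, u = 0: every success probability is exactly 1/2
  lp0 <- log_unnorm_posterior(mod, c(0, 0), c(0, 0), tau, pr)
  prior_part <- sum(dnorm(c(0, 0), 0, sqrt(10), log = TRUE)) +
    sum(dnorm(c(0, 0), 0, 1 / sqrt(tau), log = TRUE)) +
    dgamma(tau, 0.1, 0.01, log = TRUE)
  expect_equal(lp0 - prior_part, length(mod$z) * log(0.5), tolerance = 1e-12)
  # zero-row model: prior density only
  empty <- hbm_model(tibble::tibble(ptt = character(), x = numeric(),
                                    z = integer()), covariates = "x")
  expect_equal(log_unnorm_posterior(empty, beta, numeric(0), tau, pr),
               sum(dnorm(beta, 0, sqrt(10), log = TRUE)) +
                 dgamma(tau, 0.1, 0.01, log = TRUE))
  expect_error(log_unnorm_posterior(mod, beta, u, -1, pr), "tau")
  expect_error(log_unnorm_posterior(mod, c(NaN, 0), u, 1, pr), "finite")
})

test_that("sampler posterior means match a dense grid-integration oracle", {
  mod <- make_toy_model()
  pr <- prior_spec()
  cfg <- mcmc_config(n_chains = 4, n_adapt = 1500, n_burn = 1000,
                     n_iter = 12000, thin = 4, seed = 77)
  fit <- sample_posterior(mod, pr, cfg)
  sm <- summarize_posterior(fit)

  # Oracle: tau integrated analytically (gamma conjugacy), then brute-force
  # summation over a dense (beta0, beta1, u1, u2) grid.
  a <- pr$tau_shape; b <- pr$tau_rate; N <- 2
  gr_b0 <- seq(-3, 3.5, length.out = 55)
  gr_b1 <- seq(-2, 3.5, length.out = 55)
  gr_u <- seq(-4, 4, length.out = 55)
  x <- mod$X[, 2]; z <- mod$z; g <- mod$g
  # log-likelihood per (beta0, beta1) split by group as a function of u
  ll_bu <- function(b0, b1, rows) {
    eta0 <- b0 + b1 * x[rows]
    vapply(gr_u, function(u) {
      eta <- eta0 + u
      sum(z[rows] * eta - log(1 + exp(eta)))
    }, numeric(1))
  }
  tau_term <- function(u1, u2) {
    -(a + N / 2) * log(b + (u1^2 + u2^2) / 2)
  }
  TT <- outer(gr_u, gr_u, tau_term)
  tot_w <- 0; m_b0 <- 0; m_b1 <- 0
  for (i0 in seq_along(gr_b0)) {
    for (i1 in seq_along(gr_b1)) {
      l1 <- ll_bu(gr_b0[i0], gr_b1[i1], which(g == 1))
      l2 <- ll_bu(gr_b0[i0], gr_b1[i1], which(g == 2))
      lp <- outer(l1, l2, `+`) + TT +
        dnorm(gr_b0[i0], 0, sqrt(10), log = TRUE) +
        dnorm(gr_b1[i1], 0, sqrt(10), log = TRUE)
      w <- sum(exp(lp - 40))
      tot_w <- tot_w + w
      m_b0 <- m_b0 + w * gr_b0[i0]
      m_b1 <- m_b1 + w * gr_b1[i1]
    }
  }
  m_b0 <- m_b0 / tot_w; m_b1 <- m_b1 / tot_w

  # Monte-Carlo error from the spread of per-chain means
  ch_means <- apply(fit$draws[, , "B0"], 1, mean)
  se0 <- max(sd(ch_means) / sqrt(cfg$n_chains), 0.01)
  ch_means1 <- apply(fit$draws[, , "B1"], 1, mean)
  se1 <- max(sd(ch_means1) / sqrt(cfg$n_chains), 0.01)
  expect_lt(abs(sm$mean[sm$parameter == "B0"] - m_b0), 3 * se0 + 0.03)
  expect_lt(abs(sm$mean[sm$parameter == "B1"] - m_b1), 3 * se1 + 0.03)
})

test_that("the sampler is reproducible from its seed", {
  mod <- make_toy_model()
  cfg <- mcmc_config(n_chains = 2, n_adapt = 300, n_burn = 100,
                     n_iter = 1000, thin = 10, seed = 5)
  f1 <- sample_posterior(mod, config = cfg)
  f2 <- sample_posterior(mod, config = cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$acceptance, f2$acceptance)
})

test_that("gelman_rubin matches its definition and flags divergence", {
  set.seed(8)
  iid <- array(rnorm(4 * 2500 * 2), c(4, 2500, 2),
               dimnames = list(NULL, NULL, c("a", "b")))
  rh <- gelman_rubin(iid)
  expect_true(all(rh$rhat > 0.99 & rh$rhat < 1.02))
  # hand-computed classic formula on a tiny frozen array
  tiny <- array(c(1:10, 2:11) / 3, c(2, 10, 1),
                dimnames = list(NULL, NULL, "p"))
  ch <- tiny[, , 1]
  W <- mean(apply(ch, 1, var)); Bn <- var(rowMeans(ch)); n <- 10
  expect_equal(gelman_rubin(tiny)$rhat, sqrt(((n - 1) / n * W + Bn) / W))
  shifted <- iid; shifted[1, , 1] <- shifted[1, , 1] + 100
  expect_gt(gelman_rubin(shifted)$rhat[1], 5)
  expect_error(gelman_rubin(iid[1, , , drop = FALSE]), "2 chains")
  # chain relabelling changes nothing
  perm <- iid[c(3, 1, 4, 2), , , drop = FALSE]
  expect_equal(gelman_rubin(perm)$rhat, rh$rhat)
})

test_that("posterior summaries reduce to order statistics", {
  const <- array(4.2, c(2, 100, 1), dimnames = list(NULL, NULL, "c"))
  sm <- summarize_posterior(const)
  expect_equal(sm$mean, 4.2)
  expect_equal(sm$sd, 0)
  expect_equal(sm$q2.5, 4.2)
  expect_equal(sm$q97.5, 4.2)
  set.seed(2)
  x <- rnorm(1000)
  arr <- array(x, c(1, 1000, 1), dimnames = list(NULL, NULL, "x"))
  sm2 <- summarize_posterior(arr)
  # sort-based interpolation oracle for the type-7 quantile
  qs <- function(p) {
    s <- sort(x); h <- (length(x) - 1) * p + 1
    s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)])
  }
  expect_equal(sm2$q2.5, qs(0.025))
  expect_equal(sm2$q97.5, qs(0.975))
  expect_lt(abs(sm2$mean - median(x)), 0.1)
})

test_that("prior-predictive draws reproduce the prior and ignore the design", {
  mod <- make_toy_model()
  cfg <- mcmc_config(n_chains = 2, n_adapt = 100, n_burn = 100,
                     n_iter = 20000, thin = 2, seed = 12)
  pp <- run_priors_only(mod, config = cfg, mode = "prior_predictive")
  mdraws <- as.vector(pp$draws[, , "B1"])
  mtot <- length(mdraws)
  expect_lt(abs(mean(mdraws) - 0), 3 * sqrt(10 / mtot))
  expect_lt(abs(sd(mdraws) - sqrt(10)), 3 * sqrt(10) / sqrt(2 * mtot))
  # s = 1/sqrt(tau): check its distribution against the gamma prior
  s_draws <- as.vector(pp$draws[, , "s"])
  expect_gt(suppressWarnings(
    ks.test(1 / s_draws^2, pgamma, shape = 0.1, rate = 0.01))$p.value, 0.001)
  # different design matrix, same seed: identical draws
  mod2 <- make_toy_model(seed = 99)
  pp2 <- run_priors_only(mod2, config = cfg, mode = "prior_predictive")
  expect_identical(pp$draws, pp2$draws)
})

test_that("the literal priors-only variant feels the response it retains", {
  set.seed(30)
  d <- tibble::tibble(ptt = rep(c("a", "b"), each = 30),
                      x = rnorm(60), z = 0L)
  mod <- hbm_model(d, covariates = "x")
  cfg <- mcmc_config(n_chains = 2, n_adapt = 800, n_burn = 400,
                     n_iter = 4000, thin = 4, seed = 3)
  lit <- run_priors_only(mod, config = cfg, mode = "paper_literal")
  sm <- summarize_posterior(lit)
  sum_beta <- sum(sm$mean[sm$parameter %in% c("B0", "B1")])
  expect_lt(sum_beta, 0)  # all-zero responses push the summed logit down
})

test_that("prior influence is scored by density overlap and expands variances", {
  mod <- make_toy_model()
  pr <- prior_spec()
  mk_fit <- function(draws_vec, pn = c("B0", "B1")) {
    arr <- array(rep(draws_vec, length(pn)),
                 c(1, length(draws_vec), length(pn)),
                 dimnames = list(NULL, NULL, pn))
    structure(list(draws = arr, model = mod, priors = pr),
              class = "hbm_fit")
  }
  set.seed(6)
  x <- rnorm(4000)
  self <- prior_influence_check(mk_fit(x), mk_fit(x))
  expect_true(all(self$overlap > 0.9))
  expect_true(all(self$flagged))
  expect_equal(self$proposed_variance, self$variance * 10)
  # posterior N(0,1) against prior N(0,100): analytic overlap oracle
  set.seed(7)
  wide <- rnorm(4000, 0, 10)
  ovl_true <- integrate(function(t) pmin(dnorm(t, 0, 1), dnorm(t, 0, 10)),
                        -40, 40)$value
  expect_equal(ovl_true, 0.2018, tolerance = 1e-3)  # the analytic value
  chk <- prior_influence_check(mk_fit(x), mk_fit(wide))
  expect_lt(max(abs(chk$overlap - ovl_true)), 0.05)
  expect_false(any(chk$flagged))
  expect_equal(chk$proposed_variance, chk$variance)
  # widened priors propagate into a new spec
  newpr <- expand_flagged_priors(pr, self, param_names = c("B0", "B1"))
  expect_equal(newpr$beta_var, c(100, 100))
})
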