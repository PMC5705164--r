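test_that("simulated covariates honour the generator's structure", {
  cfg <- sim_config(n_individuals = 10, mean_locations = 120, seed = 15)
  covs <- simulate_covariates(cfg)
  expect_true(all(rowSums(covs[c("Spring", "Summer", "Fall", "Winter")]) == 1))
  # one constant length per individual
  per_ind <- tapply(covs$L, covs$ptt, function(x) length(unique(x)))
  expect_true(all(per_ind == 1))
  # tracks span at least a year
  spans <- tapply(as.integer(covs$date), covs$ptt, function(d) max(d) - min(d))
  expect_true(all(spans >= 300))
  # shared index: same value wherever two individuals share a date
  dup <- covs[duplicated(covs$date) | duplicated(covs$date, fromLast = TRUE), ]
  per_date <- tapply(dup$MEI_Index, as.character(dup$date),
                     function(x) diff(range(x)))
  expect_true(all(per_date == 0))
  # AR(1) stationary sd is 1; sample sd within 3 SE given the effective
  # sample size T (1 - phi) / (1 + phi)
  days <- sort(unique(covs$date))
  idx <- covs$MEI_Index[match(days, covs$date)]
  t_eff <- length(idx) * (1 - cfg$ar1_coef) / (1 + cfg$ar1_coef)
  expect_lt(abs(sd(idx) - 1), 3 / sqrt(2 * t_eff))
})

test_that("response frequencies follow the logistic model", {
  # beta = 0, sigma_u = 0: coin flips
  flat <- simulate_dataset(sim_config(n_individuals = 10,
                                      mean_locations = 200,
                                      beta = rep(0, 7), sigma_u = 0,
                                      seed = 19))
  n <- nrow(flat$data)
  expect_lt(abs(mean(flat$data$z) - 0.5), 3 * sqrt(0.25 / n))
  # strong summer effect: logistic(5) = 0.9933 conditional frequency
  summer <- simulate_dataset(sim_config(n_individuals = 10,
                                        mean_locations = 200,
                                        beta = c(0, 0, 5, 0, 0, 0, 0),
                                        sigma_u = 0, seed = 20))
  in_summer <- summer$data$z[summer$data$Summer == 1]
  expect_gt(mean(in_summer), 0.96)
  expect_gt(length(in_summer), 200)
})

test_that("the generator is reproducible and records its truth", {
  a <- small_sim(seed = 77)
  b <- small_sim(seed = 77)
  expect_identical(a$data, b$data)
  expect_identical(a$truth, b$truth)
  expect_named(a$truth$beta, paste0("B", 0:6))
  expect_length(a$truth$u, 8)
  # realized random intercepts scatter like sigma_u
  big <- simulate_dataset(sim_config(seed = 4))
  se_sd <- big$config$sigma_u / sqrt(2 * (34 - 1))
  expect_lt(abs(sd(big$truth$u) - big$config$sigma_u), 3 * se_sd)
})

test_that("recovery bookkeeping is exact with an oracle fitter", {
  cfg <- sim_config(n_individuals = 4, mean_locations = 20, seed = 5)
  truth_fitter <- function(data) {
    tibble::tibble(parameter = c(paste0("B", 0:6), "sigma_u"),
                   estimate = c(cfg$beta, cfg$sigma_u),
                   lower = estimate - 0.1, upper = estimate + 0.1)
  }
  rep <- recovery_study(cfg, n_datasets = 5, fitter = truth_fitter)
  expect_equal(nrow(rep), 8)
  expect_true(all(rep$bias == 0))
  expect_true(all(rep$rmse == 0))
  expect_true(all(rep$coverage == 1))
  expect_true(all(rep$n_fits == 5))
})

test_that("the Bayesian standard fitter returns a complete estimate table", {
  sim <- small_sim(n_ind = 5, mean_loc = 25, seed = 6, sigma_u = 1)
  fn <- standard_fitter("hier_bayes",
                        mcmc = mcmc_config(n_chains = 2, n_adapt = 400,
                                           n_burn = 200, n_iter = 2000,
                                           thin = 10, seed = 2))
  est <- fn(sim$data)
  expect_setequal(est$parameter, c(paste0("B", 0:6), "sigma_u"))
  expect_true(all(est$lower <= est$estimate & est$estimate <= est$upper))
  expect_gt(est$estimate[est$parameter == "sigma_u"], 0)
})
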