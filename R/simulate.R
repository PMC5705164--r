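#' Configuration for the synthetic telemetry generator
#'
#' Defines the study conditions the generator emulates: 34 tracked
#' individuals averaging ~278 retained locations each (about 9,440 rows),
#' every track spanning at least a year so all seasons occur; a constant
#' per-individual standardized body length; an even sex ratio; and a shared
#' slowly varying standardized climate index (daily AR(1), coefficient
#' 0.95) sampled at each location date. The binary response is drawn from
#' the logit-linear movement model with per-individual normal random
#' intercepts.
#'
#' The default truth (`beta`, `sigma_u`) is a fixture chosen to echo the
#' magnitudes a coastal/offshore movement analysis reports: intercept -1,
#' season contrasts 0.75 / -1 / 0 (Spring / Summer / Winter vs Fall),
#' length 1, sex 0.1, index -0.5, and individual-level sd 2.5.
#'
#' @param n_individuals Number of tracked individuals (>= 2).
#' @param mean_locations Mean retained locations per individual; realized
#'   counts are Poisson around this, truncated at 30.
#' @param beta True coefficients: intercept, Spring, Summer, Winter, L,
#'   sex, index.
#' @param sigma_u True random-intercept standard deviation (>= 0).
#' @param mean_gap_days Mean day gap between retained locations.
#' @param length_mean,length_sd Body-length distribution (cm) across
#'   individuals.
#' @param sex_ratio Probability an individual is male.
#' @param ar1_coef AR(1) coefficient of the daily index process.
#' @param start_year,span_years Calendar window deployments fall in.
#' @param seed RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals = 34, mean_locations = 278,
                       beta = c(-1, 0.75, -1, 0, 1, 0.1, -0.5),
                       sigma_u = 2.5, mean_gap_days = 2.08,
                       length_mean = 205, length_sd = 25,
                       sex_ratio = 0.5, ar1_coef = 0.95,
                       start_year = 2004, span_years = 10, seed = 1L) {
  if (n_individuals < 2) abort("n_individuals must be >= 2.")
  if (mean_locations < 1) abort("mean_locations must be >= 1.")
  if (sigma_u < 0) abort("sigma_u must be >= 0.")
  if (length(beta) != 7) abort("beta must have 7 entries (intercept + 6 slopes).")
  structure(
    list(n_individuals = as.integer(n_individuals),
         mean_locations = mean_locations, beta = beta, sigma_u = sigma_u,
         mean_gap_days = mean_gap_days, length_mean = length_mean,
         length_sd = length_sd, sex_ratio = sex_ratio, ar1_coef = ar1_coef,
         start_year = as.integer(start_year),
         span_years = as.integer(span_years), seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate the covariate table
#'
#' Generates dated per-individual records (season indicators derived from
#' the dates), one standardized length and one sex per individual, and a
#' shared standardized AR(1) index sampled by date. No response is drawn.
#'
#' @param config A [sim_config()].
#' @return Tibble with `ptt`, `date`, `sex`, season indicators, `L`,
#'   `MEI_Index`, contiguous by `ptt`.
#' @export
simulate_covariates <- function(config = sim_config()) {
  set.seed(config$seed)
  N <- config$n_individuals
  n_i <- pmax(30L, rpois(N, config$mean_locations))
  lengths_cm <- rnorm(N, config$length_mean, config$length_sd)
  L_std <- zscore(lengths_cm, name = "L")$values
  sex <- ifelse(runif(N) < config$sex_ratio, "M", "F")
  origin <- as.Date(sprintf("%d-01-01", config$start_year))
  starts <- origin + floor(runif(N, 0, 365.25 * config$span_years))
  per_ind <- lapply(seq_len(N), function(j) {
    # span >= 1 year; irregular day gaps, no interpolation
    span <- max(366, ceiling(n_i[j] * config$mean_gap_days))
    offs <- sort(sample.int(span, n_i[j]) - 1L)
    tibble(
      ptt = sprintf("sim%02d", j),
      date = starts[j] + offs,
      sex = sex[j],
      L = L_std[j]
    )
  })
  out <- bind_rows(per_ind)
  out <- dplyr::bind_cols(out, encode_season(out$date))
  # shared daily AR(1) index, standardized to unit stationary variance
  all_days <- seq(min(out$date), max(out$date), by = "day")
  nd <- length(all_days)
  phi <- config$ar1_coef
  innov_sd <- sqrt(1 - phi^2)
  idx <- numeric(nd)
  idx[1] <- rnorm(1)
  eps <- rnorm(nd - 1, 0, innov_sd)
  for (t in 2:nd) idx[t] <- phi * idx[t - 1] + eps[t - 1]
  out$MEI_Index <- idx[as.integer(out$date - min(out$date)) + 1L]
  out %>% select("ptt", "date", "sex", "Spring", "Summer", "Fall",
                 "Winter", "L", "MEI_Index")
}

#' Simulate a grouped binary movement dataset with known truth
#'
#' Draws per-individual random intercepts from Normal(0, sigma_u^2) and the
#' binary response from Bernoulli(logistic(beta . D + u)), on top of
#' [simulate_covariates()]. The generating parameters are recorded
#' alongside the table.
#'
#' @param config A [sim_config()].
#' @return A `sim_dataset`: list with `data` (analysis table including
#'   `z`) and `truth` (list `beta`, `sigma_u`, `u`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  covs <- simulate_covariates(config)
  N <- config$n_individuals
  u <- if (config$sigma_u > 0) rnorm(N, 0, config$sigma_u) else numeric(N)
  names(u) <- unique(covs$ptt)
  D <- cbind(1, covs$Spring, covs$Summer, covs$Winter, covs$L,
             as.integer(covs$sex == "M"), covs$MEI_Index)
  eta <- drop(D %*% config$beta) + u[covs$ptt]
  covs$z <- rbinom(nrow(covs), 1, plogis(eta))
  structure(
    list(data = covs,
         truth = list(beta = setNames(config$beta,
                                      c("B0", "B1", "B2", "B3", "B4", "B5", "B6")),
                      sigma_u = config$sigma_u, u = u),
         config = config),
    class = "sim_dataset"
  )
}

#' Parameter-recovery study
#'
#' Simulates `n_datasets` datasets from known truth, fits each with the
#' requested fitter, and aggregates per-parameter bias, RMSE and 95%
#' interval coverage — the standard check that the model machinery can
#' recover the parameters that generated the data.
#'
#' @param config A [sim_config()]; dataset seeds are derived from
#'   `config$seed`.
#' @param n_datasets Number of simulated datasets (>= 2).
#' @param fitter `"laplace"`, `"pql"`, `"hier_bayes"`, or a function taking
#'   an analysis table and returning a tibble with columns `parameter`
#'   (`B0..B6`, `sigma_u`), `estimate`, `lower`, `upper`.
#' @param mcmc An [mcmc_config()] used when `fitter = "hier_bayes"`.
#' @return A `recovery_report` tibble: per parameter `truth`, `bias`,
#'   `rmse`, `coverage`, `n_fits`; the per-dataset estimates are kept in
#'   the `estimates` attribute.
#' @export
recovery_study <- function(config = sim_config(), n_datasets = 100,
                           fitter = "laplace", mcmc = mcmc_config()) {
  if (n_datasets < 2) abort("n_datasets must be >= 2.")
  fit_fun <- standard_fitter(fitter, mcmc = mcmc)
  set.seed(config$seed)
  ds_seeds <- sample.int(.Machine$integer.max - 1L, n_datasets)
  truth_tbl <- tibble(
    parameter = c(names(sim_truth_beta(config)), "sigma_u"),
    truth = c(unname(sim_truth_beta(config)), config$sigma_u)
  )
  res <- vector("list", n_datasets)
  failures <- 0L
  for (d in seq_len(n_datasets)) {
    cfg_d <- config
    cfg_d$seed <- ds_seeds[d]
    sim <- simulate_dataset(cfg_d)
    est <- tryCatch(fit_fun(sim$data), error = function(e) NULL)
    if (is.null(est)) { failures <- failures + 1L; next }
    est$dataset <- d
    res[[d]] <- est
  }
  if (failures > 0.1 * n_datasets) {
    abort(paste0(failures, " of ", n_datasets, " fits failed (> 10%)."))
  }
  est_all <- bind_rows(res) %>% left_join(truth_tbl, by = "parameter")
  report <- est_all %>%
    group_by(.data$parameter) %>%
    summarise(
      truth = first(.data$truth),
      bias = mean(.data$estimate - .data$truth),
      rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
      coverage = mean(.data$lower <= .data$truth & .data$truth <= .data$upper),
      n_fits = dplyr::n(),
      .groups = "drop"
    )
  structure(report, class = c("recovery_report", class(report)),
            estimates = est_all, n_datasets = n_datasets,
            failures = failures, fitter = if (is.character(fitter)) fitter else "custom")
}

sim_truth_beta <- function(config) {
  setNames(config$beta, c("B0", "B1", "B2", "B3", "B4", "B5", "B6"))
}

#' Standard fitters usable by the experiments
#'
#' Resolves a fitter name into a function mapping an analysis table to a
#' tidy estimate table (`parameter`, `estimate`, `lower`, `upper`) covering
#' `B0..B6` and `sigma_u`. Intervals are Wald 95% for the likelihood
#' fitters and equal-tailed 95% credible intervals for the Bayesian fitter
#' (whose `sigma_u` row reports the posterior of s).
#'
#' @param fitter `"laplace"`, `"pql"`, `"hier_bayes"`, or a function
#'   (returned unchanged).
#' @param covariates,response,group Passed through to the model builders.
#' @param priors,mcmc Bayesian fitter settings.
#' @return A function of one argument (the analysis table).
#' @export
standard_fitter <- function(fitter,
                            covariates = c("Spring", "Summer", "Winter",
                                           "L", "sex", "MEI_Index"),
                            response = "z", group = "ptt",
                            priors = prior_spec(), mcmc = mcmc_config()) {
  if (is.function(fitter)) return(fitter)
  fitter <- match.arg(fitter, c("laplace", "pql", "hier_bayes"))
  bnames <- paste0("B", 0:length(covariates))
  if (fitter %in% c("laplace", "pql")) {
    fn <- if (fitter == "laplace") fit_laplace else fit_pql
    function(data) {
      ft <- fn(data, covariates = covariates, response = response,
               group = group)
      td <- tidy(ft)
      bind_rows(
        tibble(parameter = bnames, estimate = td$estimate,
               lower = td$conf.low, upper = td$conf.high),
        tibble(parameter = "sigma_u", estimate = ft$sigma_u,
               lower = NA_real_, upper = NA_real_)
      )
    }
  } else {
    function(data) {
      mod <- hbm_model(data, covariates = covariates, response = response,
                       group = group)
      ft <- sample_posterior(mod, priors = priors, config = mcmc)
      sm <- summarize_posterior(ft)
      sm <- sm[sm$parameter %in% c(mod$param_names, "s"), ]
      tibble(
        parameter = ifelse(sm$parameter == "s", "sigma_u", sm$parameter),
        estimate = sm$mean, lower = sm$q2.5, upper = sm$q97.5
      )
    }
  }
}

#' @exportS3Method ggplot2::autoplot
autoplot.recovery_report <- function(object, ...) {
  est <- attr(object, "estimates")
  ggplot2::ggplot(est, ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$truth),
                        colour = "firebrick") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "estimate across simulated datasets", y = "density") +
    ggplot2::theme_minimal()
}
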