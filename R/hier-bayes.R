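#' Prior specification for the hierarchical logistic model
#'
#' Independent normal priors on every regression coefficient and a gamma
#' prior on the random-intercept precision tau. The defaults are vague:
#' Normal(0, variance 10) for each coefficient (precision 0.1) and
#' Gamma(shape 0.1, rate 0.01) for tau, which has mean 10 and variance
#' 1000. The individual-level standard deviation is s = 1 / sqrt(tau).
#'
#' @param beta_mean Prior mean(s) for the coefficients; recycled to the
#'   number of coefficients at fit time.
#' @param beta_var Prior variance(s) for the coefficients (> 0).
#' @param tau_shape,tau_rate Gamma prior parameters for tau (> 0).
#' @return A `prior_spec` list.
#' @examples
#' prior_spec()
#' prior_moments(prior_spec())
#' @export
prior_spec <- function(beta_mean = 0, beta_var = 10,
                       tau_shape = 0.1, tau_rate = 0.01) {
  if (any(beta_var <= 0) || tau_shape <= 0 || tau_rate <= 0) {
    abort("Prior variances, shape and rate must all be > 0.")
  }
  structure(list(beta_mean = beta_mean, beta_var = beta_var,
                 tau_shape = tau_shape, tau_rate = tau_rate),
            class = "prior_spec")
}

#' Moments implied by a prior specification
#'
#' @param priors A [prior_spec()].
#' @return Tibble with the coefficient prior precision and the mean and
#'   variance of the gamma prior on tau.
#' @export
prior_moments <- function(priors = prior_spec()) {
  tibble(
    beta_precision = 1 / priors$beta_var[1],
    tau_mean = priors$tau_shape / priors$tau_rate,
    tau_var = priors$tau_shape / priors$tau_rate^2
  )
}

#' MCMC sampler configuration
#'
#' The `"paper"` preset mirrors a full production run: 4 chains, 100,000
#' adaptation iterations, 10,000 burn-in, 500,000 monitored iterations
#' thinned by 10. The `"desk"` preset (4 chains, 2,000 adaptation, 2,000
#' burn-in, 20,000 monitored, thin 10) is sized so a full fit on a few
#' thousand rows runs in minutes.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param n_chains,n_adapt,n_burn,n_iter,thin Explicit overrides of the
#'   preset values.
#' @param seed Master RNG seed; per-chain streams are derived from it.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(preset = c("desk", "paper"), n_chains = NULL,
                        n_adapt = NULL, n_burn = NULL, n_iter = NULL,
                        thin = NULL, seed = 1L) {
  preset <- match.arg(preset)
  def <- switch(preset,
    desk  = list(n_chains = 4L, n_adapt = 2000L, n_burn = 2000L,
                 n_iter = 20000L, thin = 10L),
    paper = list(n_chains = 4L, n_adapt = 100000L, n_burn = 10000L,
                 n_iter = 500000L, thin = 10L)
  )
  cfg <- list(
    n_chains = as.integer(n_chains %||% def$n_chains),
    n_adapt = as.integer(n_adapt %||% def$n_adapt),
    n_burn = as.integer(n_burn %||% def$n_burn),
    n_iter = as.integer(n_iter %||% def$n_iter),
    thin = as.integer(thin %||% def$thin),
    seed = as.integer(seed),
    preset = preset
  )
  if (any(unlist(cfg[c("n_chains", "n_adapt", "n_burn", "n_iter", "thin")]) < 1)) {
    abort("All MCMC counts must be >= 1.")
  }
  if (cfg$n_iter %% cfg$thin != 0) {
    abort("n_iter must be a multiple of thin.")
  }
  structure(cfg, class = "mcmc_config")
}

#' Hierarchical Bernoulli-logit model container
#'
#' Assembles the design matrix (intercept first; Fall is the season
#' reference so only Spring, Summer and Winter enter), the binary response
#' and the track-boundary index from an analysis table ordered contiguously
#' by individual. Character/factor covariates (e.g. sex) are converted to
#' 0/1 treatment indicators with the alphabetically first level as
#' reference.
#'
#' @param data Analysis table with rows contiguous by `group`.
#' @param covariates Design covariates in order; defaults to the movement
#'   model's six terms.
#' @param response Binary response column.
#' @param group Individual id column.
#' @return An `hbm_model` list: `X`, `z`, `g` (row-wise group index),
#'   `index` (track boundaries), `param_names`.
#' @export
hbm_model <- function(data,
                      covariates = c("Spring", "Summer", "Winter", "L",
                                     "sex", "MEI_Index"),
                      response = "z", group = "ptt") {
  data <- as_tibble(data)
  missing_cols <- setdiff(c(covariates, response, group), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(data)
  cols <- lapply(covariates, function(v) {
    x <- data[[v]]
    if (is.numeric(x)) return(x)
    f <- factor(as.character(x))
    if (nlevels(f) > 2) abort(paste0("Covariate `", v, "` has > 2 levels."))
    as.numeric(f) - 1
  })
  X <- if (n > 0) cbind(1, do.call(cbind, cols)) else
    matrix(numeric(0), 0, length(covariates) + 1)
  colnames(X) <- c("(Intercept)", covariates)
  if (n > 0 && any(!is.finite(X))) abort("Design matrix contains non-finite values.")
  z <- as.numeric(as.character(data[[response]]))
  if (n > 0 && !all(z %in% c(0, 1))) abort("Response must be 0/1.")
  idx <- build_track_index(data, group = group)
  g <- if (n > 0) rep(seq_len(idx$n_groups), diff(idx$boundaries)) else integer(0)
  structure(
    list(X = X, z = z, g = g, index = idx,
         param_names = paste0("B", seq_len(ncol(X)) - 1),
         covariates = covariates, response = response, group = group),
    class = "hbm_model"
  )
}

#' Log unnormalized posterior density
#'
#' Bernoulli-logit likelihood with per-individual random intercepts plus
#' the normal log-priors on the coefficients, Normal(0, 1/tau) on each
#' random intercept and the gamma log-prior on tau, all computed in
#' numerically stable form. With no data rows the value reduces to the
#' prior log-density.
#'
#' @param model An [hbm_model()].
#' @param beta Coefficient vector (length `ncol(model$X)`).
#' @param u Random-intercept vector (length `model$index$n_groups`).
#' @param tau Random-intercept precision (> 0).
#' @param priors A [prior_spec()].
#' @return A single numeric value.
#' @export
log_unnorm_posterior <- function(model, beta, u, tau,
                                 priors = prior_spec()) {
  p <- ncol(model$X)
  N <- model$index$n_groups
  if (length(beta) != p) abort("beta has the wrong length.")
  if (length(u) != N) abort("u has the wrong length.")
  if (!all(is.finite(beta)) || !all(is.finite(u)) || !is.finite(tau)) {
    abort("Parameters must be finite.")
  }
  if (tau <= 0) abort("tau must be > 0.")
  m <- rep_len(priors$beta_mean, p)
  v <- rep_len(priors$beta_var, p)
  ll <- 0
  if (nrow(model$X) > 0) {
    eta <- drop(model$X %*% beta) + u[model$g]
    ll <- sum(model$z * eta - log1pexp(eta))
  }
  lp <- sum(dnorm(beta, m, sqrt(v), log = TRUE)) +
    dgamma(tau, shape = priors$tau_shape, rate = priors$tau_rate, log = TRUE)
  if (N > 0) lp <- lp + sum(dnorm(u, 0, 1 / sqrt(tau), log = TRUE))
  ll + lp
}

#' Exact conditional draw of the random-intercept precision
#'
#' Given the random intercepts, tau is conjugate: its full conditional is
#' Gamma(shape + N/2, rate + sum(u^2)/2).
#'
#' @param u Random-intercept vector.
#' @param priors A [prior_spec()].
#' @param n Number of draws.
#' @return Numeric vector of tau draws.
#' @export
draw_tau_conditional <- function(u, priors = prior_spec(), n = 1) {
  rgamma(n, shape = priors$tau_shape + length(u) / 2,
         rate = priors$tau_rate + 0.5 * sum(u^2))
}

# One chain of the adaptive Metropolis-within-Gibbs sampler.
# Coefficients are updated jointly by random-walk Metropolis with an
# empirical-covariance proposal learnt during adaptation; the random
# intercepts are updated as conditionally independent scalar blocks in one
# vectorized step; tau is a conjugate Gibbs draw.
.hbm_chain <- function(X, z, g, N, priors, cfg, seed) {
  set.seed(seed)
  p <- ncol(X)
  n <- nrow(X)
  m <- rep_len(priors$beta_mean, p)
  v <- rep_len(priors$beta_var, p)
  sv <- sqrt(v)
  beta <- runif(p, 0, 1)
  u <- numeric(N)
  tau <- rgamma(1, priors$tau_shape, priors$tau_rate)
  eta_f <- if (n > 0) drop(X %*% beta) else numeric(0)
  llp <- function(eta) z * eta - log1pexp(eta)
  ll_total <- if (n > 0) sum(llp(eta_f + u[g])) else 0
  if (!is.finite(ll_total)) abort("Non-finite posterior at initialization.")

  log_s <- log(0.1)
  R_prop <- diag(p)              # upper chol of the proposal shape
  s_u <- rep(0.5, max(N, 1))
  # Columns constant within every group (intercept, per-individual traits)
  # are entangled with the random intercepts: shifting such a coefficient
  # while counter-shifting every u_j leaves the likelihood unchanged.
  # Dedicated translation moves along these directions, accepted on the
  # priors alone, restore mixing for them.
  trans_cols <- integer(0)
  C_grp <- NULL
  if (N > 0 && n > 0) {
    grp_const <- vapply(seq_len(p), function(k) {
      all(tapply(X[, k], g, function(x) max(x) - min(x)) == 0)
    }, logical(1))
    trans_cols <- which(grp_const)
    if (length(trans_cols) > 0) {
      C_grp <- vapply(trans_cols, function(k) X[, k][match(seq_len(N), g)],
                      numeric(N))
    }
  }
  s_t <- rep(0.5, length(trans_cols))
  hist_b <- matrix(NA_real_, cfg$n_adapt, p)
  kept <- cfg$n_iter %/% cfg$thin
  draws <- matrix(NA_real_, kept, p + 1 + N)
  acc_b <- 0L; acc_u <- 0; n_track <- 0L
  total <- cfg$n_adapt + cfg$n_burn + cfg$n_iter
  k_out <- 0L

  for (it in seq_len(total)) {
    adapting <- it <= cfg$n_adapt
    tracking <- it > cfg$n_adapt + cfg$n_burn

    # --- joint coefficient updates (several sub-moves per scan to beat
    # random-walk autocorrelation; each costs one likelihood pass) ---
    ll_old <- if (n > 0) sum(llp(eta_f + u[g])) else 0
    acc_sub <- 0L
    for (sub in 1:5) {
      step <- exp(log_s) * drop(crossprod(R_prop, rnorm(p)))
      bp <- beta + step
      eta_p <- if (n > 0) drop(X %*% bp) else numeric(0)
      ll_new <- if (n > 0) sum(llp(eta_p + u[g])) else 0
      lr <- ll_new - ll_old +
        sum(dnorm(bp, m, sv, log = TRUE) - dnorm(beta, m, sv, log = TRUE))
      acc <- is.finite(lr) && log(runif(1)) < lr
      if (acc) { beta <- bp; eta_f <- eta_p; ll_old <- ll_new; acc_sub <- acc_sub + 1L }
      if (adapting) {
        gam <- min(0.1, 5 / sqrt(it))
        log_s <- log_s + gam * ((if (acc) 1 else 0) - 0.28)
      }
    }
    if (adapting) {
      hist_b[it, ] <- beta
      if (it >= 1000 && it %% 500 == 0) {
        span <- seq(max(1, floor(it / 2)), it)
        Sig <- stats::cov(hist_b[span, , drop = FALSE]) + diag(1e-8, p)
        R_prop <- chol(Sig) * (2.38 / sqrt(p))
      }
    }
    if (tracking) acc_b <- acc_b + acc_sub / 5

    # --- random intercepts, all groups at once ---
    if (N > 0) {
      up <- u + rnorm(N, 0, s_u[seq_len(N)])
      sd_u <- 1 / sqrt(tau)
      if (n > 0) {
        ll_g_new <- rowsum(llp(eta_f + up[g]), g, reorder = TRUE)
        ll_g_old <- rowsum(llp(eta_f + u[g]), g, reorder = TRUE)
        dll <- drop(ll_g_new - ll_g_old)
      } else dll <- numeric(N)
      lr_u <- dll + dnorm(up, 0, sd_u, log = TRUE) - dnorm(u, 0, sd_u, log = TRUE)
      acc_vec <- log(runif(N)) < lr_u
      u[acc_vec] <- up[acc_vec]
      if (adapting) {
        gam <- min(0.1, 5 / sqrt(it))
        s_u[seq_len(N)] <- s_u[seq_len(N)] * exp(gam * (as.numeric(acc_vec) - 0.40))
      }
      if (tracking) acc_u <- acc_u + mean(acc_vec)

      # --- likelihood-invariant translation moves ---
      for (tk in seq_along(trans_cols)) {
        k <- trans_cols[tk]
        delta <- rnorm(1, 0, s_t[tk])
        bk_new <- beta[k] + delta
        u_new <- u - delta * C_grp[, tk]
        lr_t <- dnorm(bk_new, m[k], sv[k], log = TRUE) -
          dnorm(beta[k], m[k], sv[k], log = TRUE) +
          sum(dnorm(u_new, 0, 1 / sqrt(tau), log = TRUE) -
                dnorm(u, 0, 1 / sqrt(tau), log = TRUE))
        acc_t <- is.finite(lr_t) && log(runif(1)) < lr_t
        if (acc_t) {
          beta[k] <- bk_new
          u <- u_new
          eta_f <- eta_f + delta * X[, k]   # u[g] shift cancels this in eta
        }
        if (adapting) {
          gam <- min(0.1, 5 / sqrt(it))
          s_t[tk] <- s_t[tk] * exp(gam * ((if (acc_t) 1 else 0) - 0.40))
        }
      }

      # --- conjugate precision update ---
      tau <- rgamma(1, priors$tau_shape + N / 2,
                    priors$tau_rate + 0.5 * sum(u^2))
    } else {
      tau <- rgamma(1, priors$tau_shape, priors$tau_rate)
    }

    if (tracking) {
      n_track <- n_track + 1L
      if ((it - cfg$n_adapt - cfg$n_burn) %% cfg$thin == 0) {
        k_out <- k_out + 1L
        draws[k_out, ] <- c(beta, 1 / sqrt(tau), u)
      }
    }
  }
  list(draws = draws,
       accept_beta = acc_b / max(n_track, 1),
       accept_u = acc_u / max(n_track, 1))
}

#' Sample the posterior of the hierarchical logistic model
#'
#' Runs independent adaptive Metropolis-within-Gibbs chains: the
#' coefficient vector is updated jointly by random-walk Metropolis whose
#' proposal covariance is learnt during the adaptation phase (target
#' acceptance around 25-45%) and then frozen; each individual's random
#' intercept is a scalar Metropolis block (all individuals updated in one
#' vectorized step); the precision tau is drawn exactly from its conjugate
#' gamma conditional. Coefficients are initialized from Uniform(0, 1),
#' intercepts at 0 and tau from its prior. Draws are recorded every `thin`
#' iterations after adaptation and burn-in. Runs are fully reproducible
#' from the seed in `config`.
#'
#' @param model An [hbm_model()].
#' @param priors A [prior_spec()].
#' @param config An [mcmc_config()].
#' @return An `hbm_fit`: list with `draws` (array chains x kept x
#'   parameters, parameters `B0..Bp`, `s`, `u[j]`), `acceptance` (tibble per
#'   chain), `config`, `priors`, `model`.
#' @export
sample_posterior <- function(model, priors = prior_spec(),
                             config = mcmc_config()) {
  stopifnot(inherits(model, "hbm_model"))
  p <- ncol(model$X)
  N <- model$index$n_groups
  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)
  chains <- lapply(seq_len(config$n_chains), function(ch) {
    .hbm_chain(model$X, model$z, model$g, N, priors, config, chain_seeds[ch])
  })
  kept <- config$n_iter %/% config$thin
  par_names <- c(model$param_names, "s",
                 if (N > 0) paste0("u[", seq_len(N), "]"))
  draws <- array(NA_real_, c(config$n_chains, kept, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  for (ch in seq_len(config$n_chains)) draws[ch, , ] <- chains[[ch]]$draws
  acceptance <- tibble(
    chain = seq_len(config$n_chains),
    accept_beta = vapply(chains, `[[`, numeric(1), "accept_beta"),
    accept_u = vapply(chains, `[[`, numeric(1), "accept_u")
  )
  bad <- acceptance$accept_beta < 0.05 | acceptance$accept_beta > 0.95
  if (any(bad)) {
    warn(paste0("Coefficient acceptance rate outside [0.05, 0.95] in chain(s) ",
                paste(which(bad), collapse = ", "),
                "; adaptation may have failed."))
  }
  structure(
    list(draws = draws, acceptance = acceptance, config = config,
         priors = priors, model = model, mode = "posterior"),
    class = "hbm_fit"
  )
}

#' Gelman-Rubin convergence diagnostic
#'
#' Classic (non-split) potential scale reduction factor computed from
#' between- and within-chain variances for every monitored parameter.
#' Requires at least two chains.
#'
#' @param fit An `hbm_fit`, or a 3-d array chains x iterations x parameters.
#' @param split Also split each chain in half before computing (the modern
#'   variant); default `FALSE`.
#' @return Tibble with `parameter` and `rhat`.
#' @export
gelman_rubin <- function(fit, split = FALSE) {
  draws <- if (inherits(fit, "hbm_fit")) fit$draws else fit
  stopifnot(length(dim(draws)) == 3)
  if (dim(draws)[1] < 2) abort("Gelman-Rubin needs at least 2 chains.")
  if (dim(draws)[2] < 10) abort("Gelman-Rubin needs at least 10 kept iterations.")
  if (split) {
    half <- dim(draws)[2] %/% 2
    draws <- array(
      c(draws[, seq_len(half), , drop = FALSE],
        draws[, half + seq_len(half), , drop = FALSE]),
      c(2 * dim(draws)[1], half, dim(draws)[3]),
      dimnames = list(NULL, NULL, dimnames(draws)[[3]])
    )
  }
  n <- dim(draws)[2]
  rhat <- apply(draws, 3, function(ch) {
    mns <- rowMeans(ch)
    W <- mean(apply(ch, 1, var))
    B_over_n <- var(mns)
    if (W <= 0) return(if (B_over_n <= 0) 1 else Inf)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  })
  tibble(parameter = dimnames(draws)[[3]], rhat = unname(rhat))
}

#' Posterior summary table
#'
#' Pooled-chain mean, standard deviation and equal-tailed 95% credible
#' interval for every monitored parameter.
#'
#' @param fit An `hbm_fit`.
#' @return Tibble with `parameter`, `mean`, `sd`, `q2.5`, `q97.5`.
#' @export
summarize_posterior <- function(fit) {
  draws <- if (inherits(fit, "hbm_fit")) fit$draws else fit
  pars <- dimnames(draws)[[3]]
  purrr::map_dfr(seq_along(pars), function(k) {
    x <- as.vector(draws[, , k])
    qs <- unname(quantile(x, c(0.025, 0.975), type = 7))
    tibble(parameter = pars[k], mean = mean(x), sd = sd(x),
           q2.5 = qs[1], q97.5 = qs[2])
  })
}

#' @exportS3Method generics::tidy
tidy.hbm_fit <- function(x, ...) summarize_posterior(x)

#' @exportS3Method generics::glance
glance.hbm_fit <- function(x, ...) {
  betas <- c(x$model$param_names, "s")
  rh <- gelman_rubin(x)
  tibble(
    n_chains = x$config$n_chains,
    n_kept = dim(x$draws)[2],
    max_rhat_beta = max(rh$rhat[rh$parameter %in% betas]),
    accept_beta = mean(x$acceptance$accept_beta),
    accept_u = mean(x$acceptance$accept_u),
    preset = x$config$preset
  )
}

#' @export
print.hbm_fit <- function(x, ...) {
  cat("Hierarchical Bernoulli-logit fit (", x$mode, " mode)\n", sep = "")
  cat(x$config$n_chains, "chains x", dim(x$draws)[2], "kept draws;",
      x$model$index$n_groups, "individuals;", nrow(x$model$X), "rows\n")
  print(summarize_posterior(x) %>%
          filter(!grepl("^u\\[", .data$parameter)), n = 20)
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.hbm_fit <- function(object, parameters = NULL, ...) {
  pars <- parameters %||% c(object$model$param_names, "s")
  df <- purrr::map_dfr(pars, function(pn) {
    tibble(parameter = pn, value = as.vector(object$draws[, , pn]))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "firebrick", alpha = 0.4) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density") +
    ggplot2::theme_minimal()
}
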