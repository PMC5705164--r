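#' Maximum-likelihood fits of the random-intercept logistic model
#'
#' Frequentist counterparts of the Bayesian movement model. `fit_laplace()`
#' maximizes the Laplace-approximated marginal likelihood via
#' [lme4::glmer()]; `fit_pql()` runs the iterated working-response penalized
#' quasi-likelihood scheme via [MASS::glmmPQL()]. PQL reports no true
#' log-likelihood and is known to attenuate estimates when the
#' random-effect standard deviation is large with binary data.
#'
#' @param data Analysis table with rows grouped by individual.
#' @param covariates Design covariates (order defines `B1..Bp`).
#' @param response Binary response column.
#' @param group Individual id column.
#' @return A `glmm_fit`: list with `beta` (named estimates, intercept
#'   first), `se`, `sigma_u`, `loglik` (`NA` for PQL), `quasi` flag,
#'   `converged`, `method`, `fit` (the underlying fit object).
#' @export
fit_laplace <- function(data,
                        covariates = c("Spring", "Summer", "Winter", "L",
                                       "sex", "MEI_Index"),
                        response = "z", group = "ptt") {
  prep <- .glmm_prep(data, covariates, response, group)
  fm <- as.formula(paste(".resp ~", paste(covariates, collapse = " + "),
                         "+ (1 | .grp)"))
  fit <- lme4::glmer(fm, data = prep, family = binomial(link = "logit"),
                     nAGQ = 1L,
                     control = lme4::glmerControl(optimizer = "bobyqa"))
  sm <- summary(fit)$coefficients
  if (max(sm[, "Std. Error"]) < 1e-2) {
    # degenerate curvature at the optimum; retry with the default optimizer
    fit <- lme4::glmer(fm, data = prep, family = binomial(link = "logit"),
                       nAGQ = 1L)
    sm <- summary(fit)$coefficients
  }
  vc <- lme4::VarCorr(fit)
  conv <- length(fit@optinfo$conv$lme4) == 0
  structure(
    list(beta = setNames(sm[, "Estimate"], rownames(sm)),
         se = setNames(sm[, "Std. Error"], rownames(sm)),
         sigma_u = attr(vc$.grp, "stddev")[[1]],
         loglik = as.numeric(logLik(fit)),
         quasi = FALSE, converged = conv, method = "laplace", fit = fit),
    class = "glmm_fit"
  )
}

#' @rdname fit_laplace
#' @export
fit_pql <- function(data,
                    covariates = c("Spring", "Summer", "Winter", "L",
                                   "sex", "MEI_Index"),
                    response = "z", group = "ptt") {
  prep <- .glmm_prep(data, covariates, response, group)
  fixed <- as.formula(paste(".resp ~", paste(covariates, collapse = " + ")))
  fit <- MASS::glmmPQL(fixed, random = ~ 1 | .grp,
                       family = binomial(link = "logit"),
                       data = as.data.frame(prep), verbose = FALSE)
  sm <- summary(fit)$tTable
  sdre <- sqrt(as.numeric(nlme::VarCorr(fit)["(Intercept)", "Variance"]))
  structure(
    list(beta = setNames(sm[, "Value"], rownames(sm)),
         se = setNames(sm[, "Std.Error"], rownames(sm)),
         sigma_u = sdre,
         loglik = NA_real_,
         quasi = TRUE, converged = TRUE, method = "pql", fit = fit),
    class = "glmm_fit"
  )
}

.glmm_prep <- function(data, covariates, response, group) {
  data <- as_tibble(data)
  missing_cols <- setdiff(c(covariates, response, group), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  zr <- as.numeric(as.character(data[[response]]))
  if (!all(zr %in% c(0, 1))) abort("Response must be 0/1.")
  if (length(unique(zr)) < 2) abort("Response is constant; nothing to fit.")
  if (length(unique(data[[group]])) < 2) abort("Need at least 2 individuals.")
  out <- data
  out$.resp <- zr
  out$.grp <- factor(as.character(data[[group]]),
                     levels = unique(as.character(data[[group]])))
  for (v in covariates) {
    if (!is.numeric(out[[v]])) out[[v]] <- as.numeric(factor(out[[v]])) - 1
  }
  out
}

#' @exportS3Method generics::tidy
tidy.glmm_fit <- function(x, conf.level = 0.95, ...) {
  zq <- qnorm(1 - (1 - conf.level) / 2)
  tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(x$se),
    conf.low = unname(x$beta - zq * x$se),
    conf.high = unname(x$beta + zq * x$se)
  )
}

#' @exportS3Method generics::glance
glance.glmm_fit <- function(x, ...) {
  tibble(sigma_u = x$sigma_u, logLik = x$loglik, quasi = x$quasi,
         converged = x$converged, method = x$method)
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Random-intercept logistic fit (", x$method, ")\n", sep = "")
  print(tidy(x))
  cat("sigma_u =", format(x$sigma_u, digits = 4), "\n")
  invisible(x)
}

# Gauss-Hermite nodes/weights (weight exp(-x^2)) by Golub-Welsch.
gauss_hermite <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = (e$vectors[1, ord]^2) * sqrt(pi))
}

# Per-group posterior mode and curvature of the random intercept given
# (beta, sigma_u), by Newton iterations on the penalized log-likelihood.
.group_modes <- function(model, beta, sigma_u) {
  eta_f <- drop(model$X %*% beta)
  N <- model$index$n_groups
  b <- model$index$boundaries
  u_hat <- numeric(N); h2 <- numeric(N)
  for (j in seq_len(N)) {
    rows <- b[j]:(b[j + 1] - 1)
    ef <- eta_f[rows]; zj <- model$z[rows]
    hval <- function(u) {
      sum(zj * (ef + u) - log1pexp(ef + u)) - u^2 / (2 * sigma_u^2)
    }
    u <- 0
    h_cur <- hval(0)
    # damped Newton: the penalized objective is strictly concave, so step
    # halving guarantees convergence even from flat separated regions
    for (k in 1:100) {
      mu <- plogis(ef + u)
      g1 <- sum(zj - mu) - u / sigma_u^2
      g2 <- -sum(mu * (1 - mu)) - 1 / sigma_u^2
      step <- -g1 / g2
      for (half in 1:40) {
        h_new <- hval(u + step)
        if (h_new >= h_cur - 1e-12) break
        step <- step / 2
      }
      u <- u + step
      h_cur <- hval(u)
      if (abs(step) < 1e-10) break
    }
    u_hat[j] <- u
    mu <- plogis(ef + u)
    h2[j] <- sum(mu * (1 - mu)) + 1 / sigma_u^2
  }
  list(u_hat = u_hat, curvature = h2, eta_f = eta_f)
}

#' Marginal log-likelihood by adaptive Gauss-Hermite quadrature
#'
#' Integrates the random intercept out of each individual's likelihood with
#' Gauss-Hermite quadrature recentred and rescaled at that individual's
#' conditional mode (adaptive quadrature). With a single node this is
#' exactly the Laplace approximation; as nodes are added the value
#' converges to the exact marginal log-likelihood, which makes it the
#' natural testing oracle for Laplace-based fits. With `sigma_u = 0` the
#' random effect is a point mass and the plain logistic log-likelihood is
#' returned.
#'
#' @param model An [hbm_model()].
#' @param beta Coefficient vector.
#' @param sigma_u Random-intercept standard deviation (>= 0).
#' @param n_nodes Number of quadrature nodes (>= 1).
#' @return The marginal log-likelihood (a single number).
#' @export
marginal_loglik_quadrature <- function(model, beta, sigma_u, n_nodes = 15) {
  stopifnot(n_nodes >= 1, sigma_u >= 0)
  if (sigma_u == 0) {
    eta <- drop(model$X %*% beta)
    return(sum(model$z * eta - log1pexp(eta)))
  }
  gh <- gauss_hermite(n_nodes)
  md <- .group_modes(model, beta, sigma_u)
  b <- model$index$boundaries
  total <- 0
  for (j in seq_len(model$index$n_groups)) {
    rows <- b[j]:(b[j + 1] - 1)
    ef <- md$eta_f[rows]; zj <- model$z[rows]
    sc <- 1 / sqrt(md$curvature[j])
    uk <- md$u_hat[j] + sqrt(2) * sc * gh$nodes
    hk <- vapply(uk, function(u) {
      sum(zj * (ef + u) - log1pexp(ef + u)) + dnorm(u, 0, sigma_u, log = TRUE)
    }, numeric(1))
    hmax <- max(hk)
    total <- total + hmax + log(sqrt(2) * sc) +
      log(sum(gh$weights * exp(gh$nodes^2 + hk - hmax)))
  }
  total
}

#' Marginal log-likelihood by the Laplace approximation
#'
#' Second-order expansion of each individual's integrand around its
#' random-intercept mode; identical to one-node adaptive Gauss-Hermite
#' quadrature.
#'
#' @inheritParams marginal_loglik_quadrature
#' @return The approximate marginal log-likelihood.
#' @export
marginal_loglik_laplace <- function(model, beta, sigma_u) {
  marginal_loglik_quadrature(model, beta, sigma_u, n_nodes = 1)
}
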