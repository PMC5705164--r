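#' Additive logistic model with a per-individual random intercept
#'
#' Fits a binomial-logit additive model in which each continuous candidate
#' predictor enters as a penalized cubic regression spline and the
#' individual id enters as a random intercept, so that each smooth term's
#' effective degrees of freedom (EDF) measure how far its fitted
#' relationship departs from a straight line on the logit scale. Smoothing
#' parameters are chosen by REML via [mgcv::gam()].
#'
#' @param data Analysis table (see [read_analysis_table()]).
#' @param smooth_vars Continuous predictors to test with splines; each needs
#'   at least `basis_size` distinct values (indicator variables are
#'   rejected).
#' @param linear_vars Predictors entered linearly (e.g. the season
#'   indicators and sex).
#' @param group Individual id column used as the random intercept.
#' @param response Binary response column.
#' @param basis_size Spline basis dimension per smooth (default 10).
#' @param sp Optional fixed smoothing parameters (one per smooth term plus
#'   one for the random intercept); `NULL` (default) selects them by REML.
#' @return A `gamm_linearity` object wrapping the `gam` fit.
#' @export
fit_additive_logistic <- function(data, smooth_vars,
                                  linear_vars = character(),
                                  group = "ptt", response = "z",
                                  basis_size = 10, sp = NULL) {
  data <- as_tibble(data)
  for (v in c(smooth_vars, linear_vars, group, response)) {
    if (!v %in% names(data)) abort(paste0("Column `", v, "` not found."))
  }
  for (v in smooth_vars) {
    x <- data[[v]]
    if (!is.numeric(x)) abort(paste0("Smooth variable `", v, "` is not numeric."))
    if (length(unique(x)) < basis_size) {
      abort(paste0("Smooth variable `", v, "` has fewer than basis_size = ",
                   basis_size, " distinct values; an indicator cannot be ",
                   "tested for nonlinearity."))
    }
  }
  df <- data
  df$.grp <- factor(as.character(df[[group]]))
  if (nlevels(df$.grp) < 2) abort("The random-intercept group needs >= 2 levels.")
  df$.resp <- as.numeric(as.character(df[[response]]))
  for (v in linear_vars) {
    if (!is.numeric(df[[v]])) {
      df[[v]] <- as.numeric(factor(df[[v]])) - 1
    }
  }
  terms <- c(
    sprintf('s(%s, bs = "cr", k = %d)', smooth_vars, basis_size),
    linear_vars,
    's(.grp, bs = "re")'
  )
  form <- as.formula(paste(".resp ~", paste(terms, collapse = " + ")))
  fit <- mgcv::gam(form, family = binomial(link = "logit"), data = df,
                   method = "REML", sp = sp)
  if (!fit$converged) abort("Additive logistic fit did not converge.")
  structure(
    list(fit = fit, smooth_vars = smooth_vars, linear_vars = linear_vars,
         basis_size = basis_size, group = group),
    class = "gamm_linearity"
  )
}

#' Per-term linearity report
#'
#' Summarizes each smooth term's effective degrees of freedom (EDF) and Wald
#' chi-square; a term whose EDF falls below the cutoff is effectively a
#' straight line on the logit scale and can enter the movement model as a
#' linear term. The verdict uses EDF only; the chi-square is reported for
#' reference.
#'
#' @param object A `gamm_linearity` fit.
#' @param edf_cutoff Verdict threshold: EDF below this value counts as
#'   linear (default 1.5, allowing penalized-fit slack around the ideal 1).
#' @return Tibble with `variable`, `edf`, `chi_sq`, `p_value`, `verdict`.
#' @export
linearity_report <- function(object, edf_cutoff = 1.5) {
  stopifnot(inherits(object, "gamm_linearity"))
  st <- summary(object$fit)$s.table
  keep <- !grepl("\\.grp", rownames(st))
  st <- st[keep, , drop = FALSE]
  vars <- gsub("^s\\(|\\)$", "", rownames(st))
  tibble(
    variable = vars,
    edf = unname(st[, "edf"]),
    chi_sq = unname(st[, "Chi.sq"]),
    p_value = unname(st[, "p-value"]),
    verdict = ifelse(st[, "edf"] < edf_cutoff, "linear", "nonlinear")
  )
}

#' @exportS3Method generics::tidy
tidy.gamm_linearity <- function(x, ...) linearity_report(x, ...)

#' @exportS3Method generics::glance
glance.gamm_linearity <- function(x, ...) {
  tibble(
    deviance = x$fit$deviance,
    df_residual = x$fit$df.residual,
    n = length(x$fit$y),
    converged = x$fit$converged
  )
}
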