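#' Random-forest screening configuration
#'
#' Settings for the balanced-forest permutation screen. The `"paper"` preset
#' uses 10,000 trees and 100 response permutations at significance level 0.1
#' with 1,000 rows sampled per class without replacement; the `"desk"` preset
#' shrinks the forest to 500 trees and 50 permutations for interactive use.
#'
#' @param n_trees Number of trees per forest.
#' @param samp_per_class Rows drawn per response class for each tree.
#' @param with_replacement Sample rows with replacement? Default `FALSE`:
#'   without-replacement sampling avoids importance bias when predictor
#'   scales differ.
#' @param n_perm Number of response permutations for the null importance
#'   distribution.
#' @param alpha Significance level for keeping a variable.
#' @param seed RNG seed.
#' @param preset `"paper"` or `"desk"`; explicit arguments override preset
#'   values.
#' @return An `rf_config` list.
#' @export
rf_config <- function(n_trees = NULL, samp_per_class = NULL,
                      with_replacement = FALSE, n_perm = NULL,
                      alpha = 0.1, seed = 1L,
                      preset = c("paper", "desk")) {
  preset <- match.arg(preset)
  def <- switch(preset,
    paper = list(n_trees = 10000L, samp_per_class = 1000L, n_perm = 100L),
    desk  = list(n_trees = 500L, samp_per_class = 1000L, n_perm = 50L)
  )
  cfg <- list(
    n_trees = as.integer(n_trees %||% def$n_trees),
    samp_per_class = as.integer(samp_per_class %||% def$samp_per_class),
    with_replacement = isTRUE(with_replacement),
    n_perm = as.integer(n_perm %||% def$n_perm),
    alpha = alpha,
    seed = as.integer(seed),
    preset = preset
  )
  if (cfg$n_trees < 1 || cfg$n_perm < 1) abort("n_trees and n_perm must be >= 1.")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) abort("alpha must be in (0, 1).")
  structure(cfg, class = "rf_config")
}

#' Detect perfect predictors of a binary response
#'
#' A perfect predictor classifies the response with zero training error —
#' e.g. raw longitude when the response itself is an east/west-of-meridian
#' indicator — and must be removed before tree-based screening, which it
#' would otherwise dominate. Numeric variables are flagged when a single
#' threshold separates the classes; categorical variables when every level
#' is pure.
#'
#' @param data Data frame of candidate predictors plus the response.
#' @param response Response column name (binary).
#' @return Character vector of perfectly predictive variable names
#'   (possibly empty).
#' @export
detect_perfect_predictors <- function(data, response = "z") {
  data <- as_tibble(data)
  zc <- as.numeric(as.character(data[[response]]))
  if (!all(zc %in% c(0, 1))) abort("Response must be binary 0/1.")
  vars <- setdiff(names(data), response)
  flagged <- character(0)
  for (v in vars) {
    x <- data[[v]]
    if (is.numeric(x)) {
      r0 <- range(x[zc == 0]); r1 <- range(x[zc == 1])
      if (length(x[zc == 0]) == 0 || length(x[zc == 1]) == 0) next
      if (r0[2] < r1[1] || r1[2] < r0[1]) flagged <- c(flagged, v)
    } else {
      pure <- tapply(zc, as.character(x), function(u) length(unique(u)) == 1)
      if (all(pure)) flagged <- c(flagged, v)
    }
  }
  flagged
}

#' Fit a class-balanced random forest
#'
#' Classification forest with an equal number of rows sampled per response
#' class for every tree, guarding against the class imbalance typical of
#' east/west movement data. Wraps [randomForest::randomForest()].
#'
#' @param data Data frame of predictors plus the binary response.
#' @param config An [rf_config()].
#' @param response Response column name.
#' @param guard Reject perfect predictors before fitting (default `TRUE`);
#'   disable only for diagnostics.
#' @return A list with `forest`, `oob_error` (overall out-of-bag error),
#'   and `class_error` (per-class error rates).
#' @export
fit_balanced_forest <- function(data, config = rf_config(), response = "z",
                                guard = TRUE) {
  data <- as_tibble(data)
  y <- factor(as.character(data[[response]]), levels = c("0", "1"))
  if (anyNA(y)) abort("Response must be binary 0/1.")
  counts <- table(y)
  if (length(unique(y[!is.na(y)])) < 2) abort("Response has a single class.")
  if (any(counts < config$samp_per_class)) {
    abort(paste0("samp_per_class = ", config$samp_per_class,
                 " exceeds a class count (0: ", counts[["0"]],
                 ", 1: ", counts[["1"]], ")."))
  }
  x <- data[setdiff(names(data), response)]
  if (guard) {
    perf <- detect_perfect_predictors(data, response = response)
    if (length(perf) > 0) {
      abort(paste0("Perfect predictor(s) present; remove before screening: ",
                   paste(perf, collapse = ", ")))
    }
  }
  fr <- randomForest::randomForest(
    x = as.data.frame(x), y = y,
    ntree = config$n_trees,
    replace = config$with_replacement,
    sampsize = c(config$samp_per_class, config$samp_per_class),
    strata = y,
    importance = FALSE
  )
  conf <- fr$confusion
  list(
    forest = fr,
    oob_error = unname(1 - sum(diag(conf[, 1:2])) / sum(conf[, 1:2])),
    class_error = conf[, "class.error"]
  )
}

#' Permutation test of random-forest variable importance
#'
#' Fits the balanced forest, then refits it `n_perm` times with the response
#' randomly permuted to build a null distribution of each variable's Gini
#' importance (mean decrease in Gini impurity). The permutation p-value is
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`, so it can never be exactly 0.
#'
#' @inheritParams fit_balanced_forest
#' @return An `rf_screen` object: tibble with `variable`, `importance`,
#'   `p_value`, `selected`, plus attributes `oob_error`, `class_error`,
#'   `null_importance` (matrix n_perm x variables), and `config`.
#' @export
permutation_importance_test <- function(data, config = rf_config(),
                                        response = "z") {
  set.seed(config$seed)
  data <- as_tibble(data)
  obs <- fit_balanced_forest(data, config, response = response)
  imp_obs <- obs$forest$importance[, "MeanDecreaseGini"]
  vars <- names(imp_obs)
  null_imp <- matrix(NA_real_, config$n_perm, length(vars),
                     dimnames = list(NULL, vars))
  perm_data <- data
  for (r in seq_len(config$n_perm)) {
    perm_data[[response]] <- sample(data[[response]])
    fr <- fit_balanced_forest(perm_data, config, response = response)
    null_imp[r, ] <- fr$forest$importance[vars, "MeanDecreaseGini"]
  }
  p <- vapply(vars, function(v) {
    (1 + sum(null_imp[, v] >= imp_obs[v])) / (config$n_perm + 1)
  }, numeric(1))
  res <- tibble(
    variable = vars,
    importance = unname(imp_obs),
    p_value = unname(p),
    selected = unname(p <= config$alpha)
  ) %>% arrange(dplyr::desc(.data$importance))
  structure(res,
            class = c("rf_screen", class(res)),
            oob_error = obs$oob_error,
            class_error = obs$class_error,
            null_importance = null_imp,
            config = config)
}

#' Select variables from a permutation screen
#'
#' Keeps every variable whose permutation p-value is at or below `alpha`
#' (inclusive at the boundary). An empty selection is a warning, not an
#' error.
#'
#' @param result An `rf_screen` from [permutation_importance_test()].
#' @param alpha Significance level; defaults to the level in the screen's
#'   config.
#' @return Character vector of kept variable names.
#' @export
select_variables <- function(result, alpha = NULL) {
  alpha <- alpha %||% attr(result, "config")$alpha
  kept <- result$variable[result$p_value <= alpha]
  if (length(kept) == 0) {
    warn("No variable met the significance level; returning an empty selection.")
  }
  kept
}

#' @exportS3Method generics::glance
glance.rf_screen <- function(x, ...) {
  tibble(
    oob_error = attr(x, "oob_error"),
    class_error_0 = unname(attr(x, "class_error")["0"]),
    class_error_1 = unname(attr(x, "class_error")["1"]),
    n_trees = attr(x, "config")$n_trees,
    n_perm = attr(x, "config")$n_perm,
    n_selected = sum(x$selected)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.rf_screen <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$variable, .data$importance),
    y = .data$importance, fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey60"),
                               name = "significant") +
    ggplot2::labs(x = NULL, y = "Gini importance (mean decrease)") +
    ggplot2::theme_minimal()
}
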