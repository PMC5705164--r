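#' Design of the data-paucity experiment
#'
#' Repeated random subsampling at fixed fractions of the full dataset —
#' the default follows the standard design of 25 replicates at each of
#' 75, 50, 25 and 10 percent, giving 100 "data poor" datasets — with a
#' pluggable fitter refit on every subset.
#'
#' @param fractions Retention fractions in (0, 1].
#' @param replicates Replicates per fraction (1-256).
#' @param fitter `"laplace"`, `"pql"`, `"hier_bayes"`, or a fitter function
#'   (see [standard_fitter()]).
#' @param seed Master seed; per-replicate seeds are derived from it by a
#'   counter scheme over (fraction index, replicate index).
#' @return A `paucity_design` list.
#' @export
paucity_design <- function(fractions = c(0.75, 0.50, 0.25, 0.10),
                           replicates = 25, fitter = "laplace", seed = 1L) {
  if (any(fractions <= 0 | fractions > 1)) abort("fractions must be in (0, 1].")
  if (replicates < 1 || replicates > 256) abort("replicates must be in 1..256.")
  structure(list(fractions = fractions, replicates = as.integer(replicates),
                 fitter = fitter, seed = as.integer(seed)),
            class = "paucity_design")
}

# Counter-based replicate seed: deterministic, order-independent, < 2^31.
.paucity_seed <- function(master, frac_idx, rep_idx) {
  (master %% 1048576L) * 1024L + (frac_idx - 1L) * 260L + rep_idx
}

#' Randomly subset an analysis table
#'
#' Draws a simple random sample of `round(fraction * n)` rows without
#' replacement across the whole table, ignoring individuals: individuals
#' left with no rows simply drop out. The result is re-sorted so groups
#' stay contiguous (individuals keep their original order).
#'
#' @param data Analysis table.
#' @param fraction Retention fraction in (0, 1].
#' @param seed RNG seed.
#' @param group Individual id column.
#' @param response Binary response column.
#' @return The subset tibble.
#' @export
subset_dataset <- function(data, fraction, seed = 1L, group = "ptt",
                           response = "z") {
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1].")
  data <- as_tibble(data)
  n <- nrow(data)
  k <- round(fraction * n)
  set.seed(seed)
  keep <- sort(sample.int(n, k))
  out <- data[keep, ]
  lev <- unique(as.character(data[[group]]))
  out <- out[order(match(as.character(out[[group]]), lev)), ]
  if (length(unique(out[[group]])) < 2) {
    abort("Subset left fewer than 2 individuals; cannot fit a hierarchical model.")
  }
  zr <- as.numeric(as.character(out[[response]]))
  if (length(unique(zr)) < 2) {
    abort("Subset response is single-class; cannot fit.")
  }
  out
}

#' Run the data-paucity experiment
#'
#' Fits the full dataset once as the reference, then refits the chosen
#' fitter on every random subset. Accuracy of a subset estimate is its
#' shift from the full-data estimate; precision is the 95% interval width.
#' Individual replicate failures are recorded and skipped; more than 20%
#' failures at any fraction aborts the experiment.
#'
#' @param data Full analysis table.
#' @param design A [paucity_design()].
#' @param ... Passed to [standard_fitter()] (covariates, priors, mcmc...).
#' @return A `paucity_result` tibble in long format: `fraction`,
#'   `replicate`, `parameter`, `estimate`, `lower`, `upper`, `accuracy`,
#'   `width`; full-data reference estimates in the `full_fit` attribute.
#' @export
run_paucity_experiment <- function(data, design = paucity_design(), ...) {
  fit_fun <- standard_fitter(design$fitter, ...)
  full <- fit_fun(data)
  rows <- list()
  for (i in seq_along(design$fractions)) {
    f <- design$fractions[i]
    fails <- 0L
    for (r in seq_len(design$replicates)) {
      sd_ir <- .paucity_seed(design$seed, i, r)
      est <- tryCatch({
        sub <- subset_dataset(data, f, seed = sd_ir)
        fit_fun(sub)
      }, error = function(e) NULL)
      if (is.null(est)) { fails <- fails + 1L; next }
      est$fraction <- f
      est$replicate <- r
      est$n_rows <- round(f * nrow(data))
      rows[[length(rows) + 1L]] <- est
    }
    if (fails > 0.2 * design$replicates) {
      abort(paste0("More than 20% of replicates failed at fraction ", f, "."))
    }
  }
  res <- bind_rows(rows) %>%
    left_join(full %>% select("parameter", full_estimate = "estimate"),
              by = "parameter") %>%
    mutate(accuracy = .data$estimate - .data$full_estimate,
           width = .data$upper - .data$lower) %>%
    select("fraction", "replicate", "parameter", "estimate", "lower",
           "upper", "accuracy", "width", "n_rows")
  structure(res, class = c("paucity_result", class(res)),
            full_fit = full, design = design)
}

#' Accuracy and precision summary of a paucity experiment
#'
#' Per fraction and parameter: mean/min/max accuracy (shift from the
#' full-data estimate), median 95% interval width, the width ratio against
#' the full-data interval, and sign stability (the share of replicates
#' whose point estimate has the same sign as the full-data estimate).
#'
#' @param result A `paucity_result`.
#' @return A summary tibble.
#' @export
summarize_accuracy_precision <- function(result) {
  full <- attr(result, "full_fit") %>%
    mutate(full_width = .data$upper - .data$lower) %>%
    select("parameter", full_estimate = "estimate", "full_width")
  as_tibble(result) %>%
    left_join(full, by = "parameter") %>%
    group_by(.data$fraction, .data$parameter) %>%
    summarise(
      mean_accuracy = mean(.data$accuracy),
      min_accuracy = min(.data$accuracy),
      max_accuracy = max(.data$accuracy),
      median_width = median(.data$width),
      width_ratio = median(.data$width) / first(.data$full_width),
      sign_stability = mean(sign(.data$estimate) == sign(.data$full_estimate)),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) %>%
    arrange(dplyr::desc(.data$fraction), .data$parameter)
}

#' @exportS3Method ggplot2::autoplot
autoplot.paucity_result <- function(object, parameters = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(parameters)) df <- df %>% filter(.data$parameter %in% parameters)
  df$fraction <- factor(df$fraction, levels = sort(unique(df$fraction),
                                                   decreasing = TRUE))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 15, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, colour = "firebrick") +
    ggplot2::facet_grid(fraction ~ parameter, scales = "free_x") +
    ggplot2::labs(x = "estimate shift from full-data fit", y = "replicates") +
    ggplot2::theme_minimal()
}
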