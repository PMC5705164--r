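#' Read a standardized analysis table
#'
#' Reads a CSV in the analysis-table schema (`ptt`, `sex`, `Spring`,
#' `Summer`, `Fall`, `Winter`, `L`, `z`, plus any index/covariate columns
#' such as `MEI_Index`, `NPGO_Index`, `PDO_Index`, `Moon`, `sst`, `chl`)
#' and validates it: the response must be 0/1, exactly one season
#' indicator must be 1 per row, modelled columns must be complete, and
#' rows must be contiguous by individual.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_analysis_table <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_analysis_table(data)
  data
}

#' Write an analysis table (with optional standardization sidecar)
#'
#' @param data Analysis table.
#' @param path CSV output path.
#' @param standardization Optional tibble of z-score parameters; written as
#'   a JSON sidecar next to `path`.
#' @param counts Optional named list of filtering counts for the sidecar.
#' @return `path`, invisibly.
#' @export
write_analysis_table <- function(data, path, standardization = NULL,
                                 counts = NULL) {
  validate_analysis_table(data)
  readr::write_csv(data, path)
  if (!is.null(standardization) || !is.null(counts)) {
    side <- list(standardization = standardization, counts = counts)
    jsonlite::write_json(side, paste0(tools::file_path_sans_ext(path), ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Write posterior draws in long format
#'
#' One row per (chain, iteration, parameter) — a tool-agnostic, diff-able
#' layout.
#'
#' @param fit An `hbm_fit`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  d <- fit$draws
  pars <- dimnames(d)[[3]]
  long <- purrr::map_dfr(seq_along(pars), function(k) {
    tibble(
      chain = rep(seq_len(dim(d)[1]), each = dim(d)[2]),
      iteration = rep(seq_len(dim(d)[2]), dim(d)[1]),
      parameter = pars[k],
      value = as.vector(t(d[, , k]))
    )
  })
  readr::write_csv(long, path)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in their natural order — `simulate`,
#' `select_vars`, `linearity`, `fit_bayes`, `fit_glmm`, `priors_check`,
#' `paucity`, `recover` — on a supplied or simulated analysis table,
#' writing each stage's artifact (CSV/JSON) under `out_dir` and returning
#' a manifest. Every artifact is stamped with the master seed; the
#' manifest carries an md5 per file so a rerun with the same config and
#' seed can be verified byte-identical. A stage failure halts downstream
#' stages (partial artifacts are retained).
#'
#' @param stages Character vector of stage names (order is normalized).
#' @param data Analysis table; required unless `"simulate"` is among the
#'   stages.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed, recorded in every artifact.
#' @param sim A [sim_config()] for the simulate stage.
#' @param rf An [rf_config()] for variable screening.
#' @param priors A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @param paucity A [paucity_design()].
#' @param covariates Model covariates.
#' @param n_recovery Datasets for the recover stage.
#' @return Tibble manifest: `stage`, `artifact`, `path`, `md5`, `seed`.
#' @export
run_pipeline <- function(stages, data = NULL, out_dir = tempfile("sparsemove-"),
                         seed = 1L, sim = NULL, rf = NULL, priors = prior_spec(),
                         mcmc = NULL, paucity = NULL,
                         covariates = c("Spring", "Summer", "Winter", "L",
                                        "sex", "MEI_Index"),
                         n_recovery = 10) {
  order_all <- c("simulate", "select_vars", "linearity", "fit_bayes",
                 "fit_glmm", "priors_check", "paucity", "recover")
  unknown <- setdiff(stages, order_all)
  if (length(unknown) > 0) {
    abort(paste0("Unknown stage(s): ", paste(unknown, collapse = ", ")))
  }
  stages <- order_all[order_all %in% stages]
  if (!"simulate" %in% stages && is.null(data)) {
    abort("`data` is required unless the simulate stage is requested.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mcmc <- mcmc %||% mcmc_config(seed = seed)
  manifest <- list()
  note <- function(stage, artifact, path) {
    manifest[[length(manifest) + 1L]] <<- tibble(
      stage = stage, artifact = artifact, path = path,
      md5 = unname(tools::md5sum(path)), seed = seed
    )
  }
  bayes_fit <- NULL
  for (st in stages) {
    if (st == "simulate") {
      simc <- sim %||% sim_config(seed = seed)
      dset <- simulate_dataset(simc)
      data <- dset$data
      p <- file.path(out_dir, "simulated.csv")
      readr::write_csv(data, p); note(st, "simulated dataset", p)
      pt <- file.path(out_dir, "truth.json")
      jsonlite::write_json(dset$truth, pt, auto_unbox = TRUE, digits = NA)
      note(st, "generating truth", pt)
    } else if (st == "select_vars") {
      scr <- permutation_importance_test(
        data %>% select(-dplyr::any_of("date")),
        config = rf %||% rf_config(preset = "desk", samp_per_class = 200,
                                   seed = seed))
      p <- file.path(out_dir, "importance.csv")
      readr::write_csv(as_tibble(scr), p); note(st, "importance report", p)
    } else if (st == "linearity") {
      sm <- intersect(c("L", "MEI_Index"), covariates)
      sm <- sm[vapply(sm, function(v) length(unique(data[[v]])) >= 10, logical(1))]
      lin <- setdiff(covariates, sm)
      fitg <- fit_additive_logistic(data, smooth_vars = sm, linear_vars = lin)
      p <- file.path(out_dir, "linearity.csv")
      readr::write_csv(linearity_report(fitg), p); note(st, "linearity report", p)
    } else if (st == "fit_bayes") {
      mod <- hbm_model(data, covariates = covariates)
      bayes_fit <- sample_posterior(mod, priors = priors, config = mcmc)
      p <- file.path(out_dir, "posterior_summary.csv")
      readr::write_csv(summarize_posterior(bayes_fit), p)
      note(st, "posterior summary", p)
      pd <- file.path(out_dir, "draws.csv")
      write_draws(bayes_fit, pd); note(st, "posterior draws", pd)
      pj <- file.path(out_dir, "diagnostics.json")
      jsonlite::write_json(
        list(rhat = gelman_rubin(bayes_fit), acceptance = bayes_fit$acceptance,
             seed = seed, preset = mcmc$preset),
        pj, auto_unbox = TRUE, digits = NA)
      note(st, "convergence diagnostics", pj)
    } else if (st == "fit_glmm") {
      fits <- list(laplace = fit_laplace(data, covariates = covariates),
                   pql = fit_pql(data, covariates = covariates))
      tab <- purrr::map_dfr(names(fits), function(nm) {
        tidy(fits[[nm]]) %>% mutate(method = nm,
                                    sigma_u = fits[[nm]]$sigma_u)
      })
      p <- file.path(out_dir, "glmm_fits.csv")
      readr::write_csv(tab, p); note(st, "likelihood fits", p)
    } else if (st == "priors_check") {
      mod <- hbm_model(data, covariates = covariates)
      if (is.null(bayes_fit)) {
        bayes_fit <- sample_posterior(mod, priors = priors, config = mcmc)
      }
      pr <- run_priors_only(mod, priors = priors, config = mcmc)
      chk <- prior_influence_check(bayes_fit, pr)
      p <- file.path(out_dir, "prior_influence.csv")
      readr::write_csv(as_tibble(chk), p); note(st, "prior influence check", p)
    } else if (st == "paucity") {
      des <- paucity %||% paucity_design(seed = seed)
      res <- run_paucity_experiment(data, des, covariates = covariates,
                                    priors = priors, mcmc = mcmc)
      p <- file.path(out_dir, "paucity_results.csv")
      readr::write_csv(as_tibble(res), p); note(st, "paucity results", p)
      ps <- file.path(out_dir, "paucity_summary.csv")
      readr::write_csv(summarize_accuracy_precision(res), ps)
      note(st, "paucity summary", ps)
    } else if (st == "recover") {
      simc <- sim %||% sim_config(seed = seed)
      rep <- recovery_study(simc, n_datasets = n_recovery, fitter = "laplace")
      p <- file.path(out_dir, "recovery.csv")
      readr::write_csv(as_tibble(rep), p); note(st, "recovery report", p)
    }
  }
  bind_rows(manifest)
}
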