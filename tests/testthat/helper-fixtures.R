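# Fixtures built in code: raw Argos-like location records and small
# simulated analysis tables.

make_raw_locations <- function() {
  tibble::tibble(
    tag_id = c("t1", "t1", "t1", "t1", "t2", "t2", "t2"),
    timestamp = as.POSIXct(
      c("2010-06-01 04:00:00", "2010-06-01 10:00:00", "2010-06-02 09:00:00",
        "2010-06-04 12:00:00", "2010-06-01 01:00:00", "2010-06-01 23:00:00",
        "2010-07-02 08:00:00"),
      tz = "UTC"),
    lon = c(-120, -121, -126, -124, -130, -131, -119),
    lat = c(32, 33, 34, 33, 30, 31, 29),
    argos_class = c("B", "2", "1", "A", "1", "1", "D")
  )
}

# Small grouped binary dataset straight from the generator.
small_sim <- function(n_ind = 8, mean_loc = 50, seed = 42, ...) {
  simulate_dataset(sim_config(n_individuals = n_ind, mean_locations = mean_loc,
                              seed = seed, ...))
}

# Cheap plug-in fitter for experiment bookkeeping tests: pooled logistic
# regression (no random effect), Wald intervals, sigma_u reported as 0.
pooled_glm_fitter <- function(data) {
  d <- data
  d$sexM <- as.integer(d$sex == "M")
  fit <- stats::glm(z ~ Spring + Summer + Winter + L + sexM + MEI_Index,
                    family = stats::binomial(), data = d)
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  tibble::tibble(
    parameter = c(paste0("B", 0:6), "sigma_u"),
    estimate = c(unname(est), 0),
    lower = c(unname(est - 1.96 * se), NA),
    upper = c(unname(est + 1.96 * se), NA)
  )
}
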