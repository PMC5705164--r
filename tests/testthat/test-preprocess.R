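test_that("Argos classes rank in the documented quality order", {
  ranks <- argos_rank(c("D", "3", "2", "1", "0", "A", "B", "Z"))
  expect_identical(ranks, 0:7)
  expect_lt(argos_rank("3"), argos_rank("2"))
  expect_identical(argos_rank("Z"), 7L)
  expect_identical(argos_rank("D"), 0L)
  expect_error(argos_rank(c("3", "Q")), "Q")
})

test_that("daily filtering keeps the single best fix per tag-day", {
  raw <- make_raw_locations()
  filt <- filter_daily_best(raw)
  # t1 on 2010-06-01 had classes {B, 2}: class 2 wins
  d1 <- filt[filt$tag_id == "t1" &
               as.Date(filt$timestamp, tz = "UTC") == as.Date("2010-06-01"), ]
  expect_equal(nrow(d1), 1)
  expect_equal(d1$argos_class, "2")
  # t2 on 2010-06-01: two class-1 fixes, earlier timestamp kept
  d2 <- filt[filt$tag_id == "t2" &
               as.Date(filt$timestamp, tz = "UTC") == as.Date("2010-06-01"), ]
  expect_equal(format(d2$timestamp, "%H"), "01")
  # at most one row per tag-day; idempotent; empty in, empty out
  key <- paste(filt$tag_id, as.Date(filt$timestamp, tz = "UTC"))
  expect_false(anyDuplicated(key) > 0)
  expect_identical(filter_daily_best(filt), filt)
  expect_equal(nrow(filter_daily_best(raw[0, ])), 0)
})

test_that("retained fix rank never exceeds a discarded same-day rank", {
  set.seed(3)
  classes <- c("3", "2", "1", "0", "A", "B", "Z")
  raw <- tibble::tibble(
    tag_id = sample(c("a", "b"), 120, TRUE),
    timestamp = as.POSIXct("2012-01-01", tz = "UTC") +
      runif(120, 0, 20 * 86400),
    lon = runif(120, -140, -110), lat = runif(120, 20, 45),
    argos_class = sample(classes, 120, TRUE)
  )
  filt <- filter_daily_best(raw)
  both <- merge(
    transform(raw, day = as.Date(timestamp, tz = "UTC"),
              rank = argos_rank(argos_class)),
    transform(as.data.frame(filt), day = as.Date(timestamp, tz = "UTC"),
              kept_rank = argos_rank(argos_class))[, c("tag_id", "day", "kept_rank")],
    by = c("tag_id", "day"))
  expect_true(all(both$kept_rank <= both$rank))
})

test_that("east/west response codes the boundary meridian as east", {
  expect_identical(derive_response(-120), 0L)
  expect_identical(derive_response(-130), 1L)
  expect_identical(derive_response(-125), 0L)
  lons <- runif(200, -180, -60)
  z <- derive_response(lons)
  expect_equal(sum(z == 0) + sum(z == 1), 200)
  expect_error(derive_response(NaN), "finite")
})

test_that("z-score standardization is exact and invertible", {
  zs <- zscore(c(2, 4, 6))
  expect_equal(zs$values, c(-1, 0, 1))
  expect_equal(zs$params$mean, 4)
  expect_equal(zs$params$sd, 2)
  x <- rnorm(50, 100, 7)
  zs2 <- zscore(x)
  expect_equal(mean(zs2$values), 0, tolerance = 1e-12)
  expect_equal(sd(zs2$values), 1, tolerance = 1e-12)
  expect_equal(zs2$values * zs2$params$sd + zs2$params$mean, x,
               tolerance = 1e-12)
  expect_equal(zs2$values[which.min(abs(x - mean(x)))[1]],
               (x - mean(x))[which.min(abs(x - mean(x)))[1]] / sd(x))
  expect_error(zscore(c(5, 5, 5)), "deviation")
  expect_error(zscore(3), "at least 2")
})

test_that("season encoding partitions the calendar", {
  s <- encode_season(as.Date(c("2011-07-15", "2011-12-21", "2011-03-01",
                               "2011-09-30")))
  expect_equal(s$Summer, c(1L, 0L, 0L, 0L))
  expect_equal(s$Winter, c(0L, 1L, 0L, 0L))
  expect_equal(s$Spring, c(0L, 0L, 1L, 0L))
  expect_equal(s$Fall, c(0L, 0L, 0L, 1L))
  dates <- as.Date("2005-01-01") + sample.int(5000, 100)
  expect_true(all(rowSums(encode_season(dates)) == 1))
})

test_that("track index boundaries reproduce group counts", {
  df <- data.frame(ptt = rep(c("A", "B"), c(3, 2)))
  idx <- build_track_index(df)
  expect_identical(idx$boundaries, c(1L, 4L, 6L))
  expect_identical(idx$n_groups, 2L)
  expect_identical(build_track_index(data.frame(ptt = rep("X", 5)))$boundaries,
                   c(1L, 6L))
  expect_error(build_track_index(data.frame(ptt = c("A", "B", "A"))),
               "contiguous")
  sim <- small_sim()
  idx2 <- build_track_index(sim$data)
  expect_identical(diff(idx2$boundaries),
                   unname(as.integer(table(sim$data$ptt)[idx2$groups])))
})

test_that("grid extraction averages the error box and flags misses", {
  lon_ax <- seq(-130, -120, by = 0.5)
  lat_ax <- seq(30, 40, by = 0.5)
  grid_const <- matrix(7, length(lon_ax), length(lat_ax))
  expect_equal(
    extract_grid_covariate(grid_const, lon_ax, lat_ax, -125.2, 33.1,
                           lon_err = 50000, lat_err = 50000), 7)
  grid_var <- outer(seq_along(lon_ax), seq_along(lat_ax), `+`) * 1.0
  # error box much smaller than one cell: the containing cell's value
  v <- extract_grid_covariate(grid_var, lon_ax, lat_ax, -125.01, 33.01,
                              lon_err = 10, lat_err = 10)
  i <- which.min(abs(lon_ax + 125.01)); j <- which.min(abs(lat_ax - 33.01))
  expect_equal(v, grid_var[i, j])
  grid_na <- grid_var; grid_na[] <- NA
  expect_true(is.na(extract_grid_covariate(grid_na, lon_ax, lat_ax,
                                           -125, 33, 1000, 1000)))
  expect_warning(
    out <- extract_grid_covariate(grid_var, lon_ax, lat_ax, -150, 33, 0, 0),
    "outside")
  expect_true(is.na(out))
})

test_that("the raw-to-analysis pipeline yields a valid contiguous table", {
  raw <- make_raw_locations()
  ind <- tibble::tibble(tag_id = c("t1", "t2"), length = c(180, 220),
                        sex = c("F", "M"))
  idx <- tibble::tibble(
    date = seq(as.Date("2010-05-25"), as.Date("2010-07-10"), by = "day"),
    value = 0.3)
  built <- build_analysis_table(raw, ind, index = idx)
  expect_silent(sparsemove:::validate_analysis_table(built$data))
  expect_equal(built$standardization$sd, sd(c(180, 220)))
  expect_true(all(built$data$MEI_Index == 0.3))
  # one length value per individual, already standardized
  expect_equal(sort(unique(built$data$L)),
               sort((c(180, 220) - 200) / sd(c(180, 220))))
})
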