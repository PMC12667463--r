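test_that("ballistic tracks give the exact quadratic MSD closed form", {
  v <- c(0.1, -0.2, 0.2)
  tr <- line_track(v, dt = 10, n_samples = 40)
  curve <- compute_msd(tr, max_lag = 200)
  expect_equal(curve$msd, sum(v^2) * curve$lag^2, tolerance = 1e-12)
  # a quadratic curve is not perfectly linear
  fit <- fit_diffusion(curve)
  expect_lt(fit$r_squared, 1)
  expect_gt(fit$r_squared, 0)
})

test_that("stationary tracks have identically zero MSD and D = 0", {
  tr <- cell_track("still", t = seq(0, 100, by = 10),
                   x = rep(1, 11), y = rep(2, 11), z = rep(3, 11))
  curve <- compute_msd(tr, max_lag = 60)
  expect_true(all(curve$msd == 0))
  fit <- fit_diffusion(curve)
  expect_equal(fit$slope, 0)
  expect_equal(fit$D, 0)
  expect_true(fit$nonpositive_slope)
})

test_that("compute_msd agrees exactly with the brute-force pair loop", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:50, 1)
    tr <- cell_track(seed, t = seq(0, by = 10, length.out = n),
                     x = cumsum(rnorm(n)), y = cumsum(rnorm(n)),
                     z = cumsum(rnorm(n)))
    max_lag <- sample(c(50, 120, 400), 1)
    got <- compute_msd(tr, max_lag)
    want <- brute_msd(tr, max_lag)
    expect_equal(got$lag, want$lag)
    expect_equal(got$msd, want$msd, tolerance = 1e-12)
    expect_equal(got$n_pairs, want$n_pairs)
  }
})

test_that("the first MSD lag equals the mean single-step squared displacement", {
  set.seed(3)
  n <- 30
  tr <- cell_track("t", t = seq(0, by = 10, length.out = n),
                   x = cumsum(rnorm(n)), y = cumsum(rnorm(n)),
                   z = cumsum(rnorm(n)))
  curve <- compute_msd(tr, max_lag = 10)
  p <- as.matrix(tr[, c("x", "y", "z")])
  expect_equal(curve$msd[1], mean(rowSums(diff(p)^2)), tolerance = 1e-12)
  expect_equal(nrow(curve), 1L)
})

test_that("MSD, speed and directionality are rotation invariant", {
  set.seed(4)
  n <- 40
  tr <- cell_track("t", t = seq(0, by = 10, length.out = n),
                   x = cumsum(rnorm(n)), y = cumsum(rnorm(n)),
                   z = cumsum(rnorm(n)))
  rot <- random_rotation()
  tr_rot <- rotate_track(tr, rot)
  c1 <- compute_msd(tr, 120)
  c2 <- compute_msd(tr_rot, 120)
  expect_equal(c2$msd, c1$msd, tolerance = 1e-9)
  m1 <- migration_metrics(tr)
  m2 <- migration_metrics(tr_rot)
  expect_equal(m2$speed, m1$speed, tolerance = 1e-9)
  expect_equal(m2$directionality, m1$directionality, tolerance = 1e-9)
})

test_that("degenerate MSD inputs are rejected", {
  tr <- line_track(c(0.1, 0, 0), dt = 10, n_samples = 5)
  expect_error(compute_msd(tr, max_lag = 4), "sampling interval")
  expect_error(cell_track("one", t = 0, x = 0, y = 0, z = 0), "two samples")
  curve <- compute_msd(tr, max_lag = 20)  # two lags only
  expect_error(fit_diffusion(curve), "three lags")
})

test_that("fitting an exact 6*D*lag line recovers D with r^2 = 1", {
  curve <- make_curve(lag = seq(10, 120, by = 10),
                      msd = 6 * 0.75 * seq(10, 120, by = 10))
  fit <- fit_diffusion(curve)
  expect_equal(fit$D, 0.75, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  fit0 <- fit_diffusion(curve, intercept = FALSE)
  expect_equal(fit0$D, 0.75, tolerance = 1e-12)
  expect_equal(fit0$intercept, 0)
})

test_that("fit-level population summary matches hand mean/sd of exact D values", {
  lag <- seq(10, 100, by = 10)
  fits <- lapply(c(0.5, 1.0), function(D) fit_diffusion(make_curve(lag, 6 * D * lag)))
  D <- vapply(fits, `[[`, numeric(1), "D")
  expect_equal(mean(D), 0.75, tolerance = 1e-12)
  expect_equal(sd(D), sqrt(sum((c(0.5, 1) - 0.75)^2) / 1), tolerance = 1e-12)
  expect_equal(round(sd(D), 4), 0.3536)
})

test_that("snipping selects the smallest candidate on ties and skips short inputs", {
  # identically-zero MSD gives a perfect (degenerate) fit at every candidate
  still <- cell_track("still", t = seq(0, 1440, by = 10),
                      x = rep(0, 145), y = rep(0, 145), z = rep(0, 145))
  prof <- snipping_profile(list(still), lag_grid = c(120, 720, 1440))
  expect_equal(prof$mean_r_squared, rep(1, 3))
  expect_equal(attr(prof, "selected_max_lag"), 120)

  # candidates longer than every track are dropped with a warning
  set.seed(5)
  n <- 61  # 10 h at 10-min sampling
  short <- cell_track("s", t = seq(0, by = 10, length.out = n),
                      x = cumsum(rnorm(n)), y = cumsum(rnorm(n)),
                      z = cumsum(rnorm(n)))
  expect_warning(prof2 <- snipping_profile(list(short), c(120, 720, 1440)),
                 "exceed every track duration")
  expect_false(1440 %in% prof2$candidate_max_lag)

  # tracks shorter than the smallest candidate are skipped
  tiny <- line_track(c(0.1, 0, 0), dt = 10, n_samples = 4)
  expect_warning(snipping_profile(list(tiny, short), c(120, 600)),
                 "skipped")
  expect_error(suppressWarnings(snipping_profile(list(tiny), c(120, 600))),
               "too short")
})

test_that("population_diffusion needs at least two fittable tracks", {
  tiny <- line_track(c(0.1, 0, 0), dt = 10, n_samples = 3)  # only 2 lags
  expect_error(population_diffusion(list(tiny, tiny), max_lag = 240),
               "fewer than two")
  set.seed(6)
  trks <- lapply(1:5, function(i) brownian_track(track_sim_config(duration = 1440),
                                                 track_id = i))
  pd <- population_diffusion(trks, max_lag = 240)
  expect_length(pd$D, 5)
  expect_equal(pd$mean_D, mean(pd$D))
})
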