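test_that("survival probability matches the error-function solution", {
  # absorbing boundary: S(0, t) = 0; no time to diffuse: S(x, 0) = 1
  expect_equal(survival_probability(0, 100, 0.75), 0)
  expect_equal(survival_probability(5, 0, 0.75), 1)
  # x = 2*sqrt(D*t) gives erf(1), evaluated independently by quadrature
  D <- 0.75; t <- 300
  erf1 <- 2 / sqrt(pi) * integrate(function(u) exp(-u^2), 0, 1)$value
  expect_equal(survival_probability(2 * sqrt(D * t), t, D), erf1,
               tolerance = 1e-8)
  expect_equal(round(erf1, 4), 0.8427)
  expect_error(survival_probability(-1, 10, 0.75), "non-negative")
  expect_error(survival_probability(1, -10, 0.75), "non-negative")
})

test_that("survival probability is monotone in x and t and bounded in [0,1]", {
  set.seed(9)
  for (i in 1:25) {
    D <- runif(1, 0.05, 5)
    t <- runif(1, 1, 5000)
    x <- sort(runif(20, 0, 300))
    s <- survival_probability(x, t, D)
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all(diff(s) >= 0))
    s_later <- survival_probability(x, t * runif(1, 1.1, 3), D)
    expect_true(all(s_later <= s + 1e-12))
  }
})

test_that("closed-form egress depth equals the quadrature of 1 - S", {
  set.seed(10)
  for (i in 1:100) {
    D <- runif(1, 0.05, 5)
    t <- runif(1, 10, 5000)
    quad <- integrate(function(x) 1 - survival_probability(x, t, D),
                      0, 20 * sqrt(D * t), rel.tol = 1e-9)$value
    expect_equal(egress_depth(D, t), quad, tolerance = 1e-6)
  }
  expect_equal(egress_depth(0.75, 0), 0)
})

test_that("the default egress prediction gives 37 um, fraction 0.238, ratio 0.475", {
  lambda <- egress_depth(0.75, 1440)
  expect_equal(round(lambda), 37)
  pred <- predicted_count_ratio(D = 0.75, horizon = 1440, box_depth_L = 156,
                                proliferation_R = 2)
  expect_equal(pred$egress_depth_lambda, lambda)
  expect_equal(round(pred$fraction_f, 3), 0.238)
  expect_equal(round(pred$corrected_ratio, 3), 0.475)
  # no proliferation: the ratio is just the egressed fraction
  p1 <- predicted_count_ratio(proliferation_R = 1)
  expect_equal(p1$corrected_ratio, p1$fraction_f)
  # box depth equal to the egress depth and R = 1 gives ratio 1
  pL <- predicted_count_ratio(box_depth_L = lambda, proliferation_R = 1)
  expect_equal(pL$corrected_ratio, 1, tolerance = 1e-12)
})

test_that("the corrected ratio is linear in R^(h/di) and inversely proportional to L", {
  base <- predicted_count_ratio(proliferation_R = 2, horizon = 2880)
  other <- predicted_count_ratio(proliferation_R = 3, horizon = 2880)
  expect_equal(other$corrected_ratio / base$corrected_ratio, (3 / 2)^2,
               tolerance = 1e-12)
  halfL <- predicted_count_ratio(box_depth_L = 78)
  expect_equal(halfL$corrected_ratio,
               2 * predicted_count_ratio(box_depth_L = 156)$corrected_ratio,
               tolerance = 1e-12)
})

test_that("Monte-Carlo egress enforces preconditions and degenerate cases", {
  expect_equal(monte_carlo_egress(0.75, 0, 1, 400, 100), 0)
  expect_error(monte_carlo_egress(0.75, 1440, 10, 100, 100), "depth")
  expect_error(monte_carlo_egress(0.75, 1440, 100, 400, 100), "dt")
  # determinism
  a <- monte_carlo_egress(0.75, 1440, 10, 400, 2000, seed = 11)
  b <- monte_carlo_egress(0.75, 1440, 10, 400, 2000, seed = 11)
  expect_identical(a, b)
})

test_that("Monte-Carlo standard error shrinks with walker count", {
  small <- sapply(1:30, function(s)
    monte_carlo_egress(0.75, 200, 2, 130, 2000, seed = s))
  big <- sapply(1:30, function(s)
    monte_carlo_egress(0.75, 200, 2, 130, 8000, seed = 100 + s))
  expect_lt(sd(big), sd(small))
  # quadrupling the walkers should roughly halve the standard error
  expect_lt(sd(big) / sd(small), 0.8)
  expect_gt(sd(big) / sd(small), 0.3)
})

test_that("count regression recovers exact and hand-computed slopes", {
  x <- c(5, 10, 20, 40)
  exact <- regress_counts(data.frame(x = x, y = 0.48 * x))
  expect_equal(exact$slope_m, 0.48, tolerance = 1e-12)
  expect_equal(exact$ci_low, exact$ci_high, tolerance = 1e-10)
  expect_equal(exact$n_pairs, 4)

  pairs <- data.frame(dense = c(10, 20, 30), open = c(2, 12, 10))
  fit <- regress_counts(pairs)
  # through-origin least squares: sum(xy) / sum(x^2)
  expect_equal(fit$slope_m,
               sum(pairs$dense * pairs$open) / sum(pairs$dense^2),
               tolerance = 1e-12)
  expect_equal(round(fit$slope_m, 4), 0.4)
  expect_lte(fit$ci_low, fit$slope_m)
  expect_gte(fit$ci_high, fit$slope_m)

  with_icpt <- regress_counts(pairs, intercept = TRUE)
  expect_false(identical(with_icpt$slope_m, fit$slope_m))

  expect_error(regress_counts(pairs[1:2, ]), "three")
  expect_error(regress_counts(data.frame(x = c(0, 0, 0), y = 1:3)), "zero")
})
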