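test_that("systematic constants are symmetric with the stated spacing", {
  expect_equal(systematic_constants(2)$constants, c(1.975, 2.025))
  s25 <- systematic_constants(25)
  expect_equal(min(s25$constants), 1.4)
  expect_equal(max(s25$constants), 2.6)
  expect_equal(mean(s25$constants), 2)
  expect_equal(diff(s25$constants), rep(0.05, 24))
  expect_equal(systematic_constants(1)$constants, 2)
  expect_equal(s25$proportions, rep(1 / 25, 25))
  expect_error(systematic_constants(0), "at least 1")
})

test_that("stochastic constants are seed-deterministic and centred on the mean", {
  a <- stochastic_constants(25, seed = 14)
  b <- stochastic_constants(25, seed = 14)
  expect_identical(a$constants, b$constants)
  expect_error(stochastic_constants(5, sd = 0), "sd")
  # CLT: with sd = 0.1 and n = 25 the sample mean lies within 3*sd/sqrt(25)
  # of 2 for (at least) 95% of seeds
  hits <- sapply(1:100, function(s)
    abs(mean(stochastic_constants(25, sd = 0.1, seed = s)$constants) - 2) <=
      3 * 0.1 / 5)
  expect_gte(mean(hits), 0.95)
})

test_that("the instructive transform shifts every constant without reshaping", {
  nt <- subpop_set(c(1.9, 2.1), label = "instructive_nt")
  t_ <- instructive_transform(nt)
  expect_equal(t_$constants, c(2.1, 2.3))
  expect_equal(mean(t_$constants), mean(nt$constants) + 0.2)
  expect_equal(var(t_$constants), var(nt$constants))
  back <- instructive_transform(t_, shift = -0.2)
  expect_equal(back$constants, nt$constants)
  expect_identical(t_$label, "instructive_t")
})

test_that("the permissive transform samples the truncated normal law", {
  p <- permissive_transform(mean = 2, sd = 0.1, threshold = 2.15, n = 25,
                            seed = 15)
  expect_true(all(p$constants >= 2.15))
  expect_gt(mean(p$constants), 2)
  # empirical mean of many draws vs the truncated-normal mean by quadrature
  big <- permissive_transform(n = 10000, seed = 16)
  num <- integrate(function(x) x * dnorm(x, 2, 0.1), 2.15, Inf)$value
  den <- integrate(function(x) dnorm(x, 2, 0.1), 2.15, Inf)$value
  expect_equal(mean(big$constants), num / den, tolerance = 0.02)
  expect_error(permissive_transform(sd = 0.1, threshold = 3), "acceptance")
})

test_that("growth follows N(t) = sum N_n0 * R_n^t with t in days", {
  expect_equal(grow(1000, 2, days = 7), 128000)
  expect_equal(grow(c(0, 0, 0), c(1.5, 2, 2.5)), 0)
  # exact rational arithmetic: 2.2 = 11/5, so 2.2^7 = 11^7 / 5^7
  expect_equal(grow(c(500, 500), c(2, 2.2), days = 7),
               500 * 2^7 + 500 * 11^7 / 5^7, tolerance = 1e-12)
  expect_error(grow(c(1, 2), c(2)), "length")
  expect_error(grow(c(-1, 2), c(2, 2)), "non-negative")
})

test_that("dilution draws conserve counts and never exceed the parent well", {
  design <- plate_design(wells_per_block = 4, seed_counts = c(50, 20, 5),
                         analyzed_blocks = c(20, 5))
  set <- systematic_constants(3)
  plate <- simulate_plate(set, design, seed = 17)
  expect_equal(unname(rowSums(plate$seeded[["50"]])), rep(50, 4))
  expect_equal(unname(rowSums(plate$seeded[["20"]])), rep(20, 4))
  expect_equal(unname(rowSums(plate$seeded[["5"]])), rep(5, 4))
  expect_true(all(plate$seeded[["20"]] <= plate$seeded[["50"]]))
  expect_true(all(plate$seeded[["5"]] <= plate$seeded[["20"]]))

  # default design: every source well holds exactly 1111 cells
  full <- simulate_plate(systematic_constants(5), seed = 18)
  expect_equal(unname(rowSums(full$seeded[["1111"]])), rep(1111, 24))
  expect_equal(unname(rowSums(full$seeded[["1"]])), rep(1, 24))
})

test_that("subpopulation draws follow the hypergeometric marginal", {
  set.seed(19)
  draws <- t(replicate(4000, transmig:::rmvhyper(20, c(30, 70))))
  expect_true(all(rowSums(draws) == 20))
  expect_true(all(draws[, 1] <= 30 & draws[, 2] <= 70))
  x <- 0:20
  expected <- dhyper(x, 30, 70, 20) * 4000
  observed <- tabulate(draws[, 1] + 1L, nbins = 21)
  keep <- expected >= 5
  chi <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  expect_gt(pchisq(chi, sum(keep) - 1, lower.tail = FALSE), 0.001)
})

test_that("identical seeds reproduce a plate bit for bit", {
  set <- stochastic_constants(10, seed = 20)
  a <- simulate_plate(set, seed = 21)
  b <- simulate_plate(set, seed = 21)
  expect_identical(a$seeded, b$seeded)
  expect_identical(a$final_totals, b$final_totals)
})

test_that("homogeneous populations give CV = 0 and the 1-cell block is excluded", {
  plate <- simulate_plate(subpop_set(2), seed = 22)
  prof <- cv_profile(plate)
  expect_equal(prof$seed_count, c(1000, 100, 10))
  expect_equal(prof$cv, rep(0, 3))
  expect_equal(prof$n_wells, rep(24L, 3))
})

test_that("oversized transfers are capped with a warning", {
  expect_warning(k <- transmig:::transfer_count(2000, 0, 1111), "capped")
  expect_equal(k, 1111L)
})

test_that("mean CV rises as the seeded cell number falls", {
  set <- systematic_constants(5)
  cvs <- simulate_scenario_cv(set, replicates = 100, seed = 23)
  mean_cv <- tapply(cvs$cv, cvs$seed_count, mean)
  expect_lt(mean_cv[["1000"]], mean_cv[["100"]])
  expect_lt(mean_cv[["100"]], mean_cv[["10"]])
})

test_that("mean CV rises with the number of subpopulations at every block", {
  by_n <- lapply(c(2, 10, 25), function(n) {
    cvs <- simulate_scenario_cv(systematic_constants(n), replicates = 50,
                                seed = 24)
    tapply(cvs$cv, cvs$seed_count, mean)
  })
  for (block in c("1000", "100", "10")) {
    vals <- sapply(by_n, `[[`, block)
    expect_true(all(diff(vals) > 0))
  }
})

test_that("trend tests detect nothing in identical groups and reject degenerate input", {
  tab <- data.frame(cv = rep(c(0.1, 0.2, 0.3), 2),
                    grp = rep(c("a", "b"), each = 3))
  res <- compare_trends(tab, "grp")
  expect_gt(res$p_value, 0.99)
  tab3 <- data.frame(cv = rep(c(0.1, 0.2), 3),
                     grp = rep(c("a", "b", "c"), each = 2))
  expect_gt(compare_trends(tab3, "grp")$p_value, 0.99)
  expect_error(compare_trends(data.frame(cv = 1:3, grp = c("a", "a", "b")),
                              "grp"), "at least two")
  expect_error(compare_trends(tab, "missing"), "not found")
})
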