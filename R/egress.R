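#' Survival probability against an absorbing boundary
#'
#' Probability that a Brownian walker with diffusion coefficient `D`,
#' starting at distance `x` from an absorbing plane at 0, has not been
#' absorbed by time `t`. This is the classical one-dimensional
#' absorbing-boundary solution
#' \deqn{S(x, t) = \mathrm{erf}\!\left(\frac{x}{2\sqrt{D t}}\right).}
#'
#' @param x Distance from the boundary (µm), non-negative; vectorised.
#' @param t Elapsed time (minutes), non-negative.
#' @param D Diffusion coefficient (µm² min⁻¹), positive.
#' @return Survival probabilities in \[0, 1\].
#' @export
survival_probability <- function(x, t, D) {
  if (any(x < 0)) stop("x must be non-negative", call. = FALSE)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (D <= 0) stop("D must be positive", call. = FALSE)
  n <- max(length(x), length(t))
  x <- rep_len(x, n)
  t <- rep_len(t, n)
  out <- numeric(n)
  pos <- t > 0
  out[pos] <- erf(x[pos] / (2 * sqrt(D * t[pos])))
  out[!pos] <- as.numeric(x[!pos] > 0)
  # x = 0 corner: define as absorbed (consistent with x = 0, t > 0)
  out[x == 0] <- 0
  out
}

# error function via the normal CDF
erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1

#' Expected egress depth from a half-space
#'
#' Integrating the absorbed fraction \eqn{1 - S(x, t)} over the populated
#' half-space gives the equivalent slab depth emptied across the absorbing
#' boundary per unit interface area:
#' \deqn{\lambda(t) = \int_0^\infty \left(1 - S(x,t)\right) dx
#'       = 2\sqrt{D t / \pi}.}
#' With D = 0.75 µm² min⁻¹ and t = 24 h this evaluates to 37.08 µm.
#'
#' @inheritParams survival_probability
#' @return Egress depth in µm.
#' @export
egress_depth <- function(D, t) {
  if (D <= 0) stop("D must be positive", call. = FALSE)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  2 * sqrt(D * t / pi)
}

#' Predicted open-compartment/dense-compartment count ratio
#'
#' Converts a diffusion coefficient into the expected ratio of the
#' open-compartment cell count after `horizon` minutes to the dense-side
#' count at time 0, for a counting box of depth `box_depth_L` perpendicular
#' to the interface. The egressed fraction is
#' `egress_depth(D, horizon) / box_depth_L`; a multiplicative proliferation
#' correction `R^(horizon / doubling_interval)` accounts for cell doubling
#' over the observation window.
#'
#' With the defaults (D = 0.75 µm² min⁻¹, 24 h horizon, 156 µm box, one
#' doubling) the fraction is 0.2377 and the corrected ratio 0.4754.
#'
#' @param D Diffusion coefficient (µm² min⁻¹).
#' @param horizon Observation window (minutes).
#' @param box_depth_L Counting-box depth perpendicular to the interface (µm).
#' @param proliferation_R Per-doubling-interval proliferation factor (≥ 1).
#' @param doubling_interval Minutes per proliferation interval (default 1440).
#' @return A list of class `egress_prediction` with `egress_depth_lambda`
#'   (µm), `fraction_f` and `corrected_ratio`.
#' @export
predicted_count_ratio <- function(D = 0.75, horizon = 1440, box_depth_L = 156,
                                  proliferation_R = 2, doubling_interval = 1440) {
  if (D <= 0 || horizon <= 0 || box_depth_L <= 0) {
    stop("D, horizon and box_depth_L must be positive", call. = FALSE)
  }
  if (proliferation_R < 1) stop("proliferation_R must be >= 1", call. = FALSE)
  lambda <- egress_depth(D, horizon)
  f <- lambda / box_depth_L
  structure(
    list(egress_depth_lambda = lambda,
         fraction_f = f,
         corrected_ratio = f * proliferation_R^(horizon / doubling_interval),
         params = list(D = D, horizon = horizon, box_depth_L = box_depth_L,
                       proliferation_R = proliferation_R,
                       doubling_interval = doubling_interval)),
    class = "egress_prediction"
  )
}

#' @export
print.egress_prediction <- function(x, ...) {
  cat(sprintf(paste0("<egress_prediction: depth = %.2f um, fraction = %.4f, ",
                     "proliferation-corrected ratio = %.4f>\n"),
              x$egress_depth_lambda, x$fraction_f, x$corrected_ratio))
  invisible(x)
}

#' Monte-Carlo oracle for the egress depth
#'
#' Simulates independent 1D Brownian walkers starting uniformly in
#' `[0, depth]` with an absorbing boundary at 0 and returns
#' `depth * absorbed_fraction`, the Monte-Carlo estimate of the egress
#' depth.
#'
#' With `bridge = TRUE` (default) each surviving step from `a` to `b`
#' additionally absorbs with the Brownian-bridge crossing probability
#' `exp(-a*b / (D*dt))`, which removes the downward bias of detecting
#' absorption only at sampled times and makes the estimate converge to the
#' continuous-time closed form [egress_depth()]. With `bridge = FALSE`
#' absorption is scored only when a sampled position lies at or below the
#' boundary, matching trackers that observe positions at discrete frames.
#'
#' @inheritParams survival_probability
#' @param dt Time step (minutes); must satisfy `dt <= t / 100`.
#' @param depth Initial slab depth (µm); must be at least `10 * sqrt(D*t)`
#'   so that truncating the half-space is negligible.
#' @param n_walkers Number of walkers.
#' @param seed Optional integer seed for reproducibility.
#' @param bridge Apply the Brownian-bridge crossing correction?
#' @return Estimated egress depth (µm).
#' @export
monte_carlo_egress <- function(D, t, dt, depth, n_walkers, seed = NULL,
                               bridge = TRUE) {
  if (D <= 0) stop("D must be positive", call. = FALSE)
  if (t < 0) stop("t must be non-negative", call. = FALSE)
  if (t == 0) return(0)
  if (depth < 10 * sqrt(D * t)) {
    stop("depth must be at least 10*sqrt(D*t) = ",
         round(10 * sqrt(D * t), 1), " um", call. = FALSE)
  }
  if (dt > t / 100) {
    stop("dt must not exceed t/100 = ", t / 100, " min", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_steps <- ceiling(t / dt)
  h <- t / n_steps
  sd_step <- sqrt(2 * D * h)
  x <- stats::runif(n_walkers, 0, depth)
  n_alive <- length(x)
  for (s in seq_len(n_steps)) {
    xn <- x + stats::rnorm(length(x), 0, sd_step)
    surv <- xn > 0
    if (bridge && any(surv)) {
      p_cross <- exp(-x[surv] * xn[surv] / (D * h))
      surv[surv] <- stats::runif(sum(surv)) >= p_cross
    }
    x <- xn[surv]
    if (!length(x)) break
  }
  depth * (1 - length(x) / n_walkers)
}

#' Regression of open-side counts on dense-side counts
#'
#' Least-squares regression of the open-compartment cell count at the end
#' of the observation window on the dense-compartment count at time 0,
#' through the origin by default (the egress model predicts strict
#' proportionality), with a 95% confidence interval on the slope.
#'
#' @param pairs A two-column data frame or matrix: dense-side counts at
#'   0 h, open-side counts at the horizon. At least three pairs.
#' @param intercept Include an intercept? Default `FALSE` (through origin).
#' @param conf_level Confidence level for the slope interval.
#' @return A list of class `count_regression` with `slope_m`, `ci_low`,
#'   `ci_high` and `n_pairs`.
#' @export
regress_counts <- function(pairs, intercept = FALSE, conf_level = 0.95) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) < 3L) stop("at least three count pairs are needed", call. = FALSE)
  x <- pairs[[1L]]
  y <- pairs[[2L]]
  if (all(x == 0)) stop("all dense-side counts are zero", call. = FALSE)
  fit <- if (intercept) stats::lm(y ~ x) else stats::lm(y ~ 0 + x)
  ci <- suppressWarnings(stats::confint(fit, "x", level = conf_level))
  structure(
    list(slope_m = unname(stats::coef(fit)[["x"]]),
         ci_low = ci[1L], ci_high = ci[2L], n_pairs = nrow(pairs),
         intercept = if (intercept) unname(stats::coef(fit)[["(Intercept)"]]) else 0,
         conf_level = conf_level),
    class = "count_regression"
  )
}

#' @export
print.count_regression <- function(x, ...) {
  cat(sprintf("<count_regression: m = %.4f [%.4f, %.4f] (n = %d)>\n",
              x$slope_m, x$ci_low, x$ci_high, x$n_pairs))
  invisible(x)
}
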