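#' Time-averaged mean squared displacement of a 3D track
#'
#' For each lag \eqn{\Delta t} (a multiple of the sampling interval, up to
#' `max_lag`) the squared 3D displacement
#' \eqn{\Delta x^2 + \Delta y^2 + \Delta z^2} is averaged over all ordered,
#' overlapping sample pairs separated by that lag. For freely diffusing
#' cells the curve is linear, \eqn{\langle\Delta r^2\rangle = 6 D \Delta t}.
#'
#' Irregularly sampled tracks are handled by binning pair separations to the
#' nearest multiple of the (median) sampling interval within `lag_tol`.
#'
#' @param track A [cell_track()] with at least two samples.
#' @param max_lag Largest lag to report, in minutes.
#' @param lag_tol Tolerance for assigning a pair separation to a lag bin
#'   (minutes); defaults to half the sampling interval.
#' @return A data frame of class `msd_curve` with columns `lag` (min),
#'   `msd` (µm²) and `n_pairs`, and attributes `interval` and `max_lag`.
#' @export
compute_msd <- function(track, max_lag, lag_tol = NULL) {
  n <- nrow(track)
  if (n < 2L) stop("track needs at least two samples", call. = FALSE)
  t <- track$t
  p <- track_positions(track)
  dtv <- diff(t)
  interval <- stats::median(dtv)
  if (is.null(lag_tol)) lag_tol <- interval / 2
  kmax <- floor(max_lag / interval + 1e-9)
  if (kmax < 1L) {
    stop("max_lag (", max_lag, " min) is smaller than the sampling interval (",
         interval, " min): empty MSD curve", call. = FALSE)
  }
  uniform <- all(abs(dtv - interval) <= 1e-9 * max(interval, 1))
  if (uniform) {
    kk <- seq_len(min(kmax, n - 1L))
    msd <- numeric(length(kk))
    n_pairs <- integer(length(kk))
    for (i in seq_along(kk)) {
      k <- kk[i]
      d <- p[(k + 1L):n, , drop = FALSE] - p[seq_len(n - k), , drop = FALSE]
      msd[i] <- mean(rowSums(d^2))
      n_pairs[i] <- n - k
    }
    lags <- kk * interval
  } else {
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    sep <- t[ij[, 2L]] - t[ij[, 1L]]
    k <- round(sep / interval)
    ok <- k >= 1 & k <= kmax & abs(sep - k * interval) <= lag_tol
    if (!any(ok)) {
      stop("no sample pairs fall on the lag grid within the tolerance",
           call. = FALSE)
    }
    d2 <- rowSums((p[ij[ok, 2L], , drop = FALSE] -
                     p[ij[ok, 1L], , drop = FALSE])^2)
    kf <- factor(k[ok])
    msd <- as.numeric(tapply(d2, kf, mean))
    n_pairs <- as.integer(table(kf))
    lags <- as.numeric(levels(kf)) * interval
  }
  structure(
    data.frame(lag = lags, msd = msd, n_pairs = n_pairs),
    interval = interval, max_lag = max_lag,
    class = c("msd_curve", "data.frame")
  )
}

#' Diffusion coefficient from a linear MSD fit
#'
#' Ordinary least-squares regression of MSD against lag; for 3D diffusion
#' the slope equals \eqn{6D}, so `D = slope / 6`. The intercept absorbs
#' localisation noise and is included by default; set `intercept = FALSE`
#' to force the line through the origin.
#'
#' @param curve An `msd_curve` with at least three lags.
#' @param intercept Include an intercept term? Default `TRUE`.
#' @return A list of class `diffusion_fit` with elements `D` (µm² min⁻¹),
#'   `slope`, `intercept`, `r_squared`, `max_lag` and
#'   `nonpositive_slope` (flag; a fitted slope ≤ 0 is reported as-is).
#' @export
fit_diffusion <- function(curve, intercept = TRUE) {
  if (nrow(curve) < 3L) {
    stop("at least three lags are needed for a diffusion fit", call. = FALSE)
  }
  lag <- curve$lag
  msd <- curve$msd
  fit <- if (intercept) stats::lm(msd ~ lag) else stats::lm(msd ~ 0 + lag)
  cf <- stats::coef(fit)
  slope <- unname(cf[["lag"]])
  icpt <- if (intercept) unname(cf[["(Intercept)"]]) else 0
  # summary.lm warns on numerically perfect fits; those are legitimate here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) {
    # zero-variance curve (e.g. msd identically 0): a perfect fit
    r2 <- if (sum(stats::resid(fit)^2) < 1e-20) 1 else 0
  }
  structure(
    list(D = slope / 6, slope = slope, intercept = icpt,
         r_squared = r2, max_lag = attr(curve, "max_lag"),
         nonpositive_slope = slope <= 0),
    class = "diffusion_fit"
  )
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit: D = %.4g um^2/min, r^2 = %.4f%s>\n",
              x$D, x$r_squared,
              if (x$nonpositive_slope) ", non-positive slope" else ""))
  invisible(x)
}

#' Snipping analysis: choose the maximal MSD lag
#'
#' Scans a grid of candidate maximal lags, fits each track's MSD curve up
#' to each candidate, and records the mean regression quality (r²) and mean
#' slope across tracks. Short maximal lags waste data; long ones admit the
#' noisy, poorly sampled tail of the MSD curve. The candidate maximising
#' the mean r² is selected (ties broken towards the smallest lag); the mean
#' slope per candidate is reported as a plateau diagnostic but does not
#' drive selection.
#'
#' Tracks shorter than the smallest candidate are skipped with a warning;
#' candidates longer than every usable track are dropped with a warning.
#'
#' @param tracks A list of [cell_track()] objects.
#' @param lag_grid Increasing vector of candidate maximal lags (minutes).
#' @param intercept Passed to [fit_diffusion()].
#' @return A data frame of class `snipping_profile` with columns
#'   `candidate_max_lag`, `mean_r_squared`, `mean_slope`, `n_tracks`, and
#'   attribute `selected_max_lag`.
#' @export
snipping_profile <- function(tracks, lag_grid, intercept = TRUE) {
  if (length(tracks) < 1L) stop("no tracks given", call. = FALSE)
  if (is.unsorted(lag_grid, strictly = TRUE)) {
    stop("lag_grid must be strictly increasing", call. = FALSE)
  }
  durations <- vapply(tracks, track_duration, numeric(1))
  usable <- durations >= min(lag_grid)
  if (any(!usable)) {
    warning(sum(!usable), " track(s) shorter than the smallest candidate lag",
            " were skipped", call. = FALSE)
  }
  if (!any(usable)) stop("all tracks are too short for the lag grid", call. = FALSE)
  tracks <- tracks[usable]
  durations <- durations[usable]

  rows <- lapply(lag_grid, function(L) {
    idx <- which(durations >= L)
    if (!length(idx)) return(NULL)
    fits <- lapply(tracks[idx], function(tr) {
      fit_diffusion(compute_msd(tr, max_lag = L), intercept = intercept)
    })
    data.frame(candidate_max_lag = L,
               mean_r_squared = mean(vapply(fits, `[[`, numeric(1), "r_squared")),
               mean_slope = mean(vapply(fits, `[[`, numeric(1), "slope")),
               n_tracks = length(idx))
  })
  dropped <- vapply(rows, is.null, logical(1))
  if (any(dropped)) {
    warning("candidate lag(s) ", paste(lag_grid[dropped], collapse = ", "),
            " min exceed every track duration and were dropped", call. = FALSE)
  }
  prof <- do.call(rbind, rows[!dropped])
  best <- which(prof$mean_r_squared >= max(prof$mean_r_squared) - 1e-12)[1L]
  structure(prof,
            selected_max_lag = prof$candidate_max_lag[best],
            class = c("snipping_profile", "data.frame"))
}

#' Population diffusion coefficient
#'
#' Per-track MSD fit followed by the unweighted mean and sample standard
#' deviation of the per-track diffusion coefficients.
#'
#' @inheritParams snipping_profile
#' @param max_lag Maximal lag (minutes) for every per-track fit.
#' @return A list with `mean_D`, `sd_D`, `n_tracks`, and the per-track
#'   coefficients `D`.
#' @export
population_diffusion <- function(tracks, max_lag, intercept = TRUE) {
  fits <- lapply(tracks, function(tr) {
    curve <- compute_msd(tr, max_lag = max_lag)
    if (nrow(curve) < 3L) return(NULL)
    fit_diffusion(curve, intercept = intercept)
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) < 2L) {
    stop("fewer than two tracks could be fitted", call. = FALSE)
  }
  D <- vapply(fits, `[[`, numeric(1), "D")
  list(mean_D = mean(D), sd_D = stats::sd(D), n_tracks = length(D), D = D)
}
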