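#' Configuration for synthetic single-cell tracks
#'
#' Defaults mirror the imaging study conditions: positions sampled every
#' 10 min, random migration with D = 0.75 µm² min⁻¹ in the dense matrix,
#' directed migration at 0.3 µm min⁻¹, 72 h track duration.
#'
#' @param D Diffusion coefficient of the random-migration mode (µm² min⁻¹).
#' @param speed Speed of the directed-migration mode (µm min⁻¹).
#' @param dt Sampling interval (minutes).
#' @param duration Track duration (minutes, ≥ 2·dt).
#' @param seed Optional integer seed.
#' @return A list of class `track_sim_config`.
#' @export
track_sim_config <- function(D = 0.75, speed = 0.3, dt = 10,
                             duration = 4320, seed = NULL) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (duration < 2 * dt) stop("duration must be at least 2*dt", call. = FALSE)
  structure(list(D = D, speed = speed, dt = dt, duration = duration,
                 seed = seed),
            class = "track_sim_config")
}

#' Simulate a Brownian (random-migration) track
#'
#' Independent Gaussian per-axis displacements with variance `2*D*dt` per
#' step, the discrete-time signature of 3D diffusion. Deterministic given
#' the config seed.
#'
#' @param config A [track_sim_config()].
#' @param origin Starting position (length-3, µm).
#' @param track_id Identifier for the generated track.
#' @return A [cell_track()].
#' @export
brownian_track <- function(config = track_sim_config(), origin = c(0, 0, 0),
                           track_id = "brownian") {
  if (!is.null(config$seed)) set.seed(config$seed)
  n_steps <- floor(config$duration / config$dt)
  steps <- matrix(stats::rnorm(3L * n_steps, 0, sqrt(2 * config$D * config$dt)),
                  n_steps, 3L)
  pos <- rbind(origin, sweep(apply(steps, 2L, cumsum), 2L, origin, `+`))
  t <- seq(0, by = config$dt, length.out = n_steps + 1L)
  cell_track(track_id, t, pos[, 1L], pos[, 2L], pos[, 3L])
}

# unit vectors perpendicular to u, with uniform azimuth; m draws
random_perpendicular <- function(u, m) {
  r <- matrix(stats::rnorm(3L * m), m, 3L)
  proj <- r - (r %*% u)[, 1L] %o% u
  # realistically never degenerate; guard anyway
  nrm <- sqrt(rowSums(proj^2))
  bad <- nrm < 1e-12
  if (any(bad)) {
    fallback <- if (abs(u[3L]) < 0.9) c(-u[2L], u[1L], 0) else c(0, -u[3L], u[2L])
    proj[bad, ] <- matrix(rep(fallback, sum(bad)), ncol = 3L, byrow = TRUE)
    nrm[bad] <- sqrt(sum(fallback^2))
  }
  proj / nrm
}

#' Simulate a directed (post-transmigration) track
#'
#' Constant step length `speed * dt`; each step's heading is the base
#' direction tilted by a normally distributed angle (sd
#' `angular_noise_sd`) about a uniformly random perpendicular axis.
#' With zero noise the track is perfectly straight (directionality 1).
#'
#' @param config A [track_sim_config()].
#' @param direction Base direction (length-3, non-zero).
#' @param angular_noise_sd Angular noise sd in radians (≥ 0).
#' @param origin Starting position (µm).
#' @param track_id Identifier.
#' @return A [cell_track()].
#' @export
directed_track <- function(config = track_sim_config(), direction = c(1, 0, 0),
                           angular_noise_sd = 0.3, origin = c(0, 0, 0),
                           track_id = "directed") {
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be non-zero", call. = FALSE)
  if (angular_noise_sd < 0) stop("angular_noise_sd must be >= 0", call. = FALSE)
  u <- direction / nrm
  if (!is.null(config$seed)) set.seed(config$seed)
  n_steps <- floor(config$duration / config$dt)
  step_len <- config$speed * config$dt
  if (angular_noise_sd == 0) {
    headings <- matrix(u, n_steps, 3L, byrow = TRUE)
  } else {
    theta <- stats::rnorm(n_steps, 0, angular_noise_sd)
    perp <- random_perpendicular(u, n_steps)
    headings <- cos(theta) %o% u + sin(theta) * perp
  }
  pos <- rbind(origin, sweep(apply(step_len * headings, 2L, cumsum),
                             2L, origin, `+`))
  t <- seq(0, by = config$dt, length.out = n_steps + 1L)
  cell_track(track_id, t, pos[, 1L], pos[, 2L], pos[, 3L])
}

#' Count positions inside a half-open 3D box
#'
#' A position is counted when it lies in `[lower, upper)` on every axis
#' (points exactly on a low face count, points on a high face do not).
#'
#' @param positions Numeric matrix with columns x, y, z (or a length-3
#'   vector for a single position).
#' @param lower,upper Length-3 box bounds (µm), `lower < upper` on each axis.
#' @return Integer count.
#' @export
count_in_box <- function(positions, lower, upper) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3L)
  if (any(upper <= lower)) stop("box bounds are inverted", call. = FALSE)
  if (!nrow(positions)) return(0L)
  inside <- positions[, 1L] >= lower[1L] & positions[, 1L] < upper[1L] &
    positions[, 2L] >= lower[2L] & positions[, 2L] < upper[2L] &
    positions[, 3L] >= lower[3L] & positions[, 3L] < upper[3L]
  sum(inside)
}

#' Configuration for a two-compartment interface experiment
#'
#' Geometry follows the imaging analysis volume: counting boxes of 156 µm
#' perpendicular to the interface in each compartment, 312 µm laterally and
#' 250 µm in z. Cells are seeded beyond the dense counting box up to
#' `dense_far_depth` so the slab behaves like a half-space over the
#' observation horizon.
#'
#' @param n_cells Number of cells seeded in the dense slab.
#' @param box Named or ordered length-3 extents (x per compartment, y, z)
#'   in µm.
#' @param interface_x Interface plane coordinate (default 0; dense side
#'   `x < interface_x`).
#' @param horizon Observation window (minutes, default 1440 = 24 h).
#' @param doubling_interval Minutes between synchronized population
#'   doublings (default 1440; `Inf` disables proliferation).
#' @param dense_far_depth Total seeded dense-slab depth (µm, ≥ box x extent;
#'   default 400, at least 10·sqrt(D·t) for the default parameters).
#' @param dt Sampling interval (minutes).
#' @param seed Optional integer seed.
#' @return A list of class `interface_config`.
#' @export
interface_config <- function(n_cells = 200,
                             box = c(x = 156, y = 312, z = 250),
                             interface_x = 0, horizon = 1440,
                             doubling_interval = 1440,
                             dense_far_depth = 400, dt = 10, seed = NULL) {
  if (any(box <= 0) || horizon <= 0 || dt <= 0 || dense_far_depth < box[[1L]]) {
    stop("invalid interface experiment geometry", call. = FALSE)
  }
  structure(list(n_cells = n_cells, box = unname(box),
                 interface_x = interface_x, horizon = horizon,
                 doubling_interval = doubling_interval,
                 dense_far_depth = dense_far_depth, dt = dt, seed = seed),
            class = "interface_config")
}

#' Simulate a two-compartment interface migration experiment
#'
#' Cells start uniformly distributed in the dense slab
#' `[interface_x - dense_far_depth, interface_x)` and migrate as 3D
#' Brownian walkers with diffusion coefficient `D_dense`. On the first
#' sampled position at or beyond the interface a cell switches
#' irreversibly to directed migration away from the interface at
#' `speed_open` (the instructive rule), with per-step angular noise.
#' The population doubles synchronously (every cell duplicated in place)
#' at each multiple of `doubling_interval` up to and including the horizon.
#'
#' Counting follows the egress model's bookkeeping: `n_dense_0h` is the
#' number of cells initially inside the dense counting box (x within
#' `box[1]` of the interface), and `n_open_final` counts all transmigrated
#' cells at the horizon (the open compartment retains its cells; the
#' lateral box faces are not applied, since the lateral environment is
#' statistically homogeneous). Use [count_in_box()] on the returned
#' positions for strict 3D-box counts.
#'
#' @param config An [interface_config()].
#' @param D_dense Dense-side diffusion coefficient (µm² min⁻¹).
#' @param speed_open Open-side directed speed (µm min⁻¹).
#' @param angular_noise_sd Open-side angular noise (radians).
#' @param return_tracks Build per-cell [cell_track()] objects? (Skipping
#'   them saves memory for large ensembles.)
#' @return A list of class `interface_experiment` with `n_dense_0h`,
#'   `n_open_final`, `n_crossed` (pre-doubling crossers), `fraction_crossed`
#'   (crossers / seeded cells), `final_positions`, `crossed` (per final
#'   cell), and `tracks` (list of tracks, or `NULL`).
#' @export
interface_experiment <- function(config = interface_config(),
                                 D_dense = 0.75, speed_open = 0.3,
                                 angular_noise_sd = 0.3,
                                 return_tracks = TRUE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n0 <- config$n_cells
  ix <- config$interface_x
  bx <- config$box[1L]; by <- config$box[2L]; bz <- config$box[3L]
  x <- stats::runif(n0, ix - config$dense_far_depth, ix)
  y <- stats::runif(n0, 0, by)
  z <- stats::runif(n0, 0, bz)
  crossed <- rep(FALSE, n0)
  n_dense_0h <- sum(x >= ix - bx & x < ix)

  times <- seq(0, config$horizon, by = config$dt)
  n_steps <- length(times) - 1L
  sd_b <- sqrt(2 * D_dense * config$dt)
  step_len <- speed_open * config$dt
  ex <- c(1, 0, 0)

  hist <- if (return_tracks) {
    H <- vector("list", length(times))
    H[[1L]] <- cbind(x, y, z)
    H
  }
  birth <- rep(1L, n0)  # index into times at which each cell exists

  for (s in seq_len(n_steps)) {
    nb <- sum(!crossed)
    if (nb) {
      x[!crossed] <- x[!crossed] + stats::rnorm(nb, 0, sd_b)
      y[!crossed] <- y[!crossed] + stats::rnorm(nb, 0, sd_b)
      z[!crossed] <- z[!crossed] + stats::rnorm(nb, 0, sd_b)
    }
    nc <- sum(crossed)
    if (nc) {
      if (angular_noise_sd > 0) {
        theta <- stats::rnorm(nc, 0, angular_noise_sd)
        perp <- random_perpendicular(ex, nc)
        hd <- cos(theta) %o% ex + sin(theta) * perp
      } else {
        hd <- matrix(ex, nc, 3L, byrow = TRUE)
      }
      x[crossed] <- x[crossed] + step_len * hd[, 1L]
      y[crossed] <- y[crossed] + step_len * hd[, 2L]
      z[crossed] <- z[crossed] + step_len * hd[, 3L]
    }
    crossed <- crossed | x >= ix
    # synchronized doubling: duplicate every cell in place
    if (is.finite(config$doubling_interval) &&
        times[s + 1L] %% config$doubling_interval == 0) {
      x <- c(x, x); y <- c(y, y); z <- c(z, z)
      crossed <- c(crossed, crossed)
      if (return_tracks) birth <- c(birth, rep(s + 1L, length(birth)))
    }
    if (return_tracks) hist[[s + 1L]] <- cbind(x, y, z)
  }

  n_doublings <- if (is.finite(config$doubling_interval)) {
    floor(config$horizon / config$doubling_interval)
  } else 0L
  n_crossed <- sum(crossed) / 2^n_doublings
  tracks <- NULL
  if (return_tracks) {
    tracks <- lapply(seq_along(x), function(i) {
      idx <- birth[i]:length(times)
      if (length(idx) < 2L) return(NULL)
      P <- t(vapply(idx, function(s) {
        h <- hist[[s]]
        # cells duplicated later share the parent's earlier rows
        h[if (i <= nrow(h)) i else ((i - 1L) %% nrow(h)) + 1L, ]
      }, numeric(3L)))
      cell_track(paste0("cell_", i), times[idx], P[, 1L], P[, 2L], P[, 3L],
                 interface_x = ix)
    })
    tracks <- tracks[!vapply(tracks, is.null, logical(1))]
  }
  structure(
    list(n_dense_0h = n_dense_0h,
         n_open_final = sum(crossed),
         n_crossed = n_crossed,
         fraction_crossed = n_crossed / n0,
         final_positions = cbind(x = x, y = y, z = z),
         crossed = crossed,
         tracks = tracks,
         config = config),
    class = "interface_experiment"
  )
}

#' Replicate interface experiments for the count regression
#'
#' Runs `n_replicates` independent interface experiments with cell numbers
#' drawn uniformly from `n_cells_range` and returns the
#' (dense-at-0h, open-at-horizon) count pairs consumed by
#' [regress_counts()].
#'
#' @param n_replicates Number of replicate experiments (≥ 3).
#' @param n_cells_range Range of seeded cell numbers per replicate.
#' @param config Template [interface_config()] (its `n_cells` and `seed`
#'   are overridden per replicate).
#' @param D_dense,speed_open,angular_noise_sd Passed to
#'   [interface_experiment()].
#' @param seed Optional integer seed for the whole series.
#' @return A data frame with columns `replicate`, `n_dense_0h`,
#'   `n_open_final`.
#' @export
simulate_interface_replicates <- function(n_replicates = 20,
                                          n_cells_range = c(100, 400),
                                          config = interface_config(),
                                          D_dense = 0.75, speed_open = 0.3,
                                          angular_noise_sd = 0.3,
                                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$n_cells <- sample(seq(n_cells_range[1L], n_cells_range[2L]), 1L)
    cfg$seed <- NULL  # use the running RNG stream
    ex <- interface_experiment(cfg, D_dense, speed_open, angular_noise_sd,
                               return_tracks = FALSE)
    data.frame(replicate = r, n_dense_0h = ex$n_dense_0h,
               n_open_final = ex$n_open_final)
  })
  do.call(rbind, out)
}
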