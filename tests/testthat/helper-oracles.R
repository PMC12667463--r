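# brute-force time-averaged MSD: double loop over all ordered sample pairs,
# binned by index separation (uniform sampling assumed)
brute_msd <- function(track, max_lag) {
  n <- nrow(track)
  interval <- median(diff(track$t))
  kmax <- floor(max_lag / interval + 1e-9)
  p <- as.matrix(track[, c("x", "y", "z")])
  lag <- msd <- n_pairs <- c()
  for (k in seq_len(min(kmax, n - 1L))) {
    acc <- 0
    cnt <- 0L
    for (i in seq_len(n - k)) {
      acc <- acc + sum((p[i + k, ] - p[i, ])^2)
      cnt <- cnt + 1L
    }
    lag <- c(lag, k * interval)
    msd <- c(msd, acc / cnt)
    n_pairs <- c(n_pairs, cnt)
  }
  data.frame(lag = lag, msd = msd, n_pairs = n_pairs)
}

# a uniformly random 3D rotation matrix (QR of a Gaussian matrix)
random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotate_track <- function(track, rot) {
  p <- as.matrix(track[, c("x", "y", "z")]) %*% t(rot)
  cell_track(attr(track, "track_id"), track$t, p[, 1], p[, 2], p[, 3])
}

# straight track with constant velocity vector v (um/min)
line_track <- function(v, dt = 10, n_samples = 30, origin = c(0, 0, 0)) {
  t <- seq(0, by = dt, length.out = n_samples)
  cell_track("line", t,
             origin[1] + v[1] * t, origin[2] + v[2] * t, origin[3] + v[3] * t)
}

# an msd_curve object from raw lag/msd values (for fit-level tests)
make_curve <- function(lag, msd, max_lag = max(lag)) {
  structure(data.frame(lag = lag, msd = msd, n_pairs = rep(10L, length(lag))),
            interval = lag[1], max_lag = max_lag,
            class = c("msd_curve", "data.frame"))
}
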