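#' Construct a single-cell 3D track
#'
#' A cell track is an ordered table of time-stamped 3D positions for one
#' cell, in micrometres, sampled (typically every 10 min) from time-lapse
#' imaging. An optional interface plane perpendicular to the x-axis marks
#' the boundary between the dense ("tumor-like") and open ("stroma-like")
#' matrix compartments; by convention the dense compartment lies at
#' `x < interface_x`.
#'
#' @param track_id Identifier for the cell (coerced to character).
#' @param t Numeric vector of sampling times in minutes, strictly increasing.
#' @param x,y,z Numeric coordinate vectors in micrometres (same length as `t`).
#' @param interface_x Optional x-coordinate (µm) of the interface plane.
#'
#' @return A data frame of class `cell_track` with columns `t`, `x`, `y`,
#'   `z` and attributes `track_id` and `interface_x`.
#' @export
cell_track <- function(track_id, t, x, y, z, interface_x = NULL) {
  n <- length(t)
  if (n < 2L) {
    stop("a cell track needs at least two samples (track_id = ",
         track_id, ")", call. = FALSE)
  }
  if (length(x) != n || length(y) != n || length(z) != n) {
    stop("t, x, y, z must have equal length", call. = FALSE)
  }
  if (!all(is.finite(t)) || !all(is.finite(x)) ||
      !all(is.finite(y)) || !all(is.finite(z))) {
    stop("track coordinates and times must all be finite", call. = FALSE)
  }
  if (any(diff(t) <= 0)) {
    stop("sampling times must be strictly increasing (track_id = ",
         track_id, ")", call. = FALSE)
  }
  structure(
    data.frame(t = as.numeric(t), x = as.numeric(x),
               y = as.numeric(y), z = as.numeric(z)),
    track_id = as.character(track_id),
    interface_x = interface_x,
    class = c("cell_track", "data.frame")
  )
}

# internal: build a (possibly degenerate, < 2 sample) track segment without
# re-validating; used by split_at_interface.
new_track_segment <- function(df, track_id, interface_x = NULL) {
  structure(df,
            track_id = as.character(track_id),
            interface_x = interface_x,
            class = c("cell_track", "data.frame"))
}

#' @export
print.cell_track <- function(x, ...) {
  cat(sprintf("<cell_track '%s': %d samples, %.0f-%.0f min%s>\n",
              attr(x, "track_id"), nrow(x),
              if (nrow(x)) min(x$t) else NA, if (nrow(x)) max(x$t) else NA,
              if (!is.null(attr(x, "interface_x")))
                sprintf(", interface at x = %g um", attr(x, "interface_x"))
              else ""))
  invisible(x)
}

track_positions <- function(track) {
  as.matrix(track[, c("x", "y", "z"), drop = FALSE])
}

track_duration <- function(track) {
  if (nrow(track) < 2L) return(0)
  max(track$t) - min(track$t)
}

#' Speed and directionality of a track
#'
#' Computes the accumulated 3D path length, the Euclidean (net)
#' displacement, the mean speed, and the directionality ratio
#' (Euclidean / accumulated distance), which is 1 for perfectly straight
#' migration and approaches 0 for random or looping motion.
#'
#' @param track A [cell_track()].
#' @return A list of class `migration_metrics` with elements `speed`
#'   (µm min⁻¹), `directionality` (in \[0, 1\]), `euclidean_distance` (µm),
#'   `accumulated_distance` (µm) and `duration` (min).
#' @export
migration_metrics <- function(track) {
  if (nrow(track) < 2L) stop("track needs at least two samples", call. = FALSE)
  p <- track_positions(track)
  duration <- track_duration(track)
  if (duration <= 0) stop("track duration is zero", call. = FALSE)
  steps <- diff(p)
  accumulated <- sum(sqrt(rowSums(steps^2)))
  euclidean <- sqrt(sum((p[nrow(p), ] - p[1L, ])^2))
  directionality <- if (accumulated > 0) euclidean / accumulated else 0
  structure(
    list(speed = accumulated / duration,
         directionality = directionality,
         euclidean_distance = euclidean,
         accumulated_distance = accumulated,
         duration = duration),
    class = "migration_metrics"
  )
}

#' Split a track at the matrix interface
#'
#' The dense compartment is the half-space `x < interface_x`; a crossing is
#' the first sample with `x >= interface_x`. The pre-crossing segment ends
#' at the last dense-side sample before the crossing and the post-crossing
#' segment starts at the first open-side sample, so concatenating the two
#' reproduces the original sample sequence.
#'
#' @param track A [cell_track()].
#' @param interface_x Interface plane coordinate (µm); defaults to the
#'   track's `interface_x` attribute.
#' @return A list with elements `pre` and `post` (track segments, possibly
#'   with fewer than two samples) and `crossed` (logical; `FALSE` when the
#'   track never reaches the open side, in which case `post` is empty).
#' @export
split_at_interface <- function(track, interface_x = attr(track, "interface_x")) {
  if (is.null(interface_x)) {
    stop("no interface_x given and the track carries none", call. = FALSE)
  }
  id <- attr(track, "track_id")
  k <- which(track$x >= interface_x)[1L]
  if (is.na(k)) {
    return(list(
      pre = new_track_segment(track[, , drop = FALSE], id, interface_x),
      post = new_track_segment(track[0L, , drop = FALSE], id, interface_x),
      crossed = FALSE
    ))
  }
  list(
    pre = new_track_segment(track[seq_len(k - 1L), , drop = FALSE], id, interface_x),
    post = new_track_segment(track[seq(k, nrow(track)), , drop = FALSE], id, interface_x),
    crossed = TRUE
  )
}
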