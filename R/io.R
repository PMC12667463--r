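#' Read single-cell track tables
#'
#' Reads a comma-delimited track table with header columns `track_id`,
#' `t_min` (or `frame`, converted via `frame_interval_min`), `x`, `y`, `z`.
#' Rows are grouped by `track_id` and time-sorted; coordinates recorded in
#' pixels are converted to micrometres with `pixel_scale` (the imaging
#' default is 1.253 µm per pixel).
#'
#' @param path Path to the delimited file.
#' @param unit_mode `"um"` (default) or `"px"`; in pixel mode x/y/z are
#'   multiplied by `pixel_scale`.
#' @param pixel_scale Micrometres per pixel (default 1.253).
#' @param frame_interval_min Minutes per frame, required when the file has
#'   a `frame` column instead of `t_min`.
#' @param interface_x Optional interface plane (µm) attached to every track.
#' @return A named list of [cell_track()] objects.
#' @export
read_tracks <- function(path, unit_mode = c("um", "px"), pixel_scale = 1.253,
                        frame_interval_min = NULL, interface_x = NULL) {
  unit_mode <- match.arg(unit_mode)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("track table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if ("t_min" %in% names(df)) {
    df$t <- as.numeric(df$t_min)
  } else if ("frame" %in% names(df)) {
    if (is.null(frame_interval_min)) {
      stop("file has a 'frame' column: frame_interval_min is required",
           call. = FALSE)
    }
    df$t <- as.numeric(df$frame) * frame_interval_min
  } else {
    stop("track table is missing column(s): t_min (or frame)", call. = FALSE)
  }
  scale <- if (unit_mode == "px") pixel_scale else 1
  tracks <- lapply(split(df, df$track_id), function(g) {
    g <- g[order(g$t), , drop = FALSE]
    if (anyDuplicated(g$t)) {
      stop("duplicate time points in track '", g$track_id[1L], "'",
           call. = FALSE)
    }
    cell_track(g$track_id[1L], g$t, g$x * scale, g$y * scale, g$z * scale,
               interface_x = interface_x)
  })
  tracks
}

#' Write single-cell track tables
#'
#' Writes a list of tracks to the comma-delimited dialect read by
#' [read_tracks()] (columns `track_id`, `t_min`, `x`, `y`, `z`, in µm).
#'
#' @param tracks A list of [cell_track()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  df <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(track_id = attr(tr, "track_id"), t_min = tr$t,
               x = tr$x, y = tr$y, z = tr$z)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a 96-well plate readout table
#'
#' Reads end-point per-well signals (e.g. ATP luminescence, assumed
#' proportional to cell number) from a comma-delimited file with columns
#' `well`, `block_seed_count`, `signal`. Blocks whose well count differs
#' from `wells_per_block` are flagged with a warning.
#'
#' @param path Path to the delimited file.
#' @param wells_per_block Expected wells per dilution block (default 24).
#' @return A data frame of class `plate_readout` with the validated records.
#' @export
read_plate <- function(path, wells_per_block = 24) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "block_seed_count", "signal")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("plate table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(df$signal < 0)) stop("negative signals in plate table", call. = FALSE)
  counts <- table(df$block_seed_count)
  off <- counts != wells_per_block
  if (any(off)) {
    warning("block(s) with well count != ", wells_per_block, ": ",
            paste(sprintf("%s (%d wells)", names(counts)[off], counts[off]),
                  collapse = ", "), call. = FALSE)
  }
  structure(df, class = c("plate_readout", "data.frame"))
}

#' CV profile of an experimental plate readout
#'
#' Runs the same coefficient-of-variation computation as [cv_profile()] on
#' measured per-well signals, so experimental readouts and simulated
#' plates share one analysis path.
#'
#' @param readout A [read_plate()] result.
#' @param analyzed_blocks Seed counts to analyze (default 1000, 100, 10).
#' @return A `cv_profile` data frame.
#' @export
readout_cv_profile <- function(readout, analyzed_blocks = c(1000, 100, 10)) {
  rows <- lapply(analyzed_blocks, function(scount) {
    sig <- readout$signal[readout$block_seed_count == scount]
    if (!length(sig)) stop("block ", scount, " not present", call. = FALSE)
    m <- mean(sig)
    cv <- if (m == 0) {
      warning("block ", scount, " has zero mean signal; CV undefined",
              call. = FALSE)
      NA_real_
    } else {
      stats::sd(sig) / m
    }
    data.frame(seed_count = scount, cv = cv, n_wells = length(sig))
  })
  structure(do.call(rbind, rows), class = c("cv_profile", "data.frame"))
}

#' Write and read long-format results tables
#'
#' Thin comma-delimited writers/readers for the analysis outputs; a table
#' written by [write_results_table()] reads back to equal values.
#'
#' @param df A data frame.
#' @param path File path.
#' @return `read_results_table()` returns the data frame;
#'   `write_results_table()` returns `path` invisibly.
#' @export
write_results_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
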