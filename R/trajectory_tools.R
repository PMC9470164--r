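#' Column dialect of TrackMate-style trajectory exports
#'
#' Named character vector mapping the canonical column names used
#' throughout the package (`track_id`, `frame`, `t`, `x`, `y`,
#' `intensity`) to the column headers of a spot-tracker CSV export.
#'
#' @export
trackmate_dialect <- c(track_id = "TRACK_ID", frame = "FRAME",
                       t = "POSITION_T", x = "POSITION_X",
                       y = "POSITION_Y", intensity = "INTENSITY")

#' Read a trajectory table from a spot-tracker CSV export
#'
#' Reads per-spot rows (track id, frame, time, x, y, intensity), groups
#' them by track and sorts by frame.  Rows with missing values in any
#' required column are reported via a warning (count and row numbers
#' attached as attribute `malformed_rows`), never silently dropped
#' without notice.
#'
#' @param path path to the CSV file.
#' @param dialect named character vector mapping canonical names to file
#'   column headers; default [trackmate_dialect].
#' @return A track table: data frame with columns `track_id`, `frame`,
#'   `t`, `x`, `y`, `intensity`, sorted by track then frame.
#' @export
read_tracks <- function(path, dialect = trackmate_dialect) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(all(.track_cols %in% names(dialect)))
  raw <- read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(unname(dialect[.track_cols]), names(raw))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  df <- raw[, unname(dialect[.track_cols])]
  names(df) <- .track_cols
  for (col in c("frame", "t", "x", "y", "intensity"))
    df[[col]] <- as.numeric(df[[col]])
  bad <- !complete.cases(df)
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) dropped (missing values)")
    df <- df[!bad, ]
  }
  df <- df[order(df$track_id, df$frame), ]
  dup <- unlist(tapply(df$frame, df$track_id,
                       function(f) c(FALSE, diff(f) <= 0)), use.names = FALSE)
  if (any(dup))
    stop("non-monotone or duplicated frames within track(s): ",
         paste(unique(df$track_id[dup]), collapse = ", "))
  rownames(df) <- NULL
  attr(df, "malformed_rows") <- which(bad)
  df
}

#' Write a track table as a TrackMate-compatible CSV
#'
#' @param tracks a track table (see [read_tracks()]).
#' @param path output path.
#' @param dialect column-name mapping; default [trackmate_dialect].
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, dialect = trackmate_dialect) {
  stopifnot(all(.track_cols %in% names(tracks)))
  out <- tracks[, .track_cols]
  names(out) <- unname(dialect[.track_cols])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter trajectories with the standard single-particle-tracking rules
#'
#' Applies, in order, the track-level quality filters used for
#' single-molecule dwell and mobility analysis:
#' \enumerate{
#'   \item \emph{track start}: remove tracks that begin in the first frame
#'     (their binding time, hence dwell, is unknown);
#'   \item \emph{track end}: remove tracks present in the last frame
#'     (unbinding not observed);
#'   \item \emph{duration}: remove tracks with fewer than `min_len`
#'     observed frames (default 3, i.e. tracks of <= 2 frames go);
#'   \item \emph{immobile}: remove tracks whose maximum displacement from
#'     their first position stays below `immobile_threshold` (stuck
#'     particles; typically removes a few percent of tracks);
#'   \item \emph{edge}: remove tracks whose mean position lies within
#'     `edge_margin` of the field border (uneven TIRF illumination).
#' }
#'
#' @param tracks a track table.
#' @param movie_n_frames total number of frames in the movie.
#' @param field_bounds either `c(width, height)` or
#'   `c(xmin, xmax, ymin, ymax)`, um.
#' @param min_len minimum number of observed frames to keep a track.
#' @param edge_margin border margin, um; default 5% of the field width.
#' @param immobile_threshold maximum-displacement threshold, um; default
#'   0.04 um (twice the default localization sigma).
#' @return A list with `tracks` (the surviving track table) and `report`
#'   (class `filter_report`: `n_input`, named `n_removed`, `n_output`).
#' @export
filter_tracks <- function(tracks, movie_n_frames, field_bounds,
                          min_len = 3L, edge_margin = NULL,
                          immobile_threshold = 0.04) {
  stopifnot(all(.track_cols %in% names(tracks)), movie_n_frames >= 1)
  if (length(field_bounds) == 2L)
    field_bounds <- c(0, field_bounds[1], 0, field_bounds[2])
  stopifnot(length(field_bounds) == 4L)
  width <- field_bounds[2] - field_bounds[1]
  if (is.null(edge_margin)) edge_margin <- 0.05 * width

  removed <- c(track_start = 0L, track_end = 0L, duration = 0L,
               immobile = 0L, edge = 0L)
  ids <- unique(tracks$track_id)
  n_input <- length(ids)
  if (n_input == 0L) {
    rep <- structure(list(n_input = 0L, n_removed = removed, n_output = 0L),
                     class = "filter_report")
    return(list(tracks = tracks, report = rep))
  }
  by_id <- split(tracks, tracks$track_id)

  drop_rule <- function(keep_ids, pred, rule) {
    bad <- vapply(by_id[as.character(keep_ids)], pred, logical(1))
    removed[rule] <<- sum(bad)
    keep_ids[!bad]
  }
  keep <- ids
  keep <- drop_rule(keep, function(tr) min(tr$frame) <= 1, "track_start")
  keep <- drop_rule(keep, function(tr) max(tr$frame) >= movie_n_frames,
                    "track_end")
  keep <- drop_rule(keep, function(tr) nrow(tr) < min_len, "duration")
  keep <- drop_rule(keep, function(tr) {
    max(sqrt((tr$x - tr$x[1])^2 + (tr$y - tr$y[1])^2)) < immobile_threshold
  }, "immobile")
  keep <- drop_rule(keep, function(tr) {
    mx <- mean(tr$x); my <- mean(tr$y)
    mx < field_bounds[1] + edge_margin || mx > field_bounds[2] - edge_margin ||
      my < field_bounds[3] + edge_margin || my > field_bounds[4] - edge_margin
  }, "edge")

  out <- tracks[tracks$track_id %in% keep, ]
  rownames(out) <- NULL
  rep <- structure(list(n_input = n_input, n_removed = removed,
                        n_output = length(keep)),
                   class = "filter_report")
  list(tracks = out, report = rep)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Track filter: %d in -> %d out\n", x$n_input, x$n_output))
  for (r in names(x$n_removed))
    cat(sprintf("  removed by %-12s %d\n", paste0(r, ":"), x$n_removed[[r]]))
  invisible(x)
}

#' Extract membrane dwell times from tracks
#'
#' The dwell of a track is its observed frame span times the frame
#' interval; gapped tracks (missed detections) contribute by span, so a
#' track observed at frames 3..6 at 0.05 s yields 0.20 s.
#'
#' @param tracks a track table.
#' @param frame_interval frame interval, seconds.
#' @return Numeric vector of dwell times (seconds), one per track.
#' @export
extract_dwells <- function(tracks, frame_interval) {
  .check_pos(frame_interval, "frame_interval")
  if (nrow(tracks) == 0L) return(numeric())
  span <- tapply(tracks$frame, tracks$track_id,
                 function(f) max(f) - min(f) + 1)
  unname(as.numeric(span) * frame_interval)
}

#' Extract per-frame step sizes from tracks
#'
#' Computes 2D displacements `r = sqrt(dx^2 + dy^2)` between consecutive
#' frames only; frame pairs separated by a detection gap are excluded and
#' counted in the `n_gapped` attribute.
#'
#' @param tracks a track table.
#' @return Numeric vector of step sizes (um) with attributes `n_gapped`
#'   (number of excluded gapped pairs) and `n_tracks`.
#' @export
extract_steps <- function(tracks) {
  if (nrow(tracks) == 0L)
    return(structure(numeric(), n_gapped = 0L, n_tracks = 0L))
  by_id <- split(tracks[, c("frame", "x", "y")], tracks$track_id)
  steps <- vector("list", length(by_id))
  n_gapped <- 0L
  for (i in seq_along(by_id)) {
    tr <- by_id[[i]]
    if (nrow(tr) < 2L) next
    df <- diff(tr$frame)
    ok <- df == 1
    n_gapped <- n_gapped + sum(!ok)
    steps[[i]] <- sqrt(diff(tr$x)[ok]^2 + diff(tr$y)[ok]^2)
  }
  structure(unlist(steps, use.names = FALSE), n_gapped = n_gapped,
            n_tracks = length(by_id))
}
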