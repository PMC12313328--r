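# Frame-to-frame linking of detections into single-cell trajectories.
# Cells are sheath-focused on the channel axis and strictly advected, so a
# greedy nearest-neighbour match with a forward-motion constraint suffices;
# crossings are physically impossible.

#' Link per-frame detections into trajectories
#'
#' Greedy nearest-neighbour assignment between consecutive frames under two
#' gates: near-monotone forward motion (Delta x >= -`backward_tolerance`)
#' and displacement at most `max_displacement` (per frame of gap; a track
#' may miss up to `max_missed` consecutive frames before it is closed).
#' Unmatched detections open new tracks. Candidate pairs are matched in
#' order of increasing distance; exact ties break by smaller Delta x, then
#' lower y.
#'
#' @param detections Tibble with `frame`, `x`, `y` (um); other columns are
#'   carried through.
#' @param max_displacement Maximum frame-to-frame displacement (um).
#' @param backward_tolerance Allowed apparent backward motion (um),
#'   default 1.
#' @param max_missed Consecutive missed frames before a track terminates
#'   (default 3).
#' @return The detections tibble (sorted by frame) with a `track_id`
#'   column ("track_0001", ...).
#' @export
link_detections <- function(detections, max_displacement,
                            backward_tolerance = 1, max_missed = 3) {
  stopifnot(is.data.frame(detections),
            all(c("frame", "x", "y") %in% names(detections)))
  if (nrow(detections) == 0) {
    return(dplyr::mutate(detections, track_id = character()))
  }
  det <- dplyr::arrange(detections, .data$frame, .data$x)
  n <- nrow(det)
  track_of <- integer(n)
  # active track state
  act_track <- integer(0); act_x <- numeric(0); act_y <- numeric(0)
  act_frame <- integer(0)
  n_tracks <- 0L
  frames <- unique(det$frame)
  row_by_frame <- split(seq_len(n), factor(det$frame, levels = frames))
  for (f in seq_along(frames)) {
    fr <- frames[f]
    rows <- row_by_frame[[f]]
    # retire stale tracks
    live <- act_frame >= fr - 1L - max_missed
    act_track <- act_track[live]; act_x <- act_x[live]
    act_y <- act_y[live]; act_frame <- act_frame[live]
    assigned_det <- rep(FALSE, length(rows))
    used_track <- rep(FALSE, length(act_track))
    if (length(act_track) > 0) {
      gap <- fr - act_frame
      dx <- outer(-act_x, det$x[rows], `+`)          # x_det - x_track
      dy <- outer(-act_y, det$y[rows], `+`)
      dist <- sqrt(dx^2 + dy^2)
      ok <- dx >= -backward_tolerance & dist <= max_displacement * gap
      if (any(ok)) {
        cand <- which(ok, arr.ind = TRUE)
        o <- order(dist[ok], dx[ok], det$y[rows][cand[, 2]])
        cand <- cand[o, , drop = FALSE]
        for (r in seq_len(nrow(cand))) {
          ti <- cand[r, 1]; di <- cand[r, 2]
          if (used_track[ti] || assigned_det[di]) next
          used_track[ti] <- TRUE; assigned_det[di] <- TRUE
          track_of[rows[di]] <- act_track[ti]
          act_x[ti] <- det$x[rows[di]]; act_y[ti] <- det$y[rows[di]]
          act_frame[ti] <- fr
        }
      }
    }
    # unmatched detections open new tracks
    for (di in which(!assigned_det)) {
      n_tracks <- n_tracks + 1L
      track_of[rows[di]] <- n_tracks
      act_track <- c(act_track, n_tracks)
      act_x <- c(act_x, det$x[rows[di]])
      act_y <- c(act_y, det$y[rows[di]])
      act_frame <- c(act_frame, fr)
    }
  }
  det$track_id <- sprintf("track_%04d", track_of)
  det
}

#' Validate trajectories against channel physics
#'
#' A usable event must be watched from before the channel: a trajectory
#' whose first detection lies past `x_entry_threshold` cannot be a real
#' cell entering the channel ("impossible start"). It must also cover the
#' full alignment window ("incomplete span") so that downstream features
#' and sequences are comparable across cells.
#'
#' @param tracked Tibble from [link_detections()] (columns `track_id`,
#'   `frame`, `x`).
#' @param geometry A [channel_geometry()].
#' @param x_entry_threshold Largest credible first-detection x (um),
#'   default 0 (the first-constriction entrance).
#' @return Tibble: `track_id`, `keep`, `reason` (NA when kept),
#'   `x_first`, `x_last`, `n_frames`.
#' @export
validate_trajectories <- function(tracked, geometry, x_entry_threshold = 0) {
  stopifnot(all(c("track_id", "frame", "x") %in% names(tracked)))
  win <- geometry$alignment_window
  out <- tracked |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      x_first = .data$x[which.min(.data$frame)],
      x_last = .data$x[which.max(.data$frame)],
      n_frames = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$x_first > x_entry_threshold ~ "impossible start",
        .data$x_first > win[1] | .data$x_last < win[2] ~ "incomplete span",
        TRUE ~ NA_character_
      ),
      keep = is.na(.data$reason)
    )
  dplyr::select(out, "track_id", "keep", "reason", "x_first", "x_last",
                "n_frames")
}

#' Split tracked detections into kept trajectory tibbles
#'
#' Convenience wrapper: validates tracks, joins ground-truth phenotypes
#' when available, and returns the kept trajectories as a named list ready
#' for the feature extractors.
#'
#' @param tracked Tibble from [link_detections()].
#' @param geometry A [channel_geometry()].
#' @param cells Optional cell table (columns `cell_id`, `phenotype`) to
#'   attach phenotype labels by majority ground-truth `cell_id`.
#' @param x_entry_threshold Passed to [validate_trajectories()].
#' @return List: `trajectories` (named list of tibbles), `validation`
#'   (the [validate_trajectories()] tibble).
#' @export
collect_trajectories <- function(tracked, geometry, cells = NULL,
                                 x_entry_threshold = 0) {
  val <- validate_trajectories(tracked, geometry, x_entry_threshold)
  keep_ids <- val$track_id[val$keep]
  trajs <- split(tracked, tracked$track_id)[keep_ids]
  if (!is.null(cells) && "cell_id" %in% names(tracked)) {
    lab <- stats::setNames(cells$phenotype, cells$cell_id)
    trajs <- purrr::map(trajs, function(tr) {
      major <- names(which.max(table(tr$cell_id)))
      tr$phenotype <- unname(lab[major])
      tr
    })
  }
  list(trajectories = trajs, validation = val)
}
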