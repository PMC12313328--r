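# On-disk dataset interchange: multi-page TIFF mask stacks (one page per
# frame) with a frame-index CSV, JSON-lines sidecars for ground truth and
# trajectories, CSV feature tables. Every format is re-readable so each
# pipeline stage can run from the previous stage's artifacts alone.

#' Write a synthetic dataset to a directory
#'
#' Writes `masks.tif` (one page per frame that contains at least one cell,
#' LZW-compressed binary masks), `frames.csv` (page to frame-index map),
#' `truth.jsonl` (per-frame true state per cell), and `cells.csv` (the
#' generating population).
#'
#' @param dataset A `dc_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "dc_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  acq <- dataset$acquisition
  frames <- sort(unique(dataset$detections$frame))
  W <- acq$frame_size[1]; H <- acq$frame_size[2]
  pages <- lapply(frames, function(fr) {
    full <- matrix(0, H, W)
    rows <- which(dataset$detections$frame == fr)
    for (r in rows) {
      msk <- dataset$detections$mask[[r]]
      m <- mask_logical(msk)
      rr <- msk$origin[1] + seq_len(nrow(m))
      cc <- msk$origin[2] + seq_len(ncol(m))
      full[rr, cc] <- pmax(full[rr, cc], m * 1)
    }
    full
  })
  paths <- list(
    masks = file.path(dir, "masks.tif"),
    frames = file.path(dir, "frames.csv"),
    truth = file.path(dir, "truth.jsonl"),
    cells = file.path(dir, "cells.csv")
  )
  tiff::writeTIFF(pages, paths$masks, bits.per.sample = 8L,
                  compression = "LZW")
  readr::write_csv(
    tibble::tibble(page = seq_along(frames), frame = frames,
                   t = frames / acq$fps),
    paths$frames
  )
  write_jsonl(dataset$truth, paths$truth)
  readr::write_csv(dplyr::select(dataset$cells, -dplyr::any_of("mask")),
                   paths$cells)
  invisible(paths)
}

#' Read a binary mask stack
#'
#' Reads a multi-page TIFF of binary masks as a list of logical matrices.
#'
#' @param path TIFF file.
#' @return List of logical matrices (rows = y, cols = x).
#' @export
read_mask_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p > 0.5
  })
}

write_jsonl <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    writeLines(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

read_jsonl <- function(path) {
  lines <- readLines(path)
  dplyr::bind_rows(lapply(lines, function(l) {
    tibble::as_tibble(jsonlite::fromJSON(l))
  }))
}

# ---- detection from mask stacks -------------------------------------------

# label 8-connected components of a logical matrix by row-run union-find;
# returns a list of pixel-index bounding crops
label_components <- function(m) {
  nr <- nrow(m)
  runs <- list(); run_row <- integer(); run_c0 <- integer(); run_c1 <- integer()
  prev_ids <- integer(0); prev_c0 <- integer(0); prev_c1 <- integer(0)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  n_run <- 0L
  for (r in seq_len(nr)) {
    v <- m[r, ]
    if (!any(v)) { prev_ids <- integer(0); next }
    d <- diff(c(FALSE, v, FALSE))
    starts <- which(d == 1); ends <- which(d == -1) - 1L
    cur_ids <- integer(length(starts))
    for (k in seq_along(starts)) {
      n_run <- n_run + 1L
      parent[n_run] <- n_run
      run_row[n_run] <- r; run_c0[n_run] <- starts[k]; run_c1[n_run] <- ends[k]
      cur_ids[k] <- n_run
      if (length(prev_ids)) {
        touch <- prev_c0 <= ends[k] + 1L & prev_c1 >= starts[k] - 1L
        for (p in prev_ids[touch]) {
          ra <- find(p); rb <- find(n_run)
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
    prev_ids <- cur_ids
    prev_c0 <- starts; prev_c1 <- ends
  }
  if (n_run == 0L) return(list())
  roots <- vapply(seq_len(n_run), find, integer(1))
  comp <- split(seq_len(n_run), roots)
  lapply(comp, function(rs) {
    r0 <- min(run_row[rs]); r1 <- max(run_row[rs])
    c0 <- min(run_c0[rs]); c1 <- max(run_c1[rs])
    sub <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    for (k in rs) {
      sub[run_row[k] - r0 + 1L, (run_c0[k]:run_c1[k]) - c0 + 1L] <- TRUE
    }
    list(px = sub, origin = c(r0 - 1L, c0 - 1L))
  })
}

#' Detect cells in a stack of binary mask frames
#'
#' Segments each frame into 8-connected components (one detection per
#' component) and measures centroid and area on the acquisition grid. The
#' entry point for user-supplied mask stacks and for the tracking stage of
#' the pipeline.
#'
#' @param frames List of logical matrices, or a `masks.tif` path.
#' @param frame_index Frame number of each list element (defaults to
#'   1..n).
#' @param acquisition An [acquisition_config()].
#' @param min_area_px Discard components smaller than this (debris).
#' @return Detections tibble: `frame`, `t`, `x`, `y`, `area` (um^2),
#'   `mask` (list of `dc_mask`).
#' @export
detect_cells <- function(frames, frame_index = NULL,
                         acquisition = acquisition_config(),
                         min_area_px = 20) {
  if (is.character(frames)) frames <- read_mask_stack(frames)
  if (is.null(frame_index)) frame_index <- seq_along(frames)
  stopifnot(length(frame_index) == length(frames))
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    comps <- label_components(frames[[i]])
    comps <- comps[vapply(comps, function(cp) sum(cp$px), numeric(1)) >= min_area_px]
    if (!length(comps)) next
    rows <- lapply(comps, function(cp) {
      msk <- structure(list(px = matrix(as.raw(cp$px), nrow(cp$px), ncol(cp$px)),
                            origin = cp$origin,
                            pixel_size = acquisition$pixel_size),
                       class = "dc_mask")
      cen <- mask_centroid_um(msk, acquisition)
      tibble::tibble(frame = frame_index[i],
                     t = frame_index[i] / acquisition$fps,
                     x = cen[["x"]], y = cen[["y"]],
                     area = sum(cp$px) * acquisition$pixel_size^2,
                     mask = list(msk))
    })
    out[[i]] <- dplyr::bind_rows(rows)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res)) dplyr::arrange(res, .data$frame, .data$x) else res
}
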