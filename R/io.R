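#' Write vertex tracks to CSV
#'
#' Long format, one row per (frame, vertex): columns `track_id`, `frame`
#' (0-based), `time_s` (relative to acquisition start), `vertex` (1 or 2),
#' `x_um`, `y_um`, `phase` (`pre`/`post`, with `pre` on every frame up to and
#' including the ablation frame).
#'
#' @param tracks A list of [vertex_track()]s (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  if (inherits(tracks, "vertex_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    n <- length(tr$times)
    phase <- ifelse(tr$frames <= tr$ablation_frame, "pre", "post")
    rbind(
      data.frame(track_id = tr$track_id, frame = tr$frames, time_s = tr$times,
                 vertex = 1L, x_um = tr$vertex1[, 1], y_um = tr$vertex1[, 2],
                 phase = phase),
      data.frame(track_id = tr$track_id, frame = tr$frames, time_s = tr$times,
                 vertex = 2L, x_um = tr$vertex2[, 1], y_um = tr$vertex2[, 2],
                 phase = phase)
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read vertex tracks from CSV
#'
#' Parses the schema written by [write_tracks()] and validates each track:
#' both vertices present at every frame, uniform time spacing, a contiguous
#' `pre` phase followed by `post` frames, at least two post-ablation frames.
#' The ablation frame is inferred as the last `pre` frame. Errors name the
#' offending track and row.
#'
#' @param path CSV path.
#' @return A list of [vertex_track()]s.
#' @export
read_vertex_tracks <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("track_id", "frame", "time_s", "vertex", "x_um", "y_um", "phase")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing columns: %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  df$.row <- seq_len(nrow(df)) + 1L  # header is row 1
  if (!all(df$phase %in% c("pre", "post"))) {
    bad <- df$.row[!df$phase %in% c("pre", "post")][1]
    stop(sprintf("row %d: phase must be 'pre' or 'post'", bad), call. = FALSE)
  }
  if (!all(df$vertex %in% c(1L, 2L))) {
    bad <- df$.row[!df$vertex %in% c(1L, 2L)][1]
    stop(sprintf("row %d: vertex must be 1 or 2", bad), call. = FALSE)
  }
  lapply(split(df, df$track_id), function(d) {
    id <- d$track_id[1]
    d <- d[order(d$frame, d$vertex), ]
    frames <- sort(unique(d$frame))
    v1 <- d[d$vertex == 1L, ]
    v2 <- d[d$vertex == 2L, ]
    if (!identical(v1$frame, frames) || !identical(v2$frame, frames)) {
      stop(sprintf("track '%s': both vertices must be present at every frame", id),
           call. = FALSE)
    }
    phase_by_frame <- v1$phase
    pre_idx <- which(phase_by_frame == "pre")
    if (length(pre_idx) == 0L) {
      stop(sprintf("track '%s': no pre-ablation frame", id), call. = FALSE)
    }
    if (!identical(pre_idx, seq_len(length(pre_idx)))) {
      bad <- v1$.row[setdiff(pre_idx, seq_len(length(pre_idx)))[1]]
      stop(sprintf("track '%s', row %d: 'pre' frames must precede all 'post' frames",
                   id, bad), call. = FALSE)
    }
    if (!identical(v1$phase, v2$phase)) {
      stop(sprintf("track '%s': vertex phases disagree", id), call. = FALSE)
    }
    n_post <- length(frames) - length(pre_idx)
    if (n_post < 2L) {
      stop(sprintf("track '%s': needs at least 2 post-ablation frames (has %d)",
                   id, n_post), call. = FALSE)
    }
    tryCatch(
      vertex_track(id, v1$time_s, cbind(v1$x_um, v1$y_um),
                   cbind(v2$x_um, v2$y_um),
                   ablation_frame = frames[length(pre_idx)], frames = frames),
      error = function(e) stop(sprintf("track '%s': %s", id, conditionMessage(e)),
                               call. = FALSE))
  })
}

#' Write an image stack as multi-page TIFF plus sidecar metadata
#'
#' Intensities are scaled into [0, 1] by their maximum and written as 32-bit
#' float TIFF pages; the scale factor, pixel size and z-step are recorded in
#' a sidecar JSON (`<path>.json`) so [read_stack()] can restore physical
#' units (TIFF resolution tags cannot be written by the underlying library).
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "image_stack")) stop("'stack' must be an image_stack", call. = FALSE)
  mx <- max(stack$data)
  scale <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(dim(stack$data)[1]),
                  function(z) stack$data[z, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(scale = scale, pixel_size_um = stack$pixel_size,
         z_step_um = stack$z_step, n_slices = dim(stack$data)[1],
         schema = "recoilr-stack-1"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack from TIFF
#'
#' Pixel size is resolved in order of precedence: sidecar JSON written by
#' [write_stack()], the `pixel_size` override, then TIFF resolution tags; if
#' none is available the read fails. Intensities are rescaled by the sidecar
#' scale factor when present.
#'
#' @param path TIFF path.
#' @param pixel_size Optional override, micrometres per pixel.
#' @param z_step Optional override, micrometres.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size = NULL, z_step = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  scale <- meta$scale %||% 1
  ps <- meta$pixel_size_um %||% pixel_size
  if (is.null(ps)) {
    xres <- attr(pages[[1]], "x.resolution")
    unit <- attr(pages[[1]], "resolution.unit")
    if (!is.null(xres) && xres > 0) {
      ps <- switch(unit %||% "inch",
                   inch = 25400 / xres,   # dots per inch -> um per px
                   cm = 10000 / xres,
                   1 / xres)
    }
  }
  if (is.null(ps)) {
    stop("pixel size unavailable: no sidecar metadata, no override, no TIFF resolution tag",
         call. = FALSE)
  }
  zs <- meta$z_step_um %||% z_step %||% 0.5
  arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]] * scale
  image_stack(arr, pixel_size = as.numeric(ps), z_step = as.numeric(zs))
}

#' Read clone/control measurement sets from CSV
#'
#' Expected columns: `unit_id`, `cell_id`, `group` (`clone`/`control`),
#' `value`, `measure_kind` (`width`/`intensity`).
#'
#' @param path CSV path.
#' @return A list of [clone_set()]s, one per unit.
#' @export
read_clone_sets <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("unit_id", "cell_id", "group", "value", "measure_kind")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing columns: %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  if (!all(df$group %in% c("clone", "control"))) {
    stop("'group' must be 'clone' or 'control'", call. = FALSE)
  }
  lapply(split(df, df$unit_id), function(d) {
    clone_set(d$unit_id[1], d$value[d$group == "clone"],
              d$value[d$group == "control"], measure_kind = d$measure_kind[1])
  })
}

#' Write clone sets to CSV (inverse of [read_clone_sets()])
#'
#' @param sets List of [clone_set()]s (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_clone_sets <- function(sets, path) {
  if (inherits(sets, "clone_set")) sets <- list(sets)
  rows <- lapply(sets, function(s) {
    data.frame(unit_id = s$unit_id,
               cell_id = seq_len(length(s$clone_values) + length(s$control_values)),
               group = rep(c("clone", "control"),
                           c(length(s$clone_values), length(s$control_values))),
               value = c(s$clone_values, s$control_values),
               measure_kind = s$measure_kind)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
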