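#' Vertex track for one ablated junction
#'
#' A vertex track records the manually tracked positions of the two
#' tricellular vertices flanking a single ablated cell-cell interface, one row
#' per acquired frame, before and after ablation. Times must be uniformly
#' spaced; the ablation frame marks the last frame acquired before the cut.
#'
#' @param track_id Identifier for the junction (one junction per embryo in the
#'   reference experiments).
#' @param times Acquisition times in seconds, strictly increasing and
#'   uniformly spaced (relative spacing tolerance 1e-6).
#' @param vertex1,vertex2 Numeric matrices with one row per frame and columns
#'   x, y, in micrometres.
#' @param ablation_frame Integer, 0-based index of the last pre-ablation
#'   frame; at least one frame must lie at or before it and at least two
#'   after it.
#' @param frames Optional 0-based frame indices; defaults to
#'   `seq_along(times) - 1`.
#'
#' @return An object of class `vertex_track`: a list with elements
#'   `track_id`, `frames`, `times`, `vertex1`, `vertex2`, `ablation_frame`.
#' @seealso [interface_length()], [simulate_recoil_track()]
#' @export
vertex_track <- function(track_id, times, vertex1, vertex2, ablation_frame,
                         frames = NULL) {
  times <- as.numeric(times)
  n <- length(times)
  vertex1 <- as_xy_matrix(vertex1, n, "vertex1")
  vertex2 <- as_xy_matrix(vertex2, n, "vertex2")
  if (n < 3L) stop("a vertex track needs at least 3 frames", call. = FALSE)
  if (any(!is.finite(times))) stop("'times' must be finite", call. = FALSE)
  dt <- diff(times)
  if (any(dt <= 0)) stop("'times' must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-6 * mean(dt)) {
    stop("'times' must be uniformly spaced (tolerance 1e-6)", call. = FALSE)
  }
  ablation_frame <- check_count(ablation_frame, "ablation_frame", min = 0L)
  frames <- if (is.null(frames)) seq_len(n) - 1L else as.integer(frames)
  if (length(frames) != n) stop("'frames' length must match 'times'", call. = FALSE)
  abl_idx <- match(ablation_frame, frames)
  if (is.na(abl_idx)) stop("'ablation_frame' not among 'frames'", call. = FALSE)
  if (abl_idx < 1L) stop("need at least one pre-ablation frame", call. = FALSE)
  if (n - abl_idx < 2L) stop("need at least two post-ablation frames", call. = FALSE)
  structure(
    list(track_id = as.character(track_id), frames = frames, times = times,
         vertex1 = vertex1, vertex2 = vertex2, ablation_frame = ablation_frame),
    class = "vertex_track"
  )
}

as_xy_matrix <- function(v, n, name) {
  v <- as.matrix(v)
  if (!is.numeric(v) || ncol(v) != 2L || nrow(v) != n || any(!is.finite(v))) {
    stop(sprintf("'%s' must be a finite numeric %d x 2 matrix of x,y coordinates", name, n),
         call. = FALSE)
  }
  colnames(v) <- c("x", "y")
  v
}

#' @export
print.vertex_track <- function(x, ...) {
  abl_idx <- match(x$ablation_frame, x$frames)
  cat(sprintf("Vertex track '%s': %d frames (%d pre, %d post), dt = %g s\n",
              x$track_id, length(x$times), abl_idx, length(x$times) - abl_idx,
              diff(x$times)[1]))
  invisible(x)
}

#' Interface length series from a vertex track
#'
#' Computes the Euclidean distance between the two tracked vertices at every
#' frame and re-centres time so that the last pre-ablation frame sits at
#' t = 0 (pre-ablation frames have t <= 0).
#'
#' @param track A [vertex_track()].
#' @return An object of class `interface_length_series`: list with `t`
#'   (seconds relative to the last pre-ablation frame), `L` (interface length,
#'   micrometres) and `ablation_index` (1-based index of the t = 0 frame).
#' @examples
#' tr <- simulate_recoil_track(recoil_sim_params(D = 1.5, tau = 10, noise_sd = 0))
#' s <- interface_length(tr)
#' s$L[s$ablation_index + 1]  # length 4 s after ablation
#' @export
interface_length <- function(track) {
  if (!inherits(track, "vertex_track")) {
    stop("'track' must be a vertex_track", call. = FALSE)
  }
  d <- track$vertex2 - track$vertex1
  L <- sqrt(rowSums(d^2))
  abl_idx <- match(track$ablation_frame, track$frames)
  structure(
    list(t = track$times - track$times[abl_idx], L = L, ablation_index = abl_idx,
         track_id = track$track_id),
    class = "interface_length_series"
  )
}

#' @export
print.interface_length_series <- function(x, ...) {
  cat(sprintf("Interface length series (%d frames, t in [%g, %g] s, L in [%.3g, %.3g] um)\n",
              length(x$t), min(x$t), max(x$t), min(x$L), max(x$L)))
  invisible(x)
}

#' Initial retraction velocity after ablation
#'
#' The change in vertex-to-vertex distance between the last pre-ablation frame
#' and the first post-ablation frame, divided by the time elapsed between the
#' two images. This is the standard readout of cortical tension: released
#' tension scales the initial recoil speed.
#'
#' @param series An [interface_length()] series (or a [vertex_track()], which
#'   is converted first).
#' @return Retraction velocity in micrometres per second.
#' @export
retraction_velocity <- function(series) {
  if (inherits(series, "vertex_track")) series <- interface_length(series)
  if (!inherits(series, "interface_length_series")) {
    stop("'series' must be an interface_length_series or vertex_track", call. = FALSE)
  }
  i <- series$ablation_index
  if (i >= length(series$t)) stop("no post-ablation frame present", call. = FALSE)
  (series$L[i + 1L] - series$L[i]) / (series$t[i + 1L] - series$t[i])
}
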