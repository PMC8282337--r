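#' Synthetic epithelium image with bright junctional signal
#'
#' Generates a Voronoi-like polygonal cell lattice: cell seed points sit on a
#' jittered square grid and every pixel is assigned to its nearest seed;
#' pixels nearly equidistant from their two nearest seeds form the junction
#' mask. Junction pixels carry a bright signal, optionally modulated along
#' the tissue to mimic punctate Myosin: the junction intensity is multiplied
#' by `1 + punctateness * sin(2 * pi * s / period)` where `s` is a spatial
#' phase advancing along the junctions (arclength proxy). `punctateness = 0`
#' gives uniform junctions. Gaussian background noise is added per pixel and
#' per z-slice (slices share the geometry, noise is independent), and the
#' image is clamped at zero.
#'
#' @param n_cells Number of cells (>= 2); laid out on a near-square grid.
#' @param pixel_size Micrometres per pixel (default 0.1).
#' @param cell_size Mean cell diameter, micrometres (default 5).
#' @param junction_intensity Junction signal level, arbitrary units.
#' @param punctateness Nonnegative modulation amplitude (0 = uniform).
#' @param punctate_period Spatial period of the modulation, micrometres.
#' @param background Constant background level, arbitrary units.
#' @param background_noise_sd Gaussian noise s.d., arbitrary units.
#' @param n_slices Number of z-slices (default 5, of 0.5 um each).
#' @param z_step Micrometres between slices.
#' @param jitter Seed-point jitter as a fraction of `cell_size` (0 gives a
#'   regular rectangular lattice with axis-aligned junctions).
#' @param seed Integer seed; deterministic output for fixed arguments.
#' @return An object of class `synthetic_epithelium`: list with `stack` (an
#'   [image_stack()]), `junction_mask` (logical y x x matrix of ground-truth
#'   junction pixels), `seeds` (cell centres, um), `punctateness`,
#'   `background`, `junction_intensity`.
#' @export
synth_epithelium_image <- function(n_cells = 25L, pixel_size = 0.1,
                                   cell_size = 5, junction_intensity = 100,
                                   punctateness = 0, punctate_period = 1,
                                   background = 10, background_noise_sd = 2,
                                   n_slices = 5L, z_step = 0.5,
                                   jitter = 0.2, seed = 1L) {
  n_cells <- check_count(n_cells, "n_cells", 2L)
  check_positive(pixel_size, "pixel_size")
  check_positive(cell_size, "cell_size")
  check_nonneg(punctateness, "punctateness")
  check_positive(punctate_period, "punctate_period")
  check_nonneg(background, "background")
  check_nonneg(background_noise_sd, "background_noise_sd")
  n_slices <- check_count(n_slices, "n_slices", 1L)
  check_nonneg(jitter, "jitter")

  ngrid <- ceiling(sqrt(n_cells))
  extent <- ngrid * cell_size
  npx <- round(extent / pixel_size)

  gx <- rep(seq_len(ngrid), times = ngrid)
  gy <- rep(seq_len(ngrid), each = ngrid)
  seeds <- with_seed(seed, {
    sx <- (gx - 0.5) * cell_size + stats::runif(ngrid^2, -jitter, jitter) * cell_size
    sy <- (gy - 0.5) * cell_size + stats::runif(ngrid^2, -jitter, jitter) * cell_size
    cbind(x = sx, y = sy)
  })

  px <- ((seq_len(npx)) - 1) * pixel_size
  py <- ((seq_len(npx)) - 1) * pixel_size
  # distances from every pixel centre to every seed; npx^2 x nseed
  X <- matrix(px, nrow = npx, ncol = npx, byrow = TRUE)   # y rows, x cols
  Y <- matrix(py, nrow = npx, ncol = npx, byrow = FALSE)
  n_seed <- nrow(seeds)
  d1 <- matrix(Inf, npx, npx); d2 <- matrix(Inf, npx, npx)
  for (s in seq_len(n_seed)) {
    d <- sqrt((X - seeds[s, "x"])^2 + (Y - seeds[s, "y"])^2)
    swap <- d < d1
    d2[swap] <- d1[swap]; d1[swap] <- d[swap]
    only2 <- !swap & d < d2
    d2[only2] <- d[only2]
  }
  junction_mask <- (d2 - d1) <= pixel_size

  base <- matrix(background, npx, npx)
  phase <- (X + Y) / sqrt(2)   # advances along junctions in any orientation
  mod <- 1 + punctateness * sin(2 * pi * phase / punctate_period)
  base[junction_mask] <- junction_intensity * mod[junction_mask]

  slices <- with_seed(seed + 1L, {
    arr <- array(0, c(n_slices, npx, npx))
    for (z in seq_len(n_slices)) {
      noisy <- base
      if (background_noise_sd > 0) {
        noisy <- noisy + matrix(stats::rnorm(npx^2, sd = background_noise_sd), npx, npx)
      }
      arr[z, , ] <- pmax(noisy, 0)
    }
    arr
  })

  structure(list(stack = image_stack(slices, pixel_size = pixel_size, z_step = z_step),
                 junction_mask = junction_mask, seeds = seeds,
                 punctateness = punctateness, background = background,
                 junction_intensity = junction_intensity),
            class = "synthetic_epithelium")
}

#' @export
print.synthetic_epithelium <- function(x, ...) {
  d <- dim(x$stack$data)
  cat(sprintf("Synthetic epithelium: %d x %d px, %d slices, %d junction px, punctateness %.3g\n",
              d[2], d[3], d[1], sum(x$junction_mask), x$punctateness))
  invisible(x)
}

#' Endpoints of a linescan lying along a junction
#'
#' Finds the longest horizontal or vertical run of ground-truth junction
#' pixels and returns the physical endpoints of a line through their centres.
#' Sampling such a line at one-pixel steps hits junction pixel centres
#' exactly, so the profile reflects junctional signal only.
#'
#' @param epi A [synth_epithelium_image()] result.
#' @param min_samples Minimum run length in pixels.
#' @return List with `p0`, `p1` (um, c(x, y)) and `n_px` (run length).
#' @export
junction_linescan_endpoints <- function(epi, min_samples = 5L) {
  if (!inherits(epi, "synthetic_epithelium")) {
    stop("'epi' must be a synthetic_epithelium", call. = FALSE)
  }
  m <- epi$junction_mask
  ps <- epi$stack$pixel_size
  best <- list(len = 0L)
  runs_in <- function(v) {
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    cbind(start = starts[keep], end = ends[keep], len = r$lengths[keep])
  }
  for (r in seq_len(nrow(m))) {
    rr <- runs_in(m[r, ])
    if (nrow(rr)) {
      i <- which.max(rr[, "len"])
      if (rr[i, "len"] > best$len) {
        best <- list(len = rr[i, "len"],
                     p0 = c((rr[i, "start"] - 1) * ps, (r - 1) * ps),
                     p1 = c((rr[i, "end"] - 1) * ps, (r - 1) * ps))
      }
    }
  }
  for (cc in seq_len(ncol(m))) {
    rr <- runs_in(m[, cc])
    if (nrow(rr)) {
      i <- which.max(rr[, "len"])
      if (rr[i, "len"] > best$len) {
        best <- list(len = rr[i, "len"],
                     p0 = c((cc - 1) * ps, (rr[i, "start"] - 1) * ps),
                     p1 = c((cc - 1) * ps, (rr[i, "end"] - 1) * ps))
      }
    }
  }
  if (best$len < min_samples) {
    stop("no axis-aligned junction run long enough for a linescan", call. = FALSE)
  }
  list(p0 = best$p0, p1 = best$p1, n_px = best$len)
}
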