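#' Image stack container
#'
#' A z-stack of fluorescence intensities with physical calibration. Data are
#' stored as a 3-D array indexed `[z, y, x]`; a 2-D matrix is promoted to a
#' single-slice stack.
#'
#' @param data Numeric array `z x y x x` (or matrix `y x x`), finite and
#'   nonnegative, arbitrary units.
#' @param pixel_size Lateral pixel size, micrometres per pixel (> 0).
#' @param z_step Axial step between slices, micrometres (default 0.5).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size, z_step = 0.5) {
  if (is.matrix(data)) data <- array(data, c(1L, nrow(data), ncol(data)))
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("'data' must be a z x y x x array or a y x x matrix", call. = FALSE)
  }
  if (any(!is.finite(data)) || any(data < 0)) {
    stop("intensities must be finite and nonnegative", call. = FALSE)
  }
  check_positive(pixel_size, "pixel_size")
  check_positive(z_step, "z_step")
  structure(list(data = data, pixel_size = pixel_size, z_step = z_step),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Image stack: %d slice(s) of %d x %d px (%.3g um/px, z-step %.3g um)\n",
              d[1], d[2], d[3], x$pixel_size, x$z_step))
  invisible(x)
}

#' Maximum-intensity projection of selected slices
#'
#' Pixel-wise maximum over a contiguous range of z-slices; the standard way to
#' collapse the slices spanning the apical domain (e.g. 5 slices of 0.5 um)
#' into one 2-D image before drawing linescans.
#'
#' @param stack An [image_stack()].
#' @param slices Integer vector of slice indices (1-based); defaults to all.
#' @return A numeric matrix `y x x`.
#' @export
max_project <- function(stack, slices = NULL) {
  if (!inherits(stack, "image_stack")) stop("'stack' must be an image_stack", call. = FALSE)
  nz <- dim(stack$data)[1]
  slices <- if (is.null(slices)) seq_len(nz) else as.integer(slices)
  if (length(slices) == 0L) stop("empty slice range", call. = FALSE)
  if (any(slices < 1L | slices > nz)) {
    stop(sprintf("slice indices must be within 1..%d", nz), call. = FALSE)
  }
  sub <- stack$data[slices, , , drop = FALSE]
  apply(sub, c(2L, 3L), max)
}

#' Extract an intensity linescan from a 2-D image
#'
#' Samples intensities by bilinear interpolation at uniform arclength steps
#' along the straight segment from `p0` to `p1` (inclusive). Coordinates are
#' physical, in micrometres, with the origin at the centre of the top-left
#' pixel: pixel (row r, col c) has centre `((c-1) * pixel_size,
#' (r-1) * pixel_size)`.
#'
#' @param image Numeric matrix `y x x`.
#' @param p0,p1 Numeric `c(x, y)` endpoints in micrometres; must differ and
#'   lie within the image.
#' @param pixel_size Micrometres per pixel.
#' @param sampling_step Arclength step in micrometres; defaults to one pixel.
#' @return An object of class `linescan_profile`: list with `positions` (um
#'   along the line), `intensities`, `p0`, `p1`, `sampling_step`.
#' @export
extract_linescan <- function(image, p0, p1, pixel_size,
                             sampling_step = pixel_size) {
  if (!is.matrix(image) || !is.numeric(image)) stop("'image' must be a numeric matrix", call. = FALSE)
  check_positive(pixel_size, "pixel_size")
  check_positive(sampling_step, "sampling_step")
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  if (length(p0) != 2L || length(p1) != 2L) stop("endpoints must be c(x, y)", call. = FALSE)
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop("endpoints must differ", call. = FALSE)
  xmax <- (ncol(image) - 1) * pixel_size
  ymax <- (nrow(image) - 1) * pixel_size
  for (p in list(p0, p1)) {
    if (p[1] < 0 || p[1] > xmax || p[2] < 0 || p[2] > ymax) {
      stop("linescan endpoints must lie within the image", call. = FALSE)
    }
  }
  pos <- seq(0, len, by = sampling_step)
  if (pos[length(pos)] < len - 1e-9) pos <- c(pos, len)  # include endpoint
  frac <- pos / len
  xs <- p0[1] + frac * (p1[1] - p0[1])
  ys <- p0[2] + frac * (p1[2] - p0[2])
  vals <- bilinear_sample(image, xs / pixel_size, ys / pixel_size)
  structure(list(positions = pos, intensities = vals, p0 = p0, p1 = p1,
                 sampling_step = sampling_step),
            class = "linescan_profile")
}

# Bilinear interpolation at fractional pixel coordinates (0-based, x = column,
# y = row offsets from the top-left pixel centre).
bilinear_sample <- function(image, x, y) {
  nr <- nrow(image); nc <- ncol(image)
  x0 <- pmin(pmax(floor(x), 0), nc - 1L)
  y0 <- pmin(pmax(floor(y), 0), nr - 1L)
  x1 <- pmin(x0 + 1L, nc - 1L)
  y1 <- pmin(y0 + 1L, nr - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- image[cbind(y0 + 1L, x0 + 1L)]
  i01 <- image[cbind(y0 + 1L, x1 + 1L)]
  i10 <- image[cbind(y1 + 1L, x0 + 1L)]
  i11 <- image[cbind(y1 + 1L, x1 + 1L)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' @export
print.linescan_profile <- function(x, ...) {
  cat(sprintf("Linescan: %.3g um, %d samples (step %.3g um)\n",
              max(x$positions), length(x$positions), x$sampling_step))
  invisible(x)
}

#' Mean intensity and heterogeneity of a linescan
#'
#' Heterogeneity is the standard deviation of the sampled intensities divided
#' by their mean. It captures the variability within a linescan: a signal with
#' clear peaks and troughs (punctate junctional Myosin) has high
#' heterogeneity, a uniform signal has heterogeneity 0. The statistic is
#' dimensionless and invariant to multiplicative intensity rescaling.
#'
#' @param profile A [extract_linescan()] profile, or a numeric vector of
#'   intensities.
#' @param sd_denominator `"n-1"` (sample s.d., default) or `"n"` (population).
#' @return A list of class `heterogeneity_result`: `mean_intensity`,
#'   `sd_intensity`, `heterogeneity`, `n`.
#' @examples
#' linescan_stats(c(1, 2, 3, 4))$heterogeneity  # ~0.5164
#' @export
linescan_stats <- function(profile, sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  v <- if (inherits(profile, "linescan_profile")) profile$intensities else as.numeric(profile)
  if (length(v) < 2L) stop("need at least 2 intensity samples", call. = FALSE)
  if (any(!is.finite(v))) stop("non-finite intensities", call. = FALSE)
  m <- mean(v)
  if (m <= 0) stop("mean intensity must be positive for heterogeneity", call. = FALSE)
  s <- stats::sd(v)
  if (sd_denominator == "n") s <- s * sqrt((length(v) - 1) / length(v))
  structure(list(mean_intensity = m, sd_intensity = s, heterogeneity = s / m,
                 n = length(v)),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, digits = 4, ...) {
  cat(sprintf("Linescan stats: mean %.*g, sd %.*g, heterogeneity %.*g (n = %d)\n",
              digits, x$mean_intensity, digits, x$sd_intensity,
              digits, x$heterogeneity, x$n))
  invisible(x)
}

#' Per-embryo linescan summaries for a condition
#'
#' Reduces one or more linescans per embryo to a single (mean intensity,
#' heterogeneity) pair per embryo -- the unit of analysis when comparing
#' conditions (embryos, not linescans, are the independent replicates).
#' With several linescans per embryo, per-linescan statistics are averaged.
#'
#' @param profiles A list with one element per embryo; each element is a
#'   [extract_linescan()] profile, a numeric vector, or a list of either.
#' @param sd_denominator Passed to [linescan_stats()].
#' @return A data frame with columns `embryo`, `mean_intensity`,
#'   `heterogeneity`, `n_linescans`.
#' @export
condition_linescan_summary <- function(profiles, sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  if (length(profiles) < 1L) stop("need at least one embryo", call. = FALSE)
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    scans <- if (inherits(p, "linescan_profile") || is.numeric(p)) list(p) else p
    if (length(scans) < 1L) stop(sprintf("embryo %d has no linescans", i), call. = FALSE)
    st <- lapply(scans, linescan_stats, sd_denominator = sd_denominator)
    data.frame(embryo = names(profiles)[i] %||% as.character(i),
               mean_intensity = mean(vapply(st, `[[`, numeric(1), "mean_intensity")),
               heterogeneity = mean(vapply(st, `[[`, numeric(1), "heterogeneity")),
               n_linescans = length(scans))
  })
  out <- do.call(rbind, rows)
  if (!is.null(names(profiles))) out$embryo <- names(profiles)
  out
}
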