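#' Paired clone/control measurements within one tissue unit
#'
#' Holds per-cell measurements for genetically labelled (clone) cells and the
#' facing unlabelled control cells of the same follicle or embryonic segment.
#' The unit (follicle/segment), not the cell, is the statistical observation:
#' each unit later contributes one clone-to-control ratio.
#'
#' @param unit_id Follicle or segment identifier.
#' @param clone_values,control_values Positive per-cell measurements
#'   (micrometres for widths, arbitrary units for intensities); both
#'   non-empty.
#' @param measure_kind `"width"` or `"intensity"`.
#' @return An object of class `clone_set`.
#' @export
clone_set <- function(unit_id, clone_values, control_values,
                      measure_kind = c("width", "intensity")) {
  measure_kind <- match.arg(measure_kind)
  clone_values <- as.numeric(clone_values)
  control_values <- as.numeric(control_values)
  if (length(clone_values) < 1L || length(control_values) < 1L) {
    stop("clone and control groups must both be non-empty", call. = FALSE)
  }
  if (any(!is.finite(clone_values)) || any(clone_values <= 0) ||
      any(!is.finite(control_values)) || any(control_values <= 0)) {
    stop("all measurements must be positive and finite", call. = FALSE)
  }
  structure(list(unit_id = as.character(unit_id), clone_values = clone_values,
                 control_values = control_values, measure_kind = measure_kind),
            class = "clone_set")
}

#' @export
print.clone_set <- function(x, ...) {
  cat(sprintf("Clone set '%s' (%s): %d clone vs %d control cells\n",
              x$unit_id, x$measure_kind, length(x$clone_values),
              length(x$control_values)))
  invisible(x)
}

#' Per-cell apical widths from boundary positions
#'
#' Reduces an ordered annotation of cell boundary positions along the apical
#' surface to per-cell widths (consecutive differences).
#'
#' @param boundary_positions Strictly increasing positions in micrometres
#'   (>= 2 values).
#' @return Numeric vector of widths, one per cell.
#' @export
widths_from_boundaries <- function(boundary_positions) {
  b <- as.numeric(boundary_positions)
  if (length(b) < 2L) stop("need at least 2 boundary positions", call. = FALSE)
  if (any(!is.finite(b))) stop("boundary positions must be finite", call. = FALSE)
  if (any(diff(b) <= 0)) stop("boundary positions must be strictly increasing", call. = FALSE)
  diff(b)
}

#' Clone-to-control ratio for one unit
#'
#' The ratio of the clone-cell mean to the control-cell mean within a single
#' follicle or segment. Ratio of means (not mean of per-cell ratios): the
#' design pairs groups of cells, not individual cells, and the ratio of means
#' is well-defined for unequal group sizes. Any common multiplicative
#' calibration cancels.
#'
#' @param set A [clone_set()].
#' @return A list of class `ratio_result`: `unit_id`, `clone_mean`,
#'   `control_mean`, `ratio`, `measure_kind`.
#' @examples
#' clone_ratio(clone_set("f1", c(2, 2, 3), c(4, 4, 4)))$ratio  # ~0.5833
#' @export
clone_ratio <- function(set) {
  if (!inherits(set, "clone_set")) stop("'set' must be a clone_set", call. = FALSE)
  cm <- mean(set$clone_values)
  km <- mean(set$control_values)
  structure(list(unit_id = set$unit_id, clone_mean = cm, control_mean = km,
                 ratio = cm / km, measure_kind = set$measure_kind),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, digits = 4, ...) {
  cat(sprintf("Unit '%s': clone/control %s ratio = %.*g (means %.*g / %.*g)\n",
              x$unit_id, x$measure_kind, digits, x$ratio, digits, x$clone_mean,
              digits, x$control_mean))
  invisible(x)
}

#' Per-unit ratios for a cohort of clone sets
#'
#' @param sets A non-empty list of [clone_set()]s.
#' @return A data frame with one row per unit: `unit_id`, `clone_mean`,
#'   `control_mean`, `ratio`, `measure_kind`; input order preserved.
#' @export
cohort_ratios <- function(sets) {
  if (length(sets) < 1L) stop("need at least one clone set", call. = FALSE)
  rows <- lapply(sets, function(s) {
    r <- clone_ratio(s)
    data.frame(unit_id = r$unit_id, clone_mean = r$clone_mean,
               control_mean = r$control_mean, ratio = r$ratio,
               measure_kind = r$measure_kind)
  })
  do.call(rbind, rows)
}

#' Synthetic clone/control apical-width ensemble
#'
#' Generates one unit (follicle/segment) of per-cell apical widths: control
#' widths are lognormal with the given mean and CV; clone widths are drawn
#' from the same distribution and scaled by `constriction_factor`
#' (< 1 = apical constriction of the clone). `width_cv = 0` gives
#' deterministic widths, so the recovered ratio equals the constriction
#' factor exactly.
#'
#' @param n_cells Total cells in the unit (clone + control).
#' @param clone_fraction Fraction of cells in the clone, in (0, 1).
#' @param constriction_factor Multiplicative width effect of the clone (> 0).
#' @param width_mean Mean control apical width, micrometres.
#' @param width_cv Coefficient of variation of per-cell widths (>= 0).
#' @param unit_id Unit identifier.
#' @param seed Integer seed.
#' @return A [clone_set()] with attribute `truth` (the generating
#'   parameters).
#' @export
synth_clone_widths <- function(n_cells = 40L, clone_fraction = 0.5,
                               constriction_factor = 0.6, width_mean = 5,
                               width_cv = 0.15, unit_id = "unit1", seed = 1L) {
  n_cells <- check_count(n_cells, "n_cells", 2L)
  if (!is.numeric(clone_fraction) || clone_fraction <= 0 || clone_fraction >= 1) {
    stop("'clone_fraction' must be in (0, 1)", call. = FALSE)
  }
  check_positive(constriction_factor, "constriction_factor")
  check_positive(width_mean, "width_mean")
  check_nonneg(width_cv, "width_cv")
  n_clone <- max(1L, min(n_cells - 1L, round(n_cells * clone_fraction)))
  n_control <- n_cells - n_clone
  vals <- with_seed(seed, list(
    clone = constriction_factor * rlnorm_mean_cv(n_clone, width_mean, width_cv),
    control = rlnorm_mean_cv(n_control, width_mean, width_cv)
  ))
  out <- clone_set(unit_id, vals$clone, vals$control, measure_kind = "width")
  attr(out, "truth") <- list(constriction_factor = constriction_factor,
                             width_mean = width_mean, width_cv = width_cv,
                             seed = seed)
  out
}
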