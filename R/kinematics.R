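# Radial/longitudinal projection, six-segment partition of the equatorial
# slice, region-mean velocity-time curves and their cubic-spline
# resampling.

#' Ordered segment labels of the equatorial short-axis slice
#' @export
SEGMENT_LABELS <- c("anteroseptal", "inferoseptal", "inferior",
                    "inferolateral", "anterolateral", "anterior")

#' Segment model of the equatorial slice
#'
#' Six contiguous 60-degree sectors about the blood-pool centre, ordered
#' anteroseptal to anterior counter-clockwise as displayed (image y-axis
#' pointing down; angles measured from the positive x/column axis,
#' increasing towards the top of the image).  The anteroseptal boundary
#' sits at `reference_angle`; it must be supplied from protocol landmarks
#' (no automatic RV-insertion detection).
#'
#' @param center blood-pool centre `(row, col)` in 1-based pixels.
#' @param reference_angle radians; boundary of the first (anteroseptal)
#'   sector.
#' @param long_axis_sign +1 when the through-plane component points toward
#'   the apex, -1 otherwise.
#' @return object of class `tpm_segment_model`.
#' @export
segment_model <- function(center, reference_angle = 0, long_axis_sign = 1) {
  stopifnot(length(center) == 2L, long_axis_sign %in% c(-1, 1))
  structure(list(center = as.numeric(center),
                 reference_angle = reference_angle,
                 long_axis_sign = long_axis_sign,
                 n_segments = 6L, labels = SEGMENT_LABELS),
            class = "tpm_segment_model")
}

#' Project a velocity field onto radial and longitudinal directions
#'
#' Radial velocity at pixel p is the in-plane velocity projected onto the
#' unit vector from p towards the blood-pool centre (motion towards the
#' centre is positive).  Longitudinal velocity is
#' `long_axis_sign * v_z` (motion towards the apex is positive).  A pixel
#' coinciding with the centre has no radial direction and is NA.
#'
#' @param field a `tpm_velocity_field`.
#' @param model a [segment_model()].
#' @return list with `radial` and `longitudinal` arrays
#'   (row x col x phase, cm/s) and `times` if the field carries them.
#' @export
project_velocities <- function(field, model) {
  stopifnot(inherits(field, "tpm_velocity_field"),
            inherits(model, "tpm_segment_model"))
  d <- dim(field$v)
  g1 <- d[1L]; g2 <- d[2L]
  ctr <- model$center
  if (ctr[1L] < 1 || ctr[1L] > g1 || ctr[2L] < 1 || ctr[2L] > g2)
    stop("centre outside the image grid")
  rows <- matrix(seq_len(g1), g1, g2)
  cols <- matrix(seq_len(g2), g1, g2, byrow = TRUE)
  dx <- ctr[2L] - cols
  dy <- ctr[1L] - rows
  dist <- sqrt(dx^2 + dy^2)
  ux <- uy <- matrix(NA_real_, g1, g2)
  ok <- dist > 1e-9
  ux[ok] <- dx[ok] / dist[ok]
  uy[ok] <- dy[ok] / dist[ok]
  radial <- longitudinal <- array(NA_real_, dim = c(g1, g2, d[4L]))
  for (ph in seq_len(d[4L])) {
    radial[, , ph] <- field$v[, , 1L, ph] * ux + field$v[, , 2L, ph] * uy
    longitudinal[, , ph] <- model$long_axis_sign * field$v[, , 3L, ph]
  }
  list(radial = radial, longitudinal = longitudinal)
}

#' Partition a myocardial mask into the six equatorial segments
#'
#' Each mask pixel is assigned by its polar angle about the centre
#' (counter-clockwise as displayed, starting at `reference_angle`) to one
#' of six 60-degree sectors in the order anteroseptal, inferoseptal,
#' inferior, inferolateral, anterolateral, anterior.
#'
#' @param mask logical myocardium mask.
#' @param model a [segment_model()].
#' @return character matrix of labels (NA outside the mask) with attribute
#'   `levels` in segment order.  A pixel exactly at the centre is left
#'   unlabelled with a warning.
#' @export
partition_segments <- function(mask, model) {
  stopifnot(is.logical(mask), inherits(model, "tpm_segment_model"))
  if (!any(mask)) stop("mask is empty")
  idx <- which(mask, arr.ind = TRUE)
  dx <- idx[, "col"] - model$center[2L]
  dy <- model$center[1L] - idx[, "row"]   # flip: image y points down
  at_centre <- abs(dx) < 1e-9 & abs(dy) < 1e-9
  theta <- atan2(dy, dx) - model$reference_angle
  seg <- floor((theta %% (2 * pi)) / (pi / 3)) + 1L
  seg[seg > 6L] <- 1L   # guard the 2*pi boundary
  labels <- matrix(NA_character_, nrow(mask), ncol(mask))
  labels[mask] <- SEGMENT_LABELS[seg]
  if (any(at_centre)) {
    warning("pixel at the exact centre left unlabelled")
    labels[idx[at_centre, , drop = FALSE]] <- NA_character_
  }
  attr(labels, "levels") <- SEGMENT_LABELS
  labels
}

#' Construct a velocity-time curve
#'
#' @param times sampling instants in ms (strictly increasing).
#' @param values region-mean velocities in cm/s.
#' @param direction `"radial"` or `"longitudinal"`.
#' @param region region name (`"global"` or a segment label).
#' @return object of class `tpm_curve`.
#' @export
velocity_curve <- function(times, values, direction = "radial",
                           region = "global") {
  stopifnot(length(times) == length(values), length(times) >= 2L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 direction = direction, region = region,
                 dense_times = NULL, dense_values = NULL, dt = NULL),
            class = "tpm_curve")
}

#' @export
print.tpm_curve <- function(x, ...) {
  cat(sprintf("%s velocity curve (%s): %d phases over %g ms%s\n",
              x$direction, x$region, length(x$times),
              x$times[length(x$times)] - x$times[1L],
              if (is.null(x$dense_times)) ""
              else sprintf("; dense at dt = %g ms", x$dt)))
  cat(sprintf("  peaks %+.3f / %+.3f cm/s\n", max(x$values), min(x$values)))
  invisible(x)
}

#' @export
plot.tpm_curve <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "p", pch = 16,
                 xlab = "time from trigger [ms]", ylab = "velocity [cm/s]",
                 main = sprintf("%s velocity, %s", x$direction, x$region), ...)
  if (!is.null(x$dense_times))
    graphics::lines(x$dense_times, x$dense_values, col = "steelblue")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Resample a velocity curve on a dense uniform grid by cubic splines
#'
#' Natural cubic-spline interpolation through the measured phases,
#' evaluated on a uniform grid of step `dt` spanning the measured time
#' range.  The interpolant reproduces the knots exactly.  With fewer than
#' 4 points a linear interpolation is used and flagged; a `dt` larger than
#' the time span yields the two endpoints, flagged.
#'
#' @param curve a [velocity_curve()].
#' @param dt dense grid step in ms (> 0); the default 0.01 ms matches the
#'   step used for the curve-agreement statistics.
#' @return the curve with `dense_times`, `dense_values` and `dt` filled in
#'   (attribute `degenerate` marks fallback modes).
#' @export
spline_resample <- function(curve, dt = 0.01) {
  stopifnot(inherits(curve, "tpm_curve"))
  if (dt <= 0) stop("dt must be > 0")
  t0 <- curve$times[1L]
  t1 <- curve$times[length(curve$times)]
  if (dt > t1 - t0) {
    curve$dense_times <- c(t0, t1)
    curve$dense_values <- curve$values[c(1L, length(curve$values))]
    curve$dt <- dt
    attr(curve, "degenerate") <- "dt exceeds time span"
    return(curve)
  }
  grid <- seq(t0, t1, by = dt)
  if (length(curve$times) < 4L) {
    curve$dense_values <- approx(curve$times, curve$values, xout = grid)$y
    attr(curve, "degenerate") <- "linear fallback (< 4 points)"
  } else {
    f <- splinefun(curve$times, curve$values, method = "natural")
    curve$dense_values <- f(grid)
  }
  curve$dense_times <- grid
  curve$dt <- dt
  curve
}

#' Region-mean velocity curves from projected velocity maps
#'
#' For every requested region and direction: the arithmetic mean over the
#' labelled, defined pixels at each cardiac phase, followed by the
#' zero-integral shift and dense spline resampling.
#'
#' @param proj output of [project_velocities()].
#' @param mask logical myocardium mask (the `"global"` region).
#' @param times cardiac-phase times in ms (length = number of phases).
#' @param labels optional segment label matrix from
#'   [partition_segments()]; adds one curve per segment.
#' @param dt dense resampling step in ms.
#' @return named list of `tpm_curve` objects, keys `"<region>.<direction>"`.
#'   Empty regions are skipped with a warning.
#' @export
extract_curves <- function(proj, mask, times, labels = NULL, dt = 0.01) {
  stopifnot(is.list(proj), is.logical(mask))
  n_ph <- dim(proj$radial)[3L]
  if (length(times) != n_ph) stop("times length must equal the phase count")
  regions <- list(global = mask)
  if (!is.null(labels)) {
    for (l in attr(labels, "levels") %||% unique(labels[!is.na(labels)]))
      regions[[l]] <- !is.na(labels) & labels == l
  }
  out <- list()
  for (rg in names(regions)) {
    sel <- regions[[rg]]
    if (!any(sel)) {
      warning(sprintf("region '%s' is empty: no curve", rg))
      next
    }
    for (dir in c("radial", "longitudinal")) {
      vals <- vapply(seq_len(n_ph), function(ph) {
        m <- proj[[dir]][, , ph][sel]
        mean(m[!is.na(m)])
      }, numeric(1))
      cv <- velocity_curve(times, vals, direction = dir, region = rg)
      cv <- zero_integral_shift(cv)
      cv <- spline_resample(cv, dt)
      out[[paste(rg, dir, sep = ".")]] <- cv
    }
  }
  out
}
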