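# Four-point Hadamard velocity decoding and the two phase-error
# corrections: the linear static-tissue background fit and the
# zero-integral curve shift.

#' Decode four Hadamard velocity encodings into a 3-component velocity field
#'
#' Inter-encoding phase differences are taken as angles of conjugate
#' products (wrap-safe near +/- pi); with encoding phases `phi_e` the
#' components are
#' `v_x = venc/(2*pi) * (-phi1 + phi2 + phi3 - phi4)`,
#' `v_y = venc/(2*pi) * (-phi1 + phi2 - phi3 + phi4)`,
#' `v_z = venc/(2*pi) * (-phi1 - phi2 + phi3 + phi4)`,
#' the balanced inverse of the encoding matrix used by [encode_images()].
#' The common phase (mean of the four encoding phases, which carries the
#' shared background phase) cancels in the products and is discarded.
#' Decoding is unambiguous while `|v_x +/- v_y| <= venc` and
#' `|v_x +/- v_z| <= venc`; beyond that the phase wraps.
#'
#' @param encoded a `tpm_unfold` reconstruction, an image-domain
#'   `tpm_encoded` series (coils are combined by plain magnitude-weighted
#'   sum beforehand is not needed — pass reconstructions), or a complex
#'   array (row, col, 4) / (row, col, 4, phase).
#' @param venc velocity-encoding limit in cm/s (taken from the object when
#'   available).
#' @return object of class `tpm_velocity_field`: `v` array
#'   (row, col, component, phase) in cm/s, `venc`, and `background_fit`
#'   (`NULL` until [correct_background()] is applied).  Pixels with zero
#'   magnitude in any encoding are NA.
#' @export
hadamard_decode <- function(encoded, venc = NULL) {
  if (inherits(encoded, "tpm_unfold")) {
    venc <- venc %||% encoded$venc
    arr <- encoded$recon
  } else if (inherits(encoded, "tpm_encoded")) {
    stop("decode expects a reconstruction or a plain complex array; ",
         "run sense_unfold() (or supply single-coil images as an array)")
  } else {
    arr <- encoded
  }
  if (is.null(venc)) stop("venc must be supplied")
  stopifnot_scalar(venc, "venc", positive = TRUE)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  d <- dim(arr)
  if (d[3L] != 4L) stop("expected 4 velocity encodings")
  n_ph <- d[4L]
  v <- array(NA_real_, dim = c(d[1L], d[2L], 3L, n_ph))
  k <- venc / (2 * pi)
  for (ph in seq_len(n_ph)) {
    z1 <- arr[, , 1L, ph]; z2 <- arr[, , 2L, ph]
    z3 <- arr[, , 3L, ph]; z4 <- arr[, , 4L, ph]
    bad <- Mod(z1) == 0 | Mod(z2) == 0 | Mod(z3) == 0 | Mod(z4) == 0
    A <- Arg(z2 * Conj(z1))   # phi2 - phi1
    B <- Arg(z3 * Conj(z4))   # phi3 - phi4
    C <- Arg(z3 * Conj(z1))   # phi3 - phi1
    D <- Arg(z2 * Conj(z4))   # phi2 - phi4
    vx <- k * (A + B)
    vy <- k * (A - B)
    vz <- k * (C - D)
    vx[bad] <- vy[bad] <- vz[bad] <- NA_real_
    v[, , 1L, ph] <- vx
    v[, , 2L, ph] <- vy
    v[, , 3L, ph] <- vz
  }
  structure(list(v = v, venc = venc, background_fit = NULL),
            class = "tpm_velocity_field")
}

#' @export
print.tpm_velocity_field <- function(x, ...) {
  d <- dim(x$v)
  cat(sprintf("Velocity field: %d x %d px, %d phases, VENC %g cm/s%s\n",
              d[1L], d[2L], d[4L], x$venc,
              if (is.null(x$background_fit)) "" else ", background-corrected"))
  invisible(x)
}

#' Linear background-phase (velocity offset) fit over static tissue
#'
#' Least-squares fit of the plane `a0 + a1*x + a2*y` (x = column, y = row,
#' 1-based pixel indices) to one velocity-component map over the static
#' tissue mask; the fitted plane is subtracted everywhere.  The corrected
#' map has zero mean over the static mask by construction.
#'
#' @param vcomp numeric matrix: one velocity-component map (cm/s).
#' @param static_mask logical matrix with at least 3 non-collinear `TRUE`
#'   pixels.
#' @return list with `coefficients` (`offset`, `x_slope`, `y_slope`) and
#'   `corrected` (matrix).
#' @export
fit_background_plane <- function(vcomp, static_mask) {
  stopifnot(is.matrix(vcomp), is.logical(static_mask),
            all(dim(vcomp) == dim(static_mask)))
  idx <- which(static_mask, arr.ind = TRUE)
  ok <- !is.na(vcomp[static_mask])
  idx <- idx[ok, , drop = FALSE]
  if (nrow(idx) < 3L)
    stop("static mask needs >= 3 pixels with defined velocity")
  X <- cbind(1, idx[, "col"], idx[, "row"])
  qrX <- qr(X)
  if (qrX$rank < 3L)
    stop("static-mask pixels are collinear: background plane not identifiable")
  coef <- qr.coef(qrX, vcomp[static_mask][ok])
  names(coef) <- c("offset", "x_slope", "y_slope")
  rows <- matrix(seq_len(nrow(vcomp)), nrow(vcomp), ncol(vcomp))
  cols <- matrix(seq_len(ncol(vcomp)), nrow(vcomp), ncol(vcomp), byrow = TRUE)
  plane <- coef[1L] + coef[2L] * cols + coef[3L] * rows
  list(coefficients = coef, corrected = vcomp - plane)
}

#' Apply the static-tissue background correction to a velocity field
#'
#' Fits and removes the linear plane independently for every cardiac phase
#' and velocity component (the fit is not pooled), recording the removed
#' coefficients in `background_fit` (phase x component x coefficient).
#'
#' @param field a `tpm_velocity_field`.
#' @param static_mask logical static-tissue mask.
#' @return the corrected `tpm_velocity_field`.
#' @export
correct_background <- function(field, static_mask) {
  stopifnot(inherits(field, "tpm_velocity_field"))
  d <- dim(field$v)
  fit <- array(NA_real_, dim = c(d[4L], 3L, 3L),
               dimnames = list(NULL, c("vx", "vy", "vz"),
                               c("offset", "x_slope", "y_slope")))
  for (ph in seq_len(d[4L])) for (k in 1:3) {
    res <- fit_background_plane(field$v[, , k, ph], static_mask)
    field$v[, , k, ph] <- res$corrected
    fit[ph, k, ] <- res$coefficients
  }
  field$background_fit <- fit
  field
}

#' Estimate a static-tissue mask from temporal velocity variation
#'
#' For measured data without a known static region: pixels whose velocity
#' standard deviation over the cardiac cycle (root-sum of the per-component
#' temporal variances) falls below the given quantile are taken as static.
#'
#' @param field a `tpm_velocity_field`.
#' @param quantile fraction of pixels to keep (default 0.1, the lowest
#'   decile of temporal variation).
#' @return logical matrix.
#' @export
estimate_static_mask <- function(field, quantile = 0.1) {
  stopifnot(inherits(field, "tpm_velocity_field"))
  d <- dim(field$v)
  tv <- matrix(0, d[1L], d[2L])
  for (k in 1:3) {
    comp <- field$v[, , k, ]
    if (length(dim(comp)) == 2L) dim(comp) <- c(dim(comp), 1L)
    tv <- tv + apply(comp, c(1L, 2L), stats::var)
  }
  tv <- sqrt(tv)
  thr <- stats::quantile(tv, quantile, na.rm = TRUE)
  !is.na(tv) & tv <= thr
}

#' Zero-integral shift of a velocity curve
#'
#' Over one heart cycle the accumulated displacement of the tissue must
#' vanish, so the trapezoidal time-integral of the region-mean velocity
#' curve is constrained to zero: the constant
#' `c = integral(v dt) / duration` is subtracted from the curve (and from
#' its dense resampling, which shifts identically).
#'
#' @param curve a [velocity_curve()] (>= 2 time points, strictly
#'   increasing times).
#' @return the shifted curve, with attribute `shift` (cm/s) recording the
#'   removed constant.
#' @export
zero_integral_shift <- function(curve) {
  stopifnot(inherits(curve, "tpm_curve"))
  t <- curve$times
  if (length(t) < 2L) stop("need at least 2 time points")
  if (any(diff(t) <= 0)) stop("time axis must be strictly increasing")
  shift <- trapz(t, curve$values) / (t[length(t)] - t[1L])
  curve$values <- curve$values - shift
  if (!is.null(curve$dense_values))
    curve$dense_values <- curve$dense_values - shift
  attr(curve, "shift") <- shift
  curve
}
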