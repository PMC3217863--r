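# Cartesian SENSE unfolding, g-factor maps and local SNR maps.
#
# Uniform undersampling of every R-th phase-encode row folds the image: the
# reduced-FOV inverse DFT at row y' is the sum of the R fold-over positions
# y' + j*M (M = padded rows / R).  Per folded pixel the coil measurements
# a = S rho are solved in the least-squares sense, optionally pre-whitened
# by the coil noise covariance Psi.

# Per-group unfolding operators for one sampling geometry.
# Returns list with M, unfold matrices U (R x n_coils) and g-factor values,
# both indexed by (y', x) group, plus a rank-deficiency count.
sense_system <- function(sens, R, psi = NULL, rtol = 1e-12) {
  g_rows <- dim(sens)[1L]
  n_col <- dim(sens)[2L]
  n_coils <- dim(sens)[3L]
  if (R > n_coils) stop(sprintf(
    "R = %d exceeds the %d coils: unfolding is underdetermined", R, n_coils))
  if (g_rows %% R != 0L) stop("row count must be a multiple of R (pad first)")
  M <- g_rows %/% R
  wi <- NULL
  if (!is.null(psi)) {
    psi <- as.matrix(psi)
    if (!all(dim(psi) == n_coils)) stop("psi must be n_coils x n_coils")
    wi <- solve(psi)
  }
  U <- vector("list", M * n_col)
  gfac <- matrix(NA_real_, g_rows, n_col)
  n_deficient <- 0L
  smat <- matrix(0i, n_coils, R)
  for (x in seq_len(n_col)) {
    for (yp in seq_len(M)) {
      pos <- yp + (seq_len(R) - 1L) * M
      for (j in seq_len(R)) smat[, j] <- sens[pos[j], x, ]
      sh <- Conj(t(smat))
      A <- if (is.null(wi)) sh %*% smat else sh %*% wi %*% smat
      sv <- svd(A)
      keep <- sv$d > rtol * max(sv$d, 0)
      if (sum(keep) < R) n_deficient <- n_deficient + 1L
      Ap <- if (!any(keep)) matrix(0i, R, R) else
        sv$v[, keep, drop = FALSE] %*%
          ((1 / sv$d[keep]) * Conj(t(sv$u[, keep, drop = FALSE])))
      U[[(x - 1L) * M + yp]] <-
        if (is.null(wi)) Ap %*% sh else Ap %*% sh %*% wi
      gg <- Re(diag(Ap) * diag(A))
      gg[gg < 0] <- NA_real_
      gfac[pos, x] <- sqrt(gg)
    }
  }
  list(M = M, R = R, n_col = n_col, n_coils = n_coils, U = U,
       gfactor = gfac, n_rank_deficient = n_deficient)
}

#' SENSE unfolding of uniformly undersampled multi-coil k-space
#'
#' Inverse-transforms the acquired (every R-th row) k-space per coil,
#' encoding and cardiac phase, then solves the per-pixel-group least-squares
#' system `S rho = a` with the coil sensitivity matrix `S`, optionally
#' pre-whitened by the coil noise covariance `psi` (identity by default).
#' The pseudo-inverse uses a relative singular-value cutoff of 1e-12 and no
#' regularisation; rank-deficient pixel groups (all sensitivities ~ 0, e.g.
#' padded rows) yield zero and are counted in the diagnostics.  At R = 1 the
#' operation reduces to the psi-weighted least-squares coil combination.
#'
#' @param kspace k-space `tpm_encoded` from [sample_kspace()].
#' @param sens coil sensitivities on the original (unpadded) grid.
#' @param psi coil noise covariance matrix, or `NULL` for identity.
#' @return object of class `tpm_unfold`: `recon` complex array
#'   (row, col, encoding, phase) on the original grid, `gfactor` map
#'   (NA where undefined), `diagnostics`, and the acquisition metadata
#'   (`venc`, `sense_factor`).
#' @export
sense_unfold <- function(kspace, sens, psi = NULL) {
  stopifnot(inherits(kspace, "tpm_encoded"), kspace$domain == "kspace",
            inherits(sens, "tpm_sens"))
  samp <- kspace$sampling
  R <- kspace$sense_factor
  d <- dim(kspace$data)
  n_coils <- d[3L]
  if (dim(sens)[3L] != n_coils) stop("coil count mismatch with sensitivities")
  nrow_pad <- samp$nrow_padded
  M <- nrow_pad %/% R
  if (d[1L] != M) stop("acquired row count inconsistent with R")
  sens_pad <- array(0i, dim = c(nrow_pad, dim(sens)[2L], n_coils))
  sens_pad[seq_len(samp$nrow_orig), , ] <- sens[seq_len(samp$nrow_orig), , ]
  sys <- sense_system(sens_pad, R, psi)
  n_col <- d[2L]
  n_enc <- d[4L]
  n_ph <- d[5L]
  # folded images: unnormalised inverse FFT / (M * n_col) gives the alias sum
  folded <- array(0i, dim = c(M, n_col, n_coils, n_enc, n_ph))
  norm <- M * n_col
  for (ph in seq_len(n_ph)) for (e in seq_len(n_enc)) for (k in seq_len(n_coils))
    folded[, , k, e, ph] <-
      stats::fft(kspace$data[, , k, e, ph], inverse = TRUE) / norm
  recon <- array(0i, dim = c(nrow_pad, n_col, n_enc, n_ph))
  nslice <- n_enc * n_ph
  for (x in seq_len(n_col)) {
    for (yp in seq_len(M)) {
      amat <- matrix(folded[yp, x, , , ], nrow = n_coils, ncol = nslice)
      rho <- sys$U[[(x - 1L) * M + yp]] %*% amat
      pos <- yp + (seq_len(R) - 1L) * M
      recon[pos, x, , ] <- rho
    }
  }
  structure(list(
    recon = recon[seq_len(samp$nrow_orig), , , , drop = FALSE],
    gfactor = sys$gfactor[seq_len(samp$nrow_orig), , drop = FALSE],
    diagnostics = list(n_rank_deficient = sys$n_rank_deficient,
                       nrow_padded = nrow_pad),
    venc = kspace$venc, sense_factor = R), class = "tpm_unfold")
}

#' @export
print.tpm_unfold <- function(x, ...) {
  d <- dim(x$recon)
  cat(sprintf("SENSE reconstruction: %d x %d, %d encodings, %d phases (R = %d)\n",
              d[1L], d[2L], d[3L], d[4L], x$sense_factor))
  cat(sprintf("  g-factor: median %.3f, max %.3f; %d rank-deficient groups\n",
              median(x$gfactor, na.rm = TRUE), max(x$gfactor, na.rm = TRUE),
              x$diagnostics$n_rank_deficient))
  invisible(x)
}

#' SENSE g-factor map
#'
#' Noise amplification of the unfolding solve,
#' `g = sqrt(diag((S^H Psi^-1 S)^-1) * diag(S^H Psi^-1 S))` per fold-over
#' position; `g >= 1` wherever defined and identically 1 at R = 1.
#'
#' @param sens coil sensitivity maps (`tpm_sens` or complex array).
#' @param R acceleration factor; rows are padded to a multiple of R.
#' @param psi coil noise covariance (identity if `NULL`).
#' @return matrix of g-factor values on the input grid (NA where the
#'   system is singular).
#' @export
gfactor <- function(sens, R, psi = NULL) {
  sens <- unclass(sens)
  nrow_orig <- dim(sens)[1L]
  nrow_pad <- as.integer(R * ceiling(nrow_orig / R))
  if (nrow_pad > nrow_orig) {
    sp <- array(0i, dim = c(nrow_pad, dim(sens)[2L], dim(sens)[3L]))
    sp[seq_len(nrow_orig), , ] <- sens
    sens <- sp
  }
  sys <- sense_system(sens, as.integer(R), psi)
  sys$gfactor[seq_len(nrow_orig), , drop = FALSE]
}

#' Local signal-to-noise map
#'
#' SNR at each pixel is the mean of the surrounding `window x window`
#' neighbourhood divided by its sample (n-1) standard deviation.  Pixels
#' whose window is not fully inside the image, or whose local standard
#' deviation is zero, are undefined (NA).
#'
#' @param image numeric matrix (magnitude image or one velocity map).
#' @param window odd window size >= 3 (default 3).
#' @return matrix of SNR values with attributes `window` and
#'   `n_undefined` (count of interior pixels with zero local SD).
#' @export
snr_map <- function(image, window = 3L) {
  stopifnot(is.matrix(image), is.numeric(image))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  h <- window %/% 2L
  nr <- nrow(image); nc <- ncol(image)
  if (nr < window || nc < window) stop("image smaller than the window")
  vr <- (h + 1L):(nr - h)
  vc <- (h + 1L):(nc - h)
  s <- s2 <- matrix(0, length(vr), length(vc))
  for (dy in -h:h) for (dx in -h:h) {
    sub <- image[vr + dy, vc + dx, drop = FALSE]
    s <- s + sub
    s2 <- s2 + sub^2
  }
  n <- window^2
  m <- s / n
  v <- (s2 - n * m^2) / (n - 1)
  v[v < 0] <- 0
  sdev <- sqrt(v)
  snr <- m / sdev
  zero_sd <- sdev <= max(abs(m), 1) * 1e-12
  snr[zero_sd] <- NA_real_
  out <- matrix(NA_real_, nr, nc)
  out[vr, vc] <- snr
  structure(out, window = window, n_undefined = sum(zero_sd))
}

#' Regional mean SNR
#'
#' Mean of the defined (non-NA) SNR values per labelled segment and over
#' all labelled pixels.
#'
#' @param snr an [snr_map()] result (or any numeric matrix with NAs where
#'   undefined).
#' @param labels integer/character matrix of segment labels with `NA`
#'   outside the region of interest, or a logical mask (single region).
#' @return data.frame with columns `segment`, `mean_snr`, `n_pixels`,
#'   `n_undefined`; the last row (`"all"`) pools every labelled pixel.
#'   Empty segments yield `NA` with a warning.
#' @export
regional_snr <- function(snr, labels) {
  stopifnot(all(dim(snr) == dim(labels)))
  if (is.logical(labels)) {
    lab <- matrix(NA_character_, nrow(labels), ncol(labels))
    lab[labels] <- "region"
    labels <- lab
  }
  lv <- attr(labels, "levels") %||% sort(unique(labels[!is.na(labels)]))
  rows <- lapply(as.character(lv), function(l) {
    sel <- !is.na(labels) & labels == l
    vals <- snr[sel]
    def <- vals[!is.na(vals)]
    if (sum(sel) == 0L) {
      warning(sprintf("segment '%s' is empty", l))
      return(data.frame(segment = l, mean_snr = NA_real_, n_pixels = 0L,
                        n_undefined = 0L))
    }
    data.frame(segment = l, mean_snr = if (length(def)) mean(def) else NA_real_,
               n_pixels = sum(sel), n_undefined = sum(is.na(vals)))
  })
  sel <- !is.na(labels)
  vals <- snr[sel]
  def <- vals[!is.na(vals)]
  rows[[length(rows) + 1L]] <- data.frame(
    segment = "all", mean_snr = if (length(def)) mean(def) else NA_real_,
    n_pixels = sum(sel), n_undefined = sum(is.na(vals)))
  do.call(rbind, rows)
}
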