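# On-disk formats: NIfTI for images/labels/velocity components (the affine
# carries the pixel spacing in mm), CSV for curves and statistics, JSON
# sidecars for acquisition metadata, YAML for phantom/run configuration.
# All floating-point round trips are lossless (float64 on disk).

nifti_write <- function(arr, path, pixel_spacing = NULL) {
  img <- RNifti::asNifti(arr, internal = FALSE)
  if (!is.null(pixel_spacing)) {
    pd <- RNifti::pixdim(img)
    pd[1:2] <- pixel_spacing
    RNifti::pixdim(img) <- pd
  }
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write / read a phantom specification as YAML
#'
#' @param spec a [phantom_spec()].
#' @param path file path (`.yaml`).
#' @return `read_phantom_spec()` returns the reconstructed
#'   `tpm_phantom_spec`; the writer returns the path invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "tpm_phantom_spec"))
  x <- unclass(spec)
  x$velocity_offset_planes <- as.numeric(t(x$velocity_offset_planes))
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  x$velocity_offset_planes <- matrix(unlist(x$velocity_offset_planes),
                                     nrow = 3L, byrow = TRUE)
  x$static_band <- lapply(x$static_band, unlist)
  x$blood_pool_center <- unlist(x$blood_pool_center)
  x$background_phase_plane <- unlist(x$background_phase_plane)
  x$radial_waveform <- unlist(x$radial_waveform)
  x$longitudinal_waveform <- unlist(x$longitudinal_waveform)
  do.call(phantom_spec, x)
}

#' Write / read a velocity field as NIfTI volumes with a JSON sidecar
#'
#' One NIfTI file per velocity component (`<prefix>_vx.nii.gz` etc., each
#' row x col x phase) plus `<prefix>.json` recording the VENC and any
#' background-fit coefficients removed.
#'
#' @param field a `tpm_velocity_field`.
#' @param prefix output path prefix.
#' @param pixel_spacing in-plane pixel size in mm for the NIfTI affine.
#' @return the reader returns the reconstructed `tpm_velocity_field`.
#' @export
write_velocity_field <- function(field, prefix, pixel_spacing = NULL) {
  stopifnot(inherits(field, "tpm_velocity_field"))
  comps <- c("vx", "vy", "vz")
  for (k in 1:3)
    nifti_write(field$v[, , k, ], sprintf("%s_%s.nii.gz", prefix, comps[k]),
                pixel_spacing)
  meta <- list(venc = field$venc, units = "cm/s",
               components = comps,
               background_fit = if (is.null(field$background_fit)) NULL
                 else as.numeric(field$background_fit),
               background_fit_dim = dim(field$background_fit),
               pixel_spacing_mm = pixel_spacing)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_velocity_field
#' @export
read_velocity_field <- function(prefix) {
  meta_path <- paste0(prefix, ".json")
  if (!file.exists(meta_path)) stop("sidecar JSON missing: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$venc)) stop("sidecar lacks the mandatory 'venc' field")
  comps <- lapply(c("vx", "vy", "vz"), function(cm) {
    arr <- as.array(RNifti::readNifti(sprintf("%s_%s.nii.gz", prefix, cm)))
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    arr
  })
  d <- dim(comps[[1L]])
  v <- array(NA_real_, dim = c(d[1L], d[2L], 3L, d[3L]))
  for (k in 1:3) v[, , k, ] <- comps[[k]]
  bg <- NULL
  if (!is.null(meta$background_fit) && length(meta$background_fit))
    bg <- array(meta$background_fit, dim = meta$background_fit_dim)
  structure(list(v = v, venc = as.numeric(meta$venc), background_fit = bg),
            class = "tpm_velocity_field")
}

#' Write / read an encoded series (real/imaginary NIfTI pair + sidecar)
#'
#' @param enc a `tpm_encoded` series.
#' @param prefix output path prefix; writes `<prefix>_re.nii.gz`,
#'   `<prefix>_im.nii.gz` and `<prefix>.json`.
#' @return the reader returns the reconstructed `tpm_encoded`; a sidecar
#'   without `venc` is a hard error.
#' @export
write_encoded <- function(enc, prefix) {
  stopifnot(inherits(enc, "tpm_encoded"))
  nifti_write(Re(enc$data), paste0(prefix, "_re.nii.gz"))
  nifti_write(Im(enc$data), paste0(prefix, "_im.nii.gz"))
  meta <- list(domain = enc$domain, venc = enc$venc,
               sense_factor = enc$sense_factor,
               noise_sigma = enc$noise_sigma, seed = enc$seed,
               sampling = enc$sampling, dim = dim(enc$data))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_encoded
#' @export
read_encoded <- function(prefix) {
  meta_path <- paste0(prefix, ".json")
  if (!file.exists(meta_path)) stop("sidecar JSON missing: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$venc)) stop("sidecar lacks the mandatory 'venc' field")
  re <- as.array(RNifti::readNifti(paste0(prefix, "_re.nii.gz")))
  im <- as.array(RNifti::readNifti(paste0(prefix, "_im.nii.gz")))
  data <- array(complex(real = re, imaginary = im), dim = unlist(meta$dim))
  sampling <- meta$sampling
  if (!is.null(sampling)) sampling <- lapply(sampling, unlist)
  structure(list(data = data, domain = meta$domain, sampling = sampling,
                 venc = as.numeric(meta$venc),
                 sense_factor = as.integer(meta$sense_factor),
                 noise_sigma = meta$noise_sigma %||% 0, seed = meta$seed),
            class = "tpm_encoded")
}

#' Write / read velocity curves as CSV
#'
#' Columns `region`, `direction`, `time_ms`, `value_cm_s` (the measured
#' phases; the dense resampling is reconstructed on read from the `dt`
#' recorded in the JSON manifest).  Rows out of temporal order are sorted
#' with a warning on read.
#'
#' @param curves named list of `tpm_curve` (e.g. from [extract_curves()]).
#' @param path CSV path; a manifest `<path>.json` is written alongside.
#' @return the reader returns the named curve list.
#' @export
write_curves <- function(curves, path) {
  rows <- lapply(curves, function(cv)
    data.frame(region = cv$region, direction = cv$direction,
               time_ms = cv$times, value_cm_s = cv$values))
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  write.csv(df, path, row.names = FALSE)
  dts <- unlist(lapply(curves, function(cv) cv$dt))
  jsonlite::write_json(list(dt_ms = if (length(dts)) unname(dts[1L]) else NULL,
                            n_curves = length(curves)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "direction", "time_ms", "value_cm_s")
  if (!all(need %in% names(df)))
    stop("curve CSV must have columns ", paste(need, collapse = ", "))
  manifest <- paste0(path, ".json")
  dt <- if (file.exists(manifest))
    jsonlite::read_json(manifest, simplifyVector = TRUE)$dt_ms else NULL
  keys <- unique(df[c("region", "direction")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- df$region == keys$region[i] & df$direction == keys$direction[i]
    sub <- df[sel, ]
    if (is.unsorted(sub$time_ms, strictly = TRUE)) {
      warning("curve rows out of temporal order; sorting by time")
      sub <- sub[order(sub$time_ms), ]
    }
    cv <- velocity_curve(sub$time_ms, sub$value_cm_s,
                         direction = keys$direction[i],
                         region = keys$region[i])
    if (!is.null(dt)) cv <- spline_resample(cv, dt)
    out[[paste(keys$region[i], keys$direction[i], sep = ".")]] <- cv
  }
  out
}

#' Write a comparison table as CSV and JSON
#'
#' @param cmp a `tpm_comparison` table.
#' @param path_csv CSV output path.
#' @param path_json optional JSON output path.
#' @export
write_comparison <- function(cmp, path_csv, path_json = NULL) {
  write.csv(as.data.frame(cmp), path_csv, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(as.data.frame(cmp), path_json, dataframe = "rows",
                         digits = NA)
  invisible(path_csv)
}

#' Write a segment label map as NIfTI (integer codes + JSON legend)
#' @param labels label matrix from [partition_segments()].
#' @param prefix output path prefix.
#' @export
write_labels <- function(labels, prefix) {
  lv <- attr(labels, "levels") %||% sort(unique(labels[!is.na(labels)]))
  codes <- matrix(match(labels, lv), nrow(labels), ncol(labels))
  codes[is.na(codes)] <- 0L
  nifti_write(codes, paste0(prefix, ".nii.gz"))
  jsonlite::write_json(list(levels = lv, background = 0L),
                       paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}
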