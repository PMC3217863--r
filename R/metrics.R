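# Scalar and paired curve statistics: peak metrics, peak factor, nRMSD,
# curve correlation, Bland-Altman agreement and the paired t-test, plus the
# tidy comparison table across acquisitions.

dense_of <- function(curve) {
  stopifnot(inherits(curve, "tpm_curve"))
  if (is.null(curve$dense_values))
    stop("curve has no dense resampling; run spline_resample() first")
  curve
}

#' Peak metrics of a velocity curve
#'
#' Systolic peak = maximum of the dense curve, diastolic peak = minimum,
#' velocity range `delta_v` = their difference, and `t_dias` = the time of
#' the minimum (earliest on ties).
#'
#' @param curve a dense-resampled [velocity_curve()].
#' @return list of class `tpm_peaks` with `v_p_sys`, `v_p_dias`,
#'   `delta_v` (cm/s) and `t_dias` (ms); a flat curve is flagged via
#'   attribute `flat`.
#' @export
peak_metrics <- function(curve) {
  curve <- dense_of(curve)
  v <- curve$dense_values
  t <- curve$dense_times
  i_min <- which.min(v)
  out <- structure(list(v_p_sys = max(v), v_p_dias = v[i_min],
                        delta_v = max(v) - v[i_min], t_dias = t[i_min]),
                   class = "tpm_peaks")
  if (out$delta_v == 0) attr(out, "flat") <- TRUE
  out
}

#' @export
print.tpm_peaks <- function(x, ...) {
  cat(sprintf("peaks: sys %+.3f, dias %+.3f, range %.3f cm/s; t_dias %.1f ms\n",
              x$v_p_sys, x$v_p_dias, x$delta_v, x$t_dias))
  invisible(x)
}

#' Peak factor between two acquisitions
#'
#' Ratio of the velocity ranges, `PF = delta_v_2 / delta_v_1`; 1 means the
#' accelerated acquisition preserves the velocity amplitude of the
#' reference.
#'
#' @param delta_v_seq1 reference velocity range (> 0), cm/s.
#' @param delta_v_seq2 comparison velocity range, cm/s.
#' @return unitless ratio.
#' @export
peak_factor <- function(delta_v_seq1, delta_v_seq2) {
  stopifnot_scalar(delta_v_seq1, "delta_v_seq1")
  stopifnot_scalar(delta_v_seq2, "delta_v_seq2")
  if (delta_v_seq1 <= 0) stop("reference velocity range must be > 0")
  delta_v_seq2 / delta_v_seq1
}

#' Normalised root-mean-square deviation between two curves (percent)
#'
#' RMSD of the dense samples divided by the dynamic range
#' (max - min) of the reference curve, times 100.  An alternative
#' normaliser, the mean of the two ranges, is available.
#'
#' @param curve1 reference curve (defines the normaliser).
#' @param curve2 comparison curve on the identical dense grid.
#' @param normalizer `"reference"` (default) or `"mean_range"`.
#' @return nRMSD in percent.
#' @export
nrmsd <- function(curve1, curve2, normalizer = c("reference", "mean_range")) {
  normalizer <- match.arg(normalizer)
  curve1 <- dense_of(curve1); curve2 <- dense_of(curve2)
  x <- curve1$dense_values; y <- curve2$dense_values
  if (length(x) != length(y) ||
      max(abs(curve1$dense_times - curve2$dense_times)) > 1e-9)
    stop("curves must share the identical dense grid")
  rng1 <- diff(range(x))
  rng <- switch(normalizer, reference = rng1,
                mean_range = (rng1 + diff(range(y))) / 2)
  if (rng <= 0) stop("flat reference curve: nRMSD undefined")
  100 * sqrt(mean((x - y)^2)) / rng
}

#' Correlation coefficient between two velocity curves
#'
#' Sum over the dense samples of the product of the standardised
#' deviations, normalised by (N - 1) so that `c(x, x) = 1`:
#' `c = sum(((x - mean(x))/sd(x)) * ((y - mean(y))/sd(y))) / (N - 1)`,
#' i.e. the Pearson correlation of the spline-interpolated curves.
#'
#' @param curve1,curve2 dense-resampled curves on the identical grid.
#' @return correlation in \[-1, 1\].
#' @export
curve_correlation <- function(curve1, curve2) {
  curve1 <- dense_of(curve1); curve2 <- dense_of(curve2)
  x <- curve1$dense_values; y <- curve2$dense_values
  if (length(x) != length(y) ||
      max(abs(curve1$dense_times - curve2$dense_times)) > 1e-9)
    stop("curves must share the identical dense grid")
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0) stop("zero-variance curve: correlation undefined")
  n <- length(x)
  sum(((x - mean(x)) / sx) * ((y - mean(y)) / sy)) / (n - 1)
}

#' Bland-Altman agreement of paired measurements
#'
#' Differences are taken as sequence 2 minus sequence 1.  Reports their
#' mean, sample standard deviation and the 1.96-SD limits of agreement.
#'
#' @param a reference (sequence 1) values.
#' @param b comparison (sequence 2) values, same length >= 2.
#' @return list with `mean_diff`, `sd_diff`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- b - a
  m <- mean(d)
  s <- sd(d)
  list(mean_diff = m, sd_diff = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s)
}

#' Paired two-tailed t-test
#'
#' Standard paired Student t-test on `b - a` with `n - 1` degrees of
#' freedom; p-values below 0.05 are flagged significant.  Degenerate
#' zero-variance differences are handled explicitly: identical pairs give
#' `t = 0, p = 1`; constant nonzero differences give `p = 0` (limit),
#' both flagged.
#'
#' @param a,b paired values, length >= 2.
#' @return list with `t`, `p`, `df` and `significant` (p < 0.05);
#'   attribute `degenerate` marks the zero-variance cases.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs")
  d <- b - a
  if (sd(d) == 0) {
    out <- if (mean(d) == 0) list(t = 0, p = 1, df = n - 1L)
           else list(t = sign(mean(d)) * Inf, p = 0, df = n - 1L)
    out$significant <- out$p < 0.05
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  tt <- t.test(b, a, paired = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), significant = tt$p.value < 0.05)
}

#' Comparison table across acquisitions
#'
#' For every non-reference sequence, region and direction: the peak factor
#' (range ratio vs. the reference), nRMSD, curve correlation and the
#' diastolic timing difference `t_dias(seq) - t_dias(ref)`.  When a cohort
#' is supplied (`subjects`: a list of per-subject curve sets), per-subject
#' velocity ranges and diastolic times feed cohort-level Bland-Altman and
#' paired t-statistics per sequence/region/direction.
#'
#' @param curve_sets named list (one element per sequence) of curve sets as
#'   returned by [extract_curves()]; used when `subjects` is `NULL`.
#' @param ref name of the reference sequence.
#' @param subjects optional list of `curve_sets`-shaped lists, one per
#'   subject or replicate.
#' @param normalizer passed to [nrmsd()].
#' @return data.frame of class `tpm_comparison`: columns `sequence`,
#'   `region`, `direction`, `pf`, `nrmsd_pct`, `c`, `dt_dias_ms` and, for
#'   cohorts, `dv_mean_diff`, `dv_sd_diff`, `dv_loa_low`, `dv_loa_high`,
#'   `dv_t`, `dv_p`.  Missing counterpart curves yield NA rows.
#' @export
compare_acquisitions <- function(curve_sets, ref, subjects = NULL,
                                 normalizer = "reference") {
  if (!is.null(subjects)) {
    tabs <- lapply(subjects, compare_acquisitions, ref = ref,
                   normalizer = normalizer)
    base <- tabs[[1L]][c("sequence", "region", "direction")]
    agg <- base
    num <- c("pf", "nrmsd_pct", "c", "dt_dias_ms")
    for (cn in num)
      agg[[cn]] <- rowMeans(sapply(tabs, `[[`, cn))
    # cohort agreement on the velocity range (sequence-2 minus reference)
    for (cn in c("dv_mean_diff", "dv_sd_diff", "dv_loa_low", "dv_loa_high",
                 "dv_t", "dv_p"))
      agg[[cn]] <- NA_real_
    for (i in seq_len(nrow(base))) {
      key <- paste(base$region[i], base$direction[i], sep = ".")
      dv_ref <- vapply(subjects, function(s) peak_metrics(s[[ref]][[key]])$delta_v,
                       numeric(1))
      dv_acc <- vapply(subjects,
                       function(s) peak_metrics(s[[base$sequence[i]]][[key]])$delta_v,
                       numeric(1))
      ba <- bland_altman(dv_ref, dv_acc)
      tt <- paired_ttest(dv_ref, dv_acc)
      agg$dv_mean_diff[i] <- ba$mean_diff
      agg$dv_sd_diff[i] <- ba$sd_diff
      agg$dv_loa_low[i] <- ba$loa_low
      agg$dv_loa_high[i] <- ba$loa_high
      agg$dv_t[i] <- tt$t
      agg$dv_p[i] <- tt$p
    }
    class(agg) <- c("tpm_comparison", "data.frame")
    return(agg)
  }
  if (!ref %in% names(curve_sets)) stop("reference sequence not found")
  ref_set <- curve_sets[[ref]]
  others <- setdiff(names(curve_sets), ref)
  rows <- list()
  for (sq in others) {
    for (key in names(ref_set)) {
      cv_ref <- ref_set[[key]]
      cv <- curve_sets[[sq]][[key]]
      if (is.null(cv)) {
        warning(sprintf("sequence '%s' lacks curve '%s'", sq, key))
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = sq, region = cv_ref$region, direction = cv_ref$direction,
          pf = NA_real_, nrmsd_pct = NA_real_, c = NA_real_,
          dt_dias_ms = NA_real_)
        next
      }
      pk_ref <- peak_metrics(cv_ref)
      pk <- peak_metrics(cv)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = sq, region = cv_ref$region, direction = cv_ref$direction,
        pf = peak_factor(pk_ref$delta_v, pk$delta_v),
        nrmsd_pct = nrmsd(cv_ref, cv, normalizer),
        c = curve_correlation(cv_ref, cv),
        dt_dias_ms = pk$t_dias - pk_ref$t_dias)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("tpm_comparison", "data.frame")
  out
}

#' @export
print.tpm_comparison <- function(x, digits = 3, ...) {
  cat("Acquisition comparison (vs. reference):\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
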