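# Intrinsic-SNR estimation chain and parallel-imaging g-factor evaluation.

#' Per-echo SNR maps from a reconstruction
#'
#' snr_e = |image_e| / noise_map, using the analytic SENSE noise map carried
#' by the reconstruction result.
#'
#' @param recon A `recon_result` with a positive `noise_map`.
#' @return An `snr_series`: `snr` (4D array, echo last), `te_list`.
#' @export
snr_per_echo <- function(recon) {
  nm <- recon$noise_map
  if (all(!is.finite(nm)) || all(nm == 0, na.rm = TRUE))
    stop("reconstruction carries no usable noise map")
  d <- dim(recon$images)
  snr <- array(NA_real_, dim = d)
  for (e in seq_len(d[4]))
    snr[, , , e] <- Mod(recon$images[, , , e]) / nm
  structure(list(snr = snr, te_list = recon$te_list), class = "snr_series")
}

#' Extrapolated SNR at TE = 0
#'
#' Mono-exponential fit of the per-echo SNR values against TE (reusing the
#' R2* fitter); the fitted amplitude is SNR_TE0.
#'
#' @param series An `snr_series` (or 4D SNR array with `te_list`).
#' @param te_list Echo times if `series` is a bare array.
#' @return 3D SNR_TE0 volume.
#' @export
snr_te0 <- function(series, te_list = NULL) {
  if (inherits(series, "snr_series")) {
    snr <- series$snr; te_list <- series$te_list
  } else snr <- to_stack(series)
  fit <- fit_r2star(snr, te_list)
  fit$amplitude
}

#' Intrinsic SNR map
#'
#' iSNR = SNR_TE0 / S_ss(alpha_actual, TR, T1, TE = 0) / voxel_volume /
#' sqrt(acq_time_per_echo): dividing by the steady-state spoiled-GRE signal
#' removes the flip-angle, T1 and TR dependence; the remaining normalization
#' yields SNR of the equilibrium magnetization per unit volume (microliter)
#' and unit acquisition time (1/sqrt(s)).
#'
#' @param snr_te0 3D SNR_TE0 volume.
#' @param flip A `flip_angle_map` (actual flip angles, degrees) or a numeric
#'   volume/scalar of flip angles.
#' @param tr Repetition time, s.
#' @param t1 T1 volume (s) or scalar.
#' @param voxel_volume Nominal voxel volume, microliters.
#' @param acq_time_per_echo Total acquisition time per echo, s (from
#'   [protocol_timing()]).
#' @return An `isnr_map`: `isnr` volume (1/(ul sqrt(s))), `voxel_volume`,
#'   `acq_time_per_echo`.
#' @export
isnr_map <- function(snr_te0, flip, tr, t1, voxel_volume, acq_time_per_echo) {
  alpha <- if (inherits(flip, "flip_angle_map")) flip$alpha else flip
  s <- spoiled_gre_signal(alpha, tr, pmax(t1, 1e-9), te = 0)
  if (all(s == 0, na.rm = TRUE)) stop("steady-state signal is zero (alpha = 0?)")
  isnr <- snr_te0 / s / voxel_volume / sqrt(acq_time_per_echo)
  isnr[!is.finite(isnr)] <- NA_real_
  structure(list(isnr = isnr, voxel_volume = voxel_volume,
                 acq_time_per_echo = acq_time_per_echo),
            class = "isnr_map")
}

#' Location-wise iSNR gain between two paired samples
#'
#' The gain is the mean over locations of the per-location ratio a_i / b_i
#' (not the ratio of the means).
#'
#' @param a,b Paired numeric vectors (same layer/locations, e.g. two field
#'   strengths), equal length.
#' @return Mean location-wise ratio.
#' @export
isnr_gain <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("paired samples must have equal length")
  if (any(b == 0)) stop("zero values in the denominator sample")
  mean(a / b)
}

#' SENSE g-factor map for a sampling pattern and coil array
#'
#' g = [noise_map(pattern) / noise_map(full sampling)] / sqrt(R), the
#' noise-amplification penalty of the parallel-imaging scheme; 1/g is the
#' retained SNR.  Statistics of 1/g are computed within the support mask.
#'
#' @param sensitivities Complex 4D sensitivity array (channel last).
#' @param noise_cov Hermitian channel noise covariance.
#' @param pattern A `sampling_pattern` (lattice).
#' @param mask Optional logical support volume; defaults to voxels where the
#'   root-sum-of-squares sensitivity exceeds 5 percent of its maximum.
#' @return A `gfactor_result`: `g`, `inv_g`, `pattern`, `median_inv_g`,
#'   `quartiles`, `mask`.
#' @export
gfactor_map <- function(sensitivities, noise_cov, pattern, mask = NULL) {
  shape <- utils::head(dim(sensitivities), 3)
  nm_acc <- sense_core(sensitivities, noise_cov, pattern$mask,
                       zf = NULL, noise_scale = 1)$noise_map
  full <- matrix(TRUE, shape[2], shape[3])
  nm_full <- sense_core(sensitivities, noise_cov, full,
                        zf = NULL, noise_scale = 1)$noise_map
  R <- pattern$total_r
  g <- (nm_acc / nm_full) / sqrt(R)
  if (is.null(mask)) {
    rss <- sqrt(apply(abs(sensitivities)^2, 1:3, sum))
    mask <- rss > 0.05 * max(rss)
  }
  mask <- mask & is.finite(g)
  inv_g <- 1 / g
  st <- stats::quantile(inv_g[mask], c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(g = g, inv_g = inv_g, pattern = pattern,
                 median_inv_g = st[2], quartiles = st[c(1, 3)], mask = mask),
            class = "gfactor_result")
}

#' @export
print.gfactor_result <- function(x, ...) {
  cat("<gfactor_result> R = ", x$pattern$rp, "x", x$pattern$rs, " shift ",
      x$pattern$caipi_shift, ": median 1/g = ",
      format(x$median_inv_g, digits = 4), " [",
      format(x$quartiles[1], digits = 4), ", ",
      format(x$quartiles[2], digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Order statistics of the inverse g-factor
#'
#' @param result A `gfactor_result`.
#' @param mask Logical volume (defaults to the result's support mask).
#' @return List with `median` and `quartiles` (25th, 75th percentile).
#' @export
inv_g_stats <- function(result, mask = NULL) {
  if (is.null(mask)) mask <- result$mask
  if (!any(mask)) stop("empty mask")
  v <- result$inv_g[mask & is.finite(result$inv_g)]
  st <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  list(median = st[2], quartiles = st[c(1, 3)])
}
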