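# Fisher-information / Cramer-Rao machinery for R2*, frequency and
# susceptibility precision under the idealized continuous-acquisition model
# (instantaneous excitation, data acquired during the entire TR).

#' Idealized mono-exponential signal-model specification
#'
#' Complex signal y_j = A exp(-R2* t_j) exp(i 2 pi f t_j) sampled at
#' t_j = (j - 1/2) TR / J, j = 1..J (strictly inside (0, TR)), modeling
#' instantaneous excitation with data acquired during the entire TR.  The
#' per-sample noise standard deviation is sigma_J = sqrt(J / TR) / snr_te0:
#' results are then independent of the discretization J (continuum limit)
#' while the Fisher information collected in one excitation grows with the
#' readout duration TR, as for acquisition at a fixed noise power spectral
#' density.  snr_te0 is the SNR of a unit TE = 0 signal per unit (1 s)
#' integration time.
#'
#' @param snr_te0 Reference SNR at TE = 0 per unit integration time.
#' @param r2star 1/s. @param frequency Hz. @param tr s.
#' @param n_samples Discretization J (>= 64 approximates the continuum).
#' @param amplitude Signal at TE = 0 (1 by convention).
#' @return A `signal_model_spec` with `times` and `sigma` filled in.
#' @export
signal_model_spec <- function(snr_te0, r2star, tr, frequency = 0,
                              n_samples = 256, amplitude = 1) {
  if (snr_te0 <= 0) stop("snr_te0 must be > 0")
  if (tr <= 0) stop("tr must be > 0")
  j <- seq_len(n_samples)
  structure(list(snr_te0 = snr_te0, amplitude = amplitude, r2star = r2star,
                 frequency = frequency, tr = tr, n_samples = n_samples,
                 times = (j - 0.5) * tr / n_samples,
                 sigma = sqrt(n_samples / tr) / snr_te0),
            class = "signal_model_spec")
}

model_signal <- function(spec) {
  spec$amplitude * exp(-spec$r2star * spec$times) *
    exp(2i * pi * spec$frequency * spec$times)
}

#' Fisher information matrix of the complex mono-exponential model
#'
#' F_mn = (1/sigma^2) Re sum_j conj(dy_j/dtheta_m) dy_j/dtheta_n for complex
#' Gaussian noise with per-quadrature standard deviation sigma, using
#' analytic partial derivatives.  Parameters may be any subset of
#' `A` (amplitude), `R2star`, `f` (Hz) and `phi0` (global phase, rad).
#'
#' @param spec A `signal_model_spec`.
#' @param params Character vector of parameter names.
#' @return Symmetric positive-definite matrix with dimnames `params`.
#' @export
fisher_matrix <- function(spec, params = c("A", "R2star")) {
  if (spec$amplitude == 0) stop("degenerate model: amplitude is 0")
  y <- model_signal(spec)
  t <- spec$times
  derivs <- list(A = y / spec$amplitude, R2star = -t * y,
                 f = 2i * pi * t * y, phi0 = 1i * y)
  bad <- setdiff(params, names(derivs))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  D <- vapply(params, function(p) derivs[[p]], complex(length(t)))
  D <- matrix(D, length(t), length(params))
  F <- Re(Conj(t(D)) %*% D) / spec$sigma^2
  dimnames(F) <- list(params, params)
  (F + t(F)) / 2
}

#' Cramer-Rao bound from a Fisher matrix
#'
#' The standard-deviation bound sqrt([F^-1]_kk) for the k-th parameter.
#'
#' @param fisher Fisher information matrix.
#' @param index Parameter index (integer or name).
#' @export
crb <- function(fisher, index) {
  Finv <- tryCatch(solve(fisher),
                   error = function(e) stop("singular Fisher matrix"))
  sqrt(Finv[index, index])
}

# common normalization: rescale a single-TR bound to the stated total
# acquisition time (averaging over total_time/TR repetitions) and to unit
# voxel volume (the stated SNR_TE0 is per voxel_volume microliters)
crb_normalize <- function(value, tr, total_time, voxel_volume) {
  value * sqrt(tr / total_time) * voxel_volume
}

#' Idealized Cramer-Rao bound of R2*
#'
#' Builds the idealized continuous-acquisition model over (0, TR] with
#' parameters (A, R2*) by default, computes the standard-deviation bound of
#' R2*, and rescales it to the stated total acquisition time and unit voxel
#' volume.
#'
#' @param snr_te0 SNR at TE = 0 for a single-TR acquisition at the stated
#'   voxel volume. @param r2star 1/s. @param tr s.
#' @param total_time Total acquisition time, s (default 1).
#' @param voxel_volume Microliters (default 1).
#' @param params Parameter set (co-estimate `f` via c("A","R2star","f")).
#' @param n_samples Discretization (default 256).
#' @return Bound in 1/s.
#' @export
crb_r2star_idealized <- function(snr_te0, r2star, tr, total_time = 1,
                                 voxel_volume = 1,
                                 params = c("A", "R2star"), n_samples = 256) {
  spec <- signal_model_spec(snr_te0, r2star, tr, n_samples = n_samples)
  crb_normalize(crb(fisher_matrix(spec, params), "R2star"),
                tr, total_time, voxel_volume)
}

#' Idealized Cramer-Rao bound of the local frequency
#'
#' Variance bound of the magnitude-squared-weighted least-squares slope of
#' phase against TE (with intercept), divided by 2 pi, under the same
#' idealized sampling and normalization as [crb_r2star_idealized()].  The
#' per-sample phase variance is 1/SNR_j^2 with
#' SNR_j = snr_te0 exp(-R2* t_j) / sqrt(J).
#'
#' @inheritParams crb_r2star_idealized
#' @return Bound in Hz.
#' @export
crb_frequency_idealized <- function(snr_te0, r2star, tr, total_time = 1,
                                    voxel_volume = 1, n_samples = 256) {
  spec <- signal_model_spec(snr_te0, r2star, tr, n_samples = n_samples)
  t <- spec$times
  w <- (spec$amplitude * exp(-spec$r2star * t) / spec$sigma)^2  # = SNR_j^2
  tbar <- sum(w * t) / sum(w)
  var_slope <- 1 / sum(w * (t - tbar)^2)
  crb_normalize(sqrt(var_slope) / (2 * pi), tr, total_time, voxel_volume)
}

#' Cramer-Rao bound of magnetic susceptibility
#'
#' CRB_chi = 3 CRB_f / f0: the coefficient 3 reflects the effect of a
#' background susceptibility on the frequency distribution inside a sphere.
#'
#' @param crb_f Frequency bound, Hz. @param f0 Nominal Larmor frequency, Hz.
#' @return Dimensionless susceptibility bound (multiply by 1e9 for ppb).
#' @export
crb_chi <- function(crb_f, f0) {
  if (f0 <= 0) stop("f0 must be > 0")
  3 * crb_f / f0
}

#' ΔR2*-normalized R2* precision
#'
#' @param crb_r2star Bound, 1/s. @param delta_r2star GM-WM R2* difference,
#'   1/s (> 0).
#' @return Dimensionless ratio.
#' @export
normalized_crb_r2star <- function(crb_r2star, delta_r2star) {
  if (any(delta_r2star <= 0)) stop("delta_r2star must be > 0")
  crb_r2star / delta_r2star
}

#' Subject-averaged GM-WM R2* difference
#'
#' Mean over paired locations (and subjects) of WM minus GM.
#'
#' @param gm,wm Paired numeric vectors of layer R2* values (1/s).
#' @return Mean difference, 1/s.
#' @export
delta_r2star <- function(gm, wm) {
  gm <- as.numeric(gm); wm <- as.numeric(wm)
  if (length(gm) != length(wm)) stop("gm and wm must be paired (equal length)")
  mean(wm - gm)
}

#' Matched-TR scan-time comparison across field strengths
#'
#' Finds the TR at field A whose R2* precision per unit total scan time (the
#' unit-volume, unit-total-time normalized bound, optionally divided by a
#' supplied ΔR2*) equals field B's value at `tr_b` (bisection to 1e-3
#' relative tolerance) and reports the scan-time reduction 1 - tr_a / tr_b:
#' with matrix and acceleration held fixed, total scan time is proportional
#' to TR.
#'
#' @param field_a List with `snr_te0`, `r2star` and optionally
#'   `delta_r2star`.
#' @param field_b Same plus `tr` (s).
#' @param tr_range Search interval for tr_a, s (must bracket the match).
#' @return List with `tr_a` (s) and `reduction` (fraction of tr_b saved).
#' @export
matched_tr <- function(field_a, field_b, tr_range = c(0.005, 0.2)) {
  metric <- function(fld, tr)
    crb_r2star_idealized(fld$snr_te0, fld$r2star, tr, total_time = 1) /
      (if (is.null(fld$delta_r2star)) 1 else fld$delta_r2star)
  target <- metric(field_b, field_b$tr)
  h <- function(tr) metric(field_a, tr) - target
  lo <- tr_range[1]; hi <- tr_range[2]
  if (h(lo) * h(hi) > 0) stop("no crossing in tr_range")
  root <- stats::uniroot(h, lower = lo, upper = hi, tol = 1e-3 * field_b$tr)
  list(tr_a = root$root, reduction = 1 - root$root / field_b$tr)
}

#' T2*-weighted CNR efficiency
#'
#' CNR per unit scan time is proportional to iSNR sqrt(T1) ΔR2* / R2*bar
#' (with TR << T1, TR scaled to tissue T2* and Ernst-angle excitation);
#' ratios of this quantity across field strengths are the meaningful output.
#'
#' @param isnr Intrinsic SNR. @param t1 s. @param r2star_gm,r2star_wm 1/s.
#' @export
cnr_efficiency <- function(isnr, t1, r2star_gm, r2star_wm) {
  stopifnot(isnr > 0, t1 > 0, r2star_gm > 0, r2star_wm > 0)
  isnr * sqrt(t1) * abs(r2star_wm - r2star_gm) / mean(c(r2star_gm, r2star_wm))
}

#' Monte-Carlo check of Cramer-Rao bound attainability
#'
#' Simulates noisy realizations of the idealized complex signal, fits the
#' parameters by maximum likelihood (Gauss-Newton nonlinear least squares on
#' the stacked real/imaginary data), and compares the empirical standard
#' deviations with the bounds.
#'
#' @param spec A `signal_model_spec`.
#' @param n_reps Number of replicates (>= 100).
#' @param seed Integer seed.
#' @param params Parameters to estimate (default c("A", "R2star", "f")).
#' @return List with `empirical_std`, `crb`, `ratio` (named by parameter)
#'   and `n_fail`; more than 1 percent failed fits is flagged with a warning.
#' @export
monte_carlo_crb_check <- function(spec, n_reps = 2000, seed = 1,
                                  params = c("A", "R2star", "f")) {
  if (n_reps < 100) stop("n_reps must be >= 100")
  y0 <- model_signal(spec)
  t <- spec$times
  J <- spec$n_samples
  F <- fisher_matrix(spec, params)
  bounds <- vapply(params, function(p) crb(F, p), numeric(1))
  est <- matrix(NA_real_, n_reps, length(params),
                dimnames = list(NULL, params))
  with_seed(seed, {
    noise <- matrix(complex(real = stats::rnorm(n_reps * J, sd = spec$sigma),
                            imaginary = stats::rnorm(n_reps * J, sd = spec$sigma)),
                    n_reps, J)
    for (rep_i in seq_len(n_reps)) {
      z <- y0 + noise[rep_i, ]
      # data-driven initialization
      mag <- pmax(Mod(z), 1e-9)
      sl <- stats::lm.fit(cbind(1, t), log(mag))$coefficients
      # frequency init: magnitude-weighted mean of successive phase steps
      dphi <- Arg(z[-1] * Conj(z[-J]))
      f0_init <- stats::weighted.mean(dphi / diff(t),
                                      Mod(z[-1] * z[-J])) / (2 * pi)
      th <- c(A = unname(exp(sl[1])), R2star = unname(max(-sl[2], 0)),
              f = f0_init)
      th <- th[params]
      fit <- tryCatch(gn_complex_fit(z, t, th, params),
                      error = function(e) NULL)
      if (!is.null(fit)) est[rep_i, ] <- fit
    }
  })
  ok <- stats::complete.cases(est)
  n_fail <- sum(!ok)
  if (n_fail > 0.01 * n_reps)
    warning(n_fail, " of ", n_reps, " fits failed")
  emp <- apply(est[ok, , drop = FALSE], 2, stats::sd)
  list(empirical_std = emp, crb = bounds, ratio = emp / bounds,
       n_fail = n_fail)
}

# Gauss-Newton ML fit of the complex mono-exponential model for a subset of
# (A, R2star, f); parameters not estimated are fixed at their start values.
gn_complex_fit <- function(z, t, theta, params, max_iter = 50) {
  get <- function(nm, def) if (nm %in% names(theta)) theta[[nm]] else def
  full <- c(A = get("A", 1), R2star = get("R2star", 0), f = get("f", 0))
  model <- function(p) p["A"] * exp(-p["R2star"] * t) * exp(2i * pi * p["f"] * t)
  cost <- function(p) sum(Mod(z - model(p))^2)
  cur <- cost(full)
  for (it in seq_len(max_iter)) {
    y <- model(full)
    d <- list(A = y / full["A"], R2star = -t * y, f = 2i * pi * t * y)
    Dc <- vapply(params, function(p) d[[p]], complex(length(t)))
    Dr <- rbind(Re(Dc), Im(Dc))
    r <- c(Re(z - y), Im(z - y))
    delta <- tryCatch(qr.solve(Dr, r), error = function(e) NULL)
    if (is.null(delta)) break
    step <- 1
    for (h in 1:8) {
      cand <- full
      cand[params] <- cand[params] + step * delta
      cand["A"] <- max(cand["A"], 1e-9)
      cand["R2star"] <- min(max(cand["R2star"], 0), 2000)
      cc <- cost(cand)
      if (cc <= cur) { full <- cand; cur <- cc; break }
      step <- step / 2
    }
    if (max(abs(step * delta)) < 1e-9 * (1 + max(abs(full)))) break
  }
  full[params]
}
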