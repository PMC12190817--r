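#' Voxelwise mono-exponential R2* fit
#'
#' Fits m_e = A exp(-R2* TE_e) to per-echo magnitudes by nonlinear least
#' squares (vectorized Gauss-Newton with step halving), initialized from the
#' log-linear fit and bounded to R2* in [0, 2000] 1/s.  Voxels with fewer
#' than two finite echo values, or that fail to converge, are flagged.
#'
#' @param magnitudes Per-echo magnitude volumes (4D array, echo last, or
#'   list of 3D arrays).
#' @param te_list Echo times, s (>= 2).
#' @param mask Optional logical volume restricting the fit.
#' @param max_iter Gauss-Newton iteration cap.
#' @return A `quant_maps` list: `r2star` (1/s), `amplitude` (signal at TE 0),
#'   `fit_residual` (RMS), `converged` (logical volume), `te_list`.
#' @export
fit_r2star <- function(magnitudes, te_list, mask = NULL, max_iter = 50) {
  m <- to_stack(magnitudes)
  ne <- dim(m)[4]
  if (ne < 2 || length(te_list) != ne)
    stop("need >= 2 echoes with matching te_list")
  shape <- dim(m)[1:3]
  nvox <- prod(shape)
  M <- matrix(m, nvox, ne)
  sel <- rowSums(is.finite(M)) >= 2 & rowSums(M, na.rm = TRUE) > 0
  if (!is.null(mask)) sel <- sel & as.vector(mask)
  te <- as.numeric(te_list)

  r2 <- rep(NA_real_, nvox); A <- rep(NA_real_, nvox)
  resid <- rep(NA_real_, nvox); conv <- rep(FALSE, nvox)
  if (any(sel)) {
    Ms <- M[sel, , drop = FALSE]
    Ms[!is.finite(Ms)] <- 0
    # log-linear initialization
    L <- log(pmax(Ms, 1e-12))
    tbar <- mean(te); st2 <- sum((te - tbar)^2)
    slope <- (L %*% (te - tbar)) / st2
    r <- pmin(pmax(-as.numeric(slope), 0), 2000)
    a <- exp(rowMeans(L) + r * tbar)
    fitted <- function(a, r) a * exp(-outer(r, te))
    cost <- rowSums((Ms - fitted(a, r))^2)
    for (it in seq_len(max_iter)) {
      E <- exp(-outer(r, te))           # nsel x ne
      F <- a * E
      R <- Ms - F
      # J columns: dA = E, dR = -a t E ; 2x2 normal equations, closed form
      g1 <- rowSums(E * R)
      g2 <- rowSums(-(F * rep(te, each = nrow(E))) * R)
      a11 <- rowSums(E * E)
      a12 <- rowSums(-E * F * rep(te, each = nrow(E)))
      a22 <- rowSums((F * rep(te, each = nrow(E)))^2)
      det <- a11 * a22 - a12^2
      det[det <= 0] <- NA
      da <- (a22 * g1 - a12 * g2) / det
      dr <- (a11 * g2 - a12 * g1) / det
      da[!is.finite(da)] <- 0; dr[!is.finite(dr)] <- 0
      step <- rep(1, length(a))
      for (h in 1:6) {
        a_new <- pmax(a + step * da, 0)
        r_new <- pmin(pmax(r + step * dr, 0), 2000)
        cost_new <- rowSums((Ms - fitted(a_new, r_new))^2)
        worse <- cost_new > cost + 1e-15
        if (!any(worse)) break
        step[worse] <- step[worse] / 2
      }
      worse <- cost_new > cost + 1e-15
      a_new[worse] <- a[worse]; r_new[worse] <- r[worse]
      cost_new[worse] <- cost[worse]
      moved <- abs(a_new - a) + abs(r_new - r)
      a <- a_new; r <- r_new; cost <- cost_new
      if (max(moved) < 1e-10 * (1 + max(abs(a)))) break
    }
    r2[sel] <- r; A[sel] <- a
    resid[sel] <- sqrt(cost / ne)
    conv[sel] <- TRUE
    conv[sel][!is.finite(cost)] <- FALSE
  }
  structure(list(r2star = array(r2, shape), amplitude = array(A, shape),
                 fit_residual = array(resid, shape),
                 converged = array(conv, shape), te_list = te),
            class = "quant_maps")
}

#' @export
print.quant_maps <- function(x, ...) {
  ok <- x$converged & is.finite(x$r2star)
  cat("<quant_maps> ", paste(dim(x$r2star), collapse = "x"), " grid, ",
      length(x$te_list), " echoes; R2* median ",
      format(stats::median(x$r2star[ok]), digits = 4), " 1/s over ",
      sum(ok), " fitted voxels\n", sep = "")
  invisible(x)
}

#' Local frequency from multi-echo phase
#'
#' Weighted least-squares regression of the (temporally unwrapped) signal
#' phase against TE, per voxel, with weights equal to the squared echo
#' magnitudes; the slope divided by 2 pi is the local frequency.  An
#' intercept absorbs the echo-independent initial phase.
#'
#' @param phases Per-echo phase volumes (rad; 4D array or list).
#' @param magnitudes Matching per-echo magnitude volumes.
#' @param te_list Echo times, s.
#' @return 3D frequency volume in Hz.
#' @export
fit_frequency <- function(phases, magnitudes, te_list) {
  ph <- to_stack(phases); mg <- to_stack(magnitudes)
  ne <- dim(ph)[4]
  if (ne < 2) stop("need >= 2 echoes")
  shape <- dim(ph)[1:3]; nvox <- prod(shape)
  P <- matrix(ph, nvox, ne); Wt <- matrix(mg, nvox, ne)^2
  # temporal unwrapping: wrap successive differences into (-pi, pi]
  for (e in 2:ne) {
    d <- P[, e] - P[, e - 1]
    P[, e] <- P[, e - 1] + atan2(sin(d), cos(d))
  }
  te <- as.numeric(te_list)
  sw <- rowSums(Wt)
  if (any(sw == 0)) sw[sw == 0] <- NA
  swt <- Wt %*% te
  swt2 <- Wt %*% te^2
  swp <- rowSums(Wt * P)
  swtp <- rowSums(Wt * P * rep(te, each = nvox))
  slope <- (sw * swtp - swt * swp) / (sw * swt2 - swt^2)
  array(as.numeric(slope) / (2 * pi), shape)
}

#' Echo-averaged magnitude
#'
#' @param magnitudes Per-echo magnitude volumes (4D array or list).
#' @return Voxelwise arithmetic mean over echoes.
#' @export
echo_average <- function(magnitudes) {
  m <- to_stack(magnitudes)
  out <- apply(m, 1:3, mean)
  array(out, dim = dim(m)[1:3])
}

#' Actual flip angle imaging (AFI) flip-angle map
#'
#' Dual-TR AFI estimator: with r = s2/s1 and n = tr2/tr1,
#' alpha = acos((r n - 1)/(n - r)) in degrees.  Voxels whose arccos argument
#' falls outside [-1, 1] (or with s1 <= 0) are flagged invalid.
#'
#' @param s1,s2 Steady-state signal volumes at the two repetition times.
#' @param tr1,tr2 Repetition times, s, tr2 > tr1 > 0.
#' @return A `flip_angle_map`: `alpha` (degrees, NA where invalid), `valid`,
#'   `tr1`, `tr2`.
#' @export
afi_flip_angle <- function(s1, s2, tr1, tr2) {
  if (!(tr2 > tr1 && tr1 > 0)) stop("need tr2 > tr1 > 0")
  if (all(s1 <= 0)) stop("s1 must contain positive signal")
  n <- tr2 / tr1
  r <- ifelse(s1 > 0, s2 / s1, NA_real_)
  arg <- (r * n - 1) / (n - r)
  valid <- is.finite(arg) & arg >= -1 & arg <= 1
  alpha <- ifelse(valid, acos(pmin(pmax(arg, -1), 1)) * 180 / pi, NA_real_)
  dims <- dim(s1)
  structure(list(alpha = if (is.null(dims)) alpha else array(alpha, dims),
                 valid = if (is.null(dims)) valid else array(valid, dims),
                 tr1 = tr1, tr2 = tr2),
            class = "flip_angle_map")
}

#' Ideal AFI steady-state signal pair
#'
#' The interleaved dual-TR spoiled steady state used to simulate AFI data:
#' s1 = sin(a) (1 - E2 + (1 - E1) E2 cos(a)) / (1 - E1 E2 cos(a)^2) and s2
#' with E1 and E2 exchanged, Ei = exp(-tri/t1).
#'
#' @param alpha degrees. @param tr1,tr2 s. @param t1 s. @param m0 scale.
#' @return List with `s1` and `s2`.
#' @export
afi_signal <- function(alpha, tr1, tr2, t1, m0 = 1) {
  a <- alpha * pi / 180
  e1 <- exp(-tr1 / t1); e2 <- exp(-tr2 / t1)
  den <- 1 - e1 * e2 * cos(a)^2
  list(s1 = m0 * sin(a) * (1 - e2 + (1 - e1) * e2 * cos(a)) / den,
       s2 = m0 * sin(a) * (1 - e1 + (1 - e2) * e1 * cos(a)) / den)
}
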