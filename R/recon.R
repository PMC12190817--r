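# SENSE reconstruction, analytic noise maps, navigator-based motion and
# B0-change estimation, and the unified iterative motion/B0-corrected solver.

# Extract the image-domain aliasing kernel of a (ky, kz) sampling mask:
# zero-filled reconstruction satisfies x~(r) = sum_d h(d) x(r - d).  For a
# (possibly CAIPI-shifted) regular lattice the kernel has exactly R = 1/frac
# significant entries of modulus 1/R; anything else is rejected.  Computing h
# numerically from the same FFT code keeps every phase convention consistent.
alias_kernel <- function(mask) {
  ny <- nrow(mask); nz <- ncol(mask)
  frac <- mean(mask)
  R <- round(1 / frac)
  h <- stats::fft(mask + 0, inverse = TRUE) / (ny * nz)
  idx <- which(Mod(h) > 0.5 * max(Mod(h)))
  if (length(idx) != R || abs(frac * R - 1) > R / (ny * nz))
    stop("sampling pattern is not a (shifted) regular lattice")
  ai <- arrayInd(idx, c(ny, nz)) - 1L
  # the offsets must form a subgroup (closed under differences), otherwise
  # the pattern is not periodic on this matrix and cannot be unfolded
  key <- ai[, 1] * nz + ai[, 2]
  for (i in seq_len(R)) {
    dky <- (ai[, 1] - ai[i, 1]) %% ny
    dkz <- (ai[, 2] - ai[i, 2]) %% nz
    if (!all((dky * nz + dkz) %in% key))
      stop("sampling pattern is not periodic on this matrix size")
  }
  list(offsets = ai, weights = h[idx], R = R, frac = frac)
}

# Core SENSE machinery.  Solves per aliased voxel set
#   x = (S^H Psi^-1 S)^-1 S^H Psi^-1 a
# and computes the noise map sqrt(diag((S^H Psi^-1 S)^-1)) scaled to the data
# noise level (per-quadrature standard deviation).  `zf` is the zero-filled
# image stack (nx x ny x nz x nch x ne) or NULL for a noise-map-only pass.
sense_core <- function(sens, psi, mask, zf = NULL, noise_scale = 1) {
  shape <- utils::head(dim(sens), 3)
  nch <- dim(sens)[4]
  ny <- shape[2]; nz <- shape[3]; nx <- shape[1]
  kern <- alias_kernel(mask)
  R <- kern$R
  psi_inv <- solve(psi)
  ne <- if (is.null(zf)) 0L else dim(zf)[5]
  images <- if (ne > 0) array(0i, dim = c(shape, ne)) else NULL
  noise_map <- array(NA_real_, dim = shape)
  # per-quadrature variance of the aliased measurement
  meas_var <- noise_scale^2 * kern$frac / 2
  sens_mat <- matrix(sens, nx * ny * nz, nch)
  zf_mat <- if (ne > 0) matrix(zf, nx * ny * nz, nch * ne) else NULL
  n_sing <- 0L

  if (R == 1) {
    # fully sampled: vectorized matched-filter combination
    q <- Re(rowSums(Conj(sens_mat) * (sens_mat %*% t(psi_inv))))
    ok <- q > 1e-12 * max(q)
    noise_map[ok] <- sqrt(meas_var / q[ok])
    if (ne > 0) {
      w <- Conj(sens_mat) %*% psi_inv        # nvox x nch combination weights
      for (e in seq_len(ne)) {
        num <- rowSums(w * zf_mat[, (e - 1) * nch + seq_len(nch)])
        v <- ifelse(ok, num / q, 0i)
        images[, , , e] <- array(v, dim = shape)
      }
    }
    if (any(!ok)) warning(sum(!ok), " voxels with vanishing sensitivity masked")
    return(list(images = images, noise_map = noise_map, R = R,
                n_masked = sum(!ok)))
  }

  visited <- matrix(FALSE, ny, nz)
  thr <- 1e-8 * max(Mod(sens))^2
  for (z0 in seq_len(nz)) for (y0 in seq_len(ny)) {
    if (visited[y0, z0]) next
    py <- ((y0 - 1 - kern$offsets[, 1]) %% ny) + 1L
    pz <- ((z0 - 1 - kern$offsets[, 2]) %% nz) + 1L
    visited[cbind(py, pz)] <- TRUE
    cols <- (pz - 1L) * ny + (py - 1L)           # 0-based (y,z) plane offset
    for (x in seq_len(nx)) {
      rows <- x + nx * cols
      S <- t(sens_mat[rows, , drop = FALSE]) *
        matrix(kern$weights, nch, R, byrow = TRUE)
      M <- Conj(t(S)) %*% psi_inv %*% S
      Minv <- if (all(Re(diag(M)) > thr))
        tryCatch(solve(M), error = function(e) NULL) else NULL
      if (is.null(Minv) || any(!is.finite(Minv))) { n_sing <- n_sing + R; next }
      nm <- sqrt(pmax(Re(diag(Minv)), 0) * meas_var)
      noise_map[rows] <- nm
      if (ne > 0) {
        a <- matrix(zf_mat[x + nx * ((z0 - 1L) * ny + (y0 - 1L)), ], nch, ne)
        xhat <- Minv %*% (Conj(t(S)) %*% psi_inv %*% a)
        for (e in seq_len(ne)) images[rows + (e - 1) * nx * ny * nz] <- xhat[, e]
      }
    }
  }
  if (n_sing > 0)
    warning(n_sing, " voxels in singular aliasing sets masked")
  list(images = images, noise_map = noise_map, R = R, n_masked = n_sing)
}

new_recon_result <- function(images, noise_map, mode, iterations, residual,
                             te_list, voxel_size) {
  structure(list(images = images, noise_map = noise_map, mode = mode,
                 iterations = iterations, residual = residual,
                 te_list = te_list, voxel_size = voxel_size),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat("<recon_result> mode ", x$mode, ", ", dim(x$images)[4], " echoes on ",
      paste(utils::head(dim(x$images), 3), collapse = "x"), "; ", x$iterations,
      " iterations, residual ", format(x$residual, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Direct lattice SENSE reconstruction
#'
#' Unfolds each aliased voxel set of a (shifted) regular CAIPI lattice by the
#' generalized least-squares solve x = (S^H Psi^-1 S)^-1 S^H Psi^-1 a and
#' returns the analytic noise map sqrt(diag((S^H Psi^-1 S)^-1)) scaled to the
#' data noise level.  No motion model (mode `NoCo`).
#'
#' @param kspace A `kspace_data`.
#' @param sensitivities Complex 4D sensitivity array (channel last).
#' @param noise_cov Hermitian channel noise covariance Psi.
#' @param noise_scale Data noise level; defaults to the value recorded in
#'   `kspace` (1 if the data are noiseless, giving a relative noise map).
#' @return A `recon_result` with per-echo complex images and `noise_map`.
#' @export
sense_recon <- function(kspace, sensitivities, noise_cov,
                        noise_scale = NULL) {
  if (is.null(noise_scale))
    noise_scale <- if (kspace$noise_scale > 0) kspace$noise_scale else 1
  d <- dim(kspace$samples)
  zf <- array(0i, dim = d)
  for (e in seq_len(d[5])) for (c_i in seq_len(d[4]))
    zf[, , , c_i, e] <- ifft3(kspace$samples[, , , c_i, e])
  core <- sense_core(sensitivities, noise_cov, kspace$pattern$mask, zf,
                     noise_scale)
  new_recon_result(core$images, core$noise_map, "NoCo", 0L, 0,
                   kspace$protocol$te_list, kspace$voxel_size)
}

# ---------------------------------------------------------------------------
# Navigator-based estimation

block_downsample <- function(vol, f = 2L) {
  d <- dim(vol)
  nd <- pmax(d %/% f, 1L)
  out <- array(0, dim = nd)
  cnt <- 0
  for (dx in 0:(f - 1)) for (dy in 0:(f - 1)) for (dz in 0:(f - 1)) {
    ix <- pmin(seq_len(nd[1]) * f - dx, d[1])
    iy <- pmin(seq_len(nd[2]) * f - dy, d[2])
    iz <- pmin(seq_len(nd[3]) * f - dz, d[3])
    out <- out + vol[ix, iy, iz, drop = FALSE]
    cnt <- cnt + 1
  }
  array(out / cnt, dim = nd)
}

register_rigid_level <- function(ref, mov, voxel_size, theta, step,
                                 max_iter = 30) {
  n <- length(ref)
  transform <- function(th) rigid_gather(ref, voxel_size, th[4:6], th[1:3])
  res <- as.vector(mov) - as.vector(transform(theta))
  cost <- sum(res^2)
  diverged <- FALSE
  for (it in seq_len(max_iter)) {
    J <- matrix(0, n, 6)
    for (p in 1:6) {
      tp <- theta; tm <- theta
      tp[p] <- tp[p] + step[p]; tm[p] <- tm[p] - step[p]
      J[, p] <- as.vector(transform(tp) - transform(tm)) / (2 * step[p])
    }
    g <- crossprod(J, res)
    H <- crossprod(J) + 1e-9 * max(diag(crossprod(J))) * diag(6)
    delta <- tryCatch(as.numeric(solve(H, g)), error = function(e) rep(0, 6))
    if (all(abs(delta) < 1e-5)) break
    lam <- 1
    improved <- FALSE
    for (ls in 1:6) {
      cand <- theta + lam * delta
      res_c <- as.vector(mov) - as.vector(transform(cand))
      cost_c <- sum(res_c^2)
      if (cost_c < cost) {
        theta <- cand; res <- res_c; cost <- cost_c; improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!improved) { diverged <- it == 1; break }
  }
  list(theta = theta, cost = cost, diverged = diverged)
}

#' Estimate rigid-body motion from navigator magnitudes
#'
#' Registers each navigator magnitude volume to the reference volume with a
#' three-level multiresolution pyramid and damped Gauss-Newton least-squares
#' refinement.  The returned parameters follow the forward convention of
#' [forward_encode()]: volume k is (approximately) the reference transformed
#' by its state.
#'
#' @param navs A `navigator_series`.
#' @param reference_index Index of the reference interval (default 1).
#' @return Matrix (n_intervals x 6) of `tx ty tz` (mm) and `rx ry rz`
#'   (degrees), with attribute `diverged` (logical per interval).
#' @export
estimate_motion <- function(navs, reference_index = 1) {
  if (length(navs$volumes) < 2) stop("need at least 2 navigator volumes")
  # band-limited 2x upsampling of the complex volumes before taking the
  # magnitude: interpolation on the finer grid is markedly more accurate
  vols <- lapply(navs$volumes, function(v) Mod(fourier_upsample(v, 2L)))
  ref <- vols[[reference_index]]
  vs <- navs$voxel_size / 2
  # mild smoothing stabilizes the gradients
  sm <- function(v, s) gauss_smooth(v, s, vs)
  levels <- list(
    list(f = 4L, smooth = 2.0 * min(vs)),
    list(f = 2L, smooth = 1.0 * min(vs)),
    list(f = 1L, smooth = 0)
  )
  out <- matrix(0, length(vols), 6)
  colnames(out) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  diverged <- logical(length(vols))
  for (k in seq_along(vols)) {
    if (k == reference_index) next
    theta <- rep(0, 6)
    for (lv in levels) {
      if (any(dim(ref) %/% lv$f < 4)) next
      r <- if (lv$smooth > 0) sm(ref, lv$smooth) else ref
      m <- if (lv$smooth > 0) sm(vols[[k]], lv$smooth) else vols[[k]]
      if (lv$f > 1) { r <- block_downsample(r, lv$f); m <- block_downsample(m, lv$f) }
      vsl <- vs * lv$f
      step <- c(rep(0.2 * min(vsl), 3), rep(0.2, 3))
      fit <- register_rigid_level(r, m, vsl, theta, step)
      theta <- fit$theta
      if (fit$diverged) diverged[k] <- TRUE
    }
    out[k, ] <- theta
  }
  if (any(diverged))
    warning("registration did not improve for interval(s): ",
            paste(which(diverged), collapse = ", "))
  attr(out, "diverged") <- diverged
  attr(out, "reference_index") <- reference_index
  out
}

#' Estimate per-interval B0 changes from navigator phases
#'
#' Each navigator volume is counter-transformed by its estimated motion, the
#' phase difference to the reference volume is converted to a frequency map
#' (divided by 2 pi nav_te), and a magnitude-squared-weighted least-squares
#' fit of a constant plus three spatially linear terms is performed inside
#' the support mask.  The constant term is temporally unwrapped across
#' intervals against the +/- 1/(2 nav_te) single-TE ambiguity (branch nearest
#' the previous interval's estimate); a flag is raised whenever a branch
#' correction fires.
#'
#' @param navs A `navigator_series`.
#' @param motion Rigid parameters as returned by [estimate_motion()] (or
#'   NULL for a motion-free series).
#' @param reference_index Reference interval (default 1).
#' @return A `field_change_estimate`: `b0_offset` (Hz, per interval),
#'   `b0_gradient` (Hz/mm, n x 3), `wrapped` (logical per interval).
#' @export
estimate_b0_change <- function(navs, motion = NULL, reference_index = 1) {
  vols <- navs$volumes
  n <- length(vols)
  vs <- navs$voxel_size
  te <- navs$nav_te
  ref <- vols[[reference_index]]
  mag_ref <- Mod(ref)
  support <- mag_ref > 0.3 * max(mag_ref)
  if (!any(support)) stop("empty support mask")
  X <- cbind(1, coord_matrix(dim(ref), vs))[support, , drop = FALSE]
  offs <- numeric(n)
  grads <- matrix(0, n, 3)
  wrapped <- logical(n)
  period <- 1 / te
  prev <- 0
  for (k in seq_len(n)) {
    if (k == reference_index) { prev <- 0; next }
    v <- vols[[k]]
    if (!is.null(motion) && any(motion[k, ] != 0))
      v <- rigid_transform(v, vs, motion[k, 4:6], motion[k, 1:3], invert = TRUE)
    pdiff <- Arg(v * Conj(ref))[support]
    w <- (mag_ref[support])^2
    beta <- tryCatch(
      solve(crossprod(X, w * X), crossprod(X, w * pdiff)),
      error = function(e) stop("B0 fit failed: ", conditionMessage(e)))
    f <- as.numeric(beta) / (2 * pi * te)
    m <- round((prev - f[1]) / period)
    if (m != 0) wrapped[k] <- TRUE
    offs[k] <- f[1] + m * period
    grads[k, ] <- f[2:4]
    prev <- offs[k]
  }
  structure(list(b0_offset = offs, b0_gradient = grads, wrapped = wrapped,
                 reference_index = reference_index),
            class = "field_change_estimate")
}

#' @export
print.field_change_estimate <- function(x, ...) {
  cat("<field_change_estimate> ", length(x$b0_offset), " intervals; offsets ",
      paste(round(x$b0_offset, 2), collapse = ", "), " Hz",
      if (any(x$wrapped)) " (temporal unwrap applied)" else "", "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Unified iterative reconstruction

normalize_motion <- function(motion, n) {
  if (is.null(motion)) return(matrix(0, n, 6))
  if (inherits(motion, "motion_trajectory")) {
    return(do.call(rbind, lapply(motion$states, function(s)
      c(s$translation, s$rotation))))
  }
  as.matrix(motion)
}

normalize_field <- function(field, n) {
  if (is.null(field)) return(list(b0_offset = numeric(n),
                                  b0_gradient = matrix(0, n, 3)))
  if (inherits(field, "motion_trajectory")) {
    return(list(
      b0_offset = vapply(field$states, `[[`, numeric(1), "b0_offset"),
      b0_gradient = do.call(rbind, lapply(field$states, `[[`, "b0_gradient"))))
  }
  field
}

#' Joint motion- and B0-corrected SENSE reconstruction
#'
#' Conjugate-gradient solve of the normal equations for the unified linear
#' encoding operator E = sampling o FFT o sensitivities o B0 phase o rigid
#' transform, noise-whitened by Psi^(-1/2).  The `mode` argument selects
#' which corrections enter E: `"NoCo"` (none), `"MoCo"` (rigid motion only)
#' or `"MoCo+B0Co"` (motion plus spatially linear B0 change, applied per echo
#' as a phase at its TE).  Each echo is solved independently; the rigid
#' operator uses trilinear interpolation and its adjoint is the interpolation
#' transpose.
#'
#' @param kspace A `kspace_data` (carries the shot-to-interval map).
#' @param sensitivities Complex 4D sensitivity array.
#' @param noise_cov Hermitian channel covariance Psi.
#' @param motion Per-interval rigid parameters (n x 6 matrix from
#'   [estimate_motion()], a `motion_trajectory`, or NULL).
#' @param field A `field_change_estimate`, a `motion_trajectory`, or NULL.
#' @param mode One of `"MoCo+B0Co"`, `"MoCo"`, `"NoCo"`.
#' @param max_iter,tol CG iteration cap and relative-residual tolerance.
#' @return A `recon_result`; non-convergence is reported in `residual` /
#'   `converged`, never silently accepted.
#' @export
joint_moco_recon <- function(kspace, sensitivities, noise_cov, motion = NULL,
                             field = NULL, mode = c("MoCo+B0Co", "MoCo", "NoCo"),
                             max_iter = 50, tol = 1e-6) {
  mode <- match.arg(mode)
  d <- dim(kspace$samples)
  shape <- d[1:3]; nch <- d[4]; ne <- d[5]
  nvox <- prod(shape)
  W <- herm_sqrt(noise_cov, inverse = TRUE)
  ops <- moco_operators(kspace, sensitivities, noise_cov, motion, field, mode)
  forward <- ops$forward; adjoint <- ops$adjoint

  cdot <- function(a, b) Re(sum(Conj(a) * b))
  # Block-SENSE preconditioner: in the static case E^H E is block-diagonal
  # over the aliasing groups (up to a scalar), so this inverse makes CG exact
  # there and remains a strong approximation under motion.
  prec <- sense_preconditioner(ops$sens_w, kspace$pattern$mask)
  images <- array(0i, dim = c(shape, ne))
  iters <- integer(ne); resid <- numeric(ne)
  for (e in seq_len(ne)) {
    te <- kspace$protocol$te_list[e]
    # whiten data channels
    y <- matrix(kspace$samples[, , , , e], nvox, nch) %*% t(W)
    y <- matrix(array(y, dim = c(shape, nch)), shape[1],
                shape[2] * shape[3] * nch)
    b <- adjoint(y, te)
    bnorm <- sqrt(cdot(b, b))
    x <- array(0i, dim = shape)
    r <- b
    z <- prec(r)
    p <- z
    rz <- cdot(r, z)
    it <- 0
    while (it < max_iter && sqrt(cdot(r, r)) / bnorm > tol) {
      Ap <- adjoint(forward(p, te), te)
      alpha <- rz / cdot(p, Ap)
      x <- x + alpha * p
      r <- r - alpha * Ap
      z <- prec(r)
      rz_new <- cdot(r, z)
      p <- z + (rz_new / rz) * p
      rz <- rz_new
      it <- it + 1
    }
    images[, , , e] <- x
    iters[e] <- it
    resid[e] <- sqrt(cdot(r, r)) / bnorm
  }
  converged <- all(resid <= tol)
  if (!converged)
    warning("CG did not reach tol = ", tol, " within ", max_iter,
            " iterations (residual ", format(max(resid), digits = 3), ")")
  nm_scale <- if (kspace$noise_scale > 0) kspace$noise_scale else 1
  nm <- sense_core(sensitivities, noise_cov, kspace$pattern$mask,
                   zf = NULL, noise_scale = nm_scale)$noise_map
  out <- new_recon_result(images, nm, mode, max(iters), max(resid),
                          kspace$protocol$te_list, kspace$voxel_size)
  out$converged <- converged
  out
}

# Build the whitened unified encoding operator and its adjoint for a
# k-space container: E = sampling o FFT o (whitened sensitivities) o
# (per-interval B0 phase at TE) o (per-interval rigid transform).  The
# adjoint of the motion step is the interpolation transpose.
moco_operators <- function(kspace, sensitivities, noise_cov, motion = NULL,
                           field = NULL,
                           mode = c("MoCo+B0Co", "MoCo", "NoCo")) {
  mode <- match.arg(mode)
  d <- dim(kspace$samples)
  shape <- d[1:3]; nch <- d[4]
  vs <- kspace$voxel_size
  n_int <- kspace$n_intervals
  mot <- normalize_motion(motion, n_int)
  fld <- normalize_field(field, n_int)
  use_motion <- mode %in% c("MoCo", "MoCo+B0Co")
  use_b0 <- mode == "MoCo+B0Co"

  W <- herm_sqrt(noise_cov, inverse = TRUE)
  nvox <- prod(shape)
  sens_w <- matrix(sensitivities, nvox, nch) %*% t(W)
  # per-interval operators; intervals with identical (identity) operators are
  # merged so a static acquisition costs a single FFT pass per channel
  iv_lines <- lapply(seq_len(n_int), function(iv) which(kspace$shot_interval == iv))
  Ps <- vector("list", n_int)
  dfs <- vector("list", n_int)
  for (iv in seq_len(n_int)) {
    if (use_motion && any(mot[iv, ] != 0))
      Ps[[iv]] <- rigid_operator(shape, vs, mot[iv, 4:6], mot[iv, 1:3])
    if (use_b0 && (fld$b0_offset[iv] != 0 || any(fld$b0_gradient[iv, ] != 0)))
      dfs[[iv]] <- drift_field(motion_state(b0_offset = fld$b0_offset[iv],
                                            b0_gradient = fld$b0_gradient[iv, ]),
                               shape, vs)
  }
  static <- which(vapply(seq_len(n_int), function(iv)
    is.null(Ps[[iv]]) && is.null(dfs[[iv]]), logical(1)))
  if (length(static) > 1) {
    keep <- static[1]
    iv_lines[[keep]] <- unlist(iv_lines[static])
    for (iv in setdiff(static, keep)) iv_lines[[iv]] <- integer(0)
  }

  forward <- function(x, te) {
    y <- matrix(0i, shape[1], shape[2] * shape[3] * nch)
    for (iv in seq_len(n_int)) {
      lines <- iv_lines[[iv]]
      if (!length(lines)) next
      u <- if (!is.null(Ps[[iv]])) apply_operator(Ps[[iv]], x) else x
      if (!is.null(dfs[[iv]])) u <- u * exp(2i * pi * dfs[[iv]] * te)
      uv <- as.vector(u)
      for (c_i in seq_len(nch)) {
        k <- fft3(array(uv * sens_w[, c_i], dim = shape))
        km <- matrix(k, shape[1], shape[2] * shape[3])
        y[, lines + (c_i - 1) * shape[2] * shape[3]] <- km[, lines]
      }
    }
    y
  }
  adjoint <- function(y, te) {
    x <- array(0i, dim = shape)
    for (iv in seq_len(n_int)) {
      lines <- iv_lines[[iv]]
      if (!length(lines)) next
      w <- numeric(nvox) + 0i
      for (c_i in seq_len(nch)) {
        km <- matrix(0i, shape[1], shape[2] * shape[3])
        km[, lines] <- y[, lines + (c_i - 1) * shape[2] * shape[3]]
        img <- ifft3(array(km, dim = shape))
        w <- w + Conj(sens_w[, c_i]) * as.vector(img)
      }
      w <- array(w, dim = shape)
      if (!is.null(dfs[[iv]])) w <- w * exp(-2i * pi * dfs[[iv]] * te)
      if (!is.null(Ps[[iv]])) w <- apply_operator_adjoint(Ps[[iv]], w)
      x <- x + w
    }
    x
  }
  list(forward = forward, adjoint = adjoint, sens_w = sens_w,
       iv_lines = iv_lines)
}

# Build the block-SENSE preconditioner closure for PCG: per aliasing group
# and readout position, the (ridge-stabilized) inverse of S~^H S~ built from
# the whitened sensitivities.  Returns a function mapping a residual volume
# to the preconditioned volume.
sense_preconditioner <- function(sens_w, mask) {
  nch <- ncol(sens_w)
  ny <- nrow(mask); nz <- ncol(mask)
  nvox <- nrow(sens_w)
  nx <- nvox / (ny * nz)
  kern <- alias_kernel(mask)
  R <- kern$R
  if (R == 1) {
    q <- rowSums(Mod(sens_w)^2)
    q <- q + 1e-9 * max(q)
    return(function(r) array(as.vector(r) / q, dim = dim(r)))
  }
  visited <- matrix(FALSE, ny, nz)
  ngrp <- (ny * nz) %/% R
  rows_all <- matrix(0L, R, ngrp * nx)
  binv_all <- array(0i, dim = c(R, R, ngrp * nx))
  w <- kern$weights
  blk <- 0L
  diag_max <- max(rowSums(Mod(sens_w)^2)) / R^2
  ridge <- 1e-9 * diag_max * diag(R)
  for (z0 in seq_len(nz)) for (y0 in seq_len(ny)) {
    if (visited[y0, z0]) next
    py <- ((y0 - 1 - kern$offsets[, 1]) %% ny) + 1L
    pz <- ((z0 - 1 - kern$offsets[, 2]) %% nz) + 1L
    visited[cbind(py, pz)] <- TRUE
    cols <- (pz - 1L) * ny + (py - 1L)
    for (x in seq_len(nx)) {
      rows <- x + nx * cols
      S <- t(sens_w[rows, , drop = FALSE]) * matrix(w, nch, R, byrow = TRUE)
      B <- Conj(t(S)) %*% S + ridge
      blk <- blk + 1L
      rows_all[, blk] <- rows
      binv_all[, , blk] <- solve(B)
    }
  }
  nblk <- blk
  function(r) {
    rv <- as.vector(r)
    zv <- complex(length(rv))
    for (b in seq_len(nblk)) {
      rows <- rows_all[, b]
      zv[rows] <- binv_all[, , b] %*% rv[rows]
    }
    array(zv, dim = dim(r))
  }
}

# Sensitivity-weighted combination of fully sampled multi-channel data
# (utility for tests and reference images).
coil_combine <- function(channel_images, sensitivities, noise_cov = NULL) {
  imgs <- to_stack(channel_images)
  nch <- dim(imgs)[4]
  if (is.null(noise_cov)) noise_cov <- diag(nch)
  psi_inv <- solve(noise_cov)
  shape <- utils::head(dim(imgs), 3)
  num <- array(0i, dim = shape); den <- array(0, dim = shape)
  for (a_i in seq_len(nch)) for (b_i in seq_len(nch)) {
    num <- num + Conj(sensitivities[, , , a_i]) * psi_inv[a_i, b_i] * imgs[, , , b_i]
    den <- den + Re(Conj(sensitivities[, , , a_i]) * psi_inv[a_i, b_i] *
                      sensitivities[, , , b_i])
  }
  num / pmax(den, 1e-12 * max(den))
}
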