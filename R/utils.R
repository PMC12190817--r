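# Internal numerical utilities: FFT conventions, seeded RNG scoping,
# rigid-body transforms as sparse interpolation operators, smoothing.

GAMMA_HZ_PER_T <- 42.577e6  # proton gyromagnetic ratio / 2pi

#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

# Unitary n-dimensional FFT with DC at array index 1 (wrap-around order).
fft3 <- function(x) stats::fft(x) / sqrt(length(x))
ifft3 <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

# DFT sample frequencies (cycles per unit), wrap-around order.
fft_freq <- function(n, d = 1) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-ceiling((n - 1) / 2), -1L))
  k / (n * d)
}

# Voxel-centre coordinates (mm) relative to the volume centre, per axis.
# The centre sits at index N %/% 2 (0-based): grids derived from one another
# by Fourier resampling then share the same physical frame.
grid_coords <- function(shape, voxel_size) {
  lapply(1:3, function(i) (seq_len(shape[i]) - 1 - shape[i] %/% 2) * voxel_size[i])
}

# Dense 3-column matrix of voxel-centre coordinates (mm) for all voxels.
coord_matrix <- function(shape, voxel_size) {
  cs <- grid_coords(shape, voxel_size)
  cbind(rep(cs[[1]], times = shape[2] * shape[3]),
        rep(rep(cs[[2]], each = shape[1]), times = shape[3]),
        rep(cs[[3]], each = shape[1] * shape[2]))
}

# Extrinsic x -> y -> z rotation (degrees): R = Rz %*% Ry %*% Rx.
rotation_matrix <- function(deg) {
  a <- deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

# Sparse trilinear-interpolation operator for a rigid-body transform about the
# grid centre.  Forward convention: a point p (mm, centre-relative) of the
# object moves to R p + t, so the transformed volume is
#   out(r) = in(R^-1 (r - t)).
# invert = TRUE builds the operator of the inverse transform.  The adjoint of
# the returned operator is its transpose (interpolation transpose, not the
# inverse transform).
rigid_operator <- function(shape, voxel_size, rotation_deg, translation_mm,
                           invert = FALSE) {
  R <- rotation_matrix(rotation_deg)
  t <- as.numeric(translation_mm)
  if (invert) {
    # inverse map: p -> R^-1(p - t); sampling uses its inverse, i.e. R p + t
    A <- R
    b <- t
  } else {
    A <- t(R)              # R^-1 for a rotation
    b <- -t(R) %*% t
  }
  n <- prod(shape)
  out <- coord_matrix(shape, voxel_size)      # target coords (mm)
  src <- out %*% t(A) + matrix(b, n, 3, byrow = TRUE)
  # to continuous 0-based voxel indices
  ctr <- shape %/% 2
  gx <- src[, 1] / voxel_size[1] + ctr[1]
  gy <- src[, 2] / voxel_size[2] + ctr[2]
  gz <- src[, 3] / voxel_size[3] + ctr[3]
  fx <- floor(gx); fy <- floor(gy); fz <- floor(gz)
  wx <- gx - fx; wy <- gy - fy; wz <- gz - fz
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  rows <- seq_len(n)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    sx <- fx + dx; sy <- fy + dy; sz <- fz + dz
    w <- (if (dx) wx else 1 - wx) * (if (dy) wy else 1 - wy) *
         (if (dz) wz else 1 - wz)
    ok <- sx >= 0 & sx < shape[1] & sy >= 0 & sy < shape[2] &
          sz >= 0 & sz < shape[3] & w > 0
    if (any(ok)) {
      ii <- c(ii, rows[ok])
      jj <- c(jj, 1 + sx[ok] + shape[1] * (sy[ok] + shape[2] * sz[ok]))
      ww <- c(ww, w[ok])
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
}

# Apply a (real, sparse) operator to a possibly complex 3D volume.
apply_operator <- function(P, vol) {
  shape <- dim(vol)
  v <- as.vector(vol)
  if (is.complex(v)) {
    out <- as.numeric(P %*% Re(v)) + 1i * as.numeric(P %*% Im(v))
  } else {
    out <- as.numeric(P %*% v)
  }
  array(out, dim = shape)
}

apply_operator_adjoint <- function(P, vol) {
  shape <- dim(vol)
  v <- as.vector(vol)
  if (is.complex(v)) {
    out <- as.numeric(Matrix::crossprod(P, Re(v))) +
      1i * as.numeric(Matrix::crossprod(P, Im(v)))
  } else {
    out <- as.numeric(Matrix::crossprod(P, v))
  }
  array(out, dim = shape)
}

# Convenience rigid transform of a single volume.
rigid_transform <- function(vol, voxel_size, rotation_deg, translation_mm,
                            invert = FALSE) {
  P <- rigid_operator(dim(vol), voxel_size, rotation_deg, translation_mm,
                      invert = invert)
  apply_operator(P, vol)
}

# Fast trilinear gather of a rigid transform (forward convention of
# rigid_operator) without building the sparse operator; real volumes.
rigid_gather <- function(vol, voxel_size, rotation_deg, translation_mm) {
  shape <- dim(vol)
  A <- t(rotation_matrix(rotation_deg))
  b <- -A %*% as.numeric(translation_mm)
  n <- prod(shape)
  out <- coord_matrix(shape, voxel_size)
  src <- out %*% t(A) + matrix(b, n, 3, byrow = TRUE)
  ctr <- shape %/% 2
  gx <- src[, 1] / voxel_size[1] + ctr[1]
  gy <- src[, 2] / voxel_size[2] + ctr[2]
  gz <- src[, 3] / voxel_size[3] + ctr[3]
  fx <- floor(gx); fy <- floor(gy); fz <- floor(gz)
  wx <- gx - fx; wy <- gy - fy; wz <- gz - fz
  acc <- numeric(n)
  v <- as.vector(vol)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    sx <- fx + dx; sy <- fy + dy; sz <- fz + dz
    w <- (if (dx) wx else 1 - wx) * (if (dy) wy else 1 - wy) *
         (if (dz) wz else 1 - wz)
    ok <- sx >= 0 & sx < shape[1] & sy >= 0 & sy < shape[2] &
          sz >= 0 & sz < shape[3]
    idx <- 1 + sx + shape[1] * (sy + shape[2] * sz)
    contrib <- numeric(n)
    contrib[ok] <- w[ok] * v[idx[ok]]
    acc <- acc + contrib
  }
  array(acc, dim = shape)
}

# Band-limited (zero-padding) upsampling by an integer factor.
fourier_upsample <- function(vol, factor = 2L) {
  d <- dim(vol)
  nd <- d * factor
  ksp <- fft3(vol)
  out <- array(0i, dim = nd)
  idx <- lapply(1:3, function(i)
    c(seq_len(ceiling(d[i] / 2)), nd[i] - floor(d[i] / 2) + seq_len(floor(d[i] / 2))))
  out[idx[[1]], idx[[2]], idx[[3]]] <- ksp
  res <- ifft3(out) * sqrt(prod(nd) / prod(d))
  if (is.complex(vol)) res else Re(res)
}

# FFT-based Gaussian smoothing (works on complex volumes).  fwhm in mm.
gauss_smooth <- function(vol, fwhm_mm, voxel_size) {
  if (fwhm_mm <= 0) return(vol)
  shape <- dim(vol)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  ks <- lapply(1:3, function(i) fft_freq(shape[i], voxel_size[i]))
  atten <- exp(-2 * pi^2 * sigma^2 * (
    outer(outer(ks[[1]]^2, ks[[2]]^2, `+`), ks[[3]]^2, `+`)))
  out <- stats::fft(stats::fft(vol) * atten, inverse = TRUE) / length(vol)
  if (is.complex(vol)) out else Re(out)
}

# Hermitian square root and inverse square root via eigendecomposition.
herm_sqrt <- function(M, inverse = FALSE) {
  e <- eigen(M, symmetric = TRUE)
  lam <- pmax(Re(e$values), .Machine$double.eps)
  s <- if (inverse) 1 / sqrt(lam) else sqrt(lam)
  V <- e$vectors
  V %*% (s * Conj(t(V)))
}

# Normalize list-of-volumes / 4D-array inputs to a 4D array.
to_stack <- function(x) {
  if (is.list(x)) {
    shape <- dim(x[[1]])
    array(unlist(x, use.names = FALSE), dim = c(shape, length(x)))
  } else if (length(dim(x)) == 4) {
    x
  } else if (length(dim(x)) == 3) {
    array(x, dim = c(dim(x), 1))
  } else {
    stop("expected a 3D/4D array or a list of 3D arrays")
  }
}

wrap_phase <- function(x) Arg(exp(1i * x))
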