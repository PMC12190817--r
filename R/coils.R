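#' Simulate a multi-channel receive array
#'
#' Channels are modeled as circular loops tiled on an ellipsoidal former
#' surrounding the grid.  Each sensitivity follows the quasi-static loop
#' falloff |B| ~ (1 + (d/a)^2)^(-3/2) with a smooth distance-dependent phase.
#' The noise covariance is Psi = (1 - correlation) I + correlation * G with G
#' a unit-diagonal Hermitian Gram matrix, so Psi is Hermitian positive
#' definite with unit diagonal.
#'
#' @param shape Grid size (3 integers).
#' @param voxel_size mm, 3-vector.
#' @param n_channels Number of receive channels (>= 1).
#' @param correlation Off-diagonal noise-correlation strength in [0, 1).
#' @param seed Integer seed.
#' @return A `coil_array`: `sensitivities` (complex 4D array, channel last),
#'   `noise_cov` (Hermitian matrix), `n_channels`, `voxel_size`.
#' @export
simulate_coils <- function(shape, voxel_size = c(1, 1, 1), n_channels = 8,
                           correlation = 0.1, seed = 1) {
  if (n_channels < 1) stop("n_channels must be >= 1")
  if (correlation < 0 || correlation >= 1) stop("correlation must be in [0, 1)")
  shape <- as.integer(shape)
  half_mm <- shape * voxel_size / 2
  former <- 1.25 * half_mm                 # ellipsoidal former semi-axes (mm)
  centers <- loop_centers(n_channels, former, seed)
  # loop radius from an equal-area tiling of the former surface
  area <- 4 * pi * mean(former)^2
  r_loop <- 0.8 * sqrt(area / max(n_channels, 2) / pi)
  pts <- coord_matrix(shape, voxel_size)
  sens <- array(0i, dim = c(shape, n_channels))
  phase0 <- with_seed(seed + 1L, stats::runif(n_channels, 0, 2 * pi))
  n <- prod(shape)
  for (c_i in seq_len(n_channels)) {
    d2 <- (pts[, 1] - centers[c_i, 1])^2 + (pts[, 2] - centers[c_i, 2])^2 +
          (pts[, 3] - centers[c_i, 3])^2
    mag <- (1 + d2 / r_loop^2)^(-1.5)
    ph <- phase0[c_i] + 0.02 * sqrt(d2)
    sens[, , , c_i] <- array(complex(modulus = mag, argument = ph), dim = shape)
  }
  G <- with_seed(seed + 2L, {
    X <- matrix(complex(real = stats::rnorm(2 * n_channels^2),
                        imaginary = stats::rnorm(2 * n_channels^2)),
                2 * n_channels, n_channels)
    G <- Conj(t(X)) %*% X
    d <- sqrt(Re(diag(G)))
    G / outer(d, d)
  })
  psi <- (1 - correlation) * diag(n_channels) + correlation * G
  psi <- (psi + Conj(t(psi))) / 2
  diag(psi) <- Re(diag(psi))
  psi <- psi / mean(Re(diag(psi)))         # unit mean diagonal
  structure(list(sensitivities = sens, noise_cov = psi,
                 n_channels = n_channels, voxel_size = voxel_size,
                 centers = centers, loop_radius = r_loop, seed = seed),
            class = "coil_array")
}

# Near-uniform points on the former surface (Fibonacci spiral on the sphere,
# scaled to the ellipsoid), with a small seeded jitter.
loop_centers <- function(n, semi_axes, seed) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  jit <- with_seed(seed, matrix(stats::runif(3 * n, -0.02, 0.02), n, 3))
  cbind(semi_axes[1] * (sin(phi) * cos(theta) + jit[, 1]),
        semi_axes[2] * (sin(phi) * sin(theta) + jit[, 2]),
        semi_axes[3] * (cos(phi) + jit[, 3]))
}

#' @export
print.coil_array <- function(x, ...) {
  ev <- Re(eigen(x$noise_cov, symmetric = TRUE, only.values = TRUE)$values)
  cat("<coil_array> ", x$n_channels, " channels on ",
      paste(utils::head(dim(x$sensitivities), 3), collapse = "x"),
      " grid; Psi condition number ", format(max(ev) / min(ev), digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Estimate coil sensitivity maps from reference images
#'
#' Each channel image is divided voxelwise by the root-sum-of-squares channel
#' combination (zeroed where the combination falls below 5 percent of its
#' 99th percentile), then smoothed with a Gaussian kernel of the stated FWHM.
#'
#' @param reference_images Per-channel complex volumes (4D array, channel
#'   last, or list of 3D arrays).
#' @param smoothing_fwhm Gaussian FWHM in mm (0 disables smoothing).
#' @param voxel_size mm, 3-vector.
#' @return Complex 4D array of estimated sensitivities (channel last).
#' @export
estimate_sensitivities <- function(reference_images, smoothing_fwhm = 6,
                                   voxel_size = c(1, 1, 1)) {
  ref <- to_stack(reference_images)
  nch <- dim(ref)[4]
  shape <- dim(ref)[1:3]
  rss <- sqrt(apply(abs(ref)^2, 1:3, sum))
  if (max(rss) == 0) stop("all-zero reference images")
  thr <- 0.05 * stats::quantile(rss, 0.99, names = FALSE)
  support <- rss >= thr
  out <- array(0i, dim = dim(ref))
  denom <- ifelse(support, rss, Inf)
  if (smoothing_fwhm > 0) {
    # normalized convolution: smoothing the masked ratio and dividing by the
    # smoothed mask avoids attenuation at the support edge
    msm <- gauss_smooth(support + 0, smoothing_fwhm, voxel_size)
    msm <- pmax(msm, 1e-3)
  }
  for (c_i in seq_len(nch)) {
    s <- ref[, , , c_i] / denom
    if (smoothing_fwhm > 0) {
      s <- gauss_smooth(s, smoothing_fwhm, voxel_size) / msm
      s[!support] <- 0
    }
    out[, , , c_i] <- s
  }
  out
}
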