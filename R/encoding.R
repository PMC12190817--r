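#' Define a multi-echo GRE acquisition protocol
#'
#' @param field_strength T. @param tr Repetition time, s.
#' @param te_list Echo times, s, strictly increasing, all < tr.
#' @param flip_angle_nominal Nominal excitation flip angle, degrees.
#' @param matrix Acquisition matrix (readout, phase, slice), 3 integers.
#' @param fov Field of view, mm, 3-vector.
#' @param bandwidth_per_pixel Readout receiver bandwidth, Hz/pixel.
#' @param rp,rs Parallel-imaging acceleration in the phase and slice
#'   directions. @param caipi_shift CAIPI slice-encoding shift (0 <= shift < rs).
#' @param nav_te Navigator echo time, s. @param nav_matrix Navigator matrix.
#' @param nav_interval_trs TRs per navigator volume.
#' @return An `acq_protocol`.
#' @export
acq_protocol <- function(field_strength, tr, te_list, flip_angle_nominal,
                         matrix, fov, bandwidth_per_pixel = 208,
                         rp = 1, rs = 1, caipi_shift = 0,
                         nav_te = 0.0043, nav_matrix = NULL,
                         nav_interval_trs = 12) {
  te_list <- as.numeric(te_list)
  if (is.unsorted(te_list, strictly = TRUE)) stop("te_list must be strictly increasing")
  if (any(te_list >= tr)) stop("all echo times must be < tr")
  if (rp < 1 || rs < 1) stop("rp and rs must be >= 1")
  if (caipi_shift < 0 || caipi_shift >= rs) stop("caipi_shift must satisfy 0 <= shift < rs")
  if (is.null(nav_matrix)) nav_matrix <- pmax(as.integer(matrix) %/% 4L, 4L)
  structure(list(field_strength = field_strength, tr = tr, te_list = te_list,
                 flip_angle_nominal = flip_angle_nominal,
                 matrix = as.integer(matrix), fov = as.numeric(fov),
                 bandwidth_per_pixel = bandwidth_per_pixel,
                 rp = as.integer(rp), rs = as.integer(rs),
                 caipi_shift = as.integer(caipi_shift),
                 nav_te = nav_te, nav_matrix = as.integer(nav_matrix),
                 nav_interval_trs = as.integer(nav_interval_trs)),
            class = "acq_protocol")
}

#' Reference whole-brain mesoscopic protocols
#'
#' The published acquisition settings at each field: 10.5 T uses TR 35 ms,
#' four echoes from 10.2 ms with 4.9 ms spacing, 12 degree flip; 7 T uses TR
#' 45 ms, six echoes, 14 degree flip.  Both use 208 Hz/pixel bandwidth, 2x3
#' CAIPI acceleration and a navigator every 12 TRs at 4.3 ms TE.  The matrix
#' defaults to a simulation-scale grid; pass the full 480x360x256 matrix to
#' reproduce scanner-scale timing.
#'
#' @param field_strength 7 or 10.5.
#' @param matrix Acquisition matrix (default c(48, 48, 48)).
#' @param fov mm (default matrix * 0.5 mm).
#' @export
default_protocol <- function(field_strength = 10.5, matrix = c(48, 48, 48),
                             fov = NULL) {
  if (is.null(fov)) fov <- matrix * 0.5
  if (field_strength == 10.5) {
    acq_protocol(10.5, tr = 0.035, te_list = 0.0102 + 0.0049 * (0:3),
                 flip_angle_nominal = 12, matrix = matrix, fov = fov,
                 bandwidth_per_pixel = 208, rp = 2, rs = 3, caipi_shift = 1)
  } else if (field_strength == 7) {
    acq_protocol(7, tr = 0.045, te_list = 0.0102 + 0.0049 * (0:5),
                 flip_angle_nominal = 14, matrix = matrix, fov = fov,
                 bandwidth_per_pixel = 208, rp = 2, rs = 3, caipi_shift = 1)
  } else stop("no default protocol for field_strength = ", field_strength)
}

#' @export
print.acq_protocol <- function(x, ...) {
  cat("<acq_protocol> ", x$field_strength, " T, TR ", x$tr * 1e3, " ms, ",
      length(x$te_list), " echoes (TE1 ", x$te_list[1] * 1e3, " ms), flip ",
      x$flip_angle_nominal, " deg, ", paste(x$matrix, collapse = "x"),
      ", R = ", x$rp, "x", x$rs, " shift ", x$caipi_shift, "\n", sep = "")
  invisible(x)
}

#' 2D CAIPI sampling pattern over the phase/slice encoding plane
#'
#' Sampled points are \{(ky, kz): ky mod rp == 0 and
#' kz mod rs == (shift * (ky div rp)) mod rs\} with 0-based indices; shift 0
#' gives the regular SENSE lattice.
#'
#' @param ny,nz Phase/slice matrix sizes.
#' @param rp,rs Acceleration factors. @param shift CAIPI shift (0 <= shift < rs).
#' @return A `sampling_pattern` with logical `mask` (ny x nz), the factors
#'   and `total_r = rp * rs`.
#' @export
caipi_pattern <- function(ny, nz, rp, rs, shift = 0) {
  if (shift < 0 || shift >= rs) stop("shift must satisfy 0 <= shift < rs")
  ky <- 0:(ny - 1); kz <- 0:(nz - 1)
  sampled_ky <- ky %% rp == 0
  mask <- matrix(FALSE, ny, nz)
  for (y in ky[sampled_ky]) {
    off <- (shift * (y %/% rp)) %% rs
    mask[y + 1, (kz %% rs) == off] <- TRUE
  }
  if (!any(mask)) stop("empty sampling pattern: rp/rs do not fit the matrix")
  structure(list(mask = mask, rp = as.integer(rp), rs = as.integer(rs),
                 caipi_shift = as.integer(shift),
                 total_r = as.integer(rp * rs)),
            class = "sampling_pattern")
}

#' @export
print.sampling_pattern <- function(x, ...) {
  cat("<sampling_pattern> ", nrow(x$mask), "x", ncol(x$mask), ", R = ",
      x$rp, "x", x$rs, " shift ", x$caipi_shift, " (",
      sum(x$mask), "/", length(x$mask), " sampled)\n", sep = "")
  invisible(x)
}

#' Steady-state spoiled gradient-echo signal
#'
#' S = m0 sin(a) (1 - E1) / (1 - E1 cos(a)) exp(-te r2star), E1 = exp(-tr/t1).
#' At te = 0 this is the TE-free steady-state amplitude; the maximum over the
#' flip angle is at the Ernst angle acos(E1).
#'
#' @param alpha Flip angle, degrees. @param tr s. @param t1 s (> 0).
#' @param te Echo time, s. @param r2star 1/s. @param m0 Equilibrium signal.
#' @export
spoiled_gre_signal <- function(alpha, tr, t1, te = 0, r2star = 0, m0 = 1) {
  if (any(t1 <= 0)) stop("t1 must be > 0")
  if (any(tr <= 0)) stop("tr must be > 0")
  a <- alpha * pi / 180
  e1 <- exp(-tr / t1)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a)) * exp(-te * r2star)
}

#' Derived protocol timing
#'
#' @param protocol An `acq_protocol`.
#' @return List with `nav_interval` (s), `readout_per_line` (s),
#'   `acq_time_per_echo` (s, acquired line count x readout duration) and
#'   `n_lines` (acquired phase/slice lines).
#' @export
protocol_timing <- function(protocol) {
  pat <- caipi_pattern(protocol$matrix[2], protocol$matrix[3], protocol$rp,
                       protocol$rs, protocol$caipi_shift)
  n_lines <- sum(pat$mask)
  readout <- 1 / protocol$bandwidth_per_pixel
  list(nav_interval = protocol$nav_interval_trs * protocol$tr,
       readout_per_line = readout,
       acq_time_per_echo = n_lines * readout,
       n_lines = n_lines)
}

# Noiseless per-echo complex image of a phantom in its reference pose:
# spoiled-GRE steady-state amplitude at the nominal flip angle, R2* decay and
# static off-resonance phase at the given TE.
echo_image <- function(phantom, protocol, te) {
  amp <- spoiled_gre_signal(protocol$flip_angle_nominal, protocol$tr,
                            pmax(phantom$t1, 1e-6), te = te,
                            r2star = phantom$r2star, m0 = phantom$m0)
  amp[phantom$label_map == 0L] <- 0
  amp * exp(2i * pi * phantom$delta_f0 * te)
}

# Per-voxel drift field (Hz) of one motion state on a grid.
drift_field <- function(state, shape, voxel_size) {
  pts <- coord_matrix(shape, voxel_size)
  array(state$b0_offset + pts %*% state$b0_gradient, dim = shape)
}

# Draw correlated complex channel noise: returns (n x nch) with
# E[n n^H] = scale^2 * Psi.
draw_noise <- function(n, psi, scale) {
  nch <- nrow(psi)
  M <- herm_sqrt(psi)
  w <- matrix(complex(real = stats::rnorm(n * nch), imaginary = stats::rnorm(n * nch)),
              n, nch) / sqrt(2)
  scale * w %*% t(M)
}

#' Synthesize CAIPI-undersampled multi-echo multi-channel k-space
#'
#' Implements the unified forward signal model: for each echo and each shot
#' (one phase/slice line per TR), the reference-pose echo image is rigidly
#' transformed by the shot's motion state, given the state's B0-drift phase
#' at the echo time, multiplied by each coil sensitivity, Fourier transformed
#' (unitary FFT) and sampled on the CAIPI pattern.  Shots are assigned to
#' navigator intervals in ky-major acquisition order, `nav_interval_trs`
#' shots per interval.  Correlated channel noise with covariance
#' `noise_scale^2 * Psi` is added to every sampled point.
#'
#' @param phantom A `tissue_phantom`. @param coils A `coil_array` on the same
#'   grid. @param protocol An `acq_protocol` whose matrix equals the grid.
#' @param trajectory A `motion_trajectory` covering all shots, or NULL for a
#'   static acquisition.
#' @param noise_scale Complex noise standard deviation per k-space sample
#'   (unit-diagonal Psi); 0 for noiseless data.
#' @param seed Integer seed for the noise draw.
#' @return A `kspace_data`: `samples` (complex array nx x ny x nz x channel x
#'   echo, zero where unsampled), `pattern`, `shot_interval` (ny x nz integer
#'   map, 0 = unsampled), `protocol`, `noise_scale`, `voxel_size`.
#' @export
forward_encode <- function(phantom, coils, protocol, trajectory = NULL,
                           noise_scale = 0, seed = 1) {
  shape <- dim(phantom$label_map)
  stopifnot(all(shape == utils::head(dim(coils$sensitivities), 3)),
            all(shape == protocol$matrix))
  vs <- phantom$voxel_size
  nch <- coils$n_channels
  ne <- length(protocol$te_list)
  pat <- caipi_pattern(shape[2], shape[3], protocol$rp, protocol$rs,
                       protocol$caipi_shift)
  # ky-major acquisition order over sampled lines
  sampled <- which(pat$mask, arr.ind = TRUE)
  ord <- order(sampled[, 1], sampled[, 2])
  sampled <- sampled[ord, , drop = FALSE]
  n_shots <- nrow(sampled)
  shot_interval <- matrix(0L, shape[2], shape[3])
  interval_of <- (seq_len(n_shots) - 1L) %/% protocol$nav_interval_trs + 1L
  if (is.null(trajectory)) {
    trajectory <- make_trajectory(max(interval_of), seed = seed,
                                  interval_duration =
                                    protocol$nav_interval_trs * protocol$tr)
  }
  if (length(trajectory$states) < max(interval_of))
    stop("trajectory shorter than the ", max(interval_of),
         " intervals needed for ", n_shots, " shots")
  shot_interval[cbind(sampled[, 1], sampled[, 2])] <- interval_of

  samples <- array(0i, dim = c(shape, nch, ne))
  base <- lapply(protocol$te_list, function(te) echo_image(phantom, protocol, te))
  for (iv in sort(unique(interval_of))) {
    st <- trajectory$states[[iv]]
    moving <- !all(c(st$translation, st$rotation) == 0)
    P <- if (moving) rigid_operator(shape, vs, st$rotation, st$translation) else NULL
    df <- if (st$b0_offset != 0 || any(st$b0_gradient != 0))
      drift_field(st, shape, vs) else NULL
    lines_iv <- sampled[interval_of == iv, , drop = FALSE]
    for (e in seq_len(ne)) {
      img <- base[[e]]
      if (moving) img <- apply_operator(P, img)
      if (!is.null(df)) img <- img * exp(2i * pi * df * protocol$te_list[e])
      for (c_i in seq_len(nch)) {
        ksp <- fft3(coils$sensitivities[, , , c_i] * img)
        for (li in seq_len(nrow(lines_iv)))
          samples[, lines_iv[li, 1], lines_iv[li, 2], c_i, e] <-
            ksp[, lines_iv[li, 1], lines_iv[li, 2]]
      }
    }
  }
  if (noise_scale > 0) {
    idx_lines <- which(pat$mask)
    n_pts <- shape[1] * length(idx_lines)
    with_seed(seed, {
      for (e in seq_len(ne)) {
        nz <- draw_noise(n_pts, coils$noise_cov, noise_scale)
        for (c_i in seq_len(nch)) {
          sl <- matrix(samples[, , , c_i, e], shape[1], shape[2] * shape[3])
          sl[, idx_lines] <- sl[, idx_lines] + matrix(nz[, c_i], shape[1])
          samples[, , , c_i, e] <- array(sl, dim = shape)
        }
      }
    })
  }
  structure(list(samples = samples, pattern = pat,
                 shot_interval = shot_interval, protocol = protocol,
                 noise_scale = noise_scale, voxel_size = vs,
                 n_intervals = max(interval_of)),
            class = "kspace_data")
}

#' @export
print.kspace_data <- function(x, ...) {
  d <- dim(x$samples)
  cat("<kspace_data> ", paste(d[1:3], collapse = "x"), " matrix, ", d[4],
      " channels, ", d[5], " echoes, R = ", x$pattern$rp, "x", x$pattern$rs,
      " shift ", x$pattern$caipi_shift, ", ", x$n_intervals,
      " motion intervals, noise_scale ", x$noise_scale, "\n", sep = "")
  invisible(x)
}

#' Synthesize low-resolution navigator volumes
#'
#' One channel-combined complex volume per trajectory interval at the
#' navigator TE: the reference-pose image is rigidly transformed by the
#' interval's motion state, given its drift phase at `nav_te`, downsampled to
#' `nav_matrix` by centred k-space truncation, and combined across channels
#' with the (equally downsampled) sensitivities.  White complex noise of
#' standard deviation `noise_scale` per quadrature pair is added per volume.
#'
#' @inheritParams forward_encode
#' @return A `navigator_series`: list of complex volumes, `nav_te`,
#'   `interval_duration`, `voxel_size` (navigator grid, mm).
#' @export
simulate_navigators <- function(phantom, coils, protocol, trajectory,
                                noise_scale = 0, seed = 1) {
  shape <- dim(phantom$label_map)
  nm <- protocol$nav_matrix
  if (any(nm > shape)) stop("nav_matrix must be <= matrix componentwise")
  vs <- phantom$voxel_size
  nav_vs <- shape * vs / nm
  base <- echo_image(phantom, protocol, protocol$nav_te)
  sens_low <- lapply(seq_len(coils$n_channels), function(c_i)
    kspace_downsample(coils$sensitivities[, , , c_i], nm, apodize = TRUE))
  ssq <- Reduce(`+`, lapply(sens_low, function(s) abs(s)^2))
  ssq <- pmax(ssq, 1e-6 * max(ssq))
  vols <- vector("list", length(trajectory$states))
  noise_seeds <- with_seed(seed, sample.int(.Machine$integer.max,
                                            length(vols)))
  # motion is applied on a 2x band-limited supersampled grid: trilinear
  # interpolation there is accurate enough that the low-resolution volume
  # behaves like an ideally rotated object
  base_up <- fourier_upsample(base, 2L)
  for (iv in seq_along(trajectory$states)) {
    st <- trajectory$states[[iv]]
    if (!all(c(st$translation, st$rotation) == 0)) {
      img <- rigid_transform(base_up, vs / 2, st$rotation, st$translation)
      img <- kspace_downsample(img, shape)
    } else img <- base
    if (st$b0_offset != 0 || any(st$b0_gradient != 0))
      img <- img * exp(2i * pi * drift_field(st, shape, vs) * protocol$nav_te)
    comb <- array(0i, dim = nm)
    for (c_i in seq_len(coils$n_channels)) {
      low <- kspace_downsample(coils$sensitivities[, , , c_i] * img, nm, apodize = TRUE)
      comb <- comb + Conj(sens_low[[c_i]]) * low
    }
    comb <- comb / ssq
    if (noise_scale > 0) {
      comb <- comb + with_seed(noise_seeds[iv], array(
        complex(real = stats::rnorm(prod(nm)), imaginary = stats::rnorm(prod(nm))),
        dim = nm)) * noise_scale / sqrt(2)
    }
    vols[[iv]] <- comb
  }
  structure(list(volumes = vols, nav_te = protocol$nav_te,
                 interval_duration = trajectory$interval_duration,
                 voxel_size = nav_vs),
            class = "navigator_series")
}

# Downsample a volume by centred k-space truncation (unitary scaling).
kspace_downsample <- function(vol, new_shape, apodize = FALSE) {
  shape <- dim(vol)
  if (all(shape == new_shape) && !apodize) return(vol)
  ksp <- fft3(vol)
  idx <- lapply(1:3, function(i) {
    m <- new_shape[i]; n <- shape[i]
    c(seq_len(ceiling(m / 2)), n - floor(m / 2) + seq_len(floor(m / 2)))
  })
  low <- ksp[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  if (apodize) {
    # Radial Hann apodization: suppresses truncation ringing with a smooth,
    # rotationally symmetric point-spread function (so the low-resolution
    # volume commutes with rigid rotation, as needed for navigator use)
    fr <- lapply(1:3, function(i)
      (fft_freq(new_shape[i]) * new_shape[i] / (new_shape[i] / 2))^2)
    r <- sqrt(outer(outer(fr[[1]], fr[[2]], `+`), fr[[3]], `+`))
    wnd <- ifelse(r <= 1, 0.5 * (1 + cos(pi * r)), 0)
    low <- low * wnd
  }
  # sqrt(M/N) restores image amplitude under the unitary convention
  ifft3(array(low, dim = new_shape)) * sqrt(prod(new_shape) / prod(shape))
}

#' @export
print.navigator_series <- function(x, ...) {
  cat("<navigator_series> ", length(x$volumes), " volumes of ",
      paste(dim(x$volumes[[1]]), collapse = "x"), " @ ",
      paste(round(x$voxel_size, 2), collapse = "x"), " mm, TE ",
      x$nav_te * 1e3, " ms\n", sep = "")
  invisible(x)
}
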