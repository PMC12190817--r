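#' Field-strength-specific tissue parameter table
#'
#' Relaxation parameters for the digital brain phantom.  T1 values are
#' literature values for gray and white matter at 7 T and 10.5 T; R2* values
#' are in-vivo layer measurements for two subjects.  M0, susceptibility and
#' the CSF/deep-nucleus entries are synthetic defaults chosen as plausible
#' relative contrasts (no published values exist for this phantom); they are
#' flagged in the `synthetic` column.
#'
#' @param field_strength Main field in tesla (7 or 10.5).
#' @param subject Which R2* preset to use (1 or 2).
#' @return A data.frame with one row per tissue label: `label`, `name`,
#'   `m0` (arbitrary), `t1` (s), `r2star` (1/s), `chi` (ppm), `synthetic`.
#' @export
tissue_table <- function(field_strength, subject = 1) {
  if (!field_strength %in% c(7, 10.5))
    stop("no tabulated tissue values for field_strength = ", field_strength,
         "; supply a tissue table explicitly")
  if (!subject %in% c(1, 2)) stop("subject must be 1 or 2")
  r2 <- if (field_strength == 10.5) {
    if (subject == 1) c(gm = 47, wm = 53) else c(gm = 42, wm = 51)
  } else {
    if (subject == 1) c(gm = 33, wm = 37) else c(gm = 29, wm = 36)
  }
  t1 <- if (field_strength == 10.5) c(gm = 2.1, wm = 1.4) else c(gm = 1.8, wm = 1.2)
  data.frame(
    label = 1:4,
    name = c("csf", "gm", "wm", "nucleus"),
    m0 = c(1.0, 0.8, 0.7, 0.75),
    t1 = c(4.3, t1[["gm"]], t1[["wm"]], 1.3),
    r2star = c(5, r2[["gm"]], r2[["wm"]], r2[["gm"]] + 40),
    chi = c(0, 0.02, -0.03, 0.1),
    synthetic = c(TRUE, FALSE, FALSE, TRUE)
  )
}

#' Susceptibility-induced frequency map (forward dipole model)
#'
#' Convolves a susceptibility distribution with the unit magnetic dipole
#' kernel in k-space, D(k) = 1/3 - kz^2/|k|^2 with D(0) = 0, and scales by the
#' nominal Larmor frequency.  The main field is along the third array axis.
#'
#' @param chi 3D susceptibility volume in ppm.
#' @param voxel_size Voxel size in mm (3-vector).
#' @param f0 Nominal Larmor frequency in Hz.
#' @return 3D off-resonance volume in Hz.
#' @export
dipole_field <- function(chi, voxel_size, f0) {
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  if (!all(is.finite(chi))) stop("chi must be finite")
  D <- dipole_kernel(dim(chi), voxel_size)
  Re(stats::fft(D * stats::fft(chi * 1e-6), inverse = TRUE)) / length(chi) * f0
}

#' @keywords internal
dipole_kernel <- function(shape, voxel_size) {
  ks <- lapply(1:3, function(i) fft_freq(shape[i], voxel_size[i]))
  kx2 <- array(rep(ks[[1]]^2, times = shape[2] * shape[3]), dim = shape)
  ky2 <- array(rep(rep(ks[[2]]^2, each = shape[1]), times = shape[3]), dim = shape)
  kz2 <- array(rep(ks[[3]]^2, each = shape[1] * shape[2]), dim = shape)
  k2 <- kx2 + ky2 + kz2
  D <- 1 / 3 - kz2 / k2
  D[1, 1, 1] <- 0  # D(0) := 0 (Lorentz-consistent convention)
  D
}

# Normalized ellipsoidal radius of every voxel w.r.t. centre and semi-axes
# (in voxels).  Used for phantom construction and layer extraction.
ellipsoid_rho <- function(shape, semi_axes) {
  cs <- lapply(1:3, function(i) ((seq_len(shape[i]) - 1) - (shape[i] - 1) / 2) /
                 semi_axes[i])
  sqrt(outer(outer(cs[[1]]^2, cs[[2]]^2, `+`), cs[[3]]^2, `+`))
}

#' Generate a digital brain phantom
#'
#' Builds a concentric-ellipsoid brain (CSF rim, gray-matter ribbon,
#' white-matter core, one deep-nucleus blob with elevated R2* and
#' susceptibility), assigns field-strength-specific tissue parameters with
#' +/-5 percent seeded smooth spatial variation (zero-mean within each
#' tissue class), and populates the susceptibility-induced off-resonance map
#' via the forward dipole model.
#'
#' @param shape Grid size, 3 integers (each >= 16).
#' @param voxel_size Voxel size in mm, 3-vector.
#' @param field_strength Main field in tesla; 7 and 10.5 select tabulated
#'   tissue defaults, other values require `tissue`.
#' @param seed Integer seed; identical inputs give bit-identical phantoms.
#' @param subject R2* preset (1 or 2), passed to [tissue_table()].
#' @param tissue Optional tissue table overriding [tissue_table()].
#' @param variation Relative amplitude of the smooth spatial parameter
#'   variation (default 0.05).
#' @return A `tissue_phantom`: label_map, m0, t1, r2star, chi, delta_f0
#'   volumes plus voxel_size, field_strength, f0 and geometry metadata.
#' @export
make_phantom <- function(shape, voxel_size = c(1, 1, 1), field_strength = 10.5,
                         seed = 1, subject = 1, tissue = NULL,
                         variation = 0.05) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 16))
    stop("shape must be 3 integers, each >= 16")
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  if (is.null(tissue)) tissue <- tissue_table(field_strength, subject)
  f0 <- GAMMA_HZ_PER_T * field_strength

  # distinct semi-axes: an aspherical head outline keeps rotations observable
  # distinct semi-axes: an aspherical head outline keeps rotations observable
  semi_axes <- c(0.46, 0.40, 0.43) * shape
  rho <- ellipsoid_rho(shape, semi_axes)
  gm_band <- c(0.58, 0.88)
  # fuzzy (partial-volume) memberships: ~1-voxel sigmoid transitions avoid
  # the non-physical step edges a hard-labelled phantom would have
  tau <- 0.7 / mean(semi_axes)
  sig <- function(x) 1 / (1 + exp(-x / (tau / 4)))
  inside_head <- sig(1 - rho)
  inside_gm <- sig(gm_band[2] - rho)
  inside_wm <- sig(gm_band[1] - rho)
  blob <- function(center_frac, axes_frac) {
    ctr <- (shape - 1) / 2 + center_frac * shape
    ax <- pmax(axes_frac * shape, 1.5)
    cs <- lapply(1:3, function(i) ((seq_len(shape[i]) - 1) - ctr[i]) / ax[i])
    rb <- sqrt(outer(outer(cs[[1]]^2, cs[[2]]^2, `+`), cs[[3]]^2, `+`))
    sig((1 - rb) * mean(ax) / mean(semi_axes))
  }
  # deep nucleus offset from all three axes (rotations about any axis are
  # observable) and two ventricle-like CSF spaces inside the white matter
  w_nuc_in <- blob(c(0.16, 0.08, -0.10), c(0.10, 0.10, 0.10))
  w_vent_in <- pmin(blob(c(-0.08, 0.11, 0.05), c(0.06, 0.10, 0.08)) +
                      blob(c(-0.08, -0.11, 0.05), c(0.06, 0.10, 0.08)), 1)
  w_wm_core <- inside_wm
  w_nuc <- w_wm_core * w_nuc_in
  w_vent <- w_wm_core * pmax(w_vent_in - w_nuc_in, 0)
  w_wm <- pmax(w_wm_core - w_nuc - w_vent, 0)
  w_gm <- pmax(inside_gm - inside_wm, 0)
  w_csf <- pmax(inside_head - inside_gm, 0) + w_vent
  W <- list(csf = w_csf, gm = w_gm, wm = w_wm, nucleus = w_nuc)
  wtot <- Reduce(`+`, W)
  label <- array(0L, dim = shape)
  dominant <- array(max.col(cbind(as.vector(w_csf), as.vector(w_gm),
                                  as.vector(w_wm), as.vector(w_nuc)),
                            ties.method = "first"), dim = shape)
  label[wtot > 0.5] <- dominant[wtot > 0.5]

  u <- with_seed(seed, {
    w <- array(stats::rnorm(prod(shape)), dim = shape)
    w <- gauss_smooth(w, fwhm_mm = 3 * mean(voxel_size), voxel_size = voxel_size)
    w / max(abs(w))
  })
  maps <- list(m0 = array(0, shape), t1 = array(0, shape),
               r2star = array(0, shape), chi = array(0, shape))
  tis_row <- function(nm) tissue[match(nm, tissue$name), ]
  for (nm in names(W)) {
    row <- tis_row(nm)
    idx_cls <- which(W[[nm]] > 0.99)                 # pure-tissue voxels
    if (!length(idx_cls)) idx_cls <- which(label == row$label)
    uv <- u
    if (length(idx_cls)) uv <- u - mean(u[idx_cls])  # exact pure-class means
    fac <- W[[nm]] * (1 + variation * uv)
    maps$m0 <- maps$m0 + row$m0 * fac
    maps$t1 <- maps$t1 + row$t1 * fac
    maps$r2star <- maps$r2star + row$r2star * fac
    maps$chi <- maps$chi + row$chi * fac
  }
  # t1/r2star/chi are intensive: renormalize by the total tissue fraction
  nz <- wtot > 1e-3
  for (f in c("t1", "r2star", "chi")) {
    maps[[f]][nz] <- maps[[f]][nz] / wtot[nz]
    maps[[f]][!nz] <- 0
  }
  delta_f0 <- dipole_field(maps$chi, voxel_size, f0)
  structure(list(
    label_map = label, m0 = maps$m0, t1 = maps$t1, r2star = maps$r2star,
    chi = maps$chi, delta_f0 = delta_f0, tissue_fraction = W,
    voxel_size = voxel_size, field_strength = field_strength, f0 = f0,
    tissue = tissue, seed = seed,
    geometry = list(center = (shape - 1) / 2, semi_axes = semi_axes,
                    gm_band = gm_band)
  ), class = "tissue_phantom")
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat("<tissue_phantom> ", paste(dim(x$label_map), collapse = "x"),
      " voxels @ ", paste(x$voxel_size, collapse = "x"), " mm, ",
      x$field_strength, " T (f0 = ", format(x$f0 / 1e6, digits = 6),
      " MHz)\n", sep = "")
  tab <- table(factor(x$label_map, levels = 0:4,
                      labels = c("bg", "csf", "gm", "wm", "nucleus")))
  print(tab)
  invisible(x)
}

#' Construct a single rigid-motion / field state
#'
#' The identity state (all zeros) is the reference pose.
#'
#' @param translation mm, 3-vector. @param rotation degrees, extrinsic
#'   x->y->z about the volume centre, 3-vector.
#' @param b0_offset Spatially constant field change, Hz.
#' @param b0_gradient Spatially linear field change, Hz/mm, 3-vector.
#' @export
motion_state <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                         b0_offset = 0, b0_gradient = c(0, 0, 0)) {
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation),
                 b0_offset = as.numeric(b0_offset),
                 b0_gradient = as.numeric(b0_gradient)),
            class = "motion_state")
}

#' Seeded random-walk motion and B0-drift trajectory
#'
#' One state per navigator interval; state 1 is the identity reference.
#' Each component follows a smooth random walk rescaled so its maximum
#' excursion equals the stated bound.
#'
#' @param n_intervals Number of navigator intervals (>= 1).
#' @param max_translation mm. @param max_rotation degrees.
#' @param max_b0_offset Hz. @param max_b0_gradient Hz/mm.
#' @param interval_duration s (navigator repeat interval).
#' @param seed Integer seed.
#' @return A `motion_trajectory`.
#' @export
make_trajectory <- function(n_intervals, max_translation = 0, max_rotation = 0,
                            max_b0_offset = 0, max_b0_gradient = 0,
                            interval_duration = 0.42, seed = 1) {
  if (n_intervals < 1) stop("n_intervals must be >= 1")
  if (any(c(max_translation, max_rotation, max_b0_offset, max_b0_gradient) < 0))
    stop("amplitudes must be >= 0")
  walks <- with_seed(seed, {
    m <- matrix(0, n_intervals, 10)
    if (n_intervals > 1) {
      for (j in 1:10) {
        w <- cumsum(stats::rnorm(n_intervals))
        w <- w - w[1]
        mx <- max(abs(w))
        m[, j] <- if (mx > 0) w / mx else w
      }
    }
    m
  })
  amp <- c(rep(max_translation, 3), rep(max_rotation, 3), max_b0_offset,
           rep(max_b0_gradient, 3))
  walks <- sweep(walks, 2, amp, `*`)
  states <- lapply(seq_len(n_intervals), function(i) {
    motion_state(translation = walks[i, 1:3], rotation = walks[i, 4:6],
                 b0_offset = walks[i, 7], b0_gradient = walks[i, 8:10])
  })
  structure(list(states = states, interval_duration = interval_duration,
                 seed = seed),
            class = "motion_trajectory")
}

#' @export
print.motion_trajectory <- function(x, ...) {
  cat("<motion_trajectory> ", length(x$states), " intervals of ",
      x$interval_duration, " s\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.motion_trajectory <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$states), function(i) {
    s <- x$states[[i]]
    data.frame(interval = i, tx = s$translation[1], ty = s$translation[2],
               tz = s$translation[3], rx = s$rotation[1], ry = s$rotation[2],
               rz = s$rotation[3], b0 = s$b0_offset, gx = s$b0_gradient[1],
               gy = s$b0_gradient[2], gz = s$b0_gradient[3])
  }))
}

#' Paired cortical GM / adjacent WM layer masks
#'
#' The GM layer is the radial mid-depth of the cortical ribbon; the WM layer
#' sits inside the GM-WM boundary by 40 percent of the local ribbon
#' thickness.  Voxels are paired one-to-one along the shared radial
#' direction; GM voxels whose WM partner falls outside the white matter or
#' would be reused are dropped, so the two sets are disjoint and of equal
#' size.
#'
#' @param phantom A `tissue_phantom` with ellipsoidal geometry metadata.
#' @param wm_fraction Depth below the GM-WM boundary as a fraction of the
#'   local ribbon thickness (default 0.4).
#' @return A list with integer vectors `gm` and `wm` of linear voxel indices
#'   (paired by position), class `layer_masks`.
#' @export
layer_masks <- function(phantom, wm_fraction = 0.4) {
  g <- phantom$geometry
  shape <- dim(phantom$label_map)
  band <- g$gm_band
  thick_vox <- (band[2] - band[1]) * min(g$semi_axes)
  if (thick_vox < 2) stop("GM ribbon thinner than 2 voxels")
  rho <- ellipsoid_rho(shape, g$semi_axes)
  rho_mid <- mean(band)
  half <- 0.5 / mean(g$semi_axes)              # ~ half a voxel in rho units
  gm_idx <- which(phantom$label_map == 2L & abs(rho - rho_mid) <= half)
  # radial WM target: wm_fraction of the ribbon thickness below the boundary
  rho_wm <- band[1] - wm_fraction * (band[2] - band[1])
  ar <- arrayInd(gm_idx, shape)
  ctr <- g$center
  scl <- rho_wm / rho[gm_idx]
  wm_pos <- round(sweep(sweep(ar - 1, 2, ctr, `-`) * scl, 2, ctr, `+`)) + 1
  ok <- wm_pos[, 1] >= 1 & wm_pos[, 1] <= shape[1] &
        wm_pos[, 2] >= 1 & wm_pos[, 2] <= shape[2] &
        wm_pos[, 3] >= 1 & wm_pos[, 3] <= shape[3]
  gm_idx <- gm_idx[ok]; wm_pos <- wm_pos[ok, , drop = FALSE]
  wm_idx <- wm_pos[, 1] + shape[1] * (wm_pos[, 2] - 1 + shape[2] * (wm_pos[, 3] - 1))
  keep <- phantom$label_map[wm_idx] == 3L & !duplicated(wm_idx)
  structure(list(gm = gm_idx[keep], wm = wm_idx[keep], shape = shape),
            class = "layer_masks")
}

#' Sample a scalar map along paired layers
#'
#' @param volume 3D array on the phantom grid.
#' @param masks A `layer_masks` object.
#' @return A `layer_sample`: paired numeric vectors `gm` and `wm`.
#' @export
sample_layers <- function(volume, masks) {
  stopifnot(inherits(masks, "layer_masks"))
  structure(list(gm = as.numeric(volume[masks$gm]),
                 wm = as.numeric(volume[masks$wm])),
            class = "layer_sample")
}
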