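# Shared fixtures, memoized across test files (built once per session).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

phantom24 <- function() fixture("phantom24", function()
  make_phantom(c(24, 24, 24), c(2, 2, 2), field_strength = 10.5, seed = 11))

coils24 <- function() fixture("coils24", function()
  simulate_coils(c(24, 24, 24), c(2, 2, 2), n_channels = 8,
                 correlation = 0.1, seed = 12))

phantom16 <- function() fixture("phantom16", function()
  make_phantom(c(16, 16, 16), c(2, 2, 2), field_strength = 10.5, seed = 13))

coils16 <- function() fixture("coils16", function()
  simulate_coils(c(16, 16, 16), c(2, 2, 2), n_channels = 4,
                 correlation = 0.1, seed = 14))

# protocol on the 24-cube grid; acceleration configurable
proto24 <- function(rp = 1, rs = 1, shift = 0, te = 0.0102 + 0.0049 * (0:3),
                    nav_matrix = c(12, 12, 12), flip = 12,
                    nav_interval_trs = 12) {
  acq_protocol(10.5, tr = 0.035, te_list = te, flip_angle_nominal = flip,
               matrix = c(24, 24, 24), fov = c(48, 48, 48),
               bandwidth_per_pixel = 208, rp = rp, rs = rs,
               caipi_shift = shift, nav_matrix = nav_matrix,
               nav_interval_trs = nav_interval_trs)
}

rel_rmse <- function(a, b) sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))

# minimal spherical-shell phantom for layer-geometry checks: GM ribbon over
# radii (r_in, r_out] voxels, WM core below, CSF rim above
shell_phantom <- function(r_in = 40, r_out = 44, margin = 4) {
  n <- 2L * as.integer(ceiling(r_out + margin)) + 1L
  shape <- c(n, n, n)
  ctr <- (shape - 1) / 2
  cs <- lapply(1:3, function(i) (seq_len(n) - 1) - ctr[i])
  r <- sqrt(outer(outer(cs[[1]]^2, cs[[2]]^2, `+`), cs[[3]]^2, `+`))
  label <- array(0L, dim = shape)
  label[r <= r_out + 2] <- 1L
  label[r <= r_out] <- 2L
  label[r <= r_in] <- 3L
  structure(list(label_map = label, voxel_size = c(1, 1, 1),
                 geometry = list(center = ctr, semi_axes = c(1, 1, 1),
                                 gm_band = c(r_in, r_out))),
            class = "tissue_phantom")
}

trajectory_from_states <- function(states, interval_duration = 0.42) {
  structure(list(states = states, interval_duration = interval_duration,
                 seed = NA), class = "motion_trajectory")
}
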