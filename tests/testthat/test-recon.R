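make_moving_kspace <- function() {
  fixture("moving_kspace24", function() {
    p <- phantom24(); co <- coils24()
    pr <- proto24(rp = 2, rs = 2, shift = 1, te = c(0.0102, 0.0249),
                  nav_interval_trs = 36)      # 144 shots -> 4 intervals
    tr <- make_trajectory(4, max_translation = 2, max_rotation = 1.5,
                          max_b0_offset = 8, max_b0_gradient = 0.05,
                          seed = 7)
    list(kspace = forward_encode(p, co, pr, tr, noise_scale = 0),
         trajectory = tr, protocol = pr)
  })
}

test_that("the unified encoding operator passes the adjoint test in every mode", {
  mk <- make_moving_kspace()
  ks <- mk$kspace; co <- coils24()
  shape <- c(24, 24, 24)
  for (mode in c("NoCo", "MoCo", "MoCo+B0Co")) {
    ops <- megre:::moco_operators(ks, co$sensitivities, co$noise_cov,
                                  mk$trajectory, mk$trajectory, mode)
    set.seed(31)
    rnd <- function() array(complex(real = rnorm(prod(shape)),
                                    imaginary = rnorm(prod(shape))), shape)
    x <- rnd()
    y <- ops$forward(rnd(), 0.01)
    lhs <- sum(Conj(ops$forward(x, 0.01)) * y)
    rhs <- sum(Conj(x) * ops$adjoint(y, 0.01))
    expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-8)
  }
})

test_that("direct SENSE and iterative CG agree on static data", {
  p <- phantom24(); co <- coils24()
  pr <- proto24(rp = 2, rs = 2, shift = 1, te = c(0.0102, 0.0249))
  ks <- forward_encode(p, co, pr, trajectory = NULL, noise_scale = 0)
  direct <- sense_recon(ks, co$sensitivities, co$noise_cov)
  for (mode in c("NoCo", "MoCo", "MoCo+B0Co")) {
    cg <- joint_moco_recon(ks, co$sensitivities, co$noise_cov, NULL, NULL,
                           mode, max_iter = 30, tol = 1e-10)
    expect_true(cg$converged)
    for (e in 1:2)
      expect_lt(rel_rmse(cg$images[, , , e], direct$images[, , , e]), 1e-8)
  }
  # and both recover the encoded truth exactly on this lattice
  truth <- megre:::echo_image(p, pr, pr$te_list[1])
  expect_lt(rel_rmse(direct$images[, , , 1], truth), 1e-10)
  # reconstruction is deterministic
  direct2 <- sense_recon(ks, co$sensitivities, co$noise_cov)
  expect_identical(direct$images, direct2$images)
})

test_that("SENSE noise map matches the closed-form two-voxel solution", {
  # two aliased voxels with orthogonal sensitivity columns and Psi = I:
  # noise std per voxel is 1/norm(column), the unaccelerated value (g = 1)
  shape <- c(1, 2, 1)
  sens <- array(0i, dim = c(shape, 2))
  sens[1, 1, 1, ] <- c(2, 0)        # voxel 1 seen only by channel 1
  sens[1, 2, 1, ] <- c(0, 0.5)      # voxel 2 seen only by channel 2
  mask <- matrix(c(TRUE, FALSE), 1, 2)   # ky fully sampled, kz R = 2
  core <- megre:::sense_core(sens, diag(2), t(mask), zf = NULL,
                             noise_scale = 1)
  # orthogonal columns: [(S^H S)^-1]_jj = R^2/|c_j|^2, measurement variance
  # frac/2 per quadrature, so the noise std reduces to 1/|c_j|
  expect_equal(core$noise_map[1, 1, 1], 1 / 2, tolerance = 1e-12)
  expect_equal(core$noise_map[1, 2, 1], 1 / 0.5, tolerance = 1e-12)
  # full sampling for comparison: same up to the 1/sqrt(R) SNR loss
  full <- megre:::sense_core(sens, diag(2), matrix(TRUE, 2, 1), zf = NULL,
                             noise_scale = 1)
  g <- (core$noise_map / full$noise_map) / sqrt(2)
  expect_equal(as.numeric(g[1, , 1]), c(1, 1), tolerance = 1e-12)
})

test_that("correction modes order image quality as expected under motion", {
  mk <- make_moving_kspace()
  ks <- mk$kspace; co <- coils24(); p <- phantom24()
  truth <- lapply(mk$protocol$te_list, function(te)
    megre:::echo_image(p, mk$protocol, te))
  rmse_of <- function(mode) {
    rec <- suppressWarnings(
      joint_moco_recon(ks, co$sensitivities, co$noise_cov, mk$trajectory,
                       mk$trajectory, mode, max_iter = 25, tol = 1e-8))
    vapply(1:2, function(e) rel_rmse(rec$images[, , , e], truth[[e]]), 1)
  }
  r_no <- rmse_of("NoCo"); r_mo <- rmse_of("MoCo")
  r_mb <- rmse_of("MoCo+B0Co")
  expect_true(all(r_mb < r_mo))
  expect_true(all(r_mo < r_no))
  # residual B0 artifact grows with TE under motion-only correction
  expect_gt(r_mo[2] / r_mo[1], 1)
  # with the true motion and field supplied, the corrected reconstruction
  # removes most of the artifact energy
  expect_lt(r_mb[1], 0.5 * r_no[1])
})

test_that("rigid motion is recovered from noiseless navigators", {
  p <- phantom24(); co <- coils24()
  pr <- proto24(nav_matrix = c(24, 24, 24))
  truth <- c(1.5, -0.8, 0.4, 0.8, -0.4, 1.2)
  tr <- trajectory_from_states(list(
    motion_state(),
    motion_state(translation = truth[1:3], rotation = truth[4:6])))
  navs <- simulate_navigators(p, co, pr, tr, noise_scale = 0, seed = 3)
  mot <- estimate_motion(navs)
  expect_equal(unname(mot[1, ]), rep(0, 6))
  expect_lt(max(abs(mot[2, 1:3] - truth[1:3])), 0.2)
  expect_lt(max(abs(mot[2, 4:6] - truth[4:6])), 0.35)
  expect_error(estimate_motion(structure(list(volumes = navs$volumes[1]),
                                         class = "navigator_series")),
               "navigator")
})

test_that("B0 changes are recovered, including beyond the phase ambiguity", {
  p <- phantom24(); co <- coils24()
  pr <- proto24(nav_matrix = c(24, 24, 24))
  # no drift: coefficients at the noise floor
  tr0 <- trajectory_from_states(rep(list(motion_state()), 3))
  navs0 <- simulate_navigators(p, co, pr, tr0, noise_scale = 0)
  b00 <- estimate_b0_change(navs0, NULL)
  expect_lt(max(abs(b00$b0_offset)), 1e-6)
  # offset + linear gradient, noiseless: within 1 percent
  tr1 <- trajectory_from_states(list(
    motion_state(),
    motion_state(b0_offset = 5, b0_gradient = c(0.05, 0, 0.02))))
  navs1 <- simulate_navigators(p, co, pr, tr1, noise_scale = 0)
  b01 <- estimate_b0_change(navs1, NULL)
  expect_lt(abs(b01$b0_offset[2] - 5), 0.05)
  expect_lt(abs(b01$b0_gradient[2, 1] - 0.05), 5e-4)
  expect_lt(abs(b01$b0_gradient[2, 3] - 0.02), 5e-4)
  expect_false(any(b01$wrapped))
  # 120 Hz exceeds the +/- 1/(2 nav_te) = 116 Hz ambiguity: a smooth ramp is
  # recovered only through temporal unwrapping, and the event is flagged
  trw <- trajectory_from_states(lapply(c(0, 60, 120), function(b)
    motion_state(b0_offset = b)))
  navsw <- simulate_navigators(p, co, pr, trw, noise_scale = 0)
  b0w <- estimate_b0_change(navsw, NULL)
  expect_lt(abs(b0w$b0_offset[3] - 120), 0.5)
  expect_true(b0w$wrapped[3])
})

test_that("motion and field estimation tolerate navigator noise", {
  p <- fixture("phantom32", function()
    make_phantom(c(32, 32, 32), c(1.5, 1.5, 1.5), seed = 11))
  co <- fixture("coils32", function()
    simulate_coils(c(32, 32, 32), c(1.5, 1.5, 1.5), 8, 0.1, seed = 12))
  pr <- acq_protocol(10.5, 0.035, c(0.0102, 0.0249), 12, c(32, 32, 32),
                     c(48, 48, 48), nav_matrix = c(32, 32, 32))
  truth <- c(1.5, -0.8, 0.4, 0.8, -0.4, 1.2)
  tr <- trajectory_from_states(list(
    motion_state(b0_offset = 0),
    motion_state(translation = truth[1:3], rotation = truth[4:6],
                 b0_offset = 4)))
  # navigator SNR about 20 in tissue
  base <- megre:::echo_image(p, pr, pr$nav_te)
  noise_scale <- max(Mod(base)) / 20
  errs <- sapply(1:2, function(s) {
    navs <- simulate_navigators(p, co, pr, tr, noise_scale = noise_scale,
                                seed = 40 + s)
    mot <- estimate_motion(navs)
    b0 <- estimate_b0_change(navs, mot)
    c(max(abs(mot[2, 1:3] - truth[1:3])),
      max(abs(mot[2, 4:6] - truth[4:6])),
      abs(b0$b0_offset[2] - 4))
  })
  expect_lt(max(errs[1, ]), 0.5)   # mm
  expect_lt(max(errs[2, ]), 1.0)   # degrees: the compact phantom carries
                                   # less rotational information than a head
  expect_lt(max(errs[3, ]), 0.5)   # Hz
})
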