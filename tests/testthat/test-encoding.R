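test_that("CAIPI patterns sample the prescribed lattice", {
  full <- caipi_pattern(8, 8, 1, 1)
  expect_true(all(full$mask))
  p23 <- caipi_pattern(12, 12, 2, 3, 1)
  expect_equal(sum(p23$mask), 24)                 # 1/6 of 144
  expect_equal(p23$total_r, 6L)
  # 2x2 shift 1: sampled kz parity alternates between successive sampled ky
  p22 <- caipi_pattern(8, 8, 2, 2, 1)
  for (ky in seq(0, 6, by = 2)) {
    kz_sampled <- which(p22$mask[ky + 1, ]) - 1
    expect_true(all(kz_sampled %% 2 == ((ky / 2) %% 2)))
  }
  # sampled fraction x R = 1 within rounding, across parameter grid
  for (rp in 1:3) for (rs in 1:3) for (sh in 0:(rs - 1)) {
    pat <- caipi_pattern(24, 24, rp, rs, sh)
    expect_lt(abs(mean(pat$mask) * pat$total_r - 1),
              pat$total_r * 24 / (24 * 24))
  }
  expect_error(caipi_pattern(8, 8, 2, 2, 2), "shift")
})

test_that("spoiled GRE signal has the correct limits and Ernst maximum", {
  # saturated recovery: alpha = 90, tr >> t1
  expect_equal(spoiled_gre_signal(90, 50, 1, te = 0.01, r2star = 47, m0 = 2),
               2 * exp(-0.01 * 47), tolerance = 1e-6)
  expect_equal(spoiled_gre_signal(0, 0.035, 1.5), 0)
  # Ernst angle maximizes the TE = 0 signal
  tr <- 0.035; t1 <- 1.5
  ernst <- acos(exp(-tr / t1)) * 180 / pi
  alphas <- seq(0.5, 60, by = 0.001)
  s <- spoiled_gre_signal(alphas, tr, t1)
  expect_lt(abs(alphas[which.max(s)] - ernst), 0.1)
  expect_error(spoiled_gre_signal(12, 0.035, 0), "t1")
})

test_that("protocol timing reproduces the published navigator intervals", {
  pr105 <- default_protocol(10.5, matrix = c(24, 24, 24))
  t105 <- protocol_timing(pr105)
  expect_equal(t105$nav_interval, 0.420)          # 12 TRs x 35 ms
  pr7 <- default_protocol(7, matrix = c(24, 24, 24))
  expect_equal(protocol_timing(pr7)$nav_interval, 0.540)
  # readout duration per line: 1/208 Hz = 4.81 ms, consistent with the
  # 4.9 ms echo spacing
  expect_equal(t105$readout_per_line, 1 / 208, tolerance = 1e-12)
  expect_lt(abs(t105$readout_per_line - 0.0049), 2e-4)
  expect_equal(t105$acq_time_per_echo, t105$n_lines / 208)
  expect_error(acq_protocol(10.5, 0.035, c(0.02, 0.01), 12, c(16, 16, 16),
                            c(32, 32, 32)), "increasing")
  expect_error(acq_protocol(10.5, 0.035, c(0.01, 0.04), 12, c(16, 16, 16),
                            c(32, 32, 32)), "< tr")
})

test_that("noiseless full sampling is an exact linear round trip", {
  p <- phantom16(); co <- coils16()
  pr <- acq_protocol(10.5, 0.035, c(0.0102, 0.0151), 12, c(16, 16, 16),
                     c(32, 32, 32), nav_matrix = c(8, 8, 8))
  ks <- forward_encode(p, co, pr, trajectory = NULL, noise_scale = 0)
  rec <- sense_recon(ks, co$sensitivities, co$noise_cov)
  for (e in 1:2) {
    truth <- megre:::echo_image(p, pr, pr$te_list[e])
    expect_lt(rel_rmse(rec$images[, , , e], truth), 1e-10)
  }
  # energy conservation of the unitary FFT convention (full sampling)
  img <- megre:::echo_image(p, pr, pr$te_list[1]) * co$sensitivities[, , , 1]
  expect_equal(sum(Mod(megre:::fft3(img))^2), sum(Mod(img)^2),
               tolerance = 1e-10)
})

test_that("forward encoding is linear in the object", {
  p <- phantom16(); co <- coils16()
  pr <- acq_protocol(10.5, 0.035, c(0.0102, 0.0151), 12, c(16, 16, 16),
                     c(32, 32, 32), rp = 2, rs = 2, caipi_shift = 1,
                     nav_matrix = c(8, 8, 8))
  p2 <- p
  p2$m0 <- p$m0 * 0.5 + 0.1 * (p$label_map != 0)
  psum <- p
  psum$m0 <- p$m0 + p2$m0
  k1 <- forward_encode(p, co, pr, NULL, 0)
  k2 <- forward_encode(p2, co, pr, NULL, 0)
  ks <- forward_encode(psum, co, pr, NULL, 0)
  expect_equal(ks$samples, k1$samples + k2$samples, tolerance = 1e-10)
})

test_that("encoded noise carries the channel covariance", {
  p <- phantom16(); co <- coils16()
  pr <- acq_protocol(10.5, 0.035, 0.0102, 12, c(16, 16, 16), c(32, 32, 32),
                     nav_matrix = c(8, 8, 8))
  k0 <- forward_encode(p, co, pr, NULL, noise_scale = 0)
  k1 <- forward_encode(p, co, pr, NULL, noise_scale = 0.5, seed = 21)
  nz <- k1$samples[, , , , 1] - k0$samples[, , , , 1]
  N <- matrix(nz, ncol = co$n_channels)           # iid noise draws per point
  emp <- Conj(t(N)) %*% N / nrow(N)
  expect_lt(max(Mod(emp - 0.25 * co$noise_cov)) / 0.25, 0.10)
  # determinism of the draw
  k2 <- forward_encode(p, co, pr, NULL, noise_scale = 0.5, seed = 21)
  expect_identical(k1$samples, k2$samples)
  # trajectory too short is an error
  short <- make_trajectory(1, seed = 1)
  expect_error(forward_encode(p, co, pr, short), "shorter")
})

test_that("a global frequency offset accrues phase linearly in TE", {
  p <- phantom16(); co <- coils16()
  es <- 0.0049
  pr <- acq_protocol(10.5, 0.035, c(0.0102, 0.0102 + es), 12, c(16, 16, 16),
                     c(32, 32, 32), nav_matrix = c(8, 8, 8))
  n_int <- ceiling(16 * 16 / pr$nav_interval_trs)
  tr <- trajectory_from_states(rep(list(motion_state(b0_offset = 10)), n_int))
  ks <- forward_encode(p, co, pr, tr, noise_scale = 0)
  rec <- sense_recon(ks, co$sensitivities, co$noise_cov)
  sup <- p$label_map != 0
  dphi <- Arg(rec$images[, , , 2] * Conj(rec$images[, , , 1])) -
    2 * pi * p$delta_f0 * es              # remove the static-field phase
  expect_lt(max(abs(dphi[sup] - 2 * pi * 10 * es)), 1e-6)
})

test_that("navigators carry the motion state and B0 phase", {
  p <- phantom24(); co <- coils24()
  pr <- proto24(nav_matrix = c(12, 12, 12))
  # identity trajectory, no noise: all volumes identical
  tr0 <- trajectory_from_states(rep(list(motion_state()), 3))
  navs0 <- simulate_navigators(p, co, pr, tr0, noise_scale = 0)
  expect_length(navs0$volumes, 3)
  expect_identical(navs0$volumes[[1]], navs0$volumes[[2]])
  # pure B0 offset: phase difference 2 pi f nav_te inside the support
  trb <- trajectory_from_states(list(motion_state(),
                                     motion_state(b0_offset = 5)))
  navsb <- simulate_navigators(p, co, pr, trb, noise_scale = 0)
  mag <- Mod(navsb$volumes[[1]])
  sup <- mag > 0.5 * max(mag)
  dphi <- Arg(navsb$volumes[[2]] * Conj(navsb$volumes[[1]]))
  expect_lt(max(abs(dphi[sup] - 2 * pi * 5 * pr$nav_te)), 1e-3)
  # pure translation: registration recovers the 3 mm shift
  trt <- trajectory_from_states(list(motion_state(),
                                     motion_state(translation = c(3, 0, 0))))
  navst <- simulate_navigators(p, co, pr, trt, noise_scale = 0)
  mot <- estimate_motion(navst)
  expect_lt(max(abs(mot[2, 1:3] - c(3, 0, 0))), 0.2)
  expect_error(simulate_navigators(p, co, proto24(nav_matrix = c(48, 12, 12)),
                                   tr0), "nav_matrix")
})

test_that("k-space container round-trips through disk", {
  p <- phantom16(); co <- coils16()
  pr <- acq_protocol(10.5, 0.035, 0.0102, 12, c(16, 16, 16), c(32, 32, 32),
                     rp = 2, rs = 1, nav_matrix = c(8, 8, 8))
  ks <- forward_encode(p, co, pr, NULL, noise_scale = 0.1, seed = 3)
  path <- file.path(withr::local_tempdir(), "kspace.rds")
  save_kspace(ks, path)
  back <- load_kspace(path)
  expect_identical(back$samples, ks$samples)
  expect_identical(back$pattern$mask, ks$pattern$mask)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$tr, 0.035)
})
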