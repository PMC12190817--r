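test_that("the Fisher matrix matches analytic and numeric derivatives", {
  spec <- signal_model_spec(80, 47, tr = 0.035, frequency = 5, n_samples = 96)
  # amplitude-only information at R2* = 0: J / sigma_J^2 = snr^2 tr
  spec0 <- signal_model_spec(100, 0, tr = 0.035, n_samples = 128)
  expect_equal(as.numeric(fisher_matrix(spec0, "A")), 100^2 * 0.035,
               tolerance = 1e-12)
  # finite-difference oracle for all parameter pairs
  params <- c("A", "R2star", "f", "phi0")
  F <- fisher_matrix(spec, params)
  expect_equal(F, t(F))
  expect_gt(min(eigen(F, symmetric = TRUE, only.values = TRUE)$values), 0)
  model <- function(th) th[1] * exp(-th[2] * spec$times) *
    exp(1i * (2 * pi * th[3] * spec$times + th[4]))
  th0 <- c(1, 47, 5, 0)
  h <- c(1e-6, 1e-3, 1e-4, 1e-6)
  D <- sapply(1:4, function(k) {
    tp <- th0; tm <- th0
    tp[k] <- tp[k] + h[k]; tm[k] <- tm[k] - h[k]
    (model(tp) - model(tm)) / (2 * h[k])
  })
  F_fd <- Re(Conj(t(D)) %*% D) / spec$sigma^2
  expect_equal(unname(F), unname(F_fd), tolerance = 1e-6)
  expect_error(fisher_matrix(spec, "bogus"), "unknown")
})

test_that("CRB extraction and closed forms are correct", {
  expect_equal(crb(diag(c(4, 25)), 1), 0.5)
  expect_equal(crb(diag(c(4, 25)), 2), 0.2)
  # any 2x2 matrix against the explicit inverse
  F <- matrix(c(5, 1.2, 1.2, 3), 2, 2)
  det <- 5 * 3 - 1.2^2
  expect_equal(crb(F, 1), sqrt(3 / det), tolerance = 1e-12)
  expect_equal(crb(F, 2), sqrt(5 / det), tolerance = 1e-12)
  expect_error(crb(matrix(0, 2, 2), 1), "singular")
  # slow-decay limit: CRB of R2* approaches the log-linear slope variance
  spec <- signal_model_spec(100, 0.05, tr = 0.02, n_samples = 256)
  t <- spec$times
  var_slope <- spec$sigma^2 / sum((t - mean(t))^2)   # OLS on log signal
  expect_equal(crb(fisher_matrix(spec, c("A", "R2star")), "R2star"),
               sqrt(var_slope), tolerance = 1e-3)
})

test_that("idealized CRBs obey the stated scalings and limits", {
  base <- crb_r2star_idealized(50, 47, 0.035)
  expect_equal(crb_r2star_idealized(100, 47, 0.035), base / 2,
               tolerance = 1e-12)
  expect_equal(crb_r2star_idealized(50, 47, 0.035, total_time = 2),
               base / sqrt(2), tolerance = 1e-12)
  expect_equal(crb_r2star_idealized(50, 47, 0.035, voxel_volume = 2),
               base * 2, tolerance = 1e-12)
  # J-invariance: continuum limit reached by J = 64
  for (f in list(crb_r2star_idealized, crb_frequency_idealized)) {
    v64 <- f(50, 47, 0.035, n_samples = 64)
    v512 <- f(50, 47, 0.035, n_samples = 512)
    expect_lt(abs(v64 / v512 - 1), 0.005)
  }
  # interior minimum of the time-normalized bound near a small multiple
  # of 1/R2*
  trs <- seq(0.005, 0.4, by = 0.005)
  vals <- vapply(trs, function(tr)
    crb_r2star_idealized(50, 47, tr, total_time = 1), 1)
  tr_min <- trs[which.min(vals)]
  expect_gt(tr_min, 1 / 47); expect_lt(tr_min, 4 / 47)
  # frequency bound: monotone decreasing in SNR
  f1 <- crb_frequency_idealized(50, 47, 0.035)
  f2 <- crb_frequency_idealized(80, 47, 0.035)
  expect_lt(f2, f1)
})

test_that("frequency CRB equals OLS at R2* = 0 and the complex-model bound", {
  # uniform weights: textbook OLS slope variance
  spec <- signal_model_spec(50, 0, tr = 0.035, n_samples = 128)
  t <- spec$times
  ols <- sqrt(spec$sigma^2 / sum((t - mean(t))^2)) / (2 * pi)
  got <- crb_frequency_idealized(50, 0, 0.035, total_time = 0.035,
                                 n_samples = 128)
  expect_equal(got, ols, tolerance = 1e-10)
  # phase-regression bound coincides with the full complex-signal Fisher
  # bound once amplitude, decay and initial phase are co-estimated
  spec2 <- signal_model_spec(80, 47, tr = 0.035, n_samples = 256)
  cf <- crb(fisher_matrix(spec2, c("A", "R2star", "f", "phi0")), "f")
  pr <- crb_frequency_idealized(80, 47, 0.035, total_time = 0.035)
  expect_equal(cf, pr, tolerance = 1e-10)
})

test_that("susceptibility bound is three times the relative frequency bound", {
  expect_equal(crb_chi(0, 4.47e8), 0)
  for (crbf in c(0.01, 1, 37)) for (f0 in c(2.98e8, 4.47e8)) {
    expect_equal(f0 * crb_chi(crbf, f0) / crbf, 3, tolerance = 1e-12)
  }
  # 1 Hz at 10.5 T: 6.71 ppb
  f0 <- 42.577e6 * 10.5
  expect_equal(crb_chi(1, f0) * 1e9, 6.71, tolerance = 1e-3)
  expect_error(crb_chi(1, 0), "f0")
})

test_that("ΔR2* summaries and normalization follow the worked arithmetic", {
  expect_equal(delta_r2star(c(47, 42), c(53, 51)), 7.5)
  expect_equal(delta_r2star(c(33, 29), c(37, 36)), 5.5)
  expect_equal(delta_r2star(c(40, 50), c(40, 50)), 0)
  expect_error(delta_r2star(1:3, 1:2), "paired")
  expect_equal(normalized_crb_r2star(0.75, 7.5), 0.1)
  expect_equal(normalized_crb_r2star(1.5, 7.5), 0.2)    # linear in the bound
  expect_error(normalized_crb_r2star(1, 0), "delta")
})

test_that("matched-TR search is consistent and monotone in SNR", {
  fb <- list(snr_te0 = 1, r2star = 31, tr = 0.045)
  same <- matched_tr(list(snr_te0 = 1, r2star = 31), fb,
                     tr_range = c(0.02, 0.09))
  expect_equal(same$tr_a, 0.045, tolerance = 1e-3)
  expect_lt(abs(same$reduction), 1e-2)
  # doubling field-A SNR strictly decreases the matched TR
  m1 <- matched_tr(list(snr_te0 = 1.5, r2star = 44.5), fb,
                   tr_range = c(0.005, 0.045))
  m2 <- matched_tr(list(snr_te0 = 3.0, r2star = 44.5), fb,
                   tr_range = c(0.005, 0.045))
  expect_lt(m2$tr_a, m1$tr_a)
  expect_error(matched_tr(list(snr_te0 = 100, r2star = 44.5), fb,
                          tr_range = c(0.04, 0.05)), "crossing")
})

test_that("CNR efficiency has the stated proportionalities", {
  base <- cnr_efficiency(500, 2.1, 47, 53)
  expect_equal(cnr_efficiency(1000, 2.1, 47, 53), 2 * base)
  # equal relative contrast and equal sqrt(T1) iSNR: ratio one
  a <- cnr_efficiency(500, 1.8, 33, 37)
  b <- cnr_efficiency(500 * sqrt(1.8 / 1.8), 1.8, 66, 74)
  expect_equal(a / b, 1, tolerance = 1e-12)
  expect_equal(base, 500 * sqrt(2.1) * 6 / 50, tolerance = 1e-12)
})

test_that("Monte-Carlo ML fits are deterministic per seed and near the bound", {
  spec <- signal_model_spec(150, 47, tr = 0.035, frequency = 3,
                            n_samples = 48)
  mc1 <- monte_carlo_crb_check(spec, n_reps = 300, seed = 5)
  mc2 <- monte_carlo_crb_check(spec, n_reps = 300, seed = 5)
  expect_identical(mc1, mc2)
  expect_equal(mc1$n_fail, 0)
  # CRB is a lower bound up to Monte-Carlo error
  expect_true(all(mc1$ratio > 0.9))
  expect_true(all(mc1$ratio < 1.25))
  expect_error(monte_carlo_crb_check(spec, n_reps = 10), "n_reps")
})
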