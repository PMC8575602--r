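test_that("instantaneous phase of pure tones matches closed forms", {
  fs <- 250; n <- 500
  t_ <- seq_len(n) / fs
  ph <- instantaneous_phase(rbind(cos(2 * pi * 10 * t_),
                                  sin(2 * pi * 10 * t_),
                                  cos(2 * pi * 10 * t_)), fs)
  interior <- 51:450
  # phase advances by 2*pi*f/fs per sample, within 1% away from edges
  inc <- diff(signal::unwrap(ph$phases[1, ]))[interior]
  expect_lt(max(abs(inc - 2 * pi * 10 / 250)), 0.01 * 2 * pi * 10 / 250)
  # identical channels give identical phase rows
  expect_identical(ph$phases[1, ], ph$phases[3, ])
  # sin lags cos by pi/2 (analytic-signal quadrature)
  d <- ph$phases[1, interior] - ph$phases[2, interior]
  d <- atan2(sin(d), cos(d))
  expect_lt(max(abs(d - pi / 2)), 0.02)
})

test_that("degenerate phase inputs are rejected", {
  expect_error(instantaneous_phase(rbind(rnorm(63), rnorm(63)), 100),
               "64 samples")
  x <- rbind(rnorm(100), 0)
  expect_error(instantaneous_phase(x, 100), "all-zero channel.*2")
})

test_that("phase-locking matrix satisfies its defining contracts", {
  fs <- 250; n <- 512
  phi <- matrix(runif(3 * n, -pi, pi), 3)
  phi[2, ] <- phi[1, ]                      # identical phase series
  pm <- structure(list(phases = phi, fs = fs, edge = rep(FALSE, n)),
                  class = "phase_matrix")
  C <- plv_matrix(pm)$values
  expect_equal(C[1, 2], 1)
  expect_equal(diag(C), rep(0, 3))          # C_pp = 0 by definition
  expect_equal(C, t(C))
  expect_true(all(C >= 0 & C <= 1))
})

test_that("phase-locking is invariant to a common phase offset", {
  set.seed(8)
  phi <- matrix(runif(4 * 300, -pi, pi), 4)
  pm <- function(p) structure(list(phases = p, fs = 1,
                                   edge = rep(FALSE, ncol(p))),
                              class = "phase_matrix")
  C1 <- plv_matrix(pm(phi))$values
  C2 <- plv_matrix(pm(phi + 1.234))$values
  expect_equal(C1, C2, tolerance = 1e-12)
})

test_that("standardized squared distance matches direct hand evaluation", {
  # 3 channels x 2 samples toy fixture, evaluated arithmetically
  ep <- rbind(c(0, 0), c(1, 2), c(3, 1))
  s1 <- sd(ep[, 1]); s2 <- sd(ep[, 2])
  d12 <- ((0 - 1) / s1)^2 + ((0 - 2) / s2)^2
  d13 <- ((0 - 3) / s1)^2 + ((0 - 1) / s2)^2
  d23 <- ((1 - 3) / s1)^2 + ((2 - 1) / s2)^2
  D <- distance_matrix(ep)$values
  expect_equal(D[1, 2], d12)
  expect_equal(D[1, 3], d13)
  expect_equal(D[2, 3], d23)
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 3))
  expect_equal(distance_matrix(ep, squared = FALSE)$values[1, 2], sqrt(d12))
})

test_that("distance matrix rejects samples with zero cross-channel spread", {
  ep <- rbind(c(1, 5, 2), c(1, 4, 7))
  expect_error(distance_matrix(ep), "sample\\(s\\) 1")
})

test_that("distance matrix is permutation-equivariant", {
  set.seed(12)
  ep <- matrix(rnorm(5 * 100), 5)
  D <- distance_matrix(ep)$values
  pidx <- c(3, 1, 5, 2, 4)
  Dp <- distance_matrix(ep[pidx, ])$values
  expect_equal(Dp, D[pidx, pidx])
})

test_that("filtration conversion maps both kinds onto [0, 1] weights", {
  C <- connectivity_matrix(rbind(c(0, 1, 0), c(1, 0, 0.5), c(0, 0.5, 0)),
                           kind = "C")
  w <- to_filtration(C)$values
  expect_equal(w[1, 2], 0)                  # C = 1 enters at eps = 0+
  expect_equal(w[1, 3], 1)                  # C = 0 enters last
  expect_equal(diag(w), rep(0, 3))
  D <- connectivity_matrix(rbind(c(0, 2, 6), c(2, 0, 10), c(6, 10, 0)),
                           kind = "D")
  wd <- to_filtration(D)$values
  expect_equal(wd[1, 3], 0.5)               # min-max: (6-2)/(10-2)
  expect_equal(range(wd[upper.tri(wd)]), c(0, 1))
  flat <- connectivity_matrix(matrix(3, 3, 3) - diag(3, 3), kind = "D")
  expect_warning(wf <- to_filtration(flat), "degenerate")
  expect_equal(wf$values[1, 2], 0.5)
})

test_that("raising the coupling raises within-cluster phase locking", {
  within_c <- function(cg) {
    cfg <- session_config(n_channels = 6, fs_acquire = 250, stimulus_s = 2,
                          cluster_channels = 1:4, coupling_gst = cg,
                          coupling_rsd = 0.1, noise_sd = 1, seed = 21)
    mean(vapply(1:10, function(i) {
      stim <- generate_trial(cfg, "GST", trial_index = i)[, 251:750]
      C <- plv_matrix(instantaneous_phase(stim, 250))$values
      mean(C[1:4, 1:4][upper.tri(C[1:4, 1:4])])
    }, numeric(1)))
  }
  lv <- vapply(c(0.3, 0.6, 0.9), within_c, numeric(1))
  expect_true(all(diff(lv) > 0))
})
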