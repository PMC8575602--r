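test_that("Vietoris-Rips enumeration obeys binomial counts and the max rule", {
  W <- matrix(0.4, 3, 3); diag(W) <- 0
  fc <- vietoris_rips(W)
  expect_equal(n_simplices(fc), 7)               # 3 + 3 + 1
  expect_equal(fc$values[[3]], 0.4)              # triangle enters at 0.4
  W19 <- rand_weights(19, seed = 2)
  fc19 <- vietoris_rips(W19)
  expect_equal(n_simplices(fc19), 19 + choose(19, 2) + choose(19, 3) +
                 choose(19, 4))                  # 5035
  # VR rule: simplex value = max pairwise weight
  Vm <- fc19$simplices[[4]]
  i <- 137
  v <- Vm[, i]
  expect_equal(fc19$values[[4]][i], max(W19[v, v]))
  ones <- matrix(1, 4, 4); diag(ones) <- 0
  fco <- vietoris_rips(ones)
  expect_equal(unlist(fco$values[-1], use.names = FALSE),
               rep(1, n_simplices(fco) - 4))
  expect_equal(fco$values[[1]], rep(0, 4))
})

test_that("the simplex-count cap triggers a helpful rejection", {
  W <- rand_weights(30, seed = 1)
  expect_error(vietoris_rips(W, cap = 1000), "cap")
})

test_that("persistence recovers the homology of known fixtures", {
  bc <- persistence(hollow_triangle(0.3))
  b0 <- bc[bc$dimension == 0, ]
  expect_equal(nrow(b0), 3)
  expect_equal(sum(is.infinite(b0$death)), 1)    # one essential component
  expect_equal(sort(b0$death[is.finite(b0$death)]), c(0.3, 0.3))
  b1 <- bc[bc$dimension == 1, ]
  expect_equal(nrow(b1), 1)
  expect_equal(b1$birth, 0.3)
  expect_true(is.infinite(b1$death))             # circle: essential loop

  bt <- persistence(tetra_boundary(0.2))
  expect_equal(sum(bt$dimension == 0 & is.infinite(bt$death)), 1)
  expect_equal(sum(bt$dimension == 1 & bt$death - bt$birth > 0), 0)
  b2 <- bt[bt$dimension == 2, ]
  expect_equal(nrow(b2), 1)                      # 2-sphere: one void
  expect_true(is.infinite(b2$death))
})

test_that("non-face-closed input is rejected", {
  fc <- filtered_complex(list(1, 2, c(1, 2), c(1, 2, 3)), c(0, 0, 0.1, 0.2))
  expect_error(persistence(fc), "face-closed")
})

test_that("Betti curves follow the half-open convention", {
  bc <- barcode_of(c(0, 1), c(0, 0.2), c(Inf, 0.5))
  B <- betti_curves(bc, c(0, 0.2, 0.4, 0.5, 0.9))
  expect_equal(B[, "beta0"], rep(1L, 5))
  expect_equal(B[, "beta1"], c(0L, 1L, 1L, 0L, 0L))
})

test_that("persistence Betti curves match the brute-force rank oracle", {
  for (seed in 1:10) {
    M <- sample(4:8, 1)
    fc <- vietoris_rips(rand_weights(M, seed = seed))
    bc <- persistence(fc)
    grid <- sort(unique(unlist(fc$values)))
    B <- betti_curves(bc, grid)
    for (g in seq_along(grid)) {
      expect_equal(unname(B[g, 1:3]), as.integer(betti_oracle(fc, grid[g])),
                   info = sprintf("seed %d, eps %.3f", seed, grid[g]))
    }
  }
})

test_that("beta0 is non-increasing along a Vietoris-Rips filtration", {
  for (seed in 11:15) {
    fc <- vietoris_rips(rand_weights(7, seed = seed))
    grid <- sort(unique(unlist(fc$values)))
    b0 <- betti_curves(persistence(fc), grid)[, "beta0"]
    expect_true(all(diff(b0) <= 0))
  }
})

test_that("barcodes are invariant under vertex relabelling", {
  W <- rand_weights(7, seed = 31)
  p <- c(4, 1, 7, 3, 6, 2, 5)
  bc1 <- as.data.frame(persistence(vietoris_rips(W)))
  bc2 <- as.data.frame(persistence(vietoris_rips(W[p, p])))
  key <- function(b) b[do.call(order, b), ]
  expect_equal(key(bc1), key(bc2), ignore_attr = TRUE)
})

test_that("Euler curve of the hexagon crosses zero at the sixth edge", {
  fc <- vietoris_rips(hexagon_weights(), max_dim = 3)
  ec <- euler_curve(fc)
  expect_equal(ec$chi[ec$epsilon == 0], 6)       # isolated vertices: chi = M
  expect_equal(ec$entropy[ec$epsilon == 0], log(6))
  for (k in 1:6)                                  # each edge decrements chi
    expect_equal(ec$chi[abs(ec$epsilon - k / 10) < 1e-12], 6L - k)
  expect_true(is.infinite(ec$entropy[ec$chi == 0][1]))
  expect_equal(attr(ec, "transition_point"), 0.6)
})

test_that("full small complexes have the binomial Euler characteristic", {
  ones <- matrix(1, 4, 4); diag(ones) <- 0
  ec <- euler_curve(vietoris_rips(ones, max_dim = 3))
  expect_equal(ec$chi[ec$epsilon == 1], 4 - 6 + 4 - 1)
})

test_that("Euler-Poincare identity holds on random complexes", {
  for (seed in 41:48) {
    fc <- vietoris_rips(rand_weights(6, seed = seed))
    grid <- sort(unique(unlist(fc$values)))
    ec <- euler_curve(fc, grid)
    B <- betti_curves(persistence(fc), grid, max_dim = 3)
    chi_b <- B[, 1] - B[, 2] + B[, 3] - B[, 4]
    expect_equal(ec$chi, unname(chi_b))
  }
})

test_that("transition point follows the negative-peak rule", {
  # two vertices, one edge: S falls from log 2 to 0 at the edge weight
  fc <- filtered_complex(list(1, 2, c(1, 2)), c(0, 0, 0.7))
  expect_equal(attr(euler_curve(fc), "transition_point"), 0.7)
  # isolated vertices only: S constant, no negative peak
  fc2 <- filtered_complex(list(1, 2, 3), c(0, 0, 0))
  expect_true(is.na(attr(euler_curve(fc2), "transition_point")))
  # first-zero rule picks the first chi sign change
  fc3 <- vietoris_rips(hexagon_weights())
  expect_equal(phase_transition_point(euler_curve(fc3), rule = "first-zero"),
               0.6)
})
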