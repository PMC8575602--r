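test_that("transition comparison orders conditions by median", {
  labs <- c(rep("GST", 3), rep("RSD", 3))
  expect_equal(transition_comparison(c(.3, .3, .3, .5, .5, .5), labs),
               "GST_first")
  expect_equal(transition_comparison(c(.5, .5, .5, .3, .3, .3), labs),
               "RSD_first")
  expect_equal(transition_comparison(c(.4, .4, .4, .4, .4, .4), labs), "tie")
  expect_warning(out <- transition_comparison(c(NA, NA, NA, .4, .4, .4), labs),
                 "no defined transition")
  expect_equal(out, "tie")
})

test_that("leave-one-out rate is 1 for separated features", {
  labs <- c(rep("RSD", 10), rep("GST", 5))
  v <- c(rnorm(10, 0, 0.01), rnorm(5, 1, 0.01))
  expect_equal(as.numeric(distinguishing_rate(v, labs, "gst_high")), 1)
  expect_equal(as.numeric(distinguishing_rate(-v, labs, "gst_low")), 1)
})

test_that("constant features fall back to the majority class", {
  # brute-force check of the LOO threshold rule on constant features:
  # every training fold prefers the all-majority threshold, so each
  # held-out trial is predicted as the majority class
  labs <- c(rep("RSD", 30), rep("GST", 10))
  v <- rep(0.7, 40)
  expected <- mean("RSD" == labs)
  expect_equal(as.numeric(distinguishing_rate(v, labs, "gst_high")), expected)
  expect_equal(as.numeric(distinguishing_rate(v, labs, "gst_low")), expected)
})

test_that("the held-out trial cannot influence its own threshold", {
  set.seed(3)
  labs <- rep(c("GST", "RSD"), each = 6)
  v <- c(rnorm(6, 1), rnorm(6, 0))
  # recomputing the threshold with trial i removed must reproduce the
  # prediction the LOO loop made for trial i
  thr_wo <- function(i) {
    u <- sort(unique(v[-i]))
    cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
    acc <- vapply(cand, function(th)
      mean(ifelse(v[-i] > th, "GST", "RSD") == labs[-i]), numeric(1))
    cand[which.max(acc)]
  }
  pred <- vapply(seq_along(v), function(i)
    if (v[i] > thr_wo(i)) "GST" else "RSD", "")
  expect_equal(as.numeric(distinguishing_rate(v, labs, "gst_high")),
               mean(pred == labs))
})

test_that("single-condition input is rejected", {
  expect_error(distinguishing_rate(1:5, rep("GST", 5)), "2 trials")
})

test_that("balanced accuracy accompanies the plain rate", {
  labs <- c(rep("RSD", 8), rep("GST", 4))
  v <- c(rnorm(8, 0, .01), rnorm(4, 1, .01))
  r <- distinguishing_rate(v, labs, "gst_high")
  expect_equal(attr(r, "balanced"), 1)
})

test_that("session analysis assembles one summary row per band and kind", {
  cfg <- small_config(seed = 31)
  fit <- eeg_tda(generate_session(cfg), bands = c("alpha", "theta"),
                 kinds = "C")
  expect_s3_class(fit, "eeg_tda")
  expect_equal(nrow(fit$summary), 2)
  expect_equal(fit$summary$band, c("alpha", "theta"))
  expect_equal(unique(fit$summary$matrix_kind), "C")
  expect_equal(nrow(fit$features), 2 * 16)
  expect_true(all(fit$summary$distinguishing_rate >= 0 &
                    fit$summary$distinguishing_rate <= 1))
  expect_true(all(fit$summary$pe_direction %in%
                    c("GST>RSD", "GST<RSD", "mixed")))
  # single-band request contains exactly that band
  one <- eeg_tda(generate_session(cfg), bands = "alpha", kinds = "D")
  expect_equal(unique(one$features$band), "alpha")
})

test_that("distinguishing rate grows with the coupling separation", {
  rate_at <- function(cg) {
    cfg <- small_config(coupling_gst = cg, coupling_rsd = 0.15, seed = 63)
    ft <- eeg_tda(generate_session(cfg), bands = "alpha", kinds = "C")$features
    # direction matched to the generator's actual effect (coherence lowers
    # the pooled persistent entropy of the phase-locking filtration)
    as.numeric(distinguishing_rate(ft$H_alt, ft$condition, "gst_low"))
  }
  rates <- vapply(c(0.15, 0.5, 0.9), rate_at, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.8)
})
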