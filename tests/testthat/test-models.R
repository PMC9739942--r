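one <- function(...) {
  args <- list(...)
  f <- make_features(1, F = 1, a_r = 1)
  for (nm in names(args)) f[[nm]] <- args[[nm]]
  f$duration <- 1 / f$F
  f
}

test_that("magnitude-range model: d = K * a_r^0.1", {
  expect_equal(estimate_base(one(a_r = 7), 0), 0)
  expect_equal(estimate_base(one(a_r = 1), 1), 1)
  expect_equal(estimate_base(one(a_r = 1024), 0.5), 1)  # 1024^0.1 = 2
  expect_equal(estimate_base(one(a_r = 0), 2), 0)
  expect_error(estimate_base(one(a_r = -1), 1), "a_r")
})

test_that("adaptive-form model: d = K1 * F + K2 * a_r^0.1", {
  f <- make_features(6, F = seq(0.8, 1.2, length.out = 6))
  expect_equal(estimate_proposed(f, 0, 0.7), estimate_base(f, 0.7))
  expect_equal(estimate_proposed(one(F = 1), 0.7, 0), 0.7)
  expect_equal(estimate_proposed(one(F = 0.9, a_r = 1024), 0.3, 0.2),
               0.3 * 0.9 + 0.2 * 2)
})

test_that("inverse-frequency fourth-root model", {
  expect_equal(estimate_mikov(one(F = 2, a_max = 18, a_min = 2), 1), 1)
  expect_equal(estimate_mikov(one(F = 1), 0), 0)
  f1 <- one(F = 1, a_max = 9, a_min = 2)
  f2 <- one(F = 2, a_max = 9, a_min = 2)
  expect_equal(estimate_mikov(f2, 0.8), estimate_mikov(f1, 0.8) / 2)
  expect_error(estimate_mikov(one(F = 0), 1), "frequency")
})

test_that("mean-acceleration model and its grouping variants", {
  f <- one(F = 1, a_max = 3, a_min = 2, a_mean = 1)
  expect_equal(estimate_bylemans(f, 10), 1)        # 1^(1/2.7) = 1
  expect_equal(estimate_bylemans(one(a_mean = 0), 5), 0)
  f2 <- one(F = 1, a_max = 3, a_min = 2, a_mean = 2)
  expect_equal(estimate_bylemans(f2, 10), 2 * estimate_bylemans(f, 10))
  # inverse-root variant differs in shape but agrees at unit inputs
  expect_equal(estimate_bylemans(f, 10, variant = "inverse_root"), 1)
  f3 <- one(F = 1, a_max = 18, a_min = 2, a_mean = 1)
  expect_false(isTRUE(all.equal(estimate_bylemans(f3, 10),
                                estimate_bylemans(f3, 10,
                                                  variant = "inverse_root"))))
})

test_that("frequency + variance affine model", {
  expect_equal(estimate_shin_park(one(a_v = 3), 0, 0, 1.4), 1.4)
  expect_equal(estimate_shin_park(one(F = 2, a_v = 3), 1, 0, 3), 5)
  # affine in (F, a_v): midpoint value is the mean of endpoint values
  fa <- one(F = 0.8, a_v = 1); fb <- one(F = 1.2, a_v = 5)
  fm <- one(F = 1.0, a_v = 3)
  expect_equal(estimate_shin_park(fm, 0.4, 0.1, 0.2),
               (estimate_shin_park(fa, 0.4, 0.1, 0.2) +
                estimate_shin_park(fb, 0.4, 0.1, 0.2)) / 2)
})

test_that("height power-law model", {
  subj <- subject_profile("s", height = 1.8)
  expect_equal(estimate_sharp_yu(one(), subj, 0.9, 0, 0, 0), 0.9)
  f <- one(F = 0.5, a_max = 4, a_min = 2)
  expect_equal(estimate_sharp_yu(f, subj, 1, 0, 1, 1), 1)  # 2 * 0.5
  expect_error(estimate_sharp_yu(one(a_max = 2, a_min = 2), subj,
                                 1, 0, -1, 0), "negative exponent")
  # log d linear in logs: doubling a_r multiplies d by 2^K3
  f2 <- one(F = 0.5, a_max = 6, a_min = 2)
  expect_equal(estimate_sharp_yu(f2, subj, 1, 0.3, 0.7, 1) /
               estimate_sharp_yu(f, subj, 1, 0.3, 0.7, 1), 2^0.7)
})

test_that("estimators increase with the acceleration range", {
  f_lo <- one(F = 1, a_max = 6, a_min = 2, a_r = 4, a_mean = 3)
  f_hi <- one(F = 1, a_max = 10, a_min = 2, a_r = 8, a_mean = 3)
  subj <- subject_profile()
  expect_gt(estimate_base(f_hi, 0.4), estimate_base(f_lo, 0.4))
  expect_gt(estimate_proposed(f_hi, 0.3, 0.2), estimate_proposed(f_lo, 0.3, 0.2))
  expect_gt(estimate_mikov(f_hi, 0.4), estimate_mikov(f_lo, 0.4))
  expect_gt(estimate_bylemans(f_hi, 2), estimate_bylemans(f_lo, 2))
  expect_gt(estimate_sharp_yu(f_hi, subj, 1, 1, 0.5, 1),
            estimate_sharp_yu(f_lo, subj, 1, 1, 0.5, 1))
})

test_that("single-constant models scale linearly in K", {
  f <- make_features(5)
  for (est in list(estimate_base, estimate_mikov, estimate_bylemans))
    expect_equal(est(f, 0.9), 3 * est(f, 0.3))
})

test_that("the parameter container enforces each model's constant set", {
  p <- model_params("proposed", c(K1 = 0.3, K2 = 0.2))
  expect_equal(sl_estimate(make_features(3), p),
               estimate_proposed(make_features(3), 0.3, 0.2))
  expect_error(model_params("base", c(K1 = 1)), "requires constants")
  expect_error(model_params("shin_park", c(K1 = 1, K2 = 2)), "requires")
  expect_error(sl_estimate(make_features(3),
                           model_params("sharp_yu",
                                        c(K1 = 1, K2 = 1, K3 = 1, K4 = 1))),
               "subject_profile")
})

test_that("magnitude-input models are orientation invariant end to end", {
  sc <- gait_scenario(seed = 21, n_strides = 25, noise_sd = 0.2)
  g <- generate_trace(sc)
  tr <- g$trace
  base_feats <- segment_strides(accel_magnitude(tr), tr$t)
  p_base <- model_params("base", c(K = 0.4))
  p_prop <- model_params("proposed", c(K1 = 0.3, K2 = 0.2))
  p_sp <- model_params("shin_park", c(K1 = 0.4, K2 = 0.05, K3 = 0.1))
  d0 <- list(sl_estimate(base_feats, p_base),
             sl_estimate(base_feats, p_prop),
             sl_estimate(base_feats, p_sp))
  set.seed(33)
  for (k in 1:10) {
    R <- rotation3()
    axes <- cbind(tr$ax, tr$ay, tr$az) %*% t(R)
    trr <- accel_trace(tr$t, axes[, 1], axes[, 2], axes[, 3])
    feats <- segment_strides(accel_magnitude(trr), trr$t)
    expect_equal(nrow(feats), nrow(base_feats))
    d1 <- list(sl_estimate(feats, p_base), sl_estimate(feats, p_prop),
               sl_estimate(feats, p_sp))
    for (j in 1:3)
      expect_lt(max(abs(d1[[j]] - d0[[j]]) / abs(d0[[j]])), 1e-9)
  }
})
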