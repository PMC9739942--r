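test_that("single-constant fit has the proportional closed form", {
  # noiseless proportional data: (a_r^0.1, d_ref) = (1, 2), (2, 4) -> K = 2
  s <- data.frame(a_r = c(1, 1024, 1, 1024, 1), F = 1,
                  d_ref = c(2, 4, 2, 4, 2))
  fit <- sl_fit("base", s)
  expect_equal(unname(coef(fit)), 2)
  expect_lt(fit$rss, 1e-20)
  # explicit closed form on noisy data
  set.seed(4)
  s2 <- make_features(30)
  s2$d_ref <- 0.4 * s2$a_r^0.1 + rnorm(30, sd = 0.05)
  x <- s2$a_r^0.1
  expect_equal(unname(coef(sl_fit("base", s2))),
               sum(s2$d_ref * x) / sum(x^2))
})

test_that("two-regressor fit recovers true constants from synthetic gait", {
  strides <- pooled_speed_strides()
  fit <- sl_fit("proposed", strides)
  expect_lt(abs(coef(fit)[["K1"]] - 0.35), 0.02)
  expect_lt(abs(coef(fit)[["K2"]] - 0.20), 0.02)
})

test_that("recovery error shrinks to zero as length noise vanishes", {
  errs <- vapply(c(0.02, 0.01, 0.005, 0), function(s) {
    fit <- sl_fit("proposed", pooled_speed_strides(length_noise_sd = s))
    max(abs(coef(fit) - c(0.35, 0.20)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[4], 1e-10)
})

test_that("every fit beats or ties a surrounding grid search", {
  set.seed(55)
  subj <- subject_profile(height = 1.75)
  for (k in 1:5) {
    s <- make_features(40, F = runif(40, 0.7, 1.2), a_r = runif(40, 3, 9),
                       a_v = runif(40, 0.5, 3))
    s$d_ref <- 0.35 * s$F + 0.2 * s$a_r^0.1 + rnorm(40, sd = 0.03)
    for (m in sl_models()) {
      fit <- sl_fit(m, s, subject = subj)
      k0 <- coef(fit)
      obj <- function(kv) {
        p <- model_params(m, kv)
        est <- sl_estimate(s, p, subject = subj)
        if (fit$objective == "log_length") sum((log(s$d_ref) - log(est))^2)
        else sum((s$d_ref - est)^2)
      }
      for (ci in seq_along(k0)) {
        if (m == "sharp_yu" && names(k0)[ci] == "K2") next  # pinned to 1
        grid <- k0[ci] + seq(-0.5, 0.5, length.out = 101) *
          max(abs(k0[ci]), 0.1)
        rss_grid <- vapply(grid, function(v) {
          kv <- k0; kv[ci] <- v; obj(kv)
        }, numeric(1))
        expect_lte(fit$rss, min(rss_grid) + 1e-10)
      }
    }
  }
})

test_that("rank-deficient designs are rejected naming the regressors", {
  s <- make_features(10, F = rep(1, 10), a_r = rep(5, 10))
  s$a_v <- 2
  s$d_ref <- 1.3
  expect_error(sl_fit("shin_park", s), "collinear")
  expect_error(sl_fit("proposed", s), "collinear")
})

test_that("log-space fit rejects non-positive lengths or ranges", {
  s <- make_features(10)
  s$d_ref <- c(-0.1, rep(1.3, 9))
  expect_error(sl_fit("sharp_yu", s, subject = subject_profile()),
               "positive")
})

test_that("fits need a minimum number of reference strides", {
  s <- make_features(4); s$d_ref <- 1.3
  expect_error(sl_fit("base", s), "at least 5")
  s6 <- make_features(5); s6$d_ref <- 1.2 + 0.1 * seq_len(5)
  expect_error(sl_fit("sharp_yu", s6, subject = subject_profile()),
               "at least 6")
})

test_that("least squares is invariant to stride ordering", {
  strides <- pooled_speed_strides(n_each = 40)
  set.seed(8)
  perm <- sample(nrow(strides))
  for (m in c("base", "proposed", "shin_park"))
    expect_equal(coef(sl_fit(m, strides)),
                 coef(sl_fit(m, strides[perm, ])))
})

test_that("sharp_yu predictions are preserved despite the K2 = 1 pinning", {
  # d generated from a different (K1, K2) split of the same h^K2 product
  s <- make_features(50, F = runif(50, 0.7, 1.2), a_r = runif(50, 3, 9))
  subj <- subject_profile(height = 1.8)
  s$d_ref <- 0.5 * 1.8^1.7 * s$a_r^0.3 * s$F^0.8
  fit <- sl_fit("sharp_yu", s, subject = subj)
  expect_equal(coef(fit)[["K2"]], 1)
  expect_equal(predict(fit, s), s$d_ref, tolerance = 1e-8)
})

test_that("speed profiles store increasing frequency with speed", {
  gen <- function(seed, speed)
    generate_trace(gait_scenario(seed = seed, n_strides = 60,
                                 speed = speed))$strides
  trials <- list(slow = gen(31, "slow"), normal = gen(32, "normal"),
                 fast = gen(33, "fast"))
  prof <- fit_speed_profiles(trials)
  expect_length(prof, 3L)
  fs <- vapply(prof, `[[`, numeric(1), "mean_F")
  expect_true(all(diff(fs) > 0))
  # identical duplicate trials give identical profiles
  prof2 <- fit_speed_profiles(trials)
  expect_identical(prof, prof2)
  # single speed degenerates to static constants
  p1 <- fit_speed_profiles(trials["normal"])
  expect_length(p1, 1L)
  expect_equal(p1[[1]]$params$constants,
               coef(sl_fit("proposed", trials$normal)))
})

test_that("joined-speeds calibration behaves like one pooled fit", {
  s <- pooled_speed_strides(n_each = 40)
  # duplication invariance
  one <- sl_fit("base", s)
  three <- fit_joined("base", list(s, s, s))
  expect_equal(coef(three), coef(one))
  # nested-model inequality: pooled RSS >= sum of per-window RSS
  gen <- function(seed, K1) {
    g <- generate_trace(gait_scenario(seed = seed, n_strides = 60, K1 = K1))
    g$strides
  }
  a <- gen(41, 0.25); b <- gen(42, 0.45)
  pooled <- fit_joined("proposed", list(a, b))
  expect_gte(pooled$rss,
             sl_fit("proposed", a)$rss + sl_fit("proposed", b)$rss - 1e-12)
})

test_that("predicted values are invariant to a regressor/constant rescale", {
  s <- pooled_speed_strides(n_each = 40)
  fit <- sl_fit("proposed", s)
  s2 <- s
  s2$F <- s$F * 2          # rescaled frequency regressor
  pred <- estimate_proposed(s2, coef(fit)[["K1"]] / 2, coef(fit)[["K2"]])
  expect_equal(pred, predict(fit, s))
})

test_that("tune/evaluate split is disjoint, ordered and covers the trial", {
  g <- generate_trace(gait_scenario(seed = 77, n_strides = 60, speed = "fast"))
  sp <- calibration_split(g$strides, tune_seconds = 20)
  expect_equal(nrow(sp$tune) + nrow(sp$eval), nrow(g$strides))
  expect_lt(max(sp$tune$t_start), min(sp$eval$t_start))
  expect_lt(max(sp$tune$t_start - g$strides$t_start[1]), 20)
})
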