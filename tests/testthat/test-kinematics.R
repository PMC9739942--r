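test_that("finite differences are exact for linear series, endpoints included", {
  t <- sort(runif(20, 0, 5))
  expect_equal(finite_difference(2 * t, t), rep(2, 20))
})

test_that("central differences are exact for quadratics at interior points", {
  t <- seq(0, 2, by = 0.1)
  d <- finite_difference(t^2, t)
  i <- 2:(length(t) - 1)
  expect_equal(d[i], 2 * t[i])
})

test_that("interior error for sin(t) obeys the Taylor remainder bound", {
  h <- 0.01
  t <- seq(0, 2 * pi, by = h)
  d <- finite_difference(sin(t), t)
  i <- 2:(length(t) - 1)
  expect_lt(max(abs(d[i] - cos(t[i]))), h^2 / 6)
})

test_that("finite differencing is linear and rejects bad input", {
  t <- seq(0, 1, by = 0.05)
  f <- sin(3 * t); g <- t^3
  expect_equal(finite_difference(2 * f + 5 * g, t),
               2 * finite_difference(f, t) + 5 * finite_difference(g, t))
  expect_error(finite_difference(1:2, 1:2), "at least 3")
  expect_error(finite_difference(1:3, c(0, 0, 1)), "duplicate|decreasing")
})

test_that("kinematics of stationary and uniformly moving markers", {
  t <- seq(0, 3, by = 0.01)
  still <- marker_trajectory("M1", t, rep(1, length(t)), rep(2, length(t)),
                             rep(0.5, length(t)))
  k <- marker_kinematics(still)
  expect_equal(max(abs(k$velocity)), 0)
  expect_equal(max(abs(k$acceleration)), 0)

  lin <- marker_trajectory("M2", t, t, rep(0, length(t)), rep(1, length(t)))
  kl <- marker_kinematics(lin)
  mid <- 30:250   # away from endpoints and filter start-up
  expect_equal(unname(kl$velocity[mid, 1]), rep(1, length(mid)),
               tolerance = 1e-10)
  expect_lt(max(abs(kl$acceleration[mid, ])), 1e-8)
})

test_that("sinusoidal trajectory velocity amplitude matches omega * A", {
  A <- 0.12; om <- 2 * pi * 1
  t <- seq(0, 10, by = 0.01)
  traj <- marker_trajectory("M3", t, A * sin(om * t), rep(0, length(t)),
                            rep(1, length(t)))
  k <- marker_kinematics(traj)
  expect_equal(max(abs(k$velocity[100:900, 1])), om * A, tolerance = 0.03)
})

test_that("reference strides recover constructed overground geometry", {
  # heel with flat stances centered at x = 0, 1.2, 2.4 m
  sc <- gait_scenario(seed = 9, n_strides = 2, route = "polygon",
                      loop_length_m = 1000)
  mk <- generate_markers(sc, stride_length_m = 1.2)
  rs <- reference_strides(mk$markers$M7)
  expect_equal(nrow(rs), 2L)
  expect_equal(rs$d_ref, c(1.2, 1.2), tolerance = 0.01)
})

test_that("treadmill belt compensation reconstructs stride length", {
  # constant stride timing + exact geometry: the identity d = belt * dt
  # holds to rounding; stance centroid times then differ by exactly one
  # stride period
  # stride period of exactly 100 samples keeps every stance identical on
  # the sampling grid, so centroid displacements vanish
  sc <- gait_scenario(seed = 5, n_strides = 20, route = "treadmill",
                      f_jitter = 0, stride_frequency = 1.0)
  mk <- generate_markers(sc, stride_length_m = 1.30, marker_noise_sd = 0)
  # stationary stance points: net displacement below one stride length
  m7 <- mk$markers$M7
  expect_lt(abs(m7$x[nrow(m7)] - m7$x[1]), 1.30)
  rs <- reference_strides(m7, belt_speed = mk$belt_speed)
  expect_equal(nrow(rs), length(mk$stride_lengths))
  expect_equal(mean(rs$d_ref), mean(mk$stride_lengths), tolerance = 0.01)
  # pure kinematic identity: with belt only, d = belt_speed * interval
  # (first and final stride excluded: their stances are truncated by the
  # recording edges)
  full <- 2:(nrow(rs) - 1)
  expect_equal(rs$d_ref[full], mk$belt_speed * rs$duration[full],
               tolerance = 1e-9)
})

test_that("jittered stance positions are recovered within 2 cm", {
  sc <- gait_scenario(seed = 6, n_strides = 20, route = "polygon",
                      loop_length_m = 1000)
  mk <- generate_markers(sc, stride_length_m = 1.30, stance_jitter_sd = 0.005)
  rs <- reference_strides(mk$markers$M7)
  expect_equal(nrow(rs), length(mk$stride_lengths))
  expect_lt(max(abs(rs$d_ref - mk$stride_lengths)), 0.02)
})

test_that("reference stride lengths are invariant to in-plane rotation", {
  sc <- gait_scenario(seed = 6, n_strides = 15, route = "polygon",
                      loop_length_m = 1000)
  mk <- generate_markers(sc, stride_length_m = 1.30)
  m7 <- mk$markers$M7
  th <- 0.7
  rot <- marker_trajectory("M7", m7$t,
                           cos(th) * m7$x - sin(th) * m7$y,
                           sin(th) * m7$x + cos(th) * m7$y, m7$z)
  expect_equal(reference_strides(rot)$d_ref,
               reference_strides(m7)$d_ref, tolerance = 1e-9)
})

test_that("too few stance phases yield an empty result with a warning", {
  t <- seq(0, 2, by = 0.01)
  walkby <- marker_trajectory("M7", t, t, rep(0, length(t)), rep(0, length(t)))
  expect_warning(rs <- reference_strides(walkby), "fewer than 2 stance")
  expect_equal(nrow(rs), 0L)
})
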