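# shared fixtures, built in code

# a random 3-D rotation matrix (det +1), independent of package internals
rotation3 <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# small stride-feature table with controllable spread
make_features <- function(n = 10, F = seq(0.8, 1.1, length.out = n),
                          a_r = seq(4, 8, length.out = n),
                          a_mean = 3, a_v = 1.5) {
  data.frame(F = F, duration = 1 / F, a_max = a_r + 2, a_min = 2,
             a_r = a_r, a_mean = a_mean, a_v = a_v)
}

# strides pooled over the three treadmill speeds, the calibration design
# used throughout for parameter recovery
pooled_speed_strides <- function(seeds = c(11, 12, 13), n_each = 167,
                                 length_noise_sd = 0.02, ...) {
  do.call(rbind, Map(function(seed, speed)
    generate_trace(gait_scenario(seed = seed, n_strides = n_each,
                                 speed = speed,
                                 length_noise_sd = length_noise_sd,
                                 ...))$strides,
    seeds, c("slow", "normal", "fast")))
}
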