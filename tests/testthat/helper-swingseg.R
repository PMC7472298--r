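# Shared fixtures, all built in code.

# a 3.5 s / 700-sample window time base at 200 Hz
window_t <- function(t0 = 0, fs = 200, n = 700) t0 + (seq_len(n) - 1) / fs

# canonical example points on that window
example_points <- function() dividing_points(0.5, 1.75, 2.5, 3.25)

# noiseless generator configuration
quiet_config <- function(...) {
  generator_config(noise_acc_g = 0, noise_gyro_dps = 0, ...)
}

# one simulated swing (optionally noiseless), fixed seeds
sim_swing <- function(seed = 42, cfg = generator_config(), club = "driver",
                      placements = PLACEMENTS) {
  prof <- sample_subject_profile(cfg, seed = seed + 1000)
  simulate_swing(prof, cfg, club = club, placements = placements, seed = seed)
}

# a tiny synthetic imu_recording with a single acceleration spike
spike_recording <- function(spike_t = 1.0, spike_g = 4, n = 1200, fs = 200,
                            placement = "wrist") {
  t <- (seq_len(n) - 1) / fs
  acc <- rbind(numeric(n), numeric(n), 1 + spike_g * exp(-((t - spike_t)^2) / (2 * 0.02^2)))
  gyro <- matrix(0, 3, n)
  imu_recording(t, acc, gyro, placement, fs)
}

expect_swingseg_error <- function(expr, id) {
  expect_error(expr, class = id)
}
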