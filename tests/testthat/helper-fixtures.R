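# Shared fixtures. A 111-frame window at 30 fps leaves 100 frames after the
# 10% cut: exactly three strides at 0.9 strides/s, so the band-limited
# profiles sit on DFT bins and zero-noise recovery is exact.

aligned_hip_spec <- function(noise_sd = 0, dropout = list(), seed = 1L,
                             duration = 111L) {
  gait_signal_spec(fundamental = 0.9,
                   harmonics = list(c(1, 12, 0), c(2, 3, 0.6)),
                   offset = 160, noise_sd = noise_sd, dropout = dropout,
                   duration = duration, fps = 30, seed = seed)
}

aligned_knee_spec <- function(noise_sd = 0, dropout = list(), seed = 2L,
                              duration = 111L) {
  gait_signal_spec(fundamental = 0.9,
                   harmonics = list(c(1, 20, 0.3), c(2, 10, 1.1)),
                   offset = 140, noise_sd = noise_sd, dropout = dropout,
                   duration = duration, fps = 30, seed = seed)
}

make_walker <- function(noise_sd = 0, dropout_far = list(), seed = 1L,
                        duration = 111L, ...) {
  generate_walker(walker_spec(
    hip_spec = aligned_hip_spec(noise_sd = noise_sd, seed = seed,
                                duration = duration),
    knee_spec = aligned_knee_spec(noise_sd = noise_sd, seed = seed + 1L,
                                  duration = duration),
    dropout_far = dropout_far, ...
  ))
}

default_subject <- list(age = 25, mass = 68, height = 1.72, gender = "female")
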