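# shared fixtures, all generated in code

default_grid <- wavelength_grid()

# short noiseless protocol for fast deterministic tests
quiet_protocol <- function(baseline_duration = 20, occlusion_duration = 40,
                           recovery_duration = 40, noise_sd = 0, ...) {
  occlusion_protocol(baseline_duration = baseline_duration,
                     occlusion_duration = occlusion_duration,
                     recovery_duration = recovery_duration,
                     noise_sd = noise_sd, ...)
}

# small full-pipeline configuration (16x16 frames, 100 s protocol)
small_config <- function(protocol = quiet_protocol(), ...) {
  pipeline_config(protocol = protocol,
                  camera = list(height = 16, width = 16), ...)
}

# count local maxima of a sensitivity row above a relative threshold
n_local_maxima <- function(q, rel_threshold) {
  thr <- rel_threshold * max(q)
  hits <- 0
  for (i in seq_along(q)) {
    left <- if (i == 1) -Inf else q[i - 1]
    right <- if (i == length(q)) -Inf else q[i + 1]
    if (q[i] > thr && q[i] >= left && q[i] > right) hits <- hits + 1
  }
  hits
}

# uniform reflectance cube sequence built directly from the Beer-Lambert
# forward model on the virtual band centers (no camera in the loop)
forward_cube_series <- function(conc, centers, lib, d = 1, h = 4, w = 4) {
  eps <- extinction_at(lib, centers)
  lapply(seq_len(ncol(conc)), function(i) {
    A <- as.numeric(eps %*% conc[, i]) * d
    cube <- array(rep(10^(-A), each = h * w), c(h, w, length(centers)))
    sfaox:::new_spectral_cube(cube, centers, kind = "reflectance")
  })
}
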