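# Shared fixtures: reference-center parameters, protocols, and the video
# fixture used by tracking and round-trip tests.

human_center_params <- function(eta0 = 10) {
  visco_params(k0 = 0.12, k1 = 0.30, eta1 = 0.59, eta0 = eta0)
}

mouse_protocol <- function() pressure_protocol(-0.03, -0.345, 40e-6)
human_protocol <- function() pressure_protocol(-0.03, -0.345, 70e-6)

# random strictly positive parameter draw on a wide log scale
random_params <- function() {
  v <- exp(stats::runif(6, log(0.02), log(20)))
  visco_params(k0 = v[1], k1 = v[2], eta1 = v[3], eta0 = v[4],
               k2 = v[5], eta2 = v[6])
}

# aspiration video with a pre-step holding tongue; returns truth as well
make_aspiration_video <- function(params = human_center_params(),
                                  protocol = mouse_protocol(),
                                  duration = 5, onset = 5,
                                  noise_sd = 0.01, seed = 1,
                                  scene = video_scene()) {
  n <- onset + round(duration * 75) + 1
  tt <- ((seq_len(n) - 1) - onset) / 75
  F0 <- step_force(protocol)
  base <- 6 * scene$pixel_size # tongue drawn in by the holding pressure
  motion <- base + ifelse(tt > 0, creep(pmax(tt, 0), "modified_zener", params, F0), 0)
  list(video = render_video(motion, scene, noise_sd = noise_sd, seed = seed),
       motion = motion, base = base, onset = onset, scene = scene,
       truth_px = (motion - base) / scene$pixel_size)
}

# brute-force Mann-Whitney AUC oracle: pair counting over all pos/neg pairs
auc_pair_oracle <- function(scores, labels) {
  sp <- scores[labels]; sn <- scores[!labels]
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  mean(cmp)
}
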