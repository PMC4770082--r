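test_that("zero-dispersion viable embryos sit exactly at the reference center", {
  spec <- cohort_spec("human", n_viable = 10, n_nonviable = 0,
                      viable_spread = 0, label_noise = 0, seed = 1)
  coh <- sample_cohort(spec)
  expect_equal(unique(coh$k1), 0.30)
  expect_equal(unique(coh$eta1), 0.59)
  expect_equal(unique(coh$k0), 0.12)
  expect_true(all(coh$blastocyst))
})

test_that("cohort sampling is seed-deterministic and validates its spec", {
  s <- cohort_spec("mouse", n_viable = 15, n_nonviable = 20, seed = 7)
  expect_identical(sample_cohort(s), sample_cohort(s))
  expect_error(cohort_spec(viable_center = c(k1 = -1, eta1 = 1, k0 = 1)), "k1")
  expect_error(cohort_spec(label_noise = 1.5), "label_noise")
})

test_that("viable mechanics are tighter than non-viable, eta0 uninformative", {
  coh <- sample_cohort(cohort_spec("human", n_viable = 200, n_nonviable = 200,
                                   seed = 11))
  v <- coh[coh$mech_class, ]; n <- coh[!coh$mech_class, ]
  expect_lt(var(v$k1), var(n$k1))
  # within-class spread to the class centroid in (k1, log eta1, k0)
  d_to_centroid <- function(df) {
    M <- cbind(df$k1, log(df$eta1), df$k0)
    ctr <- colMeans(M)
    mean(sqrt(rowSums(sweep(M, 2, ctr)^2)))
  }
  expect_lt(d_to_centroid(v), d_to_centroid(n))
  # eta0 drawn from one shared distribution: similar location and spread
  expect_lt(abs(median(log(v$eta0)) - median(log(n$eta0))), 0.2)
  # labels flip at about the label_noise rate
  expect_equal(mean(coh$blastocyst != coh$mech_class), 0.1, tolerance = 0.5)
})

test_that("rendered traces equal the closed form plus calibrated noise", {
  pro <- human_protocol()
  p <- human_center_params()
  tr0 <- render_trace(p, pro, noise_sd = 0, duration = 5, seed = 1)
  expect_equal(tr0$depth_m,
               creep(tr0$time_s, "modified_zener", p, step_force(pro)))
  expect_identical(render_trace(p, pro, noise_sd = 1e-7, seed = 5),
                   render_trace(p, pro, noise_sd = 1e-7, seed = 5))
  trn <- render_trace(p, pro, noise_sd = 1e-7, duration = 1000 / 75, seed = 2)
  resid <- trn$depth_m - creep(trn$time_s, "modified_zener", p, step_force(pro))
  expect_equal(sd(resid), 1e-7, tolerance = 0.1)
  expect_error(render_trace(p, pro, noise_sd = -1), "noise_sd")
})

test_that("video rendering produces the scene it claims", {
  sc <- video_scene()
  v0 <- render_video(rep(0, 3), sc, noise_sd = 0, seed = 1)
  expect_identical(v0[[1]], v0[[2]]) # static scene, no noise: bit-identical
  expect_identical(render_video(rep(0, 2), sc, noise_sd = 0.02, seed = 9),
                   render_video(rep(0, 2), sc, noise_sd = 0.02, seed = 9))
  # a 3 px step moves pixels only near the leading edge
  step_m <- c(0, 0, 3 * sc$pixel_size)
  vs <- render_video(step_m + 6 * sc$pixel_size, sc, noise_sd = 0, seed = 1)
  dif <- abs(vs[[3]] - vs[[2]])
  changed <- which(dif > 0.05, arr.ind = TRUE)
  expect_gt(nrow(changed), 0)
  edge_cols <- sc$opening_column + 1 - c(6 + 3, 6) # 1-based band around the edge
  expect_true(all(changed[, "col"] >= min(edge_cols) - 20 &
                  changed[, "col"] <= max(edge_cols) + 20))
  expect_true(all(changed[, "row"] >= sc$lumen_center_row - sc$inner_radius &
                  changed[, "row"] <= sc$lumen_center_row + sc$inner_radius + 2))
  expect_error(video_scene(embryo_radius = 10, inner_radius = 18), "nonphysical")
})

test_that("confocal renders expose the structure the scoring relies on", {
  # smooth ring, no attenuation: annulus carries the ring level
  stk <- render_confocal(n_puncta = 0, ring_level = 0.4, cyto_level = 0.1,
                         attenuation_scale = Inf, n_slices = 3, noise_sd = 0,
                         seed = 1)
  expect_identical(stk[[1]], stk[[2]]) # attenuation off: identical slices
  img <- stk[[1]]
  ring_px <- img[128, round(127 + 0.95 * 60) + 1] # on the annulus
  expect_equal(ring_px, 0.4, tolerance = 0.3)
  expect_lt(img[128, 128], 0.15) # interior near cytoplasm level
  expect_identical(render_confocal(seed = 4), render_confocal(seed = 4))
  expect_error(render_confocal(n_slices = 0), "n_slices")
  # attenuation scales slice k by exp(-k/scale)
  stka <- render_confocal(n_puncta = 0, attenuation_scale = 2, n_slices = 4,
                          noise_sd = 0, seed = 1)
  expect_equal(max(stka[[3]]) / max(stka[[1]]), exp(-2 / 2), tolerance = 1e-6)
})

test_that("stacks survive a TIFF round trip with sidecar metadata", {
  dir <- withr::local_tempdir()
  v <- render_video(c(0, 1e-6, 2e-6), video_scene(), noise_sd = 0.01, seed = 2)
  path <- file.path(dir, "video.tiff")
  write_stack(v, path, bits = 8L)
  back <- read_stack(path)
  expect_s3_class(back, "image_sequence")
  expect_length(back, 3)
  expect_equal(attr(back, "pixel_size"), 0.5e-6)
  expect_equal(back[[2]], v[[2]], tolerance = 1 / 255) # 8-bit quantisation
  coh <- sample_cohort(cohort_spec(n_viable = 4, n_nonviable = 4, seed = 3))
  cpath <- file.path(dir, "cohort.csv")
  write_cohort(coh, cpath)
  back2 <- read_cohort(cpath)
  expect_equal(back2$k1, coh$k1, tolerance = 1e-12)
  expect_identical(back2$blastocyst, coh$blastocyst)
})
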