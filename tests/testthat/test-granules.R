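test_that("per-slice normalization is gain-invariant and flattens attenuation", {
  withr::with_seed(3, {
    base <- matrix(runif(64 * 64), 64, 64)
  })
  stk <- list(base, 3.7 * base) # same slice up to a global gain
  norm <- normalize_stack(stk)
  expect_equal(norm[[1]], norm[[2]], tolerance = 1e-12)
  # constant slice passes through unchanged
  flat <- matrix(0.42, 16, 16)
  expect_identical(normalize_stack(list(flat))[[1]], flat)
  expect_error(normalize_stack(list()), "empty")
  # rendered attenuation: ring brightness even across slices after normalization
  stka <- render_confocal(n_puncta = 0, ring_level = 0.4,
                          attenuation_scale = 3, n_slices = 8, seed = 5)
  norm_a <- normalize_stack(stka)
  ring_means <- vapply(norm_a, function(s)
    circumferential_profile(s, list(center = c(127, 127), radius = 60))$mean,
    numeric(1))
  expect_lt(diff(range(ring_means)) / mean(ring_means), 0.05)
})

test_that("projection behaves as max/mean with single-slice identity", {
  s1 <- matrix(1:12 / 12, 3, 4)
  expect_identical(project_stack(list(s1)), s1)
  s2 <- matrix(12:1 / 12, 3, 4)
  pmaxed <- project_stack(list(s1, s2), "max")
  pmeaned <- project_stack(list(s1, s2), "mean")
  expect_true(all(pmaxed >= pmeaned))
  expect_equal(pmaxed, pmax(s1, s2))
  # a punctum present in one slice survives the max projection in full
  blank <- matrix(0, 32, 32); dotted <- blank; dotted[16, 16] <- 0.9
  expect_equal(project_stack(list(blank, dotted))[16, 16], 0.9)
})

test_that("cell detection recovers the rendered geometry and fails on junk", {
  stk <- render_confocal(center = c(127, 127), radius = 60, n_puncta = 40,
                         attenuation_scale = 3, n_slices = 6, seed = 9)
  img <- project_stack(normalize_stack(stk))
  g1 <- locate_cell(img)
  expect_lt(max(abs(g1$center - c(127, 127))), 2.5)
  expect_lt(abs(g1$radius - 60), 2.5)
  expect_identical(locate_cell(img)[c("center", "radius")],
                   g1[c("center", "radius")]) # deterministic
  expect_error(locate_cell(matrix(0.3, 64, 64)), "blank")
  noise <- withr::with_seed(2, matrix(runif(128 * 128), 128, 128))
  expect_error(locate_cell(noise), "hough_circle|locate_cell")
})

test_that("the circumferential profile measures what it should", {
  # constant image: mean = v, sd = 0, exactly
  flat <- matrix(0.37, 128, 128)
  gs <- circumferential_profile(flat, list(center = c(63, 63), radius = 40))
  expect_identical(gs$mean, 0.37)
  expect_equal(gs$sd, 0, tolerance = 1e-12)
  # uniform rendered ring at 0.95R recovered within 2%
  stk <- render_confocal(n_puncta = 0, ring_level = 0.5, cyto_level = 0,
                         attenuation_scale = Inf, n_slices = 1, noise_sd = 0,
                         seed = 1)
  gs2 <- circumferential_profile(stk[[1]], list(center = c(127, 127), radius = 60))
  expect_equal(gs2$mean, 0.5 * mean(exp(-((seq(0.90, 1, length.out = 7) - 0.95)^2) /
                                           (2 * 0.05^2) * 60^2 / 60^2)),
               tolerance = 0.05)
  # profile mean rotation-invariant: rotate the image 90 degrees about
  # the grid center (127.5, 127.5), with the cell rendered there
  stkp <- render_confocal(center = c(127.5, 127.5), n_puncta = 30,
                          n_slices = 1, seed = 7)
  img <- stkp[[1]]
  rot <- t(img)[, nrow(img):1] # 90-degree rotation of a square matrix
  geom_c <- list(center = c(127.5, 127.5), radius = 60)
  p0 <- circumferential_profile(img, geom_c)
  p90 <- circumferential_profile(rot, geom_c)
  expect_equal(p90$mean, p0$mean, tolerance = 0.01)
  expect_error(circumferential_profile(flat, list(center = c(5, 5), radius = 40)),
               "clipped")
})

test_that("punctate rings score a higher angular s.d. than smooth rings", {
  smooth <- render_confocal(n_puncta = 0, ring_level = 0.5, n_slices = 1,
                            noise_sd = 0.003, seed = 11)
  punct <- render_confocal(n_puncta = 50, ring_level = 0.1, puncta_amp = 0.7,
                           n_slices = 1, noise_sd = 0.003, seed = 11)
  geom <- list(center = c(127, 127), radius = 60)
  sd_s <- circumferential_profile(project_stack(normalize_stack(smooth)), geom)$sd
  sd_p <- circumferential_profile(project_stack(normalize_stack(punct)), geom)$sd
  expect_gt(sd_p, 2 * sd_s)
  # doubling the puncta count at fixed ring level raises the angular s.d.
  p1 <- render_confocal(n_puncta = 15, ring_level = 0.1, n_slices = 1, seed = 13)
  p2 <- render_confocal(n_puncta = 30, ring_level = 0.1, n_slices = 1, seed = 13)
  expect_gt(circumferential_profile(p2[[1]], geom)$sd * 1.05,
            circumferential_profile(p1[[1]], geom)$sd)
})

test_that("group comparison reports Wilcoxon and quartile strata", {
  r <- compare_groups(c(1, 2, 3, 4, 5), c(6, 7, 8, 9, 10))
  expect_equal(r$overall$p_value, 2 / 252, tolerance = 1e-12)
  expect_equal(r$overall$median_a, 3)
  withr::with_seed(41, {
    a <- rnorm(24, 1); b <- rnorm(24, 3)
    ka <- runif(24); kb <- runif(24)
  })
  rq <- compare_groups(a, b, covariate_a = ka, covariate_b = kb)
  expect_length(rq$by_quartile, 4)
  expect_lt(rq$overall$p_value, 1e-4)
  expect_error(compare_groups(1:2, 1:5), ">= 3")
})

test_that("the full scoring pipeline separates granule-rich from depleted cells", {
  score_of <- function(dense, seed) {
    stk <- render_confocal(n_puncta = if (dense) 60 else 20,
                           attenuation_scale = 4, n_slices = 5, seed = seed)
    score_stack(stk)$mean
  }
  rich <- vapply(1:5, function(s) score_of(TRUE, s), numeric(1))
  poor <- vapply(1:5, function(s) score_of(FALSE, 100 + s), numeric(1))
  expect_lt(wilcoxon_rank_sum(rich, poor)$p_value, 0.05)
  expect_gt(median(rich), median(poor))
})
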