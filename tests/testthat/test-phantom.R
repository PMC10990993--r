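test_that("phantom generation is deterministic given spec and seed", {
  spec <- phantom_spec(frames = 8L, noise_sigma = 0.05, seed = 81,
                       closures = list(list(frames = c(3, 5), position = 0.5)))
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$run$intensities, b$run$intensities)
  expect_identical(a$masks$masks, b$masks$masks)
  expect_identical(lapply(a$outlines, `[[`, "points"),
                   lapply(b$outlines, `[[`, "points"))
})

test_that("early frames do not depend on how many frames are requested", {
  s1 <- phantom_spec(frames = 6L, noise_sigma = 0.05, seed = 82)
  s2 <- phantom_spec(frames = 12L, noise_sigma = 0.05, seed = 82)
  a <- generate_phantom(s1)
  b <- generate_phantom(s2)
  expect_identical(a$run$intensities[1:6, , ], b$run$intensities[1:6, , ])
})

test_that("closure events split the truth into exactly two cavities", {
  spec <- phantom_spec(frames = 10L, seed = 83,
                       closures = list(list(frames = c(4, 7), position = 0.55)))
  ph <- generate_phantom(spec)
  counts <- vapply(1:10, function(f)
    find_cavities(ph$masks$masks[f, , ])$count, 1L)
  expect_equal(counts[4:7], rep(2L, 4))
  expect_equal(counts[-(4:7)], rep(1L, 6))
})

test_that("a noise-free phantom is exactly two-valued inside the tube box", {
  ph <- generate_phantom(phantom_spec(frames = 4L, seed = 84))
  tube <- ph$masks$masks[1, , ]
  idx <- which(tube, arr.ind = TRUE)
  box <- ph$run$intensities[1,
                            min(idx[, 1]):max(idx[, 1]),
                            min(idx[, 2]):max(idx[, 2])]
  expect_setequal(unique(as.vector(box)), c(0.15, 1.0))
})

test_that("truth mask area tracks the analytic tube area", {
  spec <- phantom_spec(frames = 2L, width_time_amp = 0, seed = 85)
  ph <- generate_phantom(spec)
  cl <- vtshape:::sample_centreline(spec)
  seg <- sqrt(diff(cl$r)^2 + diff(cl$c)^2)
  mid_halfw <- (cl$halfw[-1] + cl$halfw[-length(cl$halfw)]) / 2
  analytic <- sum(seg * 2 * mid_halfw)
  L <- sum(seg)
  observed <- sum(ph$masks$masks[1, , ])
  # rasterization error bounded by ~half the outline perimeter (~2L + ends)
  expect_lt(abs(observed - analytic), (2 * L + 4 * max(cl$halfw)) / 2)
})

test_that("ground truth invariants hold: anchors, ROI containment, outlines", {
  spec <- phantom_spec(frames = 6L, seed = 86,
                       closures = list(list(frames = c(2, 4), position = 0.5)))
  ph <- generate_phantom(spec)
  expect_true(ph$masks$roi_used$mask[ph$anchors$larynx[1], ph$anchors$larynx[2]])
  expect_true(ph$masks$roi_used$mask[ph$anchors$lips[1], ph$anchors$lips[2]])
  for (f in 1:6)
    expect_true(all(!(ph$masks$masks[f, , ] & !ph$masks$roi_used$mask)))
  expect_equal(length(ph$outlines), 6L)
  # closure-frame truth outlines enclose both cavities' pixels
  m <- ph$masks$masks[3, , ]
  idx <- which(m, arr.ind = TRUE)
  pts_yz <- cbind(idx[, 2], idx[, 1])
  o <- ph$outlines[[3]]
  inside <- vapply(seq_len(nrow(pts_yz)), function(i)
    winding_inside(pts_yz[i, ], o$points), TRUE)
  expect_true(all(inside))
})

test_that("geometry leaving the image bounds is refused", {
  big <- phantom_spec(rows = 24L, cols = 24L, frames = 2L,
                      centreline = cbind(c(20, 10, 4), c(20, 12, 4)),
                      width = 10)
  expect_error(generate_phantom(big), "bounds")
})

test_that("the validation battery is fixed and generates cleanly", {
  suite <- default_validation_suite(1)
  expect_equal(names(suite), c("clean", "noisy", "closure", "bias", "combined"))
  expect_equal(length(suite), 5L)
  for (s in suite) {
    expect_s3_class(s, "phantom_spec")
    expect_equal(c(s$rows, s$cols, s$frames), c(64L, 64L, 50L))
  }
  expect_equal(suite$noisy$noise_sigma, 0.085)
  expect_equal(suite$bias$bias$amplitude, 0.30)
  expect_equal(length(suite$closure$closures), 1L)
  # small-frame variants of each spec generate without error
  for (s in suite) {
    s$frames <- 3L
    expect_s3_class(generate_phantom(s)$run, "image_run")
  }
})

test_that("the combined stressor run still has a bimodal ROI histogram", {
  spec <- default_validation_suite(3)$combined
  spec$frames <- 10L
  ph <- generate_phantom(spec)
  model <- fit_threshold(ph$run, ph$masks$roi_used)
  expect_true(model$bimodality_ok)
  expect_equal(length(model$mode_locations), 2L)
})
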