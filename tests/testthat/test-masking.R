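test_that("variance map matches closed forms and a two-pass oracle", {
  expect_true(all(compute_variance_map(image_run(array(3, c(5, 6, 6)))) == 0))

  alt <- array(0, c(4, 2, 2))
  alt[, 1, 1] <- c(0, 1, 0, 1)
  vm <- compute_variance_map(image_run(alt))
  expect_equal(vm[1, 1], 0.25)
  expect_equal(vm[2, 2], 0)

  set.seed(31)
  arr <- array(runif(20 * 7 * 9), c(20, 7, 9))
  vm2 <- compute_variance_map(image_run(arr))
  oracle <- matrix(0, 7, 9)
  for (r in 1:7) for (cc in 1:9) {
    x <- arr[, r, cc]
    mu <- sum(x) / length(x)
    oracle[r, cc] <- sum((x - mu)^2) / length(x)
  }
  expect_equal(unclass(vm2), oracle, tolerance = 1e-10,
               ignore_attr = TRUE)

  expect_error(compute_variance_map(image_run(array(1, c(1, 4, 4)))),
               "at least 2")
})

test_that("ROI seeding selects strictly-above-quantile pixels", {
  set.seed(32)
  vm <- matrix(0, 10, 10)
  hot <- sample(100, 10)
  vm[hot] <- runif(10, 1, 2)
  roi <- seed_roi(structure(vm, class = "variance_map"), quantile = 0.90)
  expect_identical(sort(which(roi$mask)), sort(hot))

  set.seed(33)
  vm2 <- matrix(runif(64), 8, 8)     # all-distinct values
  roi2 <- seed_roi(structure(vm2, class = "variance_map"), quantile = 1e-9)
  expect_equal(sum(roi2$mask), 63L)
  expect_false(roi2$mask[which.min(vm2)])

  expect_identical(seed_roi(vm2, 0.5)$mask, seed_roi(vm2, 0.5)$mask)
  expect_error(seed_roi(matrix(0, 4, 4), 0.5), "identically zero")
  expect_error(seed_roi(vm2, 1.2), "between 0 and 1")
})

test_that("polygon edits add, remove, and compose with removal precedence", {
  empty <- region_of_interest(matrix(FALSE, 10, 10))
  rect <- cbind(c(1.5, 4.5, 4.5, 1.5), c(2.5, 2.5, 6.5, 6.5))  # rows 2-4, cols 3-6
  r1 <- edit_roi(empty, additions = list(rect))
  expect_equal(sum(r1$mask), 12L)
  expect_true(all(r1$mask[2:4, 3:6]))

  r2 <- edit_roi(r1, removals = list(rect))
  expect_identical(r2$mask, empty$mask)

  other <- cbind(c(3.5, 8.5, 8.5, 3.5), c(4.5, 4.5, 8.5, 8.5))  # rows 4-8, cols 5-8
  r3 <- edit_roi(empty, additions = list(rect), removals = list(other))
  expect_false(any(r3$mask[4, 5:6]))       # overlap removed
  expect_true(all(r3$mask[2:3, 3:6]))

  expect_error(edit_roi(empty, additions = list(rect[1:2, ])), "3")
  expect_error(edit_roi(empty, additions = list(rect + 100)), "bounds")
  expect_equal(length(r3$provenance), 2L)
})

test_that("threshold lands in the density valley of a bimodal sample", {
  set.seed(35)
  vals <- c(rnorm(5000, 0.2, 0.05), rnorm(5000, 0.8, 0.05))
  rv <- run_from_values(vals)
  model <- fit_threshold(rv$run, rv$roi)
  expect_true(model$bimodality_ok)
  expect_gt(model$threshold, 0.45)
  expect_lt(model$threshold, 0.55)
  expect_lt(model$mode_locations[1], model$threshold)
  expect_gt(model$mode_locations[2], model$threshold)

  # two exact point masses: threshold strictly between them
  rv2 <- run_from_values(rep(c(10, 200), each = 500))
  m2 <- fit_threshold(rv2$run, rv2$roi)
  expect_gt(m2$threshold, 10)
  expect_lt(m2$threshold, 200)
})

test_that("unimodal and degenerate distributions are flagged, not guessed", {
  set.seed(36)
  rv <- run_from_values(rnorm(4000, 0.5, 0.1))
  expect_warning(m <- fit_threshold(rv$run, rv$roi), "not bimodal")
  expect_false(m$bimodality_ok)
  expect_true(is.na(m$threshold))
  expect_error(classify_run(rv$run, rv$roi, m), "not finite")

  rvc <- run_from_values(rep(1, 100))
  expect_error(fit_threshold(rvc$run, rvc$roi), "degenerate")
  expect_error(fit_threshold(rv$run,
                             region_of_interest(matrix(FALSE, 64, 64))),
               "empty")
})

test_that("threshold is affine-equivariant up to grid resolution", {
  set.seed(37)
  vals <- c(rnorm(4000, 0.2, 0.05), rnorm(4000, 0.8, 0.05))
  rv <- run_from_values(vals)
  t1 <- fit_threshold(rv$run, rv$roi)$threshold
  a <- 37; b <- 5
  rv2 <- run_from_values(a * vals + b)
  t2 <- fit_threshold(rv2$run, rv2$roi)$threshold
  grid_step <- a * diff(range(vals)) / 511
  expect_lt(abs(t2 - (a * t1 + b)), 2 * grid_step)
})

test_that("classification is the ROI-gated elementwise comparison", {
  set.seed(38)
  arr <- array(runif(6 * 12 * 12), c(6, 12, 12))
  run <- image_run(arr)
  roi <- region_of_interest(matrix(runif(144) < 0.6, 12, 12))
  thr <- 0.5
  ms <- classify_run(run, roi, thr)
  oracle <- array(FALSE, dim(arr))
  for (f in 1:6) for (r in 1:12) for (cc in 1:12)
    oracle[f, r, cc] <- roi$mask[r, cc] && arr[f, r, cc] < thr
  expect_identical(ms$masks, oracle)
  # subset-of-ROI invariant
  for (f in 1:6) expect_true(all(!(ms$masks[f, , ] & !roi$mask)))

  hi <- classify_run(image_run(arr + 10), roi, thr)
  expect_false(any(hi$masks))
})
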