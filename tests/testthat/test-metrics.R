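regular_polygon <- function(n, r = 1, cx = 0, cy = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  tract_outline(cbind(cx + r * cos(th), cy + r * sin(th)))
}

test_that("Dice score follows its defining arithmetic", {
  set.seed(71)
  x <- matrix(runif(100) < 0.4, 10, 10)
  expect_equal(dice_score(x, x), 1.0)

  a <- matrix(FALSE, 4, 4); a[1, 1:4] <- TRUE
  b <- matrix(FALSE, 4, 4); b[3, 1:4] <- TRUE
  expect_equal(dice_score(a, b), 0.0)

  c1 <- matrix(FALSE, 4, 4); c1[1, 1:4] <- TRUE
  c2 <- matrix(FALSE, 4, 4); c2[1, 3:4] <- TRUE; c2[2, 1:2] <- TRUE
  expect_equal(dice_score(c1, c2), 0.5)   # 2*2 / (4+4)

  expect_error(dice_score(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)),
               "undefined")
  expect_error(dice_score(a, matrix(TRUE, 3, 3)), "differ")
})

test_that("Dice is symmetric, bounded, and monotone in overlap", {
  set.seed(72)
  x <- matrix(runif(400) < 0.5, 20, 20)
  y <- matrix(runif(400) < 0.5, 20, 20)
  d <- dice_score(x, y)
  expect_equal(d, dice_score(y, x))
  expect_gte(d, 0); expect_lte(d, 1)
  shared <- which(x & y)
  if (length(shared) > 1) {
    y2 <- y; y2[shared[1]] <- FALSE
    expect_lt(dice_score(x, y2), d)
  }
})

test_that("the Dice matrix is symmetric with unit diagonal", {
  set.seed(73)
  sets <- lapply(1:5, function(i) matrix(runif(64) < 0.5, 8, 8))
  names(sets) <- paste0("A", 1:5)
  m <- dice_matrix(sets)
  expect_identical(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 5))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(m[i, j], dice_score(sets[[i]], sets[[j]]))
  expect_equal(unname(dice_matrix(list(sets[[1]], sets[[1]], sets[[1]]))),
               matrix(1, 3, 3))
})

test_that("arc-length resampling gives equal spacing along the contour", {
  poly <- regular_polygon(100)
  rs <- resample_contour(poly, 153L)
  expect_equal(rs$n_sites, 153L)
  pos <- arc_positions_on_polygon(rs$sites, poly$points)
  expect_false(anyNA(pos))
  gaps <- diff(pos)
  L <- 100 * 2 * sin(pi / 100)
  expect_true(all(abs(gaps - L / 153) / (L / 153) < 1e-6))
  expect_equal(rs$sites[1, ], poly$points[1, ], ignore_attr = TRUE)
})

test_that("resampling an equally spaced contour to the same n is a fixed point", {
  poly <- regular_polygon(40)
  rs <- resample_contour(poly, 40L)
  expect_equal(rs$sites, poly$points, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("resampled perimeter converges to the source perimeter", {
  # smooth closed curve: low-frequency radial wobble
  th <- 2 * pi * (0:39) / 40
  o <- tract_outline(cbind((3 + 0.4 * cos(3 * th)) * cos(th),
                           (3 + 0.4 * cos(3 * th)) * sin(th)))
  per <- function(p) sum(sqrt(rowSums(diff(rbind(p, p[1, ]))^2)))
  L0 <- per(o$points)
  L10 <- per(resample_contour(o, 400L)$sites)
  expect_lt(abs(L10 - L0) / L0, 0.001)
})

test_that("disagreement profiles match closed forms and a loop oracle", {
  poly <- regular_polygon(30, r = 5, cx = 10, cy = 10)
  s <- resample_to_common(list(poly, poly, poly), n_sites = 50L)
  prof <- disagreement_profile(s)
  expect_equal(prof$per_site, rep(0, 50))
  expect_equal(prof$n_analysts, 3L)

  # two analysts offset +1 / -1 px in y at every site: profile exactly 1
  p1 <- s[[1]]; p2 <- s[[2]]
  p1$sites[, 1] <- p1$sites[, 1] + 1
  p2$sites[, 1] <- p2$sites[, 1] - 1
  prof2 <- disagreement_profile(list(p1, p2))
  expect_equal(prof2$per_site, rep(1, 50))

  set.seed(75)
  rand <- lapply(1:4, function(i) {
    sm <- s[[1]]
    sm$sites <- sm$sites + matrix(rnorm(100), 50, 2)
    sm
  })
  prof3 <- disagreement_profile(rand, pixel_mm = 2.5)
  oracle <- numeric(50)
  for (site in 1:50) {
    coords <- t(vapply(rand, function(r) r$sites[site, ], numeric(2)))
    mu <- colMeans(coords)
    oracle[site] <- mean(sqrt(rowSums(sweep(coords, 2, mu)^2)))
  }
  expect_equal(prof3$per_site, oracle, tolerance = 1e-12)
  expect_equal(prof3$per_site_mm, oracle * 2.5, tolerance = 1e-12)
})

test_that("disagreement is invariant under a common rigid translation", {
  set.seed(76)
  base <- resample_to_common(list(regular_polygon(25, 3, 5, 5),
                                  regular_polygon(25, 3.1, 5.2, 4.9)),
                             n_sites = 60L)
  shifted <- lapply(base, function(s) {
    s$sites <- s$sites + matrix(c(17.3, -4.2), 60, 2, byrow = TRUE)
    s
  })
  expect_equal(disagreement_profile(shifted)$per_site,
               disagreement_profile(base)$per_site, tolerance = 1e-12)
})

test_that("unequal site counts are refused with advice to resample", {
  a <- resample_contour(regular_polygon(20), 30L)
  b <- resample_contour(regular_polygon(20), 40L)
  expect_error(disagreement_profile(list(a, b)), "resample")
})

test_that("anisotropic pixels scale axes before the mm distance", {
  s1 <- resample_contour(regular_polygon(12, 4, 8, 8), 24L)
  s2 <- s1
  s2$sites[, 1] <- s2$sites[, 1] + 2   # y (column axis) offset only
  prof <- disagreement_profile(list(s1, s2), pixel_mm = c(3, 1.5))
  expect_equal(prof$per_site, rep(1, 24))          # pixels: half of 2
  expect_equal(prof$per_site_mm, rep(1.5, 24))     # y axis scaled by col mm
})

test_that("mean outline distance is near zero for matching contours", {
  o <- regular_polygon(60, r = 4, cx = 6, cy = 6)
  expect_lt(mean_outline_distance(o, o), 1e-9)
  shifted <- tract_outline(o$points + 0.5)
  d <- mean_outline_distance(o, shifted)
  expect_gt(d, 0.2); expect_lt(d, 0.8)
})
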