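test_that("cavity labelling is 8-connected and matches a graph oracle", {
  m <- matrix(FALSE, 8, 8)
  m[2:3, 2:3] <- TRUE
  m[6:7, 6:7] <- TRUE
  expect_equal(find_cavities(m)$count, 2L)

  diag2 <- matrix(FALSE, 4, 4)
  diag2[1, 1] <- diag2[2, 2] <- TRUE   # touch only diagonally
  expect_equal(find_cavities(diag2)$count, 1L)

  skip_if_not_installed("igraph")
  set.seed(51)
  for (i in 1:15) {
    m <- matrix(runif(120) < 0.35, 10, 12)
    got <- find_cavities(m)
    expect_equal(got$count, components_igraph(m))
    if (got$count > 0)
      expect_setequal(unique(got$labels[m]), seq_len(got$count))
  }
})

test_that("A* walks straight along a uniform corridor", {
  I <- matrix(1, 5, 15)
  reg <- matrix(TRUE, 5, 15)
  p <- astar_path(I, reg, anchor_points(c(3, 2), c(3, 12)))
  expect_equal(nrow(p$pixels), 11L)
  expect_true(all(p$pixels[, 1] == 3))
  expect_equal(p$pixels[, 2], 2:12)
})

test_that("A* cost is optimal against Dijkstra and exhaustive enumeration", {
  skip_if_not_installed("igraph")
  set.seed(52)
  for (i in 1:10) {
    I <- matrix(runif(64), 8, 8)
    reg <- matrix(runif(64) < 0.9, 8, 8)
    reg[1, 1] <- reg[8, 8] <- TRUE
    d <- dijkstra_cost_igraph(I, reg, c(1, 1), c(8, 8))
    if (!is.finite(d)) {
      expect_error(astar_path(I, reg, anchor_points(c(1, 1), c(8, 8))),
                   "no path")
      next
    }
    a <- astar_path(I, reg, anchor_points(c(1, 1), c(8, 8)))
    expect_equal(a$total_cost, d)
  }
  for (i in 1:5) {
    I <- matrix(runif(25), 5, 5)
    reg <- matrix(TRUE, 5, 5)
    a <- astar_path(I, reg, anchor_points(c(1, 1), c(5, 5)))
    expect_equal(a$total_cost, enumerate_min_cost(I, reg, c(1, 1), c(5, 5)))
  }
})

test_that("A* paths are valid, deterministic, and validate anchors", {
  set.seed(53)
  I <- matrix(runif(100), 10, 10)
  reg <- matrix(TRUE, 10, 10)
  an <- anchor_points(c(2, 2), c(9, 9))
  p1 <- astar_path(I, reg, an)
  p2 <- astar_path(I, reg, an)
  expect_identical(p1$pixels, p2$pixels)
  expect_equal(p1$pixels[1, ], c(row = 2, col = 2))
  expect_equal(p1$pixels[nrow(p1$pixels), ], c(row = 9, col = 9))
  steps <- abs(diff(p1$pixels))
  expect_true(all(steps <= 1) && all(rowSums(steps) >= 1))
  expect_false(anyDuplicated(p1$pixels) > 0)

  reg2 <- reg; reg2[5, 5] <- FALSE
  expect_error(astar_path(I, reg2, anchor_points(c(5, 5), c(9, 9))),
               "outside the search region")
})

test_that("bridging merges cavities and adds exactly the path pixels", {
  m <- matrix(FALSE, 9, 9)
  m[2:4, 2:4] <- TRUE
  m[6:8, 6:8] <- TRUE
  I <- matrix(1, 9, 9); I[m] <- 0
  reg <- matrix(TRUE, 9, 9)
  p <- astar_path(I, reg, anchor_points(c(3, 3), c(7, 7)))
  b <- bridge_cavities(m, p)
  expect_equal(find_cavities(b)$count, 1L)
  expect_true(all(b[m]))                       # never removes pixels
  added <- which(b & !m)
  path_lin <- p$pixels[, 1] + (p$pixels[, 2] - 1) * 9
  expect_setequal(added, setdiff(path_lin, which(m)))

  # path inside an already-connected mask changes nothing
  m2 <- matrix(TRUE, 9, 9)
  expect_identical(bridge_cavities(m2, p), m2)
})

test_that("tracing a 3x3 block gives the 0.5-iso marching-squares polygon", {
  m <- matrix(FALSE, 7, 7)
  m[3:5, 3:5] <- TRUE
  o <- trace_outline(m)
  # 3x3 square of side 3 minus four corner cuts of 1/8: area 8.5
  expect_equal(shoelace_abs_area(o$points), 8.5)
  expect_true(o$closed)
  gap <- sqrt(sum((o$points[1, ] - o$points[nrow(o$points), ])^2))
  expect_lte(gap, sqrt(2))                     # cyclically adjacent
  expect_gt(signed_area(o$points[, 1], o$points[, 2]), 0)  # clockwise
})

test_that("traced polygons contain the mask and exclude the background", {
  for (seed in c(61, 62, 63, 64)) {
    m <- random_blob(seed)
    m <- fill_holes(m)
    o <- trace_outline(m)
    centres <- which(m | !m, arr.ind = TRUE)    # every pixel centre
    pts_yz <- cbind(centres[, 2], centres[, 1])
    inside <- vapply(seq_len(nrow(pts_yz)), function(i)
      winding_inside(pts_yz[i, ], o$points), TRUE)
    expect_true(all(inside[m[centres]]))
    expect_true(all(!inside[!m[centres]]))
  }
})

test_that("tracing refuses empty, multi-component, and degenerate masks", {
  expect_error(trace_outline(matrix(FALSE, 5, 5)), "empty")
  two <- matrix(FALSE, 7, 7); two[2, 2] <- TRUE; two[6, 6] <- TRUE
  expect_error(trace_outline(two), "bridge")
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_error(trace_outline(one), "fewer than 3")
})

test_that("outline orientation is clockwise on every phantom frame", {
  ph <- generate_phantom(phantom_spec(frames = 6L, seed = 7))
  signs <- vapply(ph$outlines, function(o)
    sign(signed_area(o$points[, 1], o$points[, 2])), 1)
  expect_true(all(signs == 1))
})

test_that("outline_run bridges exactly the closure frames and composes", {
  spec <- phantom_spec(frames = 12L,
                       closures = list(list(frames = c(5, 8), position = 0.55)),
                       seed = 9)
  ph <- generate_phantom(spec)
  os <- outline_run(ph$masks, ph$run, anchors = ph$anchors)
  expect_equal(which(os$status$bridged), 5:8)
  expect_true(all(os$status$ok))

  clean <- generate_phantom(phantom_spec(frames = 6L, seed = 10))
  os0 <- outline_run(clean$masks, clean$run, anchors = clean$anchors)
  expect_equal(sum(os0$status$bridged), 0L)

  # composition: manual per-frame operations reproduce outline_run
  f <- 6L
  m <- ph$masks$masks[f, , ]
  p <- astar_path(ph$run$intensities[f, , ], ph$masks$roi_used$mask,
                  ph$anchors)
  manual <- trace_outline(bridge_cavities(m, p), frame = f,
                          lips = ph$anchors$lips)
  got <- os$outlines[[f]]
  expect_equal(got$points, manual$points)
})
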