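# Independent oracles and small fixtures used across the test files.

# quick image_run around an array
make_run <- function(arr, ...) image_run(arr, ...)

# full-true ROI for a run
full_roi <- function(run) {
  d <- dim(run$intensities)
  region_of_interest(matrix(TRUE, d[2L], d[3L]))
}

# wrap a sample of intensity values into a 1-frame run + all-true ROI so
# fit_threshold can pool them; clipped at 0 like any magnitude image
run_from_values <- function(values) {
  values <- pmax(values, 0)
  n <- length(values)
  side <- ceiling(sqrt(n))
  pad <- rep(values, length.out = side * side)
  run <- image_run(array(pad, c(1L, side, side)))
  list(run = run, roi = full_roi(run))
}

# ---- A* oracles ---------------------------------------------------------

# the same cost model as astar_path, but evaluated by igraph's Dijkstra on
# an explicit edge list (independent search implementation)
dijkstra_cost_igraph <- function(intensity, region, start, goal, epsilon = 0.01) {
  nr <- nrow(intensity); nc <- ncol(intensity)
  vals <- intensity[region]
  rng <- range(vals)
  inorm <- matrix(0, nr, nc)
  if (diff(rng) > 0) inorm[region] <- (intensity[region] - rng[1]) / diff(rng)
  w <- epsilon + inorm
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!region[r, cc]) next
    p <- r + (cc - 1L) * nr
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- cc + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || !region[r2, c2]) next
      q <- r2 + (c2 - 1L) * nr
      from <- c(from, p); to <- c(to, q)
      wt <- c(wt, w[r2, c2] * sqrt(dr^2 + dc^2))
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  s <- start[1] + (start[2] - 1L) * nr
  t <- goal[1] + (goal[2] - 1L) * nr
  igraph::distances(g, v = s, to = t, mode = "out", weights = wt)[1, 1]
}

# exhaustive minimum over all simple paths (depth-first with cost pruning;
# exact because step costs are strictly positive)
enumerate_min_cost <- function(intensity, region, start, goal, epsilon = 0.01) {
  nr <- nrow(intensity); nc <- ncol(intensity)
  vals <- intensity[region]
  rng <- range(vals)
  inorm <- matrix(0, nr, nc)
  if (diff(rng) > 0) inorm[region] <- (intensity[region] - rng[1]) / diff(rng)
  w <- epsilon + inorm
  best <- Inf
  visited <- matrix(FALSE, nr, nc)
  dr8 <- c(-1, -1, 0, 1, 1, 1, 0, -1); dc8 <- c(0, 1, 1, 1, 0, -1, -1, -1)
  sl8 <- sqrt(dr8^2 + dc8^2)
  rec <- function(r, cc, cost) {
    if (cost >= best) return(invisible())
    if (r == goal[1] && cc == goal[2]) { best <<- cost; return(invisible()) }
    visited[r, cc] <<- TRUE
    for (k in 1:8) {
      r2 <- r + dr8[k]; c2 <- cc + dc8[k]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!region[r2, c2] || visited[r2, c2]) next
      rec(r2, c2, cost + w[r2, c2] * sl8[k])
    }
    visited[r, cc] <<- FALSE
    invisible()
  }
  rec(start[1], start[2], 0)
  best
}

# ---- geometry oracles ---------------------------------------------------

# shoelace polygon area, sign-free
shoelace_abs_area <- function(pts) {
  n <- nrow(pts); j <- c(2:n, 1)
  abs(sum(pts[, 1] * pts[j, 2] - pts[j, 1] * pts[, 2]) / 2)
}

# winding-number point-in-polygon (independent of the package's even-odd
# crossing test)
winding_inside <- function(pt, poly) {
  d <- sweep(poly, 2, pt)
  ang <- atan2(d[, 2], d[, 1])
  dd <- diff(c(ang, ang[1]))
  dd <- ifelse(dd > pi, dd - 2 * pi, ifelse(dd < -pi, dd + 2 * pi, dd))
  abs(sum(dd)) > pi  # ~2*pi inside, ~0 outside
}

# connected component count via igraph on the pixel adjacency graph
components_igraph <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(0L)
  from <- integer(0); to <- integer(0)
  offs <- if (connectivity == 8) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1), c(-1, -1), c(-1, 1),
         c(1, -1), c(1, 1))
  } else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  for (p in idx) {
    r <- ((p - 1) %% nr) + 1; cc <- ((p - 1) %/% nr) + 1
    for (o in offs) {
      r2 <- r + o[1]; c2 <- cc + o[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      q <- r2 + (c2 - 1) * nr
      if (mask[q]) { from <- c(from, p); to <- c(to, q) }
    }
  }
  g <- igraph::make_graph(edges = as.vector(t(cbind(match(from, idx),
                                                    match(to, idx)))),
                          n = length(idx), directed = FALSE)
  igraph::components(g)$no
}

# a small single-component blob for tracing tests
random_blob <- function(seed, nr = 12, nc = 12) {
  set.seed(seed)
  m <- matrix(FALSE, nr, nc)
  r <- sample(3:(nr - 2), 1); cc <- sample(3:(nc - 2), 1)
  m[r, cc] <- TRUE
  for (i in 1:40) {
    idx <- which(m, arr.ind = TRUE)
    p <- idx[sample(nrow(idx), 1), ]
    d <- sample(1:4, 1)
    q <- p + rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))[d, ]
    if (all(q >= 2) && q[1] <= nr - 1 && q[2] <= nc - 1) m[q[1], q[2]] <- TRUE
  }
  m
}

# arc-length position of each sample point along a closed polygon, found by
# locating the segment each point lies on (independent of resample_contour's
# bookkeeping)
arc_positions_on_polygon <- function(pts, poly, tol = 1e-7) {
  q <- rbind(poly, poly[1, ])
  seg <- sqrt(rowSums(diff(q)^2))
  cum <- c(0, cumsum(seg))
  out <- rep(NA_real_, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    for (s in seq_len(nrow(q) - 1)) {
      a <- q[s, ]; b <- q[s + 1, ]
      ab <- b - a
      L2 <- sum(ab^2)
      t <- sum((pts[i, ] - a) * ab) / L2
      if (t < -tol || t > 1 + tol) next
      proj <- a + pmin(1, pmax(0, t)) * ab
      if (sqrt(sum((pts[i, ] - proj)^2)) < tol) {
        out[i] <- cum[s] + pmin(1, pmax(0, t)) * seg[s]
        break
      }
    }
  }
  out
}
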