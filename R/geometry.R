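# Low-level raster and polygon geometry shared by the masking, outlining and
# metrics modules. Pixel centres sit at integer (row, col) coordinates.

#' Signed polygon area (shoelace formula)
#'
#' Computed in the `(y, z)` convention with z increasing downwards, so a
#' positive value corresponds to a clockwise loop in screen orientation.
#'
#' @param y,z Coordinate vectors of the polygon vertices (no duplicated
#'   closing vertex required).
#' @return Signed area; positive = clockwise on screen.
#' @export
signed_area <- function(y, z) {
  n <- length(y)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  sum(y * z[j] - y[j] * z) / 2
}

#' @keywords internal
outline_perimeter <- function(outline) {
  p <- outline$points
  q <- rbind(p, p[1L, ])
  sum(sqrt(rowSums(diff(q)^2)))
}

# Even-odd (crossing number) rasterization of a polygon onto pixel centres.
# `vertices` is a 2-column (row, col) matrix; returns a logical rows x cols
# matrix. A pixel centre exactly on an edge may fall either side (half-open
# rule); tests and callers place polygon edges between pixel centres.
polygon_to_mask <- function(vertices, nrow, ncol) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("a polygon needs at least 3 (row, col) vertices", call. = FALSE)
  if (anyNA(vertices) || any(!is.finite(vertices)))
    stop("polygon vertices must be finite", call. = FALSE)
  if (any(vertices[, 1L] < 0.5 - 1e-9) || any(vertices[, 1L] > nrow + 0.5 + 1e-9) ||
      any(vertices[, 2L] < 0.5 - 1e-9) || any(vertices[, 2L] > ncol + 0.5 + 1e-9))
    stop("polygon vertices fall outside the image bounds", call. = FALSE)
  vr <- vertices[, 1L]; vc <- vertices[, 2L]
  n <- length(vr)
  px_r <- rep(seq_len(nrow), times = ncol)
  px_c <- rep(seq_len(ncol), each = nrow)
  inside <- logical(nrow * ncol)
  j <- n
  for (i in seq_len(n)) {
    # cast a ray in +col direction; count crossings in the row coordinate
    crosses <- (vr[i] > px_r) != (vr[j] > px_r)
    if (any(crosses)) {
      xi <- vc[i] + (px_r[crosses] - vr[i]) * (vc[j] - vc[i]) / (vr[j] - vr[i])
      hit <- px_c[crosses] < xi
      inside[crosses][hit] <- !inside[crosses][hit]
    }
    j <- i
  }
  matrix(inside, nrow, ncol)
}

# 8-connected component labelling by breadth-first flood fill.
# Returns list(labels = integer matrix (0 = background), count).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  count <- 0L
  idx <- which(mask)
  if (!length(idx)) return(list(labels = labels, count = 0L))
  # neighbour offsets in column-major linear indexing
  for (start in idx) {
    if (labels[start] != 0L) next
    count <- count + 1L
    stack <- start
    labels[start] <- count
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (dr in -1L:1L) for (dc in -1L:1L) {
        if (dr == 0L && dc == 0L) next
        r2 <- r + dr; c2 <- cc + dc
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        q <- r2 + (c2 - 1L) * nr
        if (mask[q] && labels[q] == 0L) {
          labels[q] <- count
          stack <- c(stack, q)
        }
      }
    }
  }
  list(labels = labels, count = count)
}

# Fill interior holes: background connected to the image border (4-connected
# flood fill on the complement) stays background; everything else becomes
# foreground.
fill_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  outside <- matrix(FALSE, nr, nc)
  border <- unique(c(seq_len(nr), seq_len(nr) + (nc - 1L) * nr,
                     (seq_len(nc) - 1L) * nr + 1L, (seq_len(nc) - 1L) * nr + nr))
  seeds <- border[!mask[border]]
  outside[seeds] <- TRUE
  stack <- seeds
  while (length(stack)) {
    p <- stack[length(stack)]
    stack <- stack[-length(stack)]
    r <- ((p - 1L) %% nr) + 1L
    cc <- ((p - 1L) %/% nr) + 1L
    for (k in 1:4) {
      r2 <- r + c(-1L, 1L, 0L, 0L)[k]
      c2 <- cc + c(0L, 0L, -1L, 1L)[k]
      if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
      q <- r2 + (c2 - 1L) * nr
      if (!mask[q] && !outside[q]) {
        outside[q] <- TRUE
        stack <- c(stack, q)
      }
    }
  }
  mask | !outside
}

# Resolve diagonal saddles: a 2x2 block whose true pixels touch only
# diagonally is ambiguous for marching squares (the iso-contour splits into
# separate loops there). Each such block gets one deterministic filler
# pixel (the top-right for a TL/BR pair, the top-left for a TR/BL pair)
# until no saddle remains, so an 8-connected component yields exactly one
# outer contour.
resolve_saddles <- function(mask) {
  repeat {
    nr <- nrow(mask); nc <- ncol(mask)
    tl <- mask[-nr, -nc]; tr <- mask[-nr, -1L]
    bl <- mask[-1L, -nc]; br <- mask[-1L, -1L]
    sA <- tl & br & !tr & !bl   # fill top-right
    sB <- tr & bl & !tl & !br   # fill top-left
    if (!any(sA) && !any(sB)) return(mask)
    fix <- matrix(FALSE, nr, nc)
    fix[-nr, -1L] <- fix[-nr, -1L] | sA
    fix[-nr, -nc] <- fix[-nr, -nc] | sB
    mask <- mask | fix
  }
}

# Binary dilation by a disc of radius r (pixel centres, Euclidean).
dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  out <- mask
  ri <- ceiling(r)
  for (dr in -ri:ri) for (dc in -ri:ri) {
    if ((dr == 0L && dc == 0L) || dr * dr + dc * dc > r * r) next
    shifted <- matrix(FALSE, nrow(mask), ncol(mask))
    src_r <- seq_len(nrow(mask)) - dr
    src_c <- seq_len(ncol(mask)) - dc
    ok_r <- src_r >= 1L & src_r <= nrow(mask)
    ok_c <- src_c >= 1L & src_c <= ncol(mask)
    shifted[ok_r, ok_c] <- mask[src_r[ok_r], src_c[ok_c]]
    out <- out | shifted
  }
  out
}

# Minimum distance from each point (rows of `pts`) to a closed polyline
# (rows of `poly`, closing edge implied). Both are 2-column matrices in the
# same coordinate system.
points_to_polygon_distance <- function(pts, poly) {
  a <- poly
  b <- poly[c(2:nrow(poly), 1L), , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  len2[len2 == 0] <- 1e-300
  d <- rep(Inf, nrow(pts))
  for (s in seq_len(nrow(a))) {
    t <- ((pts[, 1L] - a[s, 1L]) * ab[s, 1L] + (pts[, 2L] - a[s, 2L]) * ab[s, 2L]) / len2[s]
    t <- pmin(1, pmax(0, t))
    dx <- pts[, 1L] - (a[s, 1L] + t * ab[s, 1L])
    dy <- pts[, 2L] - (a[s, 2L] + t * ab[s, 2L])
    d <- pmin(d, sqrt(dx * dx + dy * dy))
  }
  d
}

# Even-odd point-in-polygon test for arbitrary points (2-column (y, z) or
# (row, col) matrices, consistent between `pts` and `poly`).
points_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  inside <- logical(nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    crosses <- (poly[i, 2L] > pts[, 2L]) != (poly[j, 2L] > pts[, 2L])
    if (any(crosses)) {
      xi <- poly[i, 1L] + (pts[crosses, 2L] - poly[i, 2L]) *
        (poly[j, 1L] - poly[i, 1L]) / (poly[j, 2L] - poly[i, 2L])
      hit <- pts[crosses, 1L] < xi
      inside[crosses][hit] <- !inside[crosses][hit]
    }
    j <- i
  }
  inside
}
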