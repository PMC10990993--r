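# A* pathfinding over the image grid.
#
# The walk from larynx to lips is weighted against bright (tissue) pixels:
# entering pixel p costs (epsilon + I_hat(p)) * step_length, where I_hat is
# the intensity min-max normalized over the search region, epsilon is a
# small positive floor keeping costs strictly positive in fully dark air,
# and step_length is 1 (axial) or sqrt(2) (diagonal). The path therefore
# follows the dim pixels through constrictions while remaining globally
# optimal. The heuristic epsilon * Euclidean-distance-to-goal never exceeds
# the true remaining cost, so A* is admissible and returns an optimal path.
# Ties are broken deterministically: fixed neighbour expansion order
# (N, NE, E, SE, S, SW, W, NW) and a stable (insertion-ordered) priority
# queue, so outputs are reproducible bit-exactly.

# neighbour offsets in expansion order N, NE, E, SE, S, SW, W, NW
.astar_dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
.astar_dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
.astar_sl <- sqrt(.astar_dr^2 + .astar_dc^2)

#' Optimal larynx-to-lips path through the image grid (A*)
#'
#' Finds the minimum-cost 8-connected path between the two anchors, where
#' the cost of stepping into a pixel grows with its (normalized) intensity:
#' bright tissue is penalized, so the path follows dark air and, at sites of
#' closure, the dimmest available tissue.
#'
#' @param frame_intensity Numeric matrix of the frame's intensities (>= 0).
#' @param search_region Logical matrix of valid locations (normally the
#'   ROI -- constrictions are by definition not in the tract mask, and the
#'   path must be able to cross them).
#' @param anchors An [anchor_points()] pair; both inside `search_region`.
#' @param epsilon Small positive per-unit-length cost floor (default 0.01).
#' @return An object of class `path_result`: list with `pixels` (n x 2
#'   `(row, col)` matrix from larynx to lips, consecutive rows 8-adjacent,
#'   no repeats) and `total_cost`.
#' @export
astar_path <- function(frame_intensity, search_region, anchors,
                       epsilon = 0.01) {
  stopifnot(is.matrix(frame_intensity), is.matrix(search_region),
            inherits(anchors, "anchor_points"))
  if (!all(dim(frame_intensity) == dim(search_region)))
    stop("intensity and search region shapes differ", call. = FALSE)
  if (epsilon <= 0) stop("`epsilon` must be positive", call. = FALSE)
  nr <- nrow(frame_intensity); nc <- ncol(frame_intensity)
  lin <- function(rc) rc[1L] + (rc[2L] - 1L) * nr
  for (nm in c("larynx", "lips")) {
    rc <- anchors[[nm]]
    if (rc[1L] < 1L || rc[1L] > nr || rc[2L] < 1L || rc[2L] > nc ||
        !search_region[lin(rc)])
      stop(nm, " anchor (", rc[1L], ", ", rc[2L],
           ") is outside the search region", call. = FALSE)
  }
  vals <- frame_intensity[search_region]
  rng <- range(vals)
  inorm <- matrix(0, nr, nc)
  if (diff(rng) > 0)
    inorm[search_region] <- (frame_intensity[search_region] - rng[1L]) / diff(rng)
  weight <- epsilon + inorm  # per-unit-length cost of entering each pixel
  start <- lin(anchors$larynx); goal <- lin(anchors$lips)
  gr <- anchors$lips[1L]; gc <- anchors$lips[2L]

  npx <- nr * nc
  g <- rep(Inf, npx)
  parent <- integer(npx)
  closed <- logical(npx)
  # binary heap keyed on (f, insertion counter) for stable tie-breaking
  heap_node <- integer(0); heap_f <- numeric(0); heap_ord <- integer(0)
  hsize <- 0L; counter <- 0L
  less <- function(i, j) heap_f[i] < heap_f[j] ||
    (heap_f[i] == heap_f[j] && heap_ord[i] < heap_ord[j])
  push <- function(node, f) {
    hsize <<- hsize + 1L; counter <<- counter + 1L
    heap_node[hsize] <<- node; heap_f[hsize] <<- f; heap_ord[hsize] <<- counter
    i <- hsize
    while (i > 1L) {
      p <- i %/% 2L
      if (less(i, p)) {
        tmp <- heap_node[i]; heap_node[i] <<- heap_node[p]; heap_node[p] <<- tmp
        tmp <- heap_f[i]; heap_f[i] <<- heap_f[p]; heap_f[p] <<- tmp
        tmpo <- heap_ord[i]; heap_ord[i] <<- heap_ord[p]; heap_ord[p] <<- tmpo
        i <- p
      } else break
    }
  }
  pop <- function() {
    top <- heap_node[1L]
    heap_node[1L] <<- heap_node[hsize]; heap_f[1L] <<- heap_f[hsize]
    heap_ord[1L] <<- heap_ord[hsize]
    hsize <<- hsize - 1L
    i <- 1L
    repeat {
      l <- 2L * i; r <- l + 1L; m <- i
      if (l <= hsize && less(l, m)) m <- l
      if (r <= hsize && less(r, m)) m <- r
      if (m == i) break
      tmp <- heap_node[i]; heap_node[i] <<- heap_node[m]; heap_node[m] <<- tmp
      tmp <- heap_f[i]; heap_f[i] <<- heap_f[m]; heap_f[m] <<- tmp
      tmpo <- heap_ord[i]; heap_ord[i] <<- heap_ord[m]; heap_ord[m] <<- tmpo
      i <- m
    }
    top
  }
  heur <- function(r, cc) epsilon * sqrt((r - gr)^2 + (cc - gc)^2)

  g[start] <- 0
  push(start, heur(anchors$larynx[1L], anchors$larynx[2L]))
  found <- FALSE
  while (hsize > 0L) {
    cur <- pop()
    if (closed[cur]) next
    closed[cur] <- TRUE
    if (cur == goal) { found <- TRUE; break }
    r <- ((cur - 1L) %% nr) + 1L
    cc <- ((cur - 1L) %/% nr) + 1L
    for (k in 1:8) {
      r2 <- r + .astar_dr[k]; c2 <- cc + .astar_dc[k]
      if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
      nb <- r2 + (c2 - 1L) * nr
      if (!search_region[nb] || closed[nb]) next
      cand <- g[cur] + weight[nb] * .astar_sl[k]
      if (cand < g[nb]) {
        g[nb] <- cand
        parent[nb] <- cur
        push(nb, cand + heur(r2, c2))
      }
    }
  }
  if (!found)
    stop("no path exists between the anchors within the search region",
         call. = FALSE)
  # reconstruct larynx -> lips
  chain <- goal
  while (chain[1L] != start) chain <- c(parent[chain[1L]], chain)
  pixels <- cbind(row = ((chain - 1L) %% nr) + 1L,
                  col = ((chain - 1L) %/% nr) + 1L)
  structure(list(pixels = pixels, total_cost = g[goal]),
            class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  cat(sprintf("<path_result> %d pixel(s), total cost %.6g\n",
              nrow(x$pixels), x$total_cost))
  invisible(x)
}
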