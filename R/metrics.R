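# Validation metrics: Dice similarity between mask sets, arc-length contour
# resampling, and per-site inter-analyst disagreement profiles.

as_bool_set <- function(x) {
  if (inherits(x, "tract_mask_series")) return(x$masks)
  if (inherits(x, c("roi", "exclusion_mask"))) return(x$mask)
  if (is.array(x) || is.matrix(x)) return(x != 0)
  stop("expected a mask series, mask matrix, or boolean array", call. = FALSE)
}

#' Dice similarity score
#'
#' `2 |X intersect Y| / (|X| + |Y|)`: twice the number of pixels classified
#' as vocal tract by both analyses, divided by the sum of the pixel counts
#' of each. 1 means complete agreement, 0 complete disagreement.
#'
#' @param x,y Boolean matrices/arrays of identical shape, or
#'   [tract_mask_series()] objects.
#' @return A number in `[0, 1]`.
#' @export
dice_score <- function(x, y) {
  a <- as_bool_set(x); b <- as_bool_set(y)
  if (!identical(dim(a), dim(b)))
    stop("mask shapes differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L)
    stop("both masks are empty; the Dice score is undefined", call. = FALSE)
  2 * sum(a & b) / (na + nb)
}

#' Pairwise Dice similarity matrix
#'
#' @param mask_sets Named list (>= 2) of mask series/arrays with a common
#'   shape; names label the analysts/sources.
#' @return A symmetric numeric matrix with unit diagonal, dimnames taken
#'   from `mask_sets`.
#' @export
dice_matrix <- function(mask_sets) {
  if (length(mask_sets) < 2L)
    stop("need at least 2 mask sets", call. = FALSE)
  sets <- lapply(mask_sets, as_bool_set)
  d1 <- dim(sets[[1L]])
  for (i in seq_along(sets)) if (!identical(dim(sets[[i]]), d1))
    stop("mask set ", i, " has a different shape", call. = FALSE)
  labs <- names(mask_sets)
  if (is.null(labs)) labs <- paste0("set", seq_along(sets))
  n <- length(sets)
  m <- diag(1, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- dice_score(sets[[i]], sets[[j]])
  }
  dimnames(m) <- list(labs, labs)
  m
}

#' Resample an outline at equally spaced arc-length sites
#'
#' Computes cumulative arc length along the closed polyline from its start
#' site and places `n_sites` points at arc positions `k L / n_sites`
#' (`k = 0 .. n_sites - 1`, `L` = perimeter) by linear interpolation along
#' the contour. The start convention is preserved, which is what gives
#' corresponding sites across analysts.
#'
#' @param outline A [tract_outline()].
#' @param n_sites Number of sites (>= 2). The convention used for group
#'   comparisons is the point count of the largest outline in the dataset
#'   (see [resample_to_common()]).
#' @return An object of class `contour_samples`: list with `sites`
#'   (`n_sites` x 2 `(y, z)` matrix), `n_sites`, `source`, `arc_positions`.
#' @export
resample_contour <- function(outline, n_sites) {
  stopifnot(inherits(outline, "tract_outline"))
  n_sites <- as.integer(n_sites)
  if (n_sites < 2L) stop("`n_sites` must be at least 2", call. = FALSE)
  p <- outline$points
  q <- rbind(p, p[1L, ])
  seg <- sqrt(rowSums(diff(q)^2))
  L <- sum(seg)
  if (L <= 0) stop("outline has zero perimeter; degenerate", call. = FALSE)
  cum <- c(0, cumsum(seg))        # arc position of each vertex, 0..L
  targets <- (seq_len(n_sites) - 1L) * L / n_sites
  idx <- findInterval(targets, cum, rightmost.closed = TRUE)
  idx[idx >= nrow(q)] <- nrow(q) - 1L
  t <- (targets - cum[idx]) / pmax(seg[idx], 1e-300)
  sites <- q[idx, , drop = FALSE] + (q[idx + 1L, , drop = FALSE] -
                                       q[idx, , drop = FALSE]) * t
  colnames(sites) <- c("y", "z")
  structure(list(sites = sites, n_sites = n_sites,
                 source = sprintf("frame %d", outline$frame),
                 arc_positions = targets),
            class = "contour_samples")
}

#' Resample several outlines to a common site count
#'
#' All contours are upsampled to match the number of points in the largest
#' outline (or an explicit `n_sites`), so that site-wise comparison across
#' analysts is possible.
#'
#' @param outlines List of [tract_outline()] objects.
#' @param n_sites Optional site count; default is the maximum point count
#'   over the input outlines.
#' @return List of `contour_samples`.
#' @export
resample_to_common <- function(outlines, n_sites = NULL) {
  stopifnot(length(outlines) >= 1L)
  if (is.null(n_sites))
    n_sites <- max(vapply(outlines, function(o) nrow(o$points), 1L))
  lapply(outlines, resample_contour, n_sites = n_sites)
}

#' Per-site disagreement profile across analysts
#'
#' At each measurement site, the group mean coordinate is computed across
#' analysts, and the profile value is the mean Euclidean distance between
#' each analyst's coordinate and that mean. The `per_site_mm` variant
#' scales by the in-plane pixel size (per-axis before distance computation
#' when the two spacings differ).
#'
#' @param samples List (>= 2) of `contour_samples` with equal `n_sites`.
#' @param pixel_mm In-plane pixel size in mm (scalar or `c(row, col)`).
#' @param group Text tag for the analyst group (e.g. "experienced").
#' @return An object of class `disagreement_profile`: list with `per_site`
#'   (pixels), `per_site_mm`, `n_sites`, `n_analysts`, `group`.
#' @export
disagreement_profile <- function(samples, pixel_mm = c(1, 1), group = NA) {
  if (length(samples) < 2L)
    stop("need at least 2 analysts' contour samples", call. = FALSE)
  ns <- vapply(samples, function(s) s$n_sites, 1L)
  if (length(unique(ns)) != 1L)
    stop("contour samples have unequal site counts (",
         paste(unique(ns), collapse = ", "),
         "); resample to a common n_sites first (resample_to_common)",
         call. = FALSE)
  pixel_mm <- as.numeric(pixel_mm)
  if (length(pixel_mm) == 1L) pixel_mm <- rep(pixel_mm, 2L)
  n_sites <- ns[1L]
  A <- length(samples)
  ys <- vapply(samples, function(s) s$sites[, 1L], numeric(n_sites))
  zs <- vapply(samples, function(s) s$sites[, 2L], numeric(n_sites))
  my <- rowMeans(ys); mz <- rowMeans(zs)
  per_site <- rowMeans(sqrt((ys - my)^2 + (zs - mz)^2))
  # y is the column axis, z the row axis
  dy_mm <- (ys - my) * pixel_mm[2L]
  dz_mm <- (zs - mz) * pixel_mm[1L]
  per_site_mm <- rowMeans(sqrt(dy_mm^2 + dz_mm^2))
  structure(list(per_site = per_site, per_site_mm = per_site_mm,
                 n_sites = n_sites, n_analysts = A,
                 group = as.character(group)[1L]),
            class = "disagreement_profile")
}

#' @export
print.disagreement_profile <- function(x, ...) {
  cat(sprintf(
    "<disagreement_profile> %d analysts, %d sites; %.2f-%.2f px (mean %.2f)\n",
    x$n_analysts, x$n_sites, min(x$per_site), max(x$per_site),
    mean(x$per_site)))
  invisible(x)
}

#' Mean distance between two closed outlines
#'
#' Symmetric mean point-to-boundary distance: each outline is resampled to
#' `n` arc-length sites, the distance of each site to the other outline's
#' polygon is taken, and the two directed means are averaged. Used to score
#' traced outlines against phantom ground truth.
#'
#' @param a,b [tract_outline()] objects.
#' @param n Number of sample sites per outline (default 200).
#' @return Mean distance in pixels.
#' @export
mean_outline_distance <- function(a, b, n = 200L) {
  stopifnot(inherits(a, "tract_outline"), inherits(b, "tract_outline"))
  sa <- resample_contour(a, n)$sites
  sb <- resample_contour(b, n)$sites
  dab <- mean(points_to_polygon_distance(sa, b$points))
  dba <- mean(points_to_polygon_distance(sb, a$points))
  (dab + dba) / 2
}
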