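# Stage 1: spatially informed tissue masking.
#
# The vocal tract appears as dark air between bright tissues, and while it
# changes shape it does not change position in the scanner. Pixels whose
# intensity varies strongly over a run therefore trace the course of the
# tract (they alternate between air and moving tissue); a variance map seeds
# a region of interest, the analyst refines it with polygon edits, and a
# single intensity threshold -- the local minimum of the bimodal pooled
# intensity density -- classifies every frame into air vs. tissue within it.

#' Per-pixel temporal variance map
#'
#' Population variance (divisor = number of frames) of each pixel's
#' intensity time series. Static structures (skull, outside air) score zero;
#' pixels alternating between air and labile tissue score high.
#'
#' @param run An [image_run()] with at least 2 frames.
#' @return A matrix of class `variance_map` (rows x cols, all values >= 0).
#' @export
compute_variance_map <- function(run) {
  stopifnot(inherits(run, "image_run"))
  d <- dim(run$intensities)
  if (d[1L] < 2L)
    stop("variance seeding needs at least 2 frames; got ", d[1L], call. = FALSE)
  flat <- matrix(run$intensities, nrow = d[1L])  # frames x (rows*cols)
  mu <- colMeans(flat)
  v <- colMeans(sweep(flat, 2L, mu)^2)
  v[v < 0] <- 0  # guard against tiny negative rounding
  structure(matrix(v, d[2L], d[3L]), class = "variance_map")
}

#' Seed a region of interest from a variance map
#'
#' The ROI is the set of pixels whose variance lies strictly above the
#' `quantile`-th quantile of all variance values.
#'
#' @param vmap A variance map matrix (from [compute_variance_map()]).
#' @param quantile Fraction in (0, 1); default 0.75.
#' @return A [region_of_interest()] whose provenance records the seeding.
#' @export
seed_roi <- function(vmap, quantile = 0.75) {
  stopifnot(is.matrix(vmap))
  if (!(quantile > 0 && quantile < 1))
    stop("`quantile` must lie strictly between 0 and 1", call. = FALSE)
  if (all(vmap == 0))
    stop("variance map is identically zero; no ROI can be seeded - define ",
         "one manually with edit_roi() on an empty region_of_interest()",
         call. = FALSE)
  cut <- stats::quantile(vmap, quantile, names = FALSE)
  mask <- vmap > cut
  if (!any(mask))
    stop("variance quantile ", quantile, " leaves an empty ROI; lower it or ",
         "define the ROI manually", call. = FALSE)
  region_of_interest(mask, provenance = list(list(op = "seed",
                                                  quantile = quantile,
                                                  cutoff = cut)))
}

#' Edit a region of interest with polygons
#'
#' Scriptable equivalent of interactive refinement: pixels inside any
#' addition polygon are switched on, then pixels inside any removal polygon
#' are switched off (removals win where they overlap). Polygons are
#' 2-column `(row, col)` vertex matrices in pixel coordinates.
#'
#' @param roi A [region_of_interest()].
#' @param additions,removals Lists of polygon vertex matrices (>= 3 vertices
#'   each, within image bounds).
#' @return The edited [region_of_interest()]; provenance appended.
#' @export
edit_roi <- function(roi, additions = list(), removals = list()) {
  stopifnot(inherits(roi, "roi"))
  if (is.matrix(additions)) additions <- list(additions)
  if (is.matrix(removals)) removals <- list(removals)
  nr <- nrow(roi$mask); nc <- ncol(roi$mask)
  mask <- roi$mask
  for (p in additions) mask <- mask | polygon_to_mask(p, nr, nc)
  for (p in removals) mask <- mask & !polygon_to_mask(p, nr, nc)
  prov <- c(roi$provenance,
            lapply(additions, function(p) list(op = "add", vertices = p)),
            lapply(removals, function(p) list(op = "remove", vertices = p)))
  region_of_interest(mask, provenance = prov)
}

#' Fit the air/tissue classification threshold
#'
#' Pools the intensities of all ROI pixels across every frame of the run and
#' fits a Gaussian kernel density (Silverman's rule-of-thumb bandwidth,
#' 512-point grid spanning the observed range). The distribution is expected
#' to be bimodal -- a dark air mode and a bright tissue mode -- and the
#' threshold is placed at the local density minimum between the two most
#' prominent modes. When fewer than two sufficiently prominent modes exist
#' the model is flagged (`bimodality_ok = FALSE`, threshold `NA`) and a
#' warning is raised; classification then needs a manually chosen threshold.
#'
#' @param run An [image_run()].
#' @param roi A non-empty [region_of_interest()].
#' @param n_grid Density grid size (default 512).
#' @param prominence A maximum counts as a mode if its density is at least
#'   this fraction of the global density maximum (default 0.05): high enough
#'   to suppress noise wiggles, low enough to keep the (smaller) air mode.
#' @param bw Bandwidth rule passed to [stats::density()] (default `"nrd0"`,
#'   Silverman's rule of thumb).
#' @return An object of class `threshold_model` with fields `threshold`,
#'   `density_grid` (data frame `intensity`, `density`), `mode_locations`,
#'   `bimodality_ok`.
#' @export
fit_threshold <- function(run, roi, n_grid = 512L, prominence = 0.05,
                          bw = "nrd0") {
  stopifnot(inherits(run, "image_run"), inherits(roi, "roi"))
  if (!any(roi$mask)) stop("ROI is empty; cannot fit a threshold", call. = FALSE)
  if (!all(dim(run$intensities)[2:3] == dim(roi$mask)))
    stop("run and ROI shapes differ", call. = FALSE)
  d <- dim(run$intensities)
  flat <- matrix(run$intensities, nrow = d[1L])
  vals <- as.vector(flat[, as.vector(roi$mask)])
  if (diff(range(vals)) == 0)
    stop("ROI intensities are constant; the distribution is degenerate and ",
         "no threshold exists", call. = FALSE)
  dens <- stats::density(vals, bw = bw, n = n_grid,
                         from = min(vals), to = max(vals))
  x <- dens$x; y <- dens$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1L)] > y[1:(n - 2L)] &
                y[2:(n - 1L)] >= y[3:n], FALSE)
  is_max[1L] <- y[1L] > y[2L]
  is_max[n] <- y[n] > y[n - 1L]
  peaks <- which(is_max & y >= prominence * max(y))
  # collapse plateau peaks that are adjacent on the grid
  if (length(peaks) > 1L) peaks <- peaks[c(TRUE, diff(peaks) > 1L)]
  if (length(peaks) < 2L) {
    warning("intensity distribution in the ROI is not bimodal; ",
            "threshold left NA - supply one manually", call. = FALSE)
    return(structure(list(threshold = NA_real_,
                          density_grid = data.frame(intensity = x, density = y),
                          mode_locations = if (length(peaks)) x[peaks] else numeric(),
                          bimodality_ok = FALSE),
                     class = "threshold_model"))
  }
  top2 <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  between <- lo:hi
  ymin <- min(y[between])
  plateau <- between[y[between] == ymin]
  # midpoint of the minimal-density plateau (deterministic tie-break)
  thr <- mean(range(x[plateau]))
  structure(list(threshold = thr,
                 density_grid = data.frame(intensity = x, density = y),
                 mode_locations = sort(x[top2]),
                 bimodality_ok = TRUE),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> threshold %s, modes [%s], bimodal: %s\n",
              format(x$threshold), paste(format(x$mode_locations),
                                         collapse = ", "),
              x$bimodality_ok))
  invisible(x)
}

#' Classify every frame of a run into air vs. tissue
#'
#' Within the ROI, pixels strictly below the threshold are classified as
#' vocal tract (air); pixels at or above it are tissue. Applied iteratively
#' to every frame; outside the ROI everything is tissue/ignored.
#'
#' @param run An [image_run()].
#' @param roi A [region_of_interest()].
#' @param model A `threshold_model` (from [fit_threshold()]) or a single
#'   finite numeric threshold.
#' @return A [tract_mask_series()].
#' @export
classify_run <- function(run, roi, model) {
  stopifnot(inherits(run, "image_run"), inherits(roi, "roi"))
  thr <- if (inherits(model, "threshold_model")) model$threshold
         else as.numeric(model)[1L]
  if (!is.finite(thr))
    stop("classification threshold is not finite; fit_threshold() flagged a ",
         "non-bimodal distribution or no threshold was supplied", call. = FALSE)
  d <- dim(run$intensities)
  if (!all(d[2:3] == dim(roi$mask)))
    stop("run and ROI shapes differ", call. = FALSE)
  below <- run$intensities < thr
  roi3 <- aperm(array(roi$mask, c(d[2L], d[3L], d[1L])), c(3, 1, 2))
  tract_mask_series(below & roi3, roi_used = roi, threshold_used = thr)
}
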