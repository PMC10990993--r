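# Synthetic dynamic phantom: a curved dark tube (air) through a bright
# tissue background, with optional articulator closures, additive noise and
# a multiplicative bias field -- everything the pipeline's stages have to
# cope with, at desk scale and with exact ground truth.

#' Phantom specification
#'
#' Defines a synthetic mid-sagittal-like run. The tract is an offset band
#' of half-width `width/2` around a spline-interpolated centreline running
#' from the larynx (first control point) to the lips (last control point);
#' the band's width is modulated sinusoidally over time to mimic
#' articulation. Closure events interrupt the tube with tissue-level pixels
#' at a stated centreline position, splitting it into two cavities.
#'
#' @param rows,cols,frames Image and run dimensions.
#' @param centreline Control points of the tract centreline as a 2-column
#'   `(row, col)` matrix, larynx first, lips last.
#' @param width Tube width profile in pixels: a scalar or one value per
#'   control point (spline-interpolated along the tract).
#' @param width_time_amp,width_time_period Relative amplitude and period
#'   (frames) of the sinusoidal width modulation over time.
#' @param closures List of closure events; each a list with `frames =
#'   c(first, last)`, `position` (arc-length fraction in (0, 1) along the
#'   centreline), optional `radius` (pixels; default covers the local tube
#'   cross-section) and `residual` (intensity of the closing tissue as a
#'   fraction of the air-to-tissue contrast, default 0.85 -- constriction
#'   tissue images slightly dimmer than bulk tissue).
#' @param tissue_level,air_level Image intensities of tissue and air
#'   (`tissue_level > air_level >= 0`).
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @param bias Optional bias field: list with `model = "ramp"` and
#'   `amplitude` (the field runs linearly from `1 - amplitude` to
#'   `1 + amplitude` across columns), applied multiplicatively last.
#' @param seed Integer seed; the phantom is deterministic given the spec.
#' @param run_id Identifier stamped on the generated run.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(rows = 64L, cols = 64L, frames = 50L,
                         centreline = default_centreline(),
                         width = c(5, 5, 6, 6, 5, 4),
                         width_time_amp = 0.12, width_time_period = 25,
                         closures = list(),
                         tissue_level = 1.0, air_level = 0.15,
                         noise_sigma = 0, bias = NULL, seed = 1L,
                         run_id = "phantom") {
  centreline <- as.matrix(centreline)
  if (ncol(centreline) != 2L || nrow(centreline) < 2L)
    stop("`centreline` must be >= 2 (row, col) control points", call. = FALSE)
  if (!(tissue_level > air_level && air_level >= 0))
    stop("need tissue_level > air_level >= 0", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (length(width) == 1L) width <- rep(width, nrow(centreline))
  if (length(width) != nrow(centreline))
    stop("`width` must be scalar or one value per control point", call. = FALSE)
  for (cl in closures) {
    if (is.null(cl$frames) || is.null(cl$position) ||
        cl$position <= 0 || cl$position >= 1)
      stop("each closure needs frames = c(first, last) and a position in (0, 1)",
           call. = FALSE)
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 frames = as.integer(frames), centreline = centreline,
                 width = as.numeric(width),
                 width_time_amp = width_time_amp,
                 width_time_period = width_time_period,
                 closures = closures, tissue_level = tissue_level,
                 air_level = air_level, noise_sigma = noise_sigma,
                 bias = bias, seed = as.integer(seed),
                 run_id = as.character(run_id)[1L]),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_centreline <- function() {
  # larynx (inferior, posterior) up the pharynx, bending forward through the
  # oral cavity to the lips (anterior); fits comfortably in 64 x 64
  cbind(row = c(52, 40, 28, 16, 14, 18),
        col = c(44, 46, 44, 38, 28, 12))
}

# Dense spline sampling of the centreline; returns samples, per-sample
# half-width profile, and cumulative arc-length fractions.
sample_centreline <- function(spec, n = 200L) {
  t0 <- seq_len(nrow(spec$centreline))
  tt <- seq(1, nrow(spec$centreline), length.out = n)
  r <- stats::spline(t0, spec$centreline[, 1L], xout = tt)$y
  cc <- stats::spline(t0, spec$centreline[, 2L], xout = tt)$y
  w <- stats::spline(t0, spec$width, xout = tt)$y
  seg <- sqrt(diff(r)^2 + diff(cc)^2)
  arc <- c(0, cumsum(seg))
  list(r = r, c = cc, halfw = pmax(w, 0.5) / 2, frac = arc / max(arc))
}

#' Generate a phantom with exact ground truth
#'
#' Deterministic given the spec. The noise-free geometry defines the truth:
#' per-frame masks are the rasterized tube minus closure discs, truth
#' outlines are traced from that geometry (closure frames are bridged along
#' the centreline, mirroring what a perfect connector would restore), and
#' anchors sit at the tube endpoints. The generated images add closure
#' tissue, per-frame Gaussian noise (each frame is seeded independently as
#' `seed + frame`, so frame k does not depend on how many frames follow),
#' and finally the multiplicative bias field. Intensities are clamped at 0.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_truth`: list with `run`
#'   ([image_run()]), `masks` (ground-truth [tract_mask_series()], ROI =
#'   2-px dilation of the union of truth masks), `outlines` (list of
#'   [tract_outline()]), `anchors` ([anchor_points()]), `bias_truth`
#'   (matrix or `NULL`), `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$rows; nc <- spec$cols; nfr <- spec$frames
  cl <- sample_centreline(spec)
  if (any(cl$r < 1.5) || any(cl$r > nr - 0.5) ||
      any(cl$c < 1.5) || any(cl$c > nc - 0.5))
    stop("tube centreline leaves the image bounds", call. = FALSE)
  if (any(cl$r - cl$halfw < 0.5) || any(cl$r + cl$halfw > nr + 0.5) ||
      any(cl$c - cl$halfw < 0.5) || any(cl$c + cl$halfw > nc + 0.5))
    stop("tube extends outside the image bounds", call. = FALSE)
  npx <- nr * nc
  px_r <- rep(seq_len(nr), times = nc)
  px_c <- rep(seq_len(nc), each = nr)
  nsamp <- length(cl$r)
  # distance from every pixel centre to every centreline sample
  dmat <- sqrt(outer(px_r, cl$r, "-")^2 + outer(px_c, cl$c, "-")^2)

  contrast <- spec$tissue_level - spec$air_level
  intensities <- array(spec$tissue_level, c(nfr, nr, nc))
  truth <- array(FALSE, c(nfr, nr, nc))
  bridge_px <- array(FALSE, c(nfr, nr, nc))  # centreline bridge in closures

  closure_info <- lapply(spec$closures, function(ev) {
    ci <- which.min(abs(cl$frac - ev$position))
    radius <- if (!is.null(ev$radius)) ev$radius else cl$halfw[ci] + 1.5
    residual <- if (!is.null(ev$residual)) ev$residual else 0.85
    list(frames = as.integer(ev$frames), centre = c(cl$r[ci], cl$c[ci]),
         radius = radius, residual = residual)
  })

  for (f in seq_len(nfr)) {
    scale_f <- 1 + spec$width_time_amp *
      sin(2 * pi * (f - 1) / spec$width_time_period)
    halfw_f <- cl$halfw * scale_f
    inside <- Reduce(`|`, lapply(seq_len(nsamp), function(j)
      dmat[, j] <= halfw_f[j]))
    tube <- matrix(inside, nr, nc)
    frame_img <- matrix(spec$tissue_level, nr, nc)
    frame_img[tube] <- spec$air_level
    frame_truth <- tube
    for (ci in closure_info) {
      if (f < ci$frames[1L] || f > ci$frames[2L]) next
      disc <- matrix((px_r - ci$centre[1L])^2 + (px_c - ci$centre[2L])^2 <=
                       ci$radius^2, nr, nc)
      blocked <- disc & tube
      frame_img[blocked] <- spec$air_level + ci$residual * contrast
      frame_truth[blocked] <- FALSE
      on_line <- disc & matrix(Reduce(`|`, lapply(seq_len(nsamp), function(j)
        dmat[, j] <= 0.75)), nr, nc)
      bridge_px[f, , ] <- bridge_px[f, , ] | on_line
    }
    truth[f, , ] <- frame_truth
    intensities[f, , ] <- frame_img
  }

  if (spec$noise_sigma > 0) {
    for (f in seq_len(nfr)) {
      set.seed(spec$seed + f)
      intensities[f, , ] <- intensities[f, , ] +
        stats::rnorm(npx, sd = spec$noise_sigma)
    }
    intensities[intensities < 0] <- 0
  }

  bias_truth <- NULL
  if (!is.null(spec$bias)) {
    a <- spec$bias$amplitude
    bias_truth <- matrix(rep(1 + a * (2 * (seq_len(nc) - 1) / (nc - 1) - 1),
                             each = nr), nr, nc)
    for (f in seq_len(nfr)) intensities[f, , ] <- intensities[f, , ] * bias_truth
  }

  roi <- region_of_interest(
    dilate_mask(apply(truth, c(2, 3), any), 2),
    provenance = list(list(op = "phantom-truth-dilation", radius = 2)))
  anchors <- anchor_points(c(cl$r[1L], cl$c[1L]),
                           c(cl$r[nsamp], cl$c[nsamp]))
  masks <- tract_mask_series(truth, roi_used = roi)

  outlines <- vector("list", nfr)
  for (f in seq_len(nfr)) {
    m <- truth[f, , ]
    if (any(bridge_px[f, , ])) m <- fill_holes(m | bridge_px[f, , ])
    outlines[[f]] <- trace_outline(m, frame = f, lips = anchors$lips)
  }

  run <- image_run(intensities, fps = 10, pixel_mm = c(2.5, 2.5),
                   run_id = spec$run_id)
  structure(list(run = run, masks = masks, outlines = outlines,
                 anchors = anchors, bias_truth = bias_truth, spec = spec),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> '%s': %d frame(s) %d x %d, %d closure event(s)\n",
              x$spec$run_id, x$spec$frames, x$spec$rows, x$spec$cols,
              length(x$spec$closures)))
  invisible(x)
}

#' Standard phantom validation battery
#'
#' A fixed battery of five specs (64 x 64 x 50) covering the pipeline's
#' stressors: a clean run; a noisy run (sigma = 10% of the air-tissue
#' contrast); a closure run (tract bisected on frames 15-30); a bias-field
#' run (30% linear ramp, plus the default noise -- a smooth gain alone
#' cannot confuse a global threshold at realistic contrast, so the
#' interesting failure mode is the bias-noise interaction); and a combined
#' run with all stressors.
#'
#' @param seed Integer seed the specs are derived from.
#' @return Named list of 5 [phantom_spec()] objects
#'   (`clean`, `noisy`, `closure`, `bias`, `combined`).
#' @export
default_validation_suite <- function(seed = 1L) {
  seed <- as.integer(seed)
  base <- function(...) phantom_spec(rows = 64L, cols = 64L, frames = 50L, ...)
  contrast <- 1.0 - 0.15
  closure <- list(list(frames = c(15L, 30L), position = 0.55))
  list(
    clean = base(seed = seed, run_id = "phantom-clean"),
    noisy = base(noise_sigma = 0.10 * contrast, seed = seed + 100L,
                 run_id = "phantom-noisy"),
    closure = base(closures = closure, seed = seed + 200L,
                   run_id = "phantom-closure"),
    bias = base(noise_sigma = 0.10 * contrast,
                bias = list(model = "ramp", amplitude = 0.30),
                seed = seed + 300L, run_id = "phantom-bias"),
    combined = base(noise_sigma = 0.10 * contrast, closures = closure,
                    bias = list(model = "ramp", amplitude = 0.30),
                    seed = seed + 400L, run_id = "phantom-combined"))
}
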