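#' Bias field
#'
#' A smooth multiplicative intensity-inhomogeneity field: the spatial gain
#' pattern that makes identical tissue appear brighter in some parts of the
#' image than others. Normalized to mean 1 so that correction preserves the
#' overall intensity scale.
#'
#' @param field Positive numeric matrix (rows x cols).
#' @param model Text tag describing how the field was obtained
#'   (e.g. `"gaussian:sigma=15"`, `"polynomial:order=2"`).
#' @return An object of class `bias_field` (mean-1 normalized).
#' @export
bias_field <- function(field, model = "unspecified") {
  stopifnot(is.matrix(field))
  if (any(!is.finite(field)) || any(field <= 0))
    stop("a bias field must be strictly positive and finite", call. = FALSE)
  field <- field / mean(field)
  structure(list(field = field, model = as.character(model)[1L]),
            class = "bias_field")
}

# Gaussian-weighted local linear regression (a 2-D first-order
# Savitzky-Golay smoother with per-pixel validity weights). Unlike a plain
# normalized convolution it reproduces linear trends exactly, including at
# the image borders and across masked-out (air) gaps, which is what a
# slowly varying gain field looks like in the log domain. All regression
# moments are Gaussian convolutions, so the cost is nine separable smooths
# plus a closed-form 3x3 solve per pixel.
local_linear_smooth <- function(val, w, sigma) {
  nr <- nrow(val); nc <- ncol(val)
  r <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  sm <- function(x) gauss_smooth2d(x, sigma)
  A <- sm(w);            Br <- sm(w * r);        Bc <- sm(w * cc)
  Crr <- sm(w * r * r);  Ccc <- sm(w * cc * cc); Crc <- sm(w * r * cc)
  D <- sm(w * val);      Er <- sm(w * val * r);  Ec <- sm(w * val * cc)
  # centre moments at each pixel
  S10 <- Br - r * A;  S01 <- Bc - cc * A
  S20 <- Crr - 2 * r * Br + r * r * A
  S02 <- Ccc - 2 * cc * Bc + cc * cc * A
  S11 <- Crc - r * Bc - cc * Br + r * cc * A
  T0 <- D;  T1 <- Er - r * D;  T2 <- Ec - cc * D
  det3 <- A * (S20 * S02 - S11 * S11) - S10 * (S10 * S02 - S11 * S01) +
    S01 * (S10 * S11 - S20 * S01)
  a <- (T0 * (S20 * S02 - S11 * S11) - S10 * (T1 * S02 - S11 * T2) +
          S01 * (T1 * S11 - S20 * T2)) / det3
  ok <- is.finite(a) & abs(det3) > 1e-10 * pmax(A, 1e-12)^3
  fallback <- ifelse(A > 1e-8, T0 / pmax(A, 1e-8), mean(val[w > 0]))
  ifelse(ok, a, fallback)
}

# Separable Gaussian smoothing with zero padding. Used only inside
# normalized convolution, where the padding bias cancels in the ratio.
gauss_smooth2d <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- length(k)
  smooth1 <- function(m) {  # along rows of m
    nr <- nrow(m)
    pad <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
    out <- matrix(0, nr, ncol(m))
    for (i in seq_len(n)) out <- out + k[i] * pad[i:(i + nr - 1L), , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(x))))
}

#' Estimate a multiplicative intensity-inhomogeneity field
#'
#' Homomorphic estimation: the log of a reference image (temporal mean of
#' the run, or a single frame) is smoothed at a large spatial scale by
#' Gaussian-weighted local linear regression, and the exponential of the
#' smooth log-trend is taken as the gain field. Air
#' pixels (below a low intensity percentile) are excluded via normalized
#' convolution, because bias is a tissue-signal phenomenon and the log of
#' near-zero intensities is unstable. The alternative `"polynomial"` model
#' fits a quadratic log-intensity surface instead of smoothing.
#'
#' @param run An [image_run()].
#' @param smoothing_scale Gaussian sigma in pixels (> 1); the estimated
#'   field only varies at scales of this order or larger.
#' @param reference `"temporal_mean"` (default) or `"single_frame"`.
#' @param frame Frame used when `reference = "single_frame"`.
#' @param model `"gaussian"` (homomorphic smoothing) or `"polynomial"`
#'   (quadratic surface fit).
#' @param tissue_floor Quantile in `[0, 1)`; pixels at or below this
#'   intensity percentile of the reference are treated as air and excluded
#'   from estimation (default 0.10).
#' @return A [bias_field()] with mean 1.
#' @export
estimate_bias_field <- function(run, smoothing_scale = 15,
                                reference = c("temporal_mean", "single_frame"),
                                frame = 1L,
                                model = c("gaussian", "polynomial"),
                                tissue_floor = 0.10) {
  stopifnot(inherits(run, "image_run"))
  reference <- match.arg(reference)
  model <- match.arg(model)
  if (smoothing_scale <= 1)
    stop("`smoothing_scale` must exceed 1 pixel", call. = FALSE)
  ref <- if (reference == "temporal_mean") {
    apply(run$intensities, c(2, 3), mean)
  } else {
    run$intensities[frame, , ]
  }
  if (all(ref == 0))
    stop("reference image is identically zero; cannot estimate a bias field",
         call. = FALSE)
  floor_val <- stats::quantile(ref, tissue_floor, names = FALSE)
  w <- (ref > floor_val) & (ref > 0)
  if (!any(w)) w <- ref > 0
  logref <- matrix(0, nrow(ref), ncol(ref))
  logref[w] <- log(ref[w])
  if (model == "gaussian") {
    logfield <- local_linear_smooth(logref, w * 1.0, smoothing_scale)
    tag <- sprintf("gaussian:sigma=%g", smoothing_scale)
  } else {
    rr <- row(ref); cc <- col(ref)
    df <- data.frame(l = logref[w], r = rr[w], c = cc[w])
    fit <- stats::lm(l ~ r + c + I(r^2) + I(c^2) + I(r * c), data = df)
    logfield <- matrix(stats::predict(fit, data.frame(r = as.vector(rr),
                                                      c = as.vector(cc))),
                       nrow(ref), ncol(ref))
    tag <- "polynomial:order=2"
  }
  logfield <- logfield - mean(logfield)
  bias_field(exp(logfield), model = tag)
}

#' Divide a run by a bias field
#'
#' Each frame is divided pixel-wise by the (strictly positive, mean-1)
#' field; metadata is unchanged and intensities stay non-negative.
#'
#' @param run An [image_run()].
#' @param field A [bias_field()] with the run's row/col shape.
#' @return A corrected [image_run()].
#' @export
correct_run <- function(run, field) {
  stopifnot(inherits(run, "image_run"), inherits(field, "bias_field"))
  d <- dim(run$intensities)
  if (!all(d[2:3] == dim(field$field)))
    stop("bias field shape ", paste(dim(field$field), collapse = "x"),
         " does not match the run (", paste(d[2:3], collapse = "x"), ")",
         call. = FALSE)
  corrected <- run$intensities /
    aperm(array(field$field, c(d[2L], d[3L], d[1L])), c(3, 1, 2))
  image_run(corrected, fps = run$fps, pixel_mm = run$pixel_mm,
            run_id = run$run_id)
}
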