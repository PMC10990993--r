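#' Construct an image run
#'
#' An image run is one real-time MRI acquisition: a single mid-sagittal slice
#' imaged repeatedly over time, held as a `frames x rows x cols` intensity
#' array plus spatial and temporal metadata.
#'
#' @param intensities Numeric 3-D array with the frame axis first
#'   (`frame, row, col`). All values must be finite and non-negative.
#' @param fps Frames per second (temporal resolution). `NA` is a permitted
#'   sentinel: none of the processing stages require it.
#' @param pixel_mm Length-2 numeric, in-plane pixel size in mm
#'   (row spacing, column spacing); both must be positive.
#' @param run_id Character scalar identifying the run.
#' @return An object of class `image_run` with fields `intensities`, `fps`,
#'   `pixel_mm`, `run_id`.
#' @examples
#' run <- image_run(array(runif(4 * 8 * 8), c(4, 8, 8)), fps = 8, pixel_mm = c(2.5, 2.5))
#' n_frames(run)
#' @export
image_run <- function(intensities, fps = NA_real_, pixel_mm = c(1, 1),
                      run_id = "run") {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3-D array (frame, row, col); got ",
         length(dim(intensities)), " dimension(s)", call. = FALSE)
  if (dim(intensities)[1L] < 1L)
    stop("an image run needs at least one frame", call. = FALSE)
  storage.mode(intensities) <- "double"
  if (anyNA(intensities) || any(!is.finite(intensities)))
    stop("intensities must all be finite", call. = FALSE)
  if (any(intensities < 0))
    stop("intensities must be non-negative", call. = FALSE)
  pixel_mm <- as.numeric(pixel_mm)
  if (length(pixel_mm) == 1L) pixel_mm <- rep(pixel_mm, 2L)
  if (length(pixel_mm) != 2L || any(!is.na(pixel_mm) & pixel_mm <= 0))
    stop("`pixel_mm` must be two positive values", call. = FALSE)
  structure(list(intensities = intensities, fps = as.numeric(fps)[1L],
                 pixel_mm = pixel_mm, run_id = as.character(run_id)[1L]),
            class = "image_run")
}

#' @rdname image_run
#' @param run An `image_run`.
#' @export
n_frames <- function(run) {
  stopifnot(inherits(run, c("image_run", "tract_mask_series")))
  if (inherits(run, "image_run")) dim(run$intensities)[1L] else dim(run$masks)[1L]
}

#' @export
print.image_run <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<image_run '%s'> %d frame(s), %d x %d px, pixel %g x %g mm, fps %s\n",
              x$run_id, d[1L], d[2L], d[3L], x$pixel_mm[1L], x$pixel_mm[2L],
              format(x$fps)))
  invisible(x)
}

#' Frame-selection log
#'
#' Segments of interest within a run, as 1-based inclusive frame intervals
#' with optional text labels (e.g. the phone or word being articulated).
#'
#' @param onset,offset Integer vectors of first and last frame of each
#'   segment (1-based, inclusive, `onset <= offset`).
#' @param label Character vector of segment labels (recycled if length 1).
#' @return A `frame_selection_log`: a data frame with columns
#'   `onset`, `offset`, `label`, ordered by onset.
#' @export
frame_selection_log <- function(onset = integer(), offset = integer(),
                                label = character()) {
  onset <- as.integer(onset); offset <- as.integer(offset)
  if (length(label) == 0L) label <- rep("", length(onset))
  if (length(label) == 1L) label <- rep(label, length(onset))
  if (length(onset) != length(offset) || length(onset) != length(label))
    stop("onset, offset and label must have matching lengths", call. = FALSE)
  bad <- which(onset > offset)
  if (length(bad))
    stop("onset exceeds offset in segment row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(onset < 1L, na.rm = TRUE))
    stop("frame indices are 1-based; onset < 1 found", call. = FALSE)
  ord <- order(onset, offset)
  structure(data.frame(onset = onset[ord], offset = offset[ord],
                       label = label[ord], stringsAsFactors = FALSE),
            class = c("frame_selection_log", "data.frame"))
}

#' Region of interest
#'
#' The analyst-approved pixel set within which tissue classification is
#' confined. Carries a provenance list recording how it was built
#' (seeding parameters and polygon edits).
#'
#' @param mask Logical matrix (rows x cols).
#' @param provenance List of edit records.
#' @return An object of class `roi`.
#' @export
region_of_interest <- function(mask, provenance = list()) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  mask <- mask != 0
  structure(list(mask = mask, provenance = provenance), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %d x %d px, %d selected, %d edit record(s)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), length(x$provenance)))
  invisible(x)
}

#' Tract mask series
#'
#' Per-frame binary classification of vocal-tract (air) pixels, always a
#' subset of the region of interest it was classified within.
#'
#' @param masks Logical 3-D array (frame, row, col).
#' @param roi_used The [region_of_interest()] classification was confined to.
#' @param threshold_used Intensity threshold applied (may be `NA` for masks
#'   not produced by thresholding, e.g. phantom ground truth).
#' @param frame_index Original frame numbers of the retained frames
#'   (defaults to `1:frames`); preserved by frame selection.
#' @return An object of class `tract_mask_series`.
#' @export
tract_mask_series <- function(masks, roi_used, threshold_used = NA_real_,
                              frame_index = NULL) {
  if (!is.array(masks) || length(dim(masks)) != 3L)
    stop("`masks` must be a 3-D array (frame, row, col)", call. = FALSE)
  masks <- masks != 0
  if (!inherits(roi_used, "roi"))
    stop("`roi_used` must be a region_of_interest", call. = FALSE)
  if (!all(dim(masks)[2:3] == dim(roi_used$mask)))
    stop("mask series and ROI shapes differ", call. = FALSE)
  out <- aperm(masks, c(2, 3, 1))
  if (any(out & !as.vector(roi_used$mask)))
    stop("tract masks must be a subset of the ROI in every frame", call. = FALSE)
  if (is.null(frame_index)) frame_index <- seq_len(dim(masks)[1L])
  if (length(frame_index) != dim(masks)[1L])
    stop("`frame_index` length must equal the number of frames", call. = FALSE)
  structure(list(masks = masks, roi_used = roi_used,
                 threshold_used = as.numeric(threshold_used)[1L],
                 frame_index = as.integer(frame_index)),
            class = "tract_mask_series")
}

#' @export
print.tract_mask_series <- function(x, ...) {
  d <- dim(x$masks)
  cat(sprintf("<tract_mask_series> %d frame(s), %d x %d px, threshold %s\n",
              d[1L], d[2L], d[3L], format(x$threshold_used)))
  invisible(x)
}

#' Tract outline
#'
#' An ordered closed coordinate sequence around the vocal tract for one
#' frame. Points are `(y, z)` pairs in pixel units: `y` is the
#' anterior-posterior axis (column index) and `z` the ventral-dorsal axis
#' (row index, increasing superior to inferior). The sequence proceeds
#' clockwise (in screen orientation, z downwards) from the start site near
#' the upper margin of the lip aperture.
#'
#' @param points Two-column numeric matrix (columns `y`, `z`), at least 3
#'   points, without a duplicated closing point (closure is implied).
#' @param frame Frame index the outline belongs to.
#' @param closed Logical; closed contour flag.
#' @param start_convention Text tag describing the start-site rule.
#' @return An object of class `tract_outline`.
#' @export
tract_outline <- function(points, frame = 1L, closed = TRUE,
                          start_convention = "lips-upper-clockwise") {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("`points` must be a 2-column (y, z) matrix",
                               call. = FALSE)
  storage.mode(points) <- "double"
  if (anyNA(points) || any(!is.finite(points)))
    stop("outline coordinates must be finite", call. = FALSE)
  if (nrow(points) > 1L && all(points[1L, ] == points[nrow(points), ]))
    points <- points[-nrow(points), , drop = FALSE]
  if (nrow(points) < 3L)
    stop("an outline needs at least 3 distinct points", call. = FALSE)
  colnames(points) <- c("y", "z")
  structure(list(points = points, frame = as.integer(frame)[1L],
                 closed = isTRUE(closed),
                 start_convention = as.character(start_convention)[1L]),
            class = "tract_outline")
}

#' @export
print.tract_outline <- function(x, ...) {
  cat(sprintf("<tract_outline> frame %d, %d sites, %s, perimeter %.2f px\n",
              x$frame, nrow(x$points), if (x$closed) "closed" else "open",
              outline_perimeter(x)))
  invisible(x)
}

#' Anchor points for tract navigation
#'
#' Fixed endpoints of the vocal tract used by the A* bridging step: the
#' larynx (inferior end) and the lips (anterior end), as `(row, col)` pixel
#' coordinates.
#'
#' @param larynx,lips Length-2 integer-like `(row, col)` coordinates; must be
#'   distinct.
#' @return An object of class `anchor_points`.
#' @export
anchor_points <- function(larynx, lips) {
  larynx <- as.integer(round(larynx)); lips <- as.integer(round(lips))
  if (length(larynx) != 2L || length(lips) != 2L)
    stop("anchors must be (row, col) pairs", call. = FALSE)
  if (all(larynx == lips)) stop("larynx and lips anchors must be distinct",
                                call. = FALSE)
  structure(list(larynx = larynx, lips = lips), class = "anchor_points")
}

#' Analyst exclusion mask
#'
#' Pixels excluded from all further analysis (quality-assurance stage);
#' `TRUE` means exclude. Specified once per run, applied to every frame.
#'
#' @param mask Logical matrix (rows x cols); `TRUE` = exclude.
#' @param provenance List of polygon edit records.
#' @return An object of class `exclusion_mask`.
#' @export
exclusion_mask <- function(mask, provenance = list()) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  structure(list(mask = mask != 0, provenance = provenance),
            class = "exclusion_mask")
}
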