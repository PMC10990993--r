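# Stages 2-3: frame selection from logfiles and quality assurance.

#' Retain only logged frames of interest
#'
#' Keeps the frames in the union of the log's `[onset, offset]` intervals
#' (1-based inclusive), in original temporal order, each frame at most once.
#' The returned series' `frame_index` field maps retained frames back to
#' their original frame numbers; an explicit old-to-new map is attached as
#' the `"frame_map"` attribute.
#'
#' @param masks A [tract_mask_series()].
#' @param log A [frame_selection_log()] whose segments all lie within the
#'   series' original frame range.
#' @return A [tract_mask_series()] with only the retained frames.
#' @export
select_frames <- function(masks, log) {
  stopifnot(inherits(masks, "tract_mask_series"),
            inherits(log, "frame_selection_log"))
  nfr <- dim(masks$masks)[1L]
  frames_available <- masks$frame_index
  if (nrow(log)) {
    oob <- which(log$onset < min(frames_available) |
                   log$offset > max(frames_available))
    if (length(oob))
      stop("logfile segment(s) ",
           paste(sprintf("%d (%d-%d)", oob, log$onset[oob], log$offset[oob]),
                 collapse = ", "),
           " fall outside the run's frames ", min(frames_available), "..",
           max(frames_available), call. = FALSE)
  }
  wanted <- sort(unique(unlist(Map(seq.int, log$onset, log$offset))))
  keep <- which(frames_available %in% wanted)
  if (!length(keep))
    warning("frame selection retained 0 frames", call. = FALSE)
  out <- tract_mask_series(masks$masks[keep, , , drop = FALSE],
                           roi_used = masks$roi_used,
                           threshold_used = masks$threshold_used,
                           frame_index = frames_available[keep])
  attr(out, "frame_map") <- data.frame(old = frames_available[keep],
                                       new = seq_along(keep))
  out
}

#' Per-pixel classification-proportion QA map
#'
#' For each pixel, the proportion of (retained) frames in which it was
#' classified as vocal tract. Pixels that are often but not always
#' classified as tract show up as intermediate values and flag pockets of
#' likely misclassification for the analyst.
#'
#' @param masks A [tract_mask_series()] with at least one frame.
#' @return An object of class `qa_map`: list with `proportion`
#'   (rows x cols matrix in `[0, 1]`) and `n_frames`.
#' @export
compute_qa_map <- function(masks) {
  stopifnot(inherits(masks, "tract_mask_series"))
  nfr <- dim(masks$masks)[1L]
  if (nfr < 1L) stop("QA map needs at least one frame", call. = FALSE)
  d <- dim(masks$masks)
  prop <- matrix(colMeans(matrix(masks$masks, nrow = nfr)), d[2L], d[3L])
  structure(list(proportion = prop, n_frames = nfr), class = "qa_map")
}

#' @export
print.qa_map <- function(x, ...) {
  cat(sprintf("<qa_map> %d x %d px over %d frame(s); %d pixel(s) ever tract\n",
              nrow(x$proportion), ncol(x$proportion), x$n_frames,
              sum(x$proportion > 0)))
  invisible(x)
}

#' Apply analyst pixel exclusions to a whole run
#'
#' Sets every excluded pixel to FALSE in every frame; all other pixels are
#' unchanged. The exclusion is specified once per run and extrapolated to
#' all frames. Idempotent.
#'
#' @param masks A [tract_mask_series()].
#' @param excl An [exclusion_mask()] (or logical matrix, or list of
#'   `(row, col)` polygons which are rasterized first).
#' @return The filtered [tract_mask_series()].
#' @export
apply_exclusions <- function(masks, excl) {
  stopifnot(inherits(masks, "tract_mask_series"))
  d <- dim(masks$masks)
  if (is.list(excl) && !inherits(excl, "exclusion_mask") &&
      is.null(excl$mask))
    excl <- exclusion_from_polygons(excl, d[2:3])
  if (is.matrix(excl)) excl <- exclusion_mask(excl)
  stopifnot(inherits(excl, "exclusion_mask"))
  if (!all(d[2:3] == dim(excl$mask)))
    stop("exclusion mask shape ", paste(dim(excl$mask), collapse = "x"),
         " does not match the series (", paste(d[2:3], collapse = "x"), ")",
         call. = FALSE)
  keep3 <- aperm(array(!excl$mask, c(d[2L], d[3L], d[1L])), c(3, 1, 2))
  tract_mask_series(masks$masks & keep3, roi_used = masks$roi_used,
                    threshold_used = masks$threshold_used,
                    frame_index = masks$frame_index)
}

#' Build an exclusion mask from polygons
#'
#' @param polygons List of 2-column `(row, col)` vertex matrices.
#' @param dim Image dimensions `c(rows, cols)`.
#' @return An [exclusion_mask()].
#' @export
exclusion_from_polygons <- function(polygons, dim) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  mask <- matrix(FALSE, dim[1L], dim[2L])
  for (p in polygons) mask <- mask | polygon_to_mask(p, dim[1L], dim[2L])
  exclusion_mask(mask, provenance = lapply(polygons, function(p)
    list(op = "exclude", vertices = p)))
}

#' Render a QA map as a pink overlay PNG
#'
#' The proportion map is rendered as a translucent-to-opaque pink overlay on
#' a grayscale reference frame, mirroring the review display analysts use to
#' spot error-prone pockets. The numeric map (not this rendering) is the
#' canonical artifact.
#'
#' @param qa A `qa_map`.
#' @param reference Matrix used as the grayscale background (e.g. one frame
#'   of the run); rescaled to `[0, 1]`.
#' @param path Destination PNG.
#' @return `path`, invisibly.
#' @export
write_qa_png <- function(qa, reference, path) {
  stopifnot(inherits(qa, "qa_map"), is.matrix(reference))
  if (!all(dim(reference) == dim(qa$proportion)))
    stop("reference and QA map shapes differ", call. = FALSE)
  rng <- range(reference)
  g <- if (diff(rng) > 0) (reference - rng[1L]) / diff(rng) else reference * 0
  a <- qa$proportion
  rgba <- array(0, c(dim(g), 4L))
  rgba[, , 1L] <- g * (1 - a) + 1.0 * a          # pink: R = 1
  rgba[, , 2L] <- g * (1 - a) + 0.08 * a
  rgba[, , 3L] <- g * (1 - a) + 0.58 * a
  rgba[, , 4L] <- 1
  png::writePNG(rgba, path)
  invisible(path)
}
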