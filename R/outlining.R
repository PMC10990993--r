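# Stage 4: cavity detection, A* bridging, and closed-outline tracing.

#' Label discontinuous tract cavities
#'
#' 8-connected component labelling of the true pixels of a binary mask.
#' Articulator closures (e.g. stop consonants) split the tract into two or
#' more cavities, which show up here as separate components.
#'
#' @param mask Logical matrix.
#' @return List with `labels` (integer matrix, 0 = background) and `count`.
#' @export
find_cavities <- function(mask) {
  stopifnot(is.matrix(mask))
  label_components(mask != 0)
}

#' Merge cavities along a connector path
#'
#' Union of the mask with the path's pixels. Never removes pixels; all
#' cavities touched by the path merge into one 8-connected component.
#'
#' @param mask Logical matrix.
#' @param path A `path_result` from [astar_path()].
#' @return Logical matrix.
#' @export
bridge_cavities <- function(mask, path) {
  stopifnot(is.matrix(mask), inherits(path, "path_result"))
  out <- mask != 0
  out[path$pixels] <- TRUE
  out
}

#' Trace the closed outline of a single-cavity mask
#'
#' Sub-pixel boundary of the mask's one 8-connected component, taken as the
#' 0.5 iso-level contour of the binary grid (marching squares via
#' [grDevices::contourLines()]). Interior holes are filled first, so only
#' the outer boundary is returned, and diagonal-only links (e.g. along a
#' one-pixel connector) are resolved with a deterministic filler pixel so
#' the component yields a single contour. The contour is oriented clockwise (in
#' the `(y, z)` screen convention, z downwards) and rotated so that it
#' starts at the point nearest the lips anchor -- the upper margin of the
#' lip aperture; without an anchor the topmost (smallest z, then smallest y)
#' point starts.
#'
#' @param mask Logical matrix with exactly one 8-connected component of at
#'   least 3 pixels (bridge multi-cavity masks first).
#' @param frame Frame index recorded on the outline.
#' @param lips Optional `(row, col)` lips anchor fixing the start site.
#' @return A [tract_outline()].
#' @export
trace_outline <- function(mask, frame = 1L, lips = NULL) {
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  comp <- label_components(mask)
  if (comp$count == 0L)
    stop("mask is empty; nothing to trace", call. = FALSE)
  if (comp$count > 1L)
    stop("mask has ", comp$count, " components; bridge the cavities first ",
         "(bridge_cavities) so a single outline exists", call. = FALSE)
  if (sum(mask) < 3L)
    stop("component has fewer than 3 pixels; shape too degenerate to trace",
         call. = FALSE)
  filled <- resolve_saddles(fill_holes(mask))
  filled <- fill_holes(filled)
  nr <- nrow(filled); nc <- ncol(filled)
  z <- matrix(0, nr + 2L, nc + 2L)
  z[2:(nr + 1L), 2:(nc + 1L)] <- filled * 1.0
  cl <- grDevices::contourLines(x = 0:(nr + 1L), y = 0:(nc + 1L), z = z,
                                levels = 0.5)
  if (length(cl) != 1L)
    stop("expected a single outer contour, found ", length(cl), call. = FALSE)
  rr <- cl[[1L]]$x   # row coordinates
  cc <- cl[[1L]]$y   # col coordinates
  if (rr[1L] == rr[length(rr)] && cc[1L] == cc[length(cc)]) {
    rr <- rr[-length(rr)]; cc <- cc[-length(cc)]
  }
  pts <- cbind(y = cc, z = rr)
  if (signed_area(pts[, 1L], pts[, 2L]) < 0)   # enforce clockwise (z down)
    pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  start <- if (!is.null(lips)) {
    d2 <- (pts[, 1L] - lips[2L])^2 + (pts[, 2L] - lips[1L])^2
    cand <- which(d2 == min(d2))
  } else {
    cand <- which(pts[, 2L] == min(pts[, 2L]))
  }
  if (length(cand) > 1L) {
    cand <- cand[order(pts[cand, 2L], pts[cand, 1L])]  # upper, then anterior
  }
  s <- cand[1L]
  if (s > 1L) pts <- pts[c(s:nrow(pts), 1:(s - 1L)), , drop = FALSE]
  tract_outline(pts, frame = frame)
}

#' Outline every frame of a run, bridging closures where needed
#'
#' Per frame: a single-cavity mask is traced directly; a multi-cavity mask
#' first gets an A* connector from larynx to lips computed on that frame's
#' intensities within the search region (the ROI), is bridged, and is then
#' traced. Frames whose mask is empty, or whose anchors are unusable, are
#' reported in the status table and skipped rather than failing the run.
#'
#' @param masks A [tract_mask_series()].
#' @param run The [image_run()] the masks came from (same frame count and
#'   shape; intensities drive the A* weights).
#' @param anchors An [anchor_points()] pair, or `NULL` to derive a fallback
#'   from the first analysed frame (larynx = most inferior mask pixel,
#'   lips = most anterior mask pixel).
#' @param epsilon A* cost floor, see [astar_path()].
#' @param search_region Logical matrix overriding the default search region
#'   (the series' ROI).
#' @return An object of class `outline_set`: list with `outlines` (list of
#'   [tract_outline()]) and `status` (data frame: `frame`, `n_cavities`,
#'   `bridged`, `ok`, `reason`).
#' @export
outline_run <- function(masks, run, anchors = NULL, epsilon = 0.01,
                        search_region = NULL) {
  stopifnot(inherits(masks, "tract_mask_series"), inherits(run, "image_run"))
  d <- dim(masks$masks)
  drun <- dim(run$intensities)
  if (!all(d[2:3] == drun[2:3]))
    stop("mask series and run shapes differ", call. = FALSE)
  if (is.null(search_region)) search_region <- masks$roi_used$mask
  if (is.null(anchors)) {
    m1 <- NULL
    for (f in seq_len(d[1L])) if (any(masks$masks[f, , ])) {
      m1 <- masks$masks[f, , ]; break
    }
    if (is.null(m1)) stop("all frames are empty; cannot derive anchors",
                          call. = FALSE)
    idx <- which(m1, arr.ind = TRUE)
    la <- idx[idx[, 1L] == max(idx[, 1L]), , drop = FALSE]
    la <- la[order(la[, 2L]), , drop = FALSE][1L, ]
    li <- idx[idx[, 2L] == min(idx[, 2L]), , drop = FALSE]
    li <- li[order(li[, 1L]), , drop = FALSE][1L, ]
    anchors <- anchor_points(la, li)
  }
  outlines <- list()
  status <- data.frame(frame = masks$frame_index,
                       n_cavities = 0L, bridged = FALSE, ok = FALSE,
                       reason = "", stringsAsFactors = FALSE)
  for (f in seq_len(d[1L])) {
    m <- masks$masks[f, , ]
    comp <- find_cavities(m)
    status$n_cavities[f] <- comp$count
    if (comp$count == 0L) {
      status$reason[f] <- "empty mask"
      next
    }
    res <- tryCatch({
      if (comp$count > 1L) {
        # the run frame matching this (possibly selected) mask frame
        rf <- if (drun[1L] == d[1L]) f else masks$frame_index[f]
        path <- astar_path(run$intensities[rf, , ], search_region, anchors,
                           epsilon = epsilon)
        m <- bridge_cavities(m, path)
        status$bridged[f] <- TRUE
      }
      trace_outline(m, frame = masks$frame_index[f], lips = anchors$lips)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status$reason[f] <- conditionMessage(res)
      status$bridged[f] <- FALSE
    } else {
      outlines[[length(outlines) + 1L]] <- res
      status$ok[f] <- TRUE
    }
  }
  structure(list(outlines = outlines, status = status, anchors = anchors),
            class = "outline_set")
}

#' @export
print.outline_set <- function(x, ...) {
  cat(sprintf("<outline_set> %d outline(s) of %d frame(s); %d bridged, %d failed\n",
              length(x$outlines), nrow(x$status), sum(x$status$bridged),
              sum(!x$status$ok)))
  invisible(x)
}
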