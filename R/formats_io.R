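# Persistence layer: every on-disk artifact of the pipeline goes through the
# readers/writers in this file. Conventions:
#   * runs and mask series are stored with the frame axis LAST on disk
#     (row, col, frame) -- the natural NIfTI/TIFF layout -- and converted to
#     the in-memory (frame, row, col) order on read, exactly once;
#   * frame indices in logfiles are 1-based inclusive;
#   * outline coordinates are written as decimal text with 6 digits after the
#     point, so round-trips are exact to 1e-6 px.

sidecar_path <- function(path) paste0(path, ".meta")

write_sidecar <- function(path, fields) {
  lines <- sprintf("%s=%s", names(fields), vapply(fields, function(v)
    paste(format(v, digits = 17), collapse = ","), ""))
  writeLines(lines, sidecar_path(path))
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(list())
  lines <- readLines(sp, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  out <- lapply(kv, function(x) trimws(x[2L]))
  names(out) <- trimws(vapply(kv, `[`, "", 1L))
  out
}

# numeric sidecar values, treating the "NA" sentinel silently
parse_num <- function(s) {
  out <- suppressWarnings(as.numeric(s))
  out
}

guess_format <- function(path, format_hint = NULL) {
  if (!is.null(format_hint)) return(match.arg(format_hint, c("nifti", "tiff", "raw")))
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) "nifti"
  else if (grepl("\\.tiff?$", low)) "tiff"
  else "raw"
}

#' Read a dynamic image run
#'
#' Reads a real-time MRI run (one slice over time) from NIfTI
#' (`.nii`/`.nii.gz`), multi-page TIFF, or a raw little-endian double dump
#' with a `key=value` sidecar (`<path>.meta`). The frame axis is last on
#' disk and first in memory. Metadata (`fps`, `pixel_mm`, `run_id`) is taken
#' from the NIfTI header where available and from the sidecar otherwise;
#' missing `fps` becomes `NA` with a warning (no stage requires it), and
#' missing `pixel_mm` becomes 1 mm with a warning.
#'
#' @param path File to read.
#' @param format_hint Optional: `"nifti"`, `"tiff"` or `"raw"` to override
#'   extension-based detection.
#' @return An [image_run()].
#' @export
read_run <- function(path, format_hint = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fmt <- guess_format(path, format_hint)
  meta <- read_sidecar(path)
  pixel_from_header <- NULL
  arr <- switch(fmt,
    nifti = {
      img <- tryCatch(RNifti::readNifti(path), error = function(e)
        stop("could not read '", path, "' as NIfTI: ", conditionMessage(e),
             call. = FALSE))
      pd <- RNifti::pixdim(img)
      if (length(pd) >= 2L) pixel_from_header <- pd[1:2]
      a <- as.array(img)
      if (length(dim(a)) == 2L)
        stop("'", path, "' holds a single 2-D image; a run must be 3-D ",
             "(row, col, frame)", call. = FALSE)
      if (length(dim(a)) != 3L)
        stop("'", path, "' is ", length(dim(a)), "-D; expected 3-D", call. = FALSE)
      a
    },
    tiff = {
      pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                        error = function(e)
        stop("could not read '", path, "' as TIFF: ", conditionMessage(e),
             call. = FALSE))
      if (!is.list(pages)) pages <- list(pages)
      if (length(pages) < 1L) stop("empty TIFF: ", path, call. = FALSE)
      dims <- vapply(pages, dim, integer(2))
      if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
        stop("TIFF pages in '", path, "' differ in shape", call. = FALSE)
      array(unlist(pages), c(dims[1, 1], dims[2, 1], length(pages)))
    },
    raw = {
      if (is.null(meta$dim))
        stop("raw dump '", path, "' needs a sidecar '", sidecar_path(path),
             "' with a dim=rows,cols,frames entry", call. = FALSE)
      d <- as.integer(strsplit(meta$dim, ",")[[1L]])
      if (length(d) != 3L) stop("sidecar dim must have 3 entries", call. = FALSE)
      v <- readBin(path, "double", n = prod(d), endian = "little")
      if (length(v) != prod(d))
        stop("raw dump '", path, "' shorter than its declared dim", call. = FALSE)
      array(v, d)
    })
  fps <- if (!is.null(meta$fps)) parse_num(meta$fps) else NA_real_
  if (is.na(fps)) warning("no fps metadata for '", path,
                          "'; recording fps = NA (no stage requires it)",
                          call. = FALSE)
  pixel_mm <- if (!is.null(meta$pixel_mm))
    parse_num(strsplit(meta$pixel_mm, ",")[[1L]])
  else pixel_from_header
  if (is.null(pixel_mm) || !length(pixel_mm) || anyNA(pixel_mm) ||
      any(pixel_mm <= 0)) {
    warning("no pixel size metadata for '", path, "'; assuming 1 mm",
            call. = FALSE)
    pixel_mm <- c(1, 1)
  }
  if (length(pixel_mm) == 1L) pixel_mm <- rep(pixel_mm, 2L)
  run_id <- if (!is.null(meta$run_id)) meta$run_id
            else sub("\\.(nii(\\.gz)?|tiff?|bin|raw)$", "",
                     basename(path), ignore.case = TRUE)
  image_run(aperm(arr, c(3, 1, 2)), fps = fps, pixel_mm = pixel_mm[1:2],
            run_id = run_id)
}

#' Write a dynamic image run
#'
#' Inverse of [read_run()]. NIfTI stores `pixel_mm` in the header; all
#' formats additionally get a `key=value` sidecar carrying `fps`,
#' `pixel_mm` and `run_id`. TIFF storage is 32-bit float and only defined
#' for intensities in `[0, 1]`; out-of-range runs must use NIfTI or raw.
#'
#' @param run An [image_run()].
#' @param path Destination; extension selects the format.
#' @param format_hint Optional format override as in [read_run()].
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path, format_hint = NULL) {
  stopifnot(inherits(run, "image_run"))
  fmt <- guess_format(path, format_hint)
  arr <- aperm(run$intensities, c(2, 3, 1))  # (row, col, frame) on disk
  switch(fmt,
    nifti = {
      img <- RNifti::asNifti(arr)
      RNifti::pixdim(img) <- c(run$pixel_mm, 1)
      RNifti::writeNifti(img, path)
    },
    tiff = {
      if (min(arr) < 0 || max(arr) > 1)
        stop("TIFF float storage is only defined for intensities in [0, 1]; ",
             "write this run as NIfTI or raw instead", call. = FALSE)
      pages <- lapply(seq_len(dim(arr)[3L]), function(k) arr[, , k])
      tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    },
    raw = {
      writeBin(as.vector(arr), path, endian = "little")
    })
  write_sidecar(path, list(dim = dim(arr), fps = run$fps,
                           pixel_mm = run$pixel_mm, run_id = run$run_id))
  invisible(path)
}

#' Read a frame-selection logfile
#'
#' Accepts either a CSV with header columns `onset,offset,label` (frame
#' numbers, 1-based inclusive) or a Praat TextGrid (long text format,
#' interval tiers only), whose interval times are converted to frames as
#' `onset = floor(t_min * fps) + 1`, `offset = ceiling(t_max * fps)`, clamped
#' to the run length — a rule that never drops material at segment edges.
#' For TextGrids only intervals with non-empty labels are kept.
#'
#' @param path CSV or TextGrid file.
#' @param fps Frames per second; required for TextGrid input.
#' @param n_frames Optional run length used to validate (CSV) or clamp
#'   (TextGrid) frame indices.
#' @param tier For TextGrids: name or index of the interval tier to read
#'   (default: first interval tier).
#' @return A [frame_selection_log()] ordered by onset.
#' @export
read_logfile <- function(path, fps = NULL, n_frames = NULL, tier = 1L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  head_txt <- paste(readLines(path, n = 5L, warn = FALSE), collapse = "\n")
  if (grepl("ooTextFile|TextGrid", head_txt)) {
    log <- read_textgrid_log(path, fps = fps, n_frames = n_frames, tier = tier)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    req <- c("onset", "offset")
    if (!all(req %in% names(df)))
      stop("logfile CSV must have header columns onset, offset[, label]",
           call. = FALSE)
    if (nrow(df) == 0L) return(frame_selection_log())
    on_num <- suppressWarnings(as.numeric(df$onset))
    off_num <- suppressWarnings(as.numeric(df$offset))
    bad <- which(is.na(on_num) | is.na(off_num) |
                   on_num != round(on_num) | off_num != round(off_num))
    if (length(bad))
      stop("non-integer frame index in logfile row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    swapped <- which(on_num > off_num)
    if (length(swapped))
      stop("onset exceeds offset in logfile row(s) ",
           paste(swapped, collapse = ", "), call. = FALSE)
    lab <- if ("label" %in% names(df)) df$label else rep("", nrow(df))
    log <- frame_selection_log(on_num, off_num, lab)
  }
  if (!is.null(n_frames) && nrow(log)) {
    oob <- which(log$onset < 1L | log$offset > n_frames)
    if (length(oob))
      stop("logfile segment(s) ", paste(oob, collapse = ", "),
           " fall outside frames 1..", n_frames, call. = FALSE)
  }
  log
}

# Minimal Praat TextGrid (long text format) interval-tier parser.
read_textgrid_log <- function(path, fps, n_frames = NULL, tier = 1L) {
  if (is.null(fps) || is.na(fps) || fps <= 0)
    stop("TextGrid input needs a positive `fps` to convert times to frames",
         call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  grab <- function(pattern, x) {
    m <- regmatches(x, regexec(pattern, x))
    vapply(m[lengths(m) == 2L], `[`, "", 2L)
  }
  item_starts <- grep("^\\s*item\\s*\\[\\d+\\]", lines)
  if (!length(item_starts)) stop("no tiers found in TextGrid: ", path,
                                 call. = FALSE)
  bounds <- c(item_starts, length(lines) + 1L)
  tiers <- lapply(seq_along(item_starts), function(i)
    lines[bounds[i]:(bounds[i + 1L] - 1L)])
  classes <- vapply(tiers, function(tl)
    grab('class\\s*=\\s*"([^"]*)"', tl[grep("class", tl)[1L]]), "")
  names(tiers) <- vapply(tiers, function(tl) {
    hit <- grep('^\\s*name\\s*=', tl)
    if (length(hit)) grab('name\\s*=\\s*"([^"]*)"', tl[hit[1L]]) else ""
  }, "")
  interval_tiers <- which(classes == "IntervalTier")
  if (!length(interval_tiers))
    stop("TextGrid '", path, "' has no interval tiers", call. = FALSE)
  sel <- if (is.numeric(tier)) interval_tiers[tier]
         else interval_tiers[match(tier, names(tiers)[interval_tiers])]
  if (is.na(sel)) stop("interval tier '", tier, "' not found in ", path,
                       call. = FALSE)
  tl <- tiers[[sel]]
  iv_starts <- grep("^\\s*intervals\\s*\\[\\d+\\]", tl)
  if (!length(iv_starts)) return(frame_selection_log())
  iv_bounds <- c(iv_starts, length(tl) + 1L)
  seg <- lapply(seq_along(iv_starts), function(i) {
    block <- tl[iv_bounds[i]:(iv_bounds[i + 1L] - 1L)]
    xmin <- as.numeric(grab("xmin\\s*=\\s*([0-9.eE+-]+)",
                            block[grep("xmin", block)[1L]]))
    xmax <- as.numeric(grab("xmax\\s*=\\s*([0-9.eE+-]+)",
                            block[grep("xmax", block)[1L]]))
    lab <- grab('text\\s*=\\s*"([^"]*)"', block[grep("text", block)[1L]])
    if (!length(lab)) lab <- ""
    data.frame(xmin = xmin, xmax = xmax, label = lab,
               stringsAsFactors = FALSE)
  })
  seg <- do.call(rbind, seg)
  seg <- seg[nzchar(seg$label), , drop = FALSE]
  if (!nrow(seg)) return(frame_selection_log())
  onset <- floor(seg$xmin * fps) + 1
  offset <- ceiling(seg$xmax * fps)
  onset <- pmax(onset, 1)
  if (!is.null(n_frames)) {
    offset <- pmin(offset, n_frames)
    onset <- pmin(onset, n_frames)
  }
  offset <- pmax(offset, onset)
  frame_selection_log(onset, offset, seg$label)
}

#' Write a frame-selection logfile
#'
#' @param log A [frame_selection_log()].
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_logfile <- function(log, path) {
  stopifnot(inherits(log, "frame_selection_log"))
  utils::write.csv(as.data.frame(unclass(log))[c("onset", "offset", "label")],
                   path, row.names = FALSE)
  invisible(path)
}

mask_array_to_disk <- function(arr01, path, format_hint = NULL) {
  fmt <- guess_format(path, format_hint)
  switch(fmt,
    nifti = {
      img <- RNifti::asNifti(array(as.integer(arr01), dim(arr01)),
                             datatype = "uint8")
      RNifti::writeNifti(img, path)
    },
    tiff = {
      pages <- lapply(seq_len(dim(arr01)[3L]), function(k) arr01[, , k] * 1.0)
      tiff::writeTIFF(pages, path, bits.per.sample = 8L)
    },
    raw = {
      writeBin(as.vector(arr01 * 1.0), path, endian = "little")
    })
  invisible(path)
}

disk_to_mask_array <- function(path, format_hint = NULL) {
  fmt <- guess_format(path, format_hint)
  arr <- switch(fmt,
    nifti = as.array(RNifti::readNifti(path)),
    tiff = {
      pages <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      array(unlist(pages), c(dim(pages[[1L]]), length(pages)))
    },
    raw = {
      meta <- read_sidecar(path)
      if (is.null(meta$dim)) stop("raw mask dump needs a sidecar dim entry",
                                  call. = FALSE)
      d <- as.integer(strsplit(meta$dim, ",")[[1L]])
      array(readBin(path, "double", n = prod(d), endian = "little"), d)
    })
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  vals <- unique(round(as.vector(arr), 9))
  if (!all(vals %in% c(0, 1)))
    stop("'", path, "' contains non-binary values; not a mask file",
         call. = FALSE)
  arr != 0
}

#' Persist and restore tract mask series
#'
#' Boolean stacks stored losslessly as NIfTI uint8 or 8-bit multi-page TIFF,
#' frame axis last on disk. A sidecar records the on-disk shape, threshold
#' and retained frame indices; shape disagreement on read is an error.
#'
#' @param masks A [tract_mask_series()].
#' @param path Destination (`.nii`, `.nii.gz`, `.tif`).
#' @return `write_mask_series`: `path`, invisibly. `read_mask_series`: a
#'   [tract_mask_series()] (its `roi_used` is reconstructed as the union of
#'   frames unless a companion ROI file `<path>.roi` exists).
#' @export
write_mask_series <- function(masks, path) {
  stopifnot(inherits(masks, "tract_mask_series"))
  arr <- aperm(masks$masks, c(2, 3, 1))
  mask_array_to_disk(arr, path)
  write_sidecar(path, list(dim = dim(arr), threshold = masks$threshold_used,
                           frame_index = masks$frame_index))
  mask_array_to_disk(array(masks$roi_used$mask, c(dim(arr)[1:2], 1L)),
                     paste0(path, ".roi"), format_hint = "tiff")
  invisible(path)
}

#' @rdname write_mask_series
#' @export
read_mask_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  arr <- disk_to_mask_array(path)
  meta <- read_sidecar(path)
  if (!is.null(meta$dim)) {
    d <- as.integer(strsplit(meta$dim, ",")[[1L]])
    if (!identical(d, dim(arr)))
      stop("mask series '", path, "' shape ", paste(dim(arr), collapse = "x"),
           " does not match its sidecar (", paste(d, collapse = "x"), ")",
           call. = FALSE)
  }
  roi_path <- paste0(path, ".roi")
  roi <- if (file.exists(roi_path)) {
    region_of_interest(disk_to_mask_array(roi_path, "tiff")[, , 1L])
  } else {
    region_of_interest(apply(arr, c(1, 2), any))
  }
  thr <- if (!is.null(meta$threshold)) parse_num(meta$threshold) else NA_real_
  fidx <- if (!is.null(meta$frame_index))
    as.integer(strsplit(meta$frame_index, ",")[[1L]]) else NULL
  tract_mask_series(aperm(arr, c(3, 1, 2)), roi, threshold_used = thr,
                    frame_index = fidx)
}

#' Persist and restore 2-D masks (ROIs, exclusions)
#'
#' @param mask Logical matrix, or an object with a `$mask` field
#'   ([region_of_interest()], [exclusion_mask()]).
#' @param path Destination (`.tif` or `.nii`).
#' @return `write_mask`: `path` invisibly; `read_mask`: a logical matrix.
#' @export
write_mask <- function(mask, path) {
  if (is.list(mask) && !is.null(mask$mask)) mask <- mask$mask
  stopifnot(is.matrix(mask))
  mask_array_to_disk(array(mask != 0, c(dim(mask), 1L)), path)
  write_sidecar(path, list(dim = dim(mask)))
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  disk_to_mask_array(path)[, , 1L]
}

#' Write and read tract outlines as CSV
#'
#' One row per outline site with columns `run_id, frame, site_index, y, z`;
#' coordinates are written with 6 decimal digits, so a write-then-read
#' round-trip is exact to 1e-6 px.
#'
#' @param outlines Non-empty list of [tract_outline()] objects.
#' @param path Destination CSV.
#' @param run_id Run identifier written into the file.
#' @return `write_outlines`: `path` invisibly; `read_outlines`: a list of
#'   [tract_outline()] ordered by frame.
#' @export
write_outlines <- function(outlines, path, run_id = "run") {
  if (inherits(outlines, "tract_outline")) outlines <- list(outlines)
  if (!length(outlines)) stop("no outlines to write", call. = FALSE)
  stopifnot(all(vapply(outlines, inherits, TRUE, "tract_outline")))
  rows <- lapply(outlines, function(o)
    data.frame(run_id = run_id, frame = o$frame,
               site_index = seq_len(nrow(o$points)),
               y = sprintf("%.6f", o$points[, 1L]),
               z = sprintf("%.6f", o$points[, 2L]),
               stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = 1L)
  invisible(path)
}

#' @rdname write_outlines
#' @export
read_outlines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("frame", "site_index", "y", "z")
  if (!all(req %in% names(df)))
    stop("outline CSV must have columns run_id, frame, site_index, y, z",
         call. = FALSE)
  out <- lapply(split(df, df$frame), function(g) {
    g <- g[order(g$site_index), , drop = FALSE]
    tract_outline(cbind(g$y, g$z), frame = g$frame[1L])
  })
  out[order(vapply(out, function(o) o$frame, 1L))]
}
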