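# Stage 5: reproducible outline correction.
#
# The interactive review/erase/redraw step is replaced by declarative edit
# scripts: pure functions over outlines, validated before anything is
# applied (all-or-nothing), with an audit log that fully determines the
# transformation.

#' Erase a run of sites from an outline
#'
#' Removes the sites in `site_range` (1-based inclusive `c(from, to)`); the
#' outline is re-closed by joining the flanking points, and orientation is
#' preserved. An empty range (`NULL` or `c(from, from - 1)`) is the
#' identity.
#'
#' @param outline A [tract_outline()].
#' @param site_range `c(from, to)` within the outline length, or `NULL`.
#' @return The edited [tract_outline()] (at least 3 points must remain).
#' @export
erase_segment <- function(outline, site_range) {
  stopifnot(inherits(outline, "tract_outline"))
  n <- nrow(outline$points)
  if (is.null(site_range) || !length(site_range)) return(outline)
  site_range <- as.integer(site_range)
  if (length(site_range) != 2L)
    stop("`site_range` must be c(from, to)", call. = FALSE)
  from <- site_range[1L]; to <- site_range[2L]
  if (to == from - 1L) return(outline)  # empty range
  if (from < 1L || to > n || from > to)
    stop("site range [", from, ", ", to, "] invalid for an outline of ", n,
         " sites", call. = FALSE)
  keep <- setdiff(seq_len(n), from:to)
  if (length(keep) < 3L)
    stop("erasing sites ", from, "-", to, " would leave fewer than 3 points",
         call. = FALSE)
  tract_outline(outline$points[keep, , drop = FALSE], frame = outline$frame,
                closed = outline$closed,
                start_convention = outline$start_convention)
}

#' Insert new sites into an outline
#'
#' Splices `new_points` after site `at_site` (`0` prepends before the first
#' site). Closure is preserved; if the splice flipped the contour's signed
#' area (orientation), the sequence is reversed and re-rotated so the
#' original first point stays first.
#'
#' @param outline A [tract_outline()].
#' @param at_site Site index in `0..n` after which to insert.
#' @param new_points Non-empty 2-column `(y, z)` matrix of finite
#'   coordinates.
#' @return The edited [tract_outline()].
#' @export
insert_segment <- function(outline, at_site, new_points) {
  stopifnot(inherits(outline, "tract_outline"))
  n <- nrow(outline$points)
  at_site <- as.integer(at_site)[1L]
  if (at_site < 0L || at_site > n)
    stop("`at_site` must lie in 0..", n, call. = FALSE)
  new_points <- matrix(as.numeric(new_points), ncol = 2L)
  if (!nrow(new_points)) stop("`new_points` is empty", call. = FALSE)
  if (anyNA(new_points) || any(!is.finite(new_points)))
    stop("`new_points` must be finite coordinates", call. = FALSE)
  before_sign <- sign(signed_area(outline$points[, 1L], outline$points[, 2L]))
  pts <- if (at_site == 0L) rbind(new_points, outline$points)
         else rbind(outline$points[seq_len(at_site), , drop = FALSE],
                    new_points,
                    if (at_site < n)
                      outline$points[(at_site + 1L):n, , drop = FALSE])
  after_sign <- sign(signed_area(pts[, 1L], pts[, 2L]))
  if (before_sign != 0 && after_sign != 0 && before_sign != after_sign) {
    pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
    s <- which(pts[, 1L] == outline$points[1L, 1L] &
                 pts[, 2L] == outline$points[1L, 2L])[1L]
    if (!is.na(s) && s > 1L)
      pts <- pts[c(s:nrow(pts), 1:(s - 1L)), , drop = FALSE]
  }
  tract_outline(pts, frame = outline$frame, closed = outline$closed,
                start_convention = outline$start_convention)
}

#' Replace a run of sites
#'
#' [erase_segment()] followed by [insert_segment()] at the erased position.
#'
#' @inheritParams erase_segment
#' @param new_points Replacement `(y, z)` coordinates (non-empty).
#' @return The edited [tract_outline()].
#' @export
replace_segment <- function(outline, site_range, new_points) {
  out <- erase_segment(outline, site_range)
  insert_segment(out, at_site = site_range[1L] - 1L, new_points = new_points)
}

#' Edit script constructor
#'
#' @param edits List of edits; each a list with fields `frame`, `action`
#'   (`"erase"`, `"insert"`, `"replace"`), `range` (`c(from, to)`, for
#'   erase/replace), `at` (site index, for insert) and `points` (coordinate
#'   matrix or list of `(y, z)` pairs, for insert/replace).
#' @return An object of class `edit_script`.
#' @export
edit_script <- function(edits = list()) {
  for (i in seq_along(edits)) {
    e <- edits[[i]]
    if (is.null(e$frame) || is.null(e$action) ||
        !e$action %in% c("erase", "insert", "replace"))
      stop("edit ", i, " needs a frame and an action of erase/insert/replace",
           call. = FALSE)
    if (e$action %in% c("insert", "replace")) {
      if (is.null(e$points) || !length(e$points))
        stop("edit ", i, " (", e$action, ") needs non-empty points",
             call. = FALSE)
      edits[[i]]$points <- coerce_points(e$points)
    }
    if (e$action == "erase" && !is.null(e$points))
      stop("edit ", i, " (erase) must not carry points", call. = FALSE)
    if (e$action %in% c("erase", "replace") && length(e$range) != 2L)
      stop("edit ", i, " (", e$action, ") needs range = c(from, to)",
           call. = FALSE)
    if (e$action == "insert" && is.null(e$at))
      stop("edit ", i, " (insert) needs `at`", call. = FALSE)
  }
  structure(list(edits = edits), class = "edit_script")
}

coerce_points <- function(p) {
  if (is.matrix(p)) return(matrix(as.numeric(p), ncol = 2L))
  if (is.data.frame(p)) return(as.matrix(p[, 1:2]))
  if (is.list(p)) return(do.call(rbind, lapply(p, function(q)
    as.numeric(q)[1:2])))
  matrix(as.numeric(p), ncol = 2L, byrow = TRUE)
}

#' Apply an edit script to a set of outlines
#'
#' Validates every edit (referenced frames must have outlines) before any
#' edit is applied, then applies them in order. Unedited frames pass
#' through untouched; an audit log records each edit with before/after
#' point counts.
#'
#' @param outlines List of [tract_outline()] objects.
#' @param script An [edit_script()] (or path to an edit-script JSON file).
#' @return List with `outlines` (edited list, same order) and `audit`
#'   (data frame: `edit`, `frame`, `action`, `before_n`, `after_n`).
#' @export
apply_edit_script <- function(outlines, script) {
  if (is.character(script)) script <- read_edit_script(script)
  stopifnot(inherits(script, "edit_script"))
  if (inherits(outlines, "tract_outline")) outlines <- list(outlines)
  frames <- vapply(outlines, function(o) o$frame, 1L)
  wanted <- vapply(script$edits, function(e) as.integer(e$frame), 1L)
  missing <- setdiff(wanted, frames)
  if (length(missing))
    stop("edit script references frame(s) without an outline: ",
         paste(missing, collapse = ", "), " - no edits were applied",
         call. = FALSE)
  audit <- data.frame(edit = integer(), frame = integer(),
                      action = character(), before_n = integer(),
                      after_n = integer(), stringsAsFactors = FALSE)
  for (i in seq_along(script$edits)) {
    e <- script$edits[[i]]
    j <- which(frames == as.integer(e$frame))[1L]
    before_n <- nrow(outlines[[j]]$points)
    outlines[[j]] <- switch(e$action,
      erase = erase_segment(outlines[[j]], e$range),
      insert = insert_segment(outlines[[j]], e$at, e$points),
      replace = replace_segment(outlines[[j]], e$range, e$points))
    audit <- rbind(audit, data.frame(edit = i, frame = as.integer(e$frame),
                                     action = e$action, before_n = before_n,
                                     after_n = nrow(outlines[[j]]$points),
                                     stringsAsFactors = FALSE))
  }
  list(outlines = outlines, audit = audit)
}

#' Read / write edit scripts as JSON
#'
#' Format: `{"edits": [{"frame": 3, "action": "erase", "range": [10, 14]},`
#' `{"frame": 3, "action": "insert", "at": 9, "points": [[y, z], ...]}]}`.
#'
#' @param path JSON file.
#' @return `read_edit_script`: an [edit_script()];
#'   `write_edit_script`: `path`, invisibly.
#' @export
read_edit_script <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (is.null(raw$edits)) stop("edit-script JSON needs an `edits` array",
                               call. = FALSE)
  edit_script(lapply(raw$edits, function(e) {
    if (!is.null(e$range)) e$range <- as.integer(unlist(e$range))
    if (!is.null(e$points)) e$points <- coerce_points(e$points)
    e
  }))
}

#' @rdname read_edit_script
#' @param script An [edit_script()].
#' @export
write_edit_script <- function(script, path) {
  stopifnot(inherits(script, "edit_script"))
  edits <- lapply(script$edits, function(e) {
    if (!is.null(e$points))
      e$points <- lapply(seq_len(nrow(e$points)), function(i)
        as.numeric(e$points[i, ]))
    e
  })
  jsonlite::write_json(list(edits = edits), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
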