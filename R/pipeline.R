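# End-to-end orchestration of stages 1-5 for one run, with a content-hashed
# manifest so analyst interventions stay auditable.

#' Pipeline configuration
#'
#' Collects inputs, stage toggles and parameters for [run_pipeline()].
#' Stage order is fixed (bias correction, masking, selection, QA,
#' outlining, correction); stages 2 (selection), 3 (QA exclusions) and
#' 5 (correction) are optional and pass data through unchanged when their
#' input is absent or they are disabled.
#'
#' @param run Path to the run image file, or an [image_run()].
#' @param out_dir Output directory (created if needed).
#' @param logfile Optional frame-selection logfile path or
#'   [frame_selection_log()] (stage 2).
#' @param roi Optional ROI mask path or [region_of_interest()]; when absent
#'   the ROI is seeded from the variance map.
#' @param roi_edits Optional list with `additions`/`removals` polygon lists
#'   applied to the ROI.
#' @param exclusions Optional exclusion polygons (list), mask path, or
#'   [exclusion_mask()] (stage 3).
#' @param anchors Optional [anchor_points()] or path to an anchors JSON
#'   (`{"larynx": [row, col], "lips": [row, col]}`).
#' @param edit_script Optional [edit_script()] or path to its JSON (stage 5).
#' @param stages Named logical vector toggling the optional stages,
#'   e.g. `c(select = TRUE, qa = TRUE, correct = TRUE)`.
#' @param bias_correct Apply intensity-inhomogeneity correction before
#'   stage 1 (default FALSE; decide per dataset).
#' @param params Named list of tunables: `quantile` (ROI seeding, 0.75),
#'   `smoothing_scale` (bias, 15), `epsilon` (A*, 0.01), `n_sites`
#'   (outline resampling for the sites artifact; default largest outline).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(run, out_dir, logfile = NULL, roi = NULL,
                            roi_edits = NULL, exclusions = NULL,
                            anchors = NULL, edit_script = NULL,
                            stages = c(select = TRUE, qa = TRUE,
                                       correct = TRUE),
                            bias_correct = FALSE, params = list()) {
  defaults <- list(quantile = 0.75, smoothing_scale = 15, epsilon = 0.01,
                   n_sites = NULL)
  params <- utils::modifyList(defaults, params)
  st <- c(select = TRUE, qa = TRUE, correct = TRUE)
  st[names(stages)] <- stages
  structure(list(run = run, out_dir = out_dir, logfile = logfile, roi = roi,
                 roi_edits = roi_edits, exclusions = exclusions,
                 anchors = anchors, edit_script = edit_script, stages = st,
                 bias_correct = isTRUE(bias_correct), params = params),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML/JSON
#'
#' File paths in the config are interpreted relative to the config file's
#' directory.
#'
#' @param path YAML or JSON configuration file mirroring the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", tolower(path))) jsonlite::fromJSON(path)
         else yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p) || grepl("^/", p)) p else file.path(base, p)
  pipeline_config(run = rel(raw$run),
                  out_dir = rel(if (is.null(raw$out_dir)) "." else raw$out_dir),
                  logfile = rel(raw$logfile), roi = rel(raw$roi),
                  roi_edits = raw$roi_edits, exclusions = raw$exclusions,
                  anchors = rel_or_anchors(raw$anchors, rel),
                  edit_script = rel(raw$edit_script),
                  stages = unlist(raw$stages) %||% c(select = TRUE, qa = TRUE,
                                                     correct = TRUE),
                  bias_correct = isTRUE(raw$bias_correct),
                  params = raw$params %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rel_or_anchors <- function(a, rel) {
  if (is.null(a)) return(NULL)
  if (is.character(a)) return(rel(a))
  anchor_points(unlist(a$larynx), unlist(a$lips))
}

read_anchors_json <- function(path) {
  raw <- jsonlite::fromJSON(path)
  anchor_points(unlist(raw$larynx), unlist(raw$lips))
}

resolve_input <- function(x, reader) {
  if (is.null(x)) NULL else if (is.character(x)) reader(x) else x
}

#' Run the full pipeline for one imaging run
#'
#' Executes the enabled stages in order, writes every intermediate artifact
#' into `out_dir`, and returns a manifest (inputs, parameters, artifact
#' content hashes, package version). The pipeline is a pure composition of
#' the module functions, so identical configuration and inputs yield an
#' identical manifest.
#'
#' Artifacts written: `corrected.nii` (optional), `roi.tif`, `masks.nii`,
#' `threshold.json`, `masks_selected.nii` (optional), `qa.tif` + `qa.png`,
#' `masks_final.nii`, `outlines.csv`, `bridging.json`, and with stage 5
#' `outlines_corrected.csv` + `audit.json`; plus `manifest.json`.
#'
#' @param config A [pipeline_config()] or path to a YAML/JSON config.
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  # -- validate inputs before executing anything
  for (field in c("run", "logfile", "roi", "edit_script")) {
    v <- config[[field]]
    if (is.character(v) && !file.exists(v))
      stop("configured ", field, " file does not exist: ", v, call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  artifacts <- character()
  note <- function(path) artifacts[[basename(path)]] <<- path

  run <- resolve_input(config$run, read_run)
  stopifnot(inherits(run, "image_run"))

  if (config$bias_correct) {
    field <- estimate_bias_field(run,
                                 smoothing_scale = config$params$smoothing_scale)
    run <- correct_run(run, field)
    write_run(run, out("corrected.nii")); note(out("corrected.nii"))
  }

  # -- stage 1: ROI + threshold + classification
  roi <- resolve_input(config$roi, function(p) region_of_interest(read_mask(p)))
  if (is.null(roi)) {
    roi <- seed_roi(compute_variance_map(run), quantile = config$params$quantile)
  }
  if (!is.null(config$roi_edits)) {
    roi <- edit_roi(roi, additions = config$roi_edits$additions %||% list(),
                    removals = config$roi_edits$removals %||% list())
  }
  write_mask(roi, out("roi.tif")); note(out("roi.tif"))
  model <- fit_threshold(run, roi)
  jsonlite::write_json(list(threshold = model$threshold,
                            mode_locations = model$mode_locations,
                            bimodality_ok = model$bimodality_ok),
                       out("threshold.json"), auto_unbox = TRUE, digits = NA)
  note(out("threshold.json"))
  masks <- classify_run(run, roi, model)
  write_mask_series(masks, out("masks.nii")); note(out("masks.nii"))

  # -- stage 2: frame selection
  if (isTRUE(config$stages[["select"]]) && !is.null(config$logfile)) {
    log <- resolve_input(config$logfile, function(p)
      read_logfile(p, fps = run$fps, n_frames = n_frames(run)))
    masks <- select_frames(masks, log)
    write_mask_series(masks, out("masks_selected.nii"))
    note(out("masks_selected.nii"))
  }

  # -- stage 3: QA map + exclusions
  if (isTRUE(config$stages[["qa"]])) {
    qa <- compute_qa_map(masks)
    tiff::writeTIFF(qa$proportion, out("qa.tif"), bits.per.sample = 32L)
    note(out("qa.tif"))
    write_qa_png(qa, run$intensities[1L, , ], out("qa.png"))
    note(out("qa.png"))
    if (!is.null(config$exclusions)) {
      excl <- config$exclusions
      if (is.character(excl)) excl <- exclusion_mask(read_mask(excl))
      masks <- apply_exclusions(masks, excl)
    }
  }
  write_mask_series(masks, out("masks_final.nii")); note(out("masks_final.nii"))

  # -- stage 4: outlining
  anchors <- if (is.character(config$anchors)) read_anchors_json(config$anchors)
             else config$anchors
  oset <- outline_run(masks, run, anchors = anchors,
                      epsilon = config$params$epsilon)
  if (!length(oset$outlines))
    stop("outlining produced no outlines; see the status table", call. = FALSE)
  write_outlines(oset$outlines, out("outlines.csv"), run_id = run$run_id)
  note(out("outlines.csv"))
  jsonlite::write_json(oset$status, out("bridging.json"), digits = NA)
  note(out("bridging.json"))

  # -- stage 5: correction
  outlines <- oset$outlines
  if (isTRUE(config$stages[["correct"]]) && !is.null(config$edit_script)) {
    script <- resolve_input(config$edit_script, read_edit_script)
    res <- apply_edit_script(outlines, script)
    outlines <- res$outlines
    write_outlines(outlines, out("outlines_corrected.csv"), run_id = run$run_id)
    note(out("outlines_corrected.csv"))
    jsonlite::write_json(res$audit, out("audit.json"), digits = NA)
    note(out("audit.json"))
  }

  hashes <- as.list(tools::md5sum(unname(unlist(artifacts))))
  names(hashes) <- basename(names(hashes))
  manifest <- list(
    run_id = run$run_id,
    parameters = config$params[!vapply(config$params, is.null, TRUE)],
    stages = as.list(config$stages),
    bias_correct = config$bias_correct,
    threshold = model$threshold,
    n_frames_analysed = dim(masks$masks)[1L],
    n_outlines = length(outlines),
    n_bridged = sum(oset$status$bridged),
    artifacts = hashes,
    package_version = as.character(utils::packageVersion("vtshape")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
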