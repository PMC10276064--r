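# Disk round-trip for sections and study tables. Channels go to a multipage
# TIFF (one page per channel), the ground truth to a JSON sidecar, tables to
# CSV.

#' Write a section to disk
#'
#' Writes the channels as a multipage TIFF (`<prefix>.tif`, one page per
#' channel, 8 or 16 bit as needed), the label map as a separate 16-bit TIFF
#' (`<prefix>_labels.tif`), and the ground truth (fiber, fragment, spot and
#' calibration tables, pixel size, seed) as a JSON sidecar
#' (`<prefix>_truth.json`).
#'
#' @param section A `muscle_section`.
#' @param prefix Path prefix (without extension).
#' @return Invisibly, the paths written.
#' @export
write_section <- function(section, prefix) {
  stopifnot(inherits(section, "muscle_section"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  img_path <- paste0(prefix, ".tif")
  tiff::writeTIFF(lapply(section$channels, function(m) m / 255),
                  img_path, bits.per.sample = 8L)
  lab_path <- NULL
  if (!is.null(section$truth$label)) {
    lab_path <- paste0(prefix, "_labels.tif")
    tiff::writeTIFF(section$truth$label / 65535, lab_path,
                    bits.per.sample = 16L)
  }
  truth <- section$truth
  truth$label <- NULL
  truth$lamina <- NULL
  if (!is.null(truth$spots)) truth$spots$pixels <- NULL
  sidecar <- list(
    channels = names(section$channels),
    pixel_size = section$pixel_size,
    pixel_aspect = section$pixel_aspect,
    margin_cols = section$margin_cols,
    subject_id = section$subject_id,
    seed = section$seed,
    truth = truth
  )
  json_path <- paste0(prefix, "_truth.json")
  jsonlite::write_json(sidecar, json_path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(image = img_path, labels = lab_path, truth = json_path))
}

#' Read a section written by [write_section()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `muscle_section`. The lamina mask is not stored and is rebuilt
#'   from the label map (non-fiber tissue pixels).
#' @export
read_section <- function(prefix) {
  img_path <- paste0(prefix, ".tif")
  json_path <- paste0(prefix, "_truth.json")
  if (!file.exists(img_path) || !file.exists(json_path)) {
    abort("Missing section files for this prefix.")
  }
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(img_path, all = TRUE)
  channels <- lapply(pages, function(p) round(p * 255))
  names(channels) <- side$channels
  lab <- NULL
  lab_path <- paste0(prefix, "_labels.tif")
  if (file.exists(lab_path)) {
    lab <- round(tiff::readTIFF(lab_path) * 65535)
    storage.mode(lab) <- "integer"
  }
  truth <- lapply(side$truth, function(x) {
    if (is.data.frame(x)) as_tibble(x) else x
  })
  truth$label <- lab
  if (!is.null(lab)) {
    lamina <- matrix(FALSE, nrow(lab), ncol(lab))
    tissue_cols <- setdiff(seq_len(ncol(lab)), side$margin_cols)
    lamina[, tissue_cols] <- lab[, tissue_cols] == 0L
    truth$lamina <- lamina
  }
  structure(list(
    channels = channels,
    pixel_size = side$pixel_size,
    pixel_aspect = side$pixel_aspect,
    optics = NULL,
    margin_cols = as.integer(side$margin_cols),
    truth = truth,
    subject_id = side$subject_id,
    seed = as.integer(side$seed)
  ), class = "muscle_section")
}

#' Write a study's tables and report
#'
#' Writes per-subject measurements, ground-truth cohort, comparisons and
#' qPCR tables as CSV, plus a JSON report with the headline summary, the
#' pooled correlation, and all generation parameters and seeds.
#'
#' @param study An `mb_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "mb_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    subjects = file.path(dir, "subjects.csv"),
    cohort_truth = file.path(dir, "cohort_truth.csv"),
    comparisons = file.path(dir, "comparisons.csv"),
    qpcr = file.path(dir, "qpcr.csv"),
    report = file.path(dir, "report.json")
  )
  readr::write_csv(study$subjects, paths["subjects"])
  readr::write_csv(study$cohort, paths["cohort_truth"])
  readr::write_csv(study$comparisons, paths["comparisons"])
  readr::write_csv(study$qpcr, paths["qpcr"])
  report <- list(
    summary = glance(study),
    correlation = study$correlation,
    seed = study$seed,
    n_per_group = as.list(study$params$n_per_group),
    optics = study$optics[setdiff(names(study$optics), "fit")]
  )
  jsonlite::write_json(report, paths["report"], dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
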