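#' Sort a directory of images into focused and defocused
#'
#' Reads every TIFF/PNG in `dir`, crops the central 536 x 536 region
#' (matching the sorter's training augmentation), resizes to the sorter's
#' input side, standardizes, and scores it. Unreadable files are skipped
#' with a warning and recorded in the manifest with status "skipped".
#'
#' @param dir directory of images with side >= `crop_side`
#' @param sorter trained `sdcnn` model or path to a checkpoint
#' @param crop_side central crop applied before scoring (default 536)
#' @param threshold probability-of-focused below which an image is flagged
#'   defocused (default 0.5, i.e. plain argmax)
#' @return manifest data.frame: path, status, prob_focused, label
#' @export
sort_directory <- function(dir, sorter, crop_side = 536L, threshold = 0.5) {
  if (is.character(sorter)) sorter <- load_checkpoint(sorter)
  files <- sort(list.files(dir, pattern = "\\.(tif|tiff|png)$",
                           ignore.case = TRUE, full.names = TRUE))
  n <- length(files)
  manifest <- data.frame(path = character(0), status = character(0),
                         prob_focused = numeric(0), label = character(0),
                         stringsAsFactors = FALSE)
  for (f in files) {
    row <- tryCatch({
      img <- read_image(f)
      img <- center_crop(img, min(crop_side, min(dim(img)[1:2])))
      p <- predict_focus(sorter, img)$probabilities[1, 1]
      data.frame(path = f, status = "scored", prob_focused = p,
                 label = if (p >= threshold) "focused" else "defocused",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("skipping ", f, ": ", conditionMessage(e))
      data.frame(path = f, status = "skipped", prob_focused = NA_real_,
                 label = NA_character_, stringsAsFactors = FALSE)
    })
    manifest <- rbind(manifest, row)
  }
  manifest
}

#' Reconstruct every image flagged defocused in a sorting manifest
#'
#' Each flagged image is reconstructed at its full frame size (no cropping
#' or resizing) via the overlap-tile scheme and written beside the input
#' (or into `out_dir`) with a filename suffix.
#'
#' @param manifest data.frame from [sort_directory()]
#' @param recon trained `resunet` model or checkpoint path
#' @param out_dir output directory (default: alongside the inputs)
#' @param suffix filename suffix for reconstructions
#' @return the manifest with a `recon_path` column
#' @export
reconstruct_flagged <- function(manifest, recon, out_dir = NULL,
                                suffix = "_reconstructed") {
  if (is.character(recon)) recon <- load_checkpoint(recon)
  manifest$recon_path <- NA_character_
  flagged <- which(!is.na(manifest$label) & manifest$label == "defocused")
  for (i in flagged) {
    img <- read_image(manifest$path[i])
    rec <- reconstruct_image(recon, img)
    base <- basename(manifest$path[i])
    stem <- tools::file_path_sans_ext(base)
    ext <- tools::file_ext(base)
    dest_dir <- out_dir %||% dirname(manifest$path[i])
    dir.create(dest_dir, showWarnings = FALSE, recursive = TRUE)
    dest <- file.path(dest_dir, paste0(stem, suffix, ".", ext))
    write_image(rec, dest)
    manifest$recon_path[i] <- dest
  }
  manifest
}

#' Run the end-to-end sorting + reconstruction pipeline
#'
#' Sorts a directory, reconstructs the flagged images, and writes a JSON
#' report with counts and per-image scores. When a directory of focused
#' reference images with matching filenames is supplied, the report also
#' contains per-image SSIM of the defocused input and of its
#' reconstruction against the reference. Inference is deterministic:
#' re-running with the same checkpoints reproduces the manifest.
#'
#' @param config list or path to a YAML file with fields: `input_dir`,
#'   `output_dir`, `sorter` (checkpoint path or model), `recon` (checkpoint
#'   path or model), optional `threshold` (0.5), `crop_side` (536),
#'   `reference_dir`
#' @return list with `manifest` and `report`
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("input_dir", "output_dir", "sorter", "recon")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    stop("pipeline config missing fields: ", paste(missing, collapse = ", "))
  }
  sorter <- if (is.character(config$sorter)) load_checkpoint(config$sorter) else config$sorter
  recon <- if (is.character(config$recon)) load_checkpoint(config$recon) else config$recon
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- sort_directory(config$input_dir, sorter,
                             crop_side = config$crop_side %||% 536L,
                             threshold = config$threshold %||% 0.5)
  manifest <- reconstruct_flagged(manifest, recon, out_dir = config$output_dir)
  report <- list(
    n_images = nrow(manifest),
    n_scored = sum(manifest$status == "scored"),
    n_skipped = sum(manifest$status == "skipped"),
    n_flagged = sum(manifest$label == "defocused", na.rm = TRUE),
    n_reconstructed = sum(!is.na(manifest$recon_path)))
  if (!is.null(config$reference_dir)) {
    flagged <- which(!is.na(manifest$recon_path))
    ssim_rows <- list()
    for (i in flagged) {
      ref_path <- file.path(config$reference_dir, basename(manifest$path[i]))
      if (!file.exists(ref_path)) next
      ref <- read_image(ref_path)
      before <- ssim(read_image(manifest$path[i]), ref)
      after <- ssim(read_image(manifest$recon_path[i]), ref)
      ssim_rows[[length(ssim_rows) + 1L]] <-
        data.frame(path = manifest$path[i], ssim_before = before,
                   ssim_after = after)
    }
    if (length(ssim_rows) > 0) {
      report$ssim <- do.call(rbind, ssim_rows)
    }
  }
  jsonlite::write_json(
    c(report["n_images"], report["n_scored"], report["n_skipped"],
      report["n_flagged"], report["n_reconstructed"],
      list(images = manifest)),
    file.path(config$output_dir, "report.json"),
    auto_unbox = TRUE, pretty = TRUE, na = "null")
  utils::write.csv(manifest, file.path(config$output_dir, "manifest.csv"),
                   row.names = FALSE)
  list(manifest = manifest, report = report)
}
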