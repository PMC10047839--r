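#' Write a synthetic scene to disk as a fixture file set
#'
#' Writes channel TIFFs (16-bit grayscale), the ROI polygons in both the
#' JSON dialect and an ImageJ ROI zip, the ground-truth table and per-round
#' gain table as CSV, the configuration as YAML, and a manifest listing
#' every written file with its MD5 checksum. Output is deterministic for a
#' given scene, so identical configurations produce bit-identical fixtures.
#'
#' @param scene A `spine_scene` from [build_scene()].
#' @param out_dir Output directory (created if missing).
#' @param channels Optional pre-rendered result of [render_channels()];
#'   rendered from the scene when omitted.
#' @return Invisibly, the manifest tibble (`file`, `md5`).
#' @export
write_scene_fixture <- function(scene, out_dir, channels = NULL) {
  stopifnot(inherits(scene, "spine_scene"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  if (is.null(channels)) channels <- render_channels(scene)

  written <- character(0)
  wpath <- function(f) file.path(out_dir, f)
  for (ch in names(channels$channels)) {
    f <- paste0(ch, ".tif")
    write_channel_tiff(channels$channels[[ch]], wpath(f))
    written <- c(written, f)
  }

  rois <- as_roi_set(scene)
  write_rois(rois, wpath("rois.json"))
  write_rois(rois, wpath("rois_imagej.zip"))
  written <- c(written, "rois.json", "rois_imagej.zip")

  gt <- scene$spines[, c("spine_id", "round_id", "true_nf_amount",
                         "true_marker_amount", "crossed_by_axon",
                         "nf_present")]
  utils::write.csv(gt, wpath("ground_truth.csv"), row.names = FALSE)
  utils::write.csv(channels$gains, wpath("gains.csv"), row.names = FALSE)
  written <- c(written, "ground_truth.csv", "gains.csv")

  cfg <- scene$config
  cfg_ser <- unclass(cfg)
  cfg_ser$mixing_matrix <- as.numeric(cfg$mixing_matrix)  # column-major
  cfg_ser$marginal_params <- lapply(cfg$marginal_params, as.numeric)
  yaml::write_yaml(cfg_ser, wpath("config.yaml"))
  written <- c(written, "config.yaml")

  manifest <- tibble::tibble(
    file = written,
    md5 = unname(tools::md5sum(vapply(written, wpath, character(1)))))
  utils::write.csv(manifest, wpath("manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a scene fixture back from disk
#'
#' Verifies the manifest checksums and reconstructs the channel images,
#' ROI set, ground-truth and gain tables, and configuration.
#'
#' @param dir Fixture directory written by [write_scene_fixture()].
#' @return List with `channels`, `rois`, `ground_truth`, `gains`, `config`,
#'   `manifest`.
#' @export
read_scene_fixture <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) stop("no manifest.csv in ", dir)
  manifest <- tibble::as_tibble(utils::read.csv(manifest_path))
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(dir, manifest$file[i])
    if (!file.exists(f)) stop("manifest lists missing file: ", f)
    md5 <- unname(tools::md5sum(f))
    if (!identical(md5, manifest$md5[i]))
      stop("checksum mismatch for ", f)
  }
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$mixing_matrix <- matrix(unlist(cfg$mixing_matrix), 2, 2)
  modal <- c(volume = "confocal", axon_marker = "confocal",
             nf = "STED", marker = "STED")
  tif_files <- grep("\\.tif$", manifest$file, value = TRUE)
  channels <- lapply(stats::setNames(tif_files, sub("\\.tif$", "", tif_files)),
                     function(f) {
                       ch <- sub("\\.tif$", "", f)
                       read_channel_tiff(file.path(dir, f), channel = ch,
                                         modality = if (ch %in% names(modal))
                                           modal[[ch]] else "STED",
                                         pixel_size_nm = cfg$pixel_size_nm)
                     })
  list(channels = channels,
       rois = read_rois(file.path(dir, "rois.json")),
       ground_truth = tibble::as_tibble(
         utils::read.csv(file.path(dir, "ground_truth.csv"))),
       gains = tibble::as_tibble(
         utils::read.csv(file.path(dir, "gains.csv"))),
       config = cfg, manifest = manifest)
}
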