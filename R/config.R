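# Pipeline configuration: one YAML-serializable list that carries every
# tunable of the analysis stages. Times are seconds internally; minutes are
# accepted with an explicit unit.

#' Pipeline configuration
#'
#' @param pixel_size_um pixel size (um/px).
#' @param frame_interval frame interval value.
#' @param frame_interval_unit `"s"` or `"min"`.
#' @param segmentation list: `ridge_sigma_px`, `h_minima`,
#'   `min_cell_area_px`.
#' @param band_halfwidth_px junctional ROI half-width (px), default 5.
#' @param dmean_aggregation `"sum"` or `"mean"` of the two neighbour-frame
#'   border distances.
#' @param coherency list: `gradient_sigma_px`, `window_sigma_px`.
#' @param recoil_line optional list: `row0`, `col0`, `row1`, `col1`,
#'   `width_px`, `cut_frame`.
#' @param seed integer seed.
#' @param output_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size_um = 0.53,
                            frame_interval = 1,
                            frame_interval_unit = c("min", "s"),
                            segmentation = list(ridge_sigma_px = c(1, 2),
                                                h_minima = 0.05,
                                                min_cell_area_px = 64),
                            band_halfwidth_px = 5,
                            dmean_aggregation = c("sum", "mean"),
                            coherency = list(gradient_sigma_px = 1,
                                             window_sigma_px = 4),
                            recoil_line = NULL,
                            seed = 1L,
                            output_dir = ".") {
  frame_interval_unit <- match.arg(frame_interval_unit)
  dmean_aggregation <- match.arg(dmean_aggregation)
  check_positive(pixel_size_um, "pixel_size_um")
  check_positive(frame_interval, "frame_interval")
  structure(list(pixel_size_um = pixel_size_um,
                 frame_interval = frame_interval,
                 frame_interval_unit = frame_interval_unit,
                 segmentation = segmentation,
                 band_halfwidth_px = band_halfwidth_px,
                 dmean_aggregation = dmean_aggregation,
                 coherency = coherency,
                 recoil_line = recoil_line,
                 seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#' @param config a [pipeline_config()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file written by [write_config()].
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  # cfg[nm] <- list(...) keeps NULL-valued fields instead of deleting them
  for (nm in names(x)) cfg[nm] <- list(x[[nm]])
  cfg$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$segmentation$ridge_sigma_px))
    cfg$segmentation$ridge_sigma_px <-
      as.numeric(unlist(cfg$segmentation$ridge_sigma_px))
  cfg
}
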