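# Calibrated 2D+t image container. Data layout: a list of channels, each a
# numeric array (frames x rows x cols). Single-frame data is stored with a
# leading unit dimension so every stage sees the same layout.

#' Calibrated image series
#'
#' Container for 2D + time intensity data with spatial and temporal
#' calibration, the raw input of every analysis stage.
#'
#' @param data a matrix (one frame), a 3D array (frames x rows x cols), or a
#'   named list of such, one per channel.
#' @param pixel_size_um pixel size in micrometres per pixel.
#' @param frame_interval frame interval (time between frames).
#' @param frame_interval_unit `"s"` or `"min"`.
#' @param channel_names optional channel names; defaults to the list names or
#'   `"ch1"`, `"ch2"`, ...
#'
#' @return an object of class `image_series`.
#' @export
image_series <- function(data, pixel_size_um, frame_interval = 1,
                         frame_interval_unit = c("min", "s"),
                         channel_names = NULL) {
  frame_interval_unit <- match.arg(frame_interval_unit)
  check_positive(pixel_size_um, "pixel_size_um")
  if (frame_interval <= 0) stop("invalid calibration", call. = FALSE)
  if (!is.list(data)) data <- list(data)
  data <- lapply(data, function(d) {
    if (is.matrix(d)) d <- array(d, c(1L, nrow(d), ncol(d)))
    if (length(dim(d)) != 3) stop("each channel must be 2D or 3D",
                                  call. = FALSE)
    if (any(!is.finite(d)) || any(d < 0))
      stop("intensities must be finite and >= 0", call. = FALSE)
    d
  })
  dims <- unique(lapply(data, dim))
  if (length(dims) != 1) stop("all channels must share shape", call. = FALSE)
  if (is.null(channel_names))
    channel_names <- if (!is.null(names(data)) && all(nzchar(names(data))))
      names(data) else paste0("ch", seq_along(data))
  names(data) <- channel_names
  structure(list(data = data, channel_names = channel_names,
                 pixel_size_um = pixel_size_um,
                 frame_interval = frame_interval,
                 frame_interval_unit = frame_interval_unit),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data[[1]])
  cat(sprintf(
    "<image_series> %d frame(s) of %d x %d px, %d channel(s) [%s]\n",
    d[1], d[2], d[3], length(x$data), paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  pixel size %.4g um/px, frame interval %.4g %s\n",
              x$pixel_size_um, x$frame_interval, x$frame_interval_unit))
  invisible(x)
}

#' @export
dim.image_series <- function(x) dim(x$data[[1]])

#' Extract one frame of one channel as a matrix
#'
#' @param x an [image_series].
#' @param frame frame index (1-based).
#' @param channel channel name or index.
#' @return a numeric matrix (rows x cols).
#' @export
get_frame <- function(x, frame = 1, channel = 1) {
  stopifnot(inherits(x, "image_series"))
  ch <- x$data[[channel]]
  if (frame < 1 || frame > dim(ch)[1]) stop("frame out of range",
                                            call. = FALSE)
  matrix(ch[frame, , ], dim(ch)[2], dim(ch)[3])
}

#' Frame interval in minutes
#' @param x an [image_series].
#' @return interval in minutes.
#' @export
frame_interval_min <- function(x) {
  if (x$frame_interval_unit == "s") x$frame_interval / 60 else x$frame_interval
}

# ---- TIFF I/O ---------------------------------------------------------------

#' Write an image series to multi-page TIFF
#'
#' One file per channel (suffix `_c0`, `_c1`, ... when there are several),
#' pages are frames, float32 samples. A JSON sidecar (`<base>.json`) records
#' the calibration.
#'
#' @param x an [image_series].
#' @param path output path; `.tif` appended if missing.
#' @return invisibly, the file paths written.
#' @export
write_series_tiff <- function(x, path) {
  stopifnot(inherits(x, "image_series"))
  base <- sub("\\.tiff?$", "", path)
  files <- character(0)
  multi <- length(x$data) > 1
  # TIFF samples are stored in [0, 1]; the scale is recorded in the sidecar
  scales <- vapply(x$data, function(ch) max(ch, 1e-300), numeric(1))
  for (i in seq_along(x$data)) {
    f <- if (multi) sprintf("%s_c%d.tif", base, i - 1L) else
      paste0(base, ".tif")
    ch <- x$data[[i]] / scales[i]
    pages <- lapply(seq_len(dim(ch)[1]),
                    function(k) matrix(ch[k, , ], dim(ch)[2], dim(ch)[3]))
    tiff::writeTIFF(pages, f, bits.per.sample = 32L)
    files <- c(files, f)
  }
  meta <- list(pixel_size_um = x$pixel_size_um,
               frame_interval = x$frame_interval,
               frame_interval_unit = x$frame_interval_unit,
               channel_names = x$channel_names,
               intensity_scale = unname(scales))
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(files)
}

#' Read a multi-page TIFF into an image series
#'
#' @param files one path per channel.
#' @param pixel_size_um,frame_interval,frame_interval_unit calibration; read
#'   from the JSON sidecar of the first file when present and not supplied.
#' @param channel_names optional channel names.
#' @return an [image_series].
#' @export
read_series_tiff <- function(files, pixel_size_um = NULL, frame_interval = NULL,
                             frame_interval_unit = NULL, channel_names = NULL) {
  sidecar <- paste0(sub("(_c[0-9]+)?\\.tiff?$", "", files[1]), ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um %||% 1
  frame_interval <- frame_interval %||% meta$frame_interval %||% 1
  frame_interval_unit <- frame_interval_unit %||% meta$frame_interval_unit %||%
    "min"
  scales <- unlist(meta$intensity_scale) %||% rep(1, length(files))
  chans <- lapply(seq_along(files), function(i) {
    pages <- tiff::readTIFF(files[i], all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (k in seq_along(pages)) arr[k, , ] <- pages[[k]]
    arr * scales[min(i, length(scales))]
  })
  image_series(chans, pixel_size_um = pixel_size_um,
               frame_interval = frame_interval,
               frame_interval_unit = frame_interval_unit,
               channel_names = channel_names %||%
                 unlist(meta$channel_names)[seq_along(files)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
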