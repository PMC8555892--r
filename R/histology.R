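#' HSB windows for AT8-stained slides
#'
#' Hue/saturation/brightness windows on the 0-255 scale used to segment
#' hematoxylin-stained cells and DAB (AT8-positive) tau deposits in
#' brightfield immunohistochemistry images. The tau hue window wraps
#' around zero (DAB browns straddle the red end of the hue circle):
#' hues at or below `hue[1]` or at or above `hue[2]` pass.
#'
#' @param hue,saturation,brightness Length-2 numeric intervals in
#'   `[0, 255]`.
#' @param hue_wrap Whether the hue interval is a wrapping (OR) window.
#' @return An `hsb_window` list.
#' @export
#'
#' @examples
#' cell_hsb_window()
#' tau_hsb_window()
hsb_window <- function(hue, saturation, brightness, hue_wrap = FALSE) {
  chk <- function(x) all(x >= 0 & x <= 255) && length(x) == 2
  if (!chk(hue) || !chk(saturation) || !chk(brightness)) {
    abort("all window bounds must be length-2 vectors within [0, 255].")
  }
  structure(list(hue = hue, saturation = saturation, brightness = brightness,
                 hue_wrap = hue_wrap),
            class = "hsb_window")
}

#' @rdname hsb_window
#' @export
cell_hsb_window <- function() {
  hsb_window(hue = c(108, 200), saturation = c(25, 141),
             brightness = c(145, 230))
}

#' @rdname hsb_window
#' @export
tau_hsb_window <- function() {
  hsb_window(hue = c(44, 222), saturation = c(42, 255),
             brightness = c(0, 206), hue_wrap = TRUE)
}

# RGB (0-255, array w x h x 3) -> HSB channels on the 0-255 scale.
.rgb_to_hsb255 <- function(image) {
  d <- dim(image)
  px <- matrix(aperm(image, c(3, 1, 2)), nrow = 3)
  hsv <- grDevices::rgb2hsv(px, maxColorValue = 255)
  list(h = matrix(hsv[1, ] * 255, d[1], d[2]),
       s = matrix(hsv[2, ] * 255, d[1], d[2]),
       b = matrix(hsv[3, ] * 255, d[1], d[2]))
}

.check_slide <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    abort("a slide image must be a width x height x 3 RGB array.")
  }
  if (min(image) < 0 || max(image) > 255) {
    abort("pixel values must be 8-bit (0-255).")
  }
  if (max(image) <= 1 && any(image != round(image))) {
    abort("pixel values look like [0,1] floats; supply an 8-bit (0-255) image.")
  }
  invisible(image)
}

#' Threshold a slide with an HSB window
#'
#' Converts 8-bit RGB pixels to hue/saturation/brightness on the 0-255
#' scale and passes a pixel iff all three channels lie inside their
#' windows; a wrapping hue window passes hues at or below its lower
#' bound or at or above its upper bound.
#'
#' @param image RGB array (width x height x 3, values 0-255), e.g. from
#'   [read_slide()] or [gen_histology_image()].
#' @param window An [hsb_window()].
#' @return Logical matrix mask (TRUE = pixel passes).
#' @export
hsb_threshold <- function(image, window) {
  .check_slide(image)
  stopifnot(inherits(window, "hsb_window"))
  ch <- .rgb_to_hsb255(image)
  hue_ok <- if (window$hue_wrap) {
    ch$h <= window$hue[1] | ch$h >= window$hue[2]
  } else {
    ch$h >= window$hue[1] & ch$h <= window$hue[2]
  }
  hue_ok &
    ch$s >= window$saturation[1] & ch$s <= window$saturation[2] &
    ch$b >= window$brightness[1] & ch$b <= window$brightness[2]
}

#' Count hematoxylin-stained cells in a slide
#'
#' Reproduces the standard brightfield nucleus-counting chain: HSB
#' threshold with the cell window, one 3x3 dilation (boundary
#' smoothing), hole filling, watershed splitting of touching cells on
#' the negated Euclidean distance transform (tolerance 1 px), then a
#' particle filter keeping components with area >= `min_area` square
#' pixels and circularity 4 pi A / P^2 above `min_circularity`.
#'
#' @param image RGB slide array (0-255).
#' @param window Segmentation window (default [cell_hsb_window()]).
#' @param min_area Minimum particle area in px^2 (default 200).
#' @param min_circularity Minimum circularity (default 0.5).
#' @return A list with `count` and `labels` (integer label matrix of
#'   the retained cells).
#' @export
count_cells <- function(image, window = cell_hsb_window(),
                        min_area = 200, min_circularity = 0.5) {
  mask <- hsb_threshold(image, window)
  if (!any(mask)) {
    return(list(count = 0L, labels = matrix(0L, nrow(mask), ncol(mask))))
  }
  m <- EBImage::Image(mask * 1)
  m <- EBImage::dilate(m, EBImage::makeBrush(3, shape = "box"))
  m <- EBImage::fillHull(m)
  dm <- EBImage::distmap(m)
  labels <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  shp <- EBImage::computeFeatures.shape(labels)
  if (is.null(shp) || nrow(shp) == 0) {
    return(list(count = 0L, labels = matrix(0L, nrow(mask), ncol(mask))))
  }
  area <- shp[, "s.area"]
  perim <- pmax(shp[, "s.perimeter"], 1)
  circ <- 4 * pi * area / perim^2
  keep <- which(area >= min_area & circ > min_circularity)
  lab_mat <- EBImage::imageData(labels)
  lab_mat[!(lab_mat %in% keep)] <- 0L
  list(count = length(keep), labels = lab_mat)
}

#' Tau burden of a slide
#'
#' Counts the pixels passing the tau (DAB) window as tau plaque area
#' and normalises by the number of cells, yielding the tau area per
#' cell.
#'
#' @param image RGB slide array (0-255).
#' @param cell_window,tau_window Segmentation windows.
#' @param min_area,min_circularity Particle filter passed to
#'   [count_cells()].
#' @return A tibble with `cell_count`, `tau_area_px`, and `burden`
#'   (NA with a warning flag when no cells are found).
#' @export
#'
#' @examples
#' \donttest{
#' img <- gen_histology_image(seed = 1, n_cells = 10, n_tau = 2,
#'                            width = 256, height = 256)
#' tau_burden(img$image)
#' }
tau_burden <- function(image, cell_window = cell_hsb_window(),
                       tau_window = tau_hsb_window(),
                       min_area = 200, min_circularity = 0.5) {
  cells <- count_cells(image, cell_window, min_area, min_circularity)
  tau_area <- sum(hsb_threshold(image, tau_window))
  burden <- if (cells$count > 0) tau_area / cells$count else NA_real_
  tibble(cell_count = cells$count, tau_area_px = as.integer(tau_area),
         burden = burden, burden_defined = cells$count > 0)
}

#' Read a slide image from disk
#'
#' Reads a PNG or TIFF brightfield image into the 8-bit RGB array the
#' quantification functions consume.
#'
#' @param path Image path.
#' @return Width x height x 3 array of values 0-255.
#' @export
read_slide <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 2) abort("expected an RGB image, got a single channel.")
  arr <- EBImage::imageData(img)[, , 1:3] * 255
  round(arr)
}

#' Write a slide image to disk
#'
#' @param image RGB array (0-255).
#' @param path Output path (`.png` or `.tif`).
#' @return `path`, invisibly.
#' @export
write_slide <- function(image, path) {
  .check_slide(image)
  EBImage::writeImage(EBImage::Image(image / 255, colormode = "Color"), path)
  invisible(path)
}
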