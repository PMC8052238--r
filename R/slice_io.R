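#' Stack acquisition configuration
#'
#' Physical geometry of a serial-section stack. Slices cut at 2 um are
#' mounted every 100 um, so the inter-slice distance (not the section
#' thickness) sets the z spacing of the reconstruction. Segmented label
#' images are piecewise constant, so their resolution is reduced by 85%
#' (keep fraction 0.15) before reconstruction.
#'
#' @param pixel_pitch um per pixel of the (isotropic) input images.
#' @param slice_distance um between consecutive slices (default 100).
#' @param section_thickness um physical section thickness, informational
#'   (default 2).
#' @param downsample_keep_fraction linear downsampling factor in (0, 1];
#'   default 0.15, i.e. an 85% reduction.
#' @return object of class `stack_config`.
#' @export
stack_config <- function(pixel_pitch, slice_distance = 100,
                         section_thickness = 2,
                         downsample_keep_fraction = 0.15) {
  check_that(is_number(pixel_pitch) && pixel_pitch > 0,
             "pixel_pitch", "must be > 0 (um/pixel)")
  check_that(is_number(slice_distance) && slice_distance > 0,
             "slice_distance", "must be > 0 (um)")
  check_that(is_number(downsample_keep_fraction) &&
               downsample_keep_fraction > 0 && downsample_keep_fraction <= 1,
             "downsample_keep_fraction", "must lie in (0, 1]")
  structure(list(
    pixel_pitch = pixel_pitch,
    slice_distance = slice_distance,
    section_thickness = section_thickness,
    downsample_keep_fraction = downsample_keep_fraction
  ), class = "stack_config")
}

#' @export
print.stack_config <- function(x, ...) {
  cat(sprintf(
    "Stack config: %.3g um/px, slices every %g um (%g um thick), keep %g%%\n",
    x$pixel_pitch, x$slice_distance, x$section_thickness,
    100 * x$downsample_keep_fraction))
  invisible(x)
}

.valid_labels <- c(0:9, 10L, 11L)

#' Construct a labeled slice
#'
#' A labeled slice is one segmented histologic section: an integer label
#' raster (0 background, 1-9 tissue classes, 10 lumen marker, 11 optional
#' exterior marker) plus its physical geometry. The z position is derived
#' from the slice index and the stack's inter-slice distance.
#'
#' @param labels integer matrix of label values.
#' @param pixel_pitch um per pixel (isotropic).
#' @param slice_index integer >= 0.
#' @param slice_distance um between slices.
#' @return object of class `labeled_slice` with fields `labels`,
#'   `pixel_pitch`, `slice_index`, `z` (um).
#' @export
labeled_slice <- function(labels, pixel_pitch, slice_index,
                          slice_distance = 100) {
  check_that(is.matrix(labels), "labels", "must be a matrix")
  labels <- matrix(as.integer(labels), nrow = nrow(labels))
  bad <- setdiff(unique(as.vector(labels)), .valid_labels)
  check_that(length(bad) == 0, "labels",
             sprintf("values outside the label set: %s",
                     paste(bad, collapse = ", ")))
  check_that(is_number(pixel_pitch) && pixel_pitch > 0,
             "pixel_pitch", "must be > 0")
  check_that(is_number(slice_index) && slice_index >= 0 &&
               slice_index == round(slice_index),
             "slice_index", "must be a non-negative integer")
  structure(list(
    labels = labels,
    pixel_pitch = pixel_pitch,
    slice_index = as.integer(slice_index),
    z = slice_index * slice_distance
  ), class = "labeled_slice")
}

#' @export
print.labeled_slice <- function(x, ...) {
  counts <- table(factor(x$labels, levels = .valid_labels))
  present <- counts[counts > 0]
  cat(sprintf("Labeled slice %d (z = %g um): %d x %d px at %.3g um/px\n",
              x$slice_index, x$z, nrow(x$labels), ncol(x$labels),
              x$pixel_pitch))
  cat("  labels:", paste(sprintf("%s=%d", names(present), present),
                         collapse = " "), "\n")
  invisible(x)
}

#' Read a segmented label image
#'
#' Reads a PNG label image - either an RGB image painted with the class
#' palette or a grayscale image storing raw label values - and attaches the
#' stack geometry. Unknown colors are an error listing the offending colors
#' and their pixel count.
#'
#' @param path PNG file path.
#' @param palette color-to-class mapping ([class_palette()]).
#' @param config a [stack_config()].
#' @param slice_index index of this slice in the stack (z = index x
#'   slice_distance).
#' @return a [labeled_slice()].
#' @export
read_label_slice <- function(path, palette = class_palette(), config,
                             slice_index) {
  check_that(file.exists(path), "path",
             sprintf("file '%s' does not exist", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {
    labels <- matrix(as.integer(round(img * 255)), nrow = nrow(img))
  } else {
    labels <- palette_to_labels(img[, , 1:3] * 255, palette)
  }
  sl <- labeled_slice(labels, config$pixel_pitch, slice_index,
                      config$slice_distance)
  counts <- table(factor(sl$labels, levels = .valid_labels))
  hw_log(sprintf("read %s: %s", basename(path),
                 paste(sprintf("%s=%d", names(counts[counts > 0]),
                               counts[counts > 0]), collapse = " ")),
         "debug")
  sl
}

#' Write a labeled slice as a PNG label image
#'
#' Losslessly writes the raster, either as an RGB image using the class
#' palette (`mode = "rgb"`) or as 8-bit grayscale raw labels
#' (`mode = "gray"`). Reading the file back reproduces the raster exactly.
#'
#' @param slice a [labeled_slice()].
#' @param path output PNG path.
#' @param palette the class palette.
#' @param mode `"rgb"` or `"gray"`.
#' @return `path`, invisibly.
#' @export
write_label_slice <- function(slice, path, palette = class_palette(),
                              mode = c("rgb", "gray")) {
  mode <- match.arg(mode)
  if (mode == "gray") {
    png::writePNG(slice$labels / 255, path)
  } else {
    png::writePNG(labels_to_palette(slice$labels, palette) / 255, path)
  }
  invisible(path)
}

#' Downsample a label raster
#'
#' Nearest-neighbor downsampling to `round(dims * keep_fraction)` pixels
#' per axis. Labels are categorical, so no interpolation is performed (any
#' averaging would create spurious classes); the pixel pitch is rescaled so
#' the physical extent is preserved to within one output pixel.
#'
#' @param slice a [labeled_slice()].
#' @param keep_fraction linear keep fraction in (0, 1]; the default 0.15
#'   realizes an 85% resolution reduction.
#' @return a downsampled [labeled_slice()].
#' @export
downsample_labels <- function(slice, keep_fraction = 0.15) {
  check_that(is_number(keep_fraction) && keep_fraction > 0 &&
               keep_fraction <= 1,
             "keep_fraction", "must lie in (0, 1]")
  if (keep_fraction == 1) return(slice)
  nr <- nrow(slice$labels); nc <- ncol(slice$labels)
  nr2 <- max(1L, round(nr * keep_fraction))
  nc2 <- max(1L, round(nc * keep_fraction))
  # sample at the centers of the new pixel grid
  ri <- pmin(nr, pmax(1L, ceiling((seq_len(nr2) - 0.5) * nr / nr2)))
  ci <- pmin(nc, pmax(1L, ceiling((seq_len(nc2) - 0.5) * nc / nc2)))
  out <- slice$labels[ri, ci, drop = FALSE]
  sl <- slice
  sl$labels <- out
  sl$pixel_pitch <- slice$pixel_pitch * nr / nr2
  sl
}

#' Read a directory of label images as a stack
#'
#' Files are taken in lexicographic order; the position in that order is
#' the slice index.
#'
#' @param dir directory containing PNG label images.
#' @param config a [stack_config()].
#' @param palette the class palette.
#' @param pattern filename regular expression (default `\\.png$`).
#' @return list of [labeled_slice()] objects.
#' @export
read_label_stack <- function(dir, config, palette = class_palette(),
                             pattern = "\\.png$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  check_that(length(files) > 0, "dir",
             sprintf("no files matching '%s' in '%s'", pattern, dir))
  lapply(seq_along(files), function(i) {
    read_label_slice(files[i], palette, config, slice_index = i - 1L)
  })
}
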