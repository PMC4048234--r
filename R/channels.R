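# Channel stacks and islet masks: construction plus TIFF/PNG reading and
# writing. Grids are plain numeric matrices indexed [row, col] with row = the
# first image axis, and intensities in [0, 1] (integer images are divided by
# their type maximum on load, so thresholds are bit-depth independent).

CHANNEL_ROLES <- c("dapi", "target488", "counter555")

#' Three-channel fluorescence image
#'
#' Bundles the three co-registered analysis layers of an islet picture: the
#' DAPI nuclear stain, the 488-channel beta-cell marker and the 555-channel
#' alpha-cell counterstain.
#'
#' @param dapi,target488,counter555 Numeric matrices with intensities in
#'   `[0, 1]`, all of identical dimensions. Rows are the first image axis.
#' @param pixel_size Optional physical edge length of one pixel in micrometres.
#' @return An object of class `channel_stack` with elements `dapi`,
#'   `target488`, `counter555` and `pixel_size`.
#' @export
channel_stack <- function(dapi, target488, counter555, pixel_size = NULL) {
  grids <- list(dapi = dapi, target488 = target488, counter555 = counter555)
  for (role in CHANNEL_ROLES) {
    g <- grids[[role]]
    if (!is.matrix(g) || !is.numeric(g)) {
      stop_format(sprintf("channel `%s` must be a numeric matrix", role))
    }
    if (anyNA(g) || min(g) < 0 || max(g) > 1) {
      stop_format(sprintf("channel `%s` must have finite intensities in [0, 1]", role))
    }
  }
  check_same_dims(dapi, target488, "dapi", "target488")
  check_same_dims(dapi, counter555, "dapi", "counter555")
  if (!is.null(pixel_size)) check_number(pixel_size, "pixel_size", lower = 1e-12)
  structure(
    list(dapi = dapi, target488 = target488, counter555 = counter555,
         pixel_size = pixel_size),
    class = "channel_stack"
  )
}

#' @export
dim.channel_stack <- function(x) dim(x$dapi)

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<channel_stack> %d x %d px (dapi / target488 / counter555)\n", d[1], d[2]))
  if (!is.null(x$pixel_size)) cat(sprintf("  pixel size: %g um\n", x$pixel_size))
  invisible(x)
}

#' Binary islet segmentation mask
#'
#' @param mask Logical matrix; `TRUE` marks islet pixels.
#' @return An object of class `islet_mask` with elements `mask` and `area_px`.
#' @export
islet_mask <- function(mask) {
  if (!is.matrix(mask)) stop_format("`mask` must be a matrix")
  mask <- mask != 0
  area <- sum(mask)
  if (area == 0L) {
    abort("islet mask contains no pixels", class = "isletscore_error_empty_islet")
  }
  structure(list(mask = mask, area_px = area), class = "islet_mask")
}

#' @export
dim.islet_mask <- function(x) dim(x$mask)

#' @export
print.islet_mask <- function(x, ...) {
  cat(sprintf("<islet_mask> %d x %d px, islet area %d px\n",
              nrow(x$mask), ncol(x$mask), x$area_px))
  invisible(x)
}

read_image_grid <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop_format(sprintf("unsupported image extension `.%s` (use TIFF or PNG): %s",
                        ext, path))
  )
  img
}

default_channel_mapping <- function() {
  c(red = "counter555", green = "target488", blue = "dapi")
}

check_channel_mapping <- function(mapping) {
  if (!is.character(mapping) || length(mapping) != 3L ||
      !setequal(names(mapping), c("red", "green", "blue")) ||
      !setequal(unname(mapping), CHANNEL_ROLES)) {
    stop_parameter(paste(
      "`mapping` must be a character vector naming the roles of the red,",
      "green and blue planes, e.g. c(red = 'counter555', green = 'target488',",
      "blue = 'dapi')"
    ))
  }
  mapping[c("red", "green", "blue")]
}

#' Load a three-channel islet image
#'
#' Reads either a composite RGB image or three single-plane image files and
#' assigns the planes to analysis roles. The default mapping follows the usual
#' fluorophore display convention: red shows the 555 counterstain, green the
#' 488 marker and blue the DAPI nuclear stain.
#'
#' @param path For `layout = "rgb_composite"`, one TIFF/PNG path. For
#'   `layout = "three_files"`, a character vector of three single-plane image
#'   paths named `dapi`, `target488` and `counter555`.
#' @param layout Either `"rgb_composite"` or `"three_files"`.
#' @param mapping Plane-to-role assignment for composites; see
#'   [default_channel_mapping()].
#' @param pixel_size Optional micrometres per pixel, carried through to
#'   physical-area features.
#' @return A [channel_stack()].
#' @export
load_channels <- function(path, layout = c("rgb_composite", "three_files"),
                          mapping = default_channel_mapping(),
                          pixel_size = NULL) {
  layout <- match.arg(layout)
  if (layout == "rgb_composite") {
    mapping <- check_channel_mapping(mapping)
    img <- read_image_grid(path)
    if (length(dim(img)) != 3L || dim(img)[3] < 3L) {
      stop_format(sprintf("composite image must have 3 planes, got dims [%s]: %s",
                          paste(dim(img), collapse = " x "), path))
    }
    planes <- list(red = img[, , 1], green = img[, , 2], blue = img[, , 3])
    grids <- setNames(planes, unname(mapping))
  } else {
    if (!is.character(path) || length(path) != 3L ||
        !setequal(names(path), CHANNEL_ROLES)) {
      stop_parameter(
        "for layout 'three_files', `path` must be three paths named dapi, target488, counter555"
      )
    }
    grids <- lapply(path[CHANNEL_ROLES], function(p) {
      g <- read_image_grid(p)
      if (length(dim(g)) == 3L) g <- g[, , 1]
      g
    })
  }
  channel_stack(grids$dapi, grids$target488, grids$counter555,
                pixel_size = pixel_size)
}

#' Write a channel stack to a composite image
#'
#' Writes the three layers as an RGB composite using the inverse of the given
#' plane mapping. TIFF output is 16-bit, which round-trips 8- and 16-bit
#' source data exactly.
#'
#' @param stack A [channel_stack()].
#' @param path Output TIFF or PNG path.
#' @param mapping Plane-to-role assignment, as in [load_channels()].
#' @return `path`, invisibly.
#' @export
write_channels <- function(stack, path, mapping = default_channel_mapping()) {
  stopifnot(inherits(stack, "channel_stack"))
  mapping <- check_channel_mapping(mapping)
  d <- dim(stack)
  img <- array(0, dim = c(d[1], d[2], 3L))
  for (i in 1:3) img[, , i] <- stack[[mapping[i]]]
  ext <- tolower(tools::file_ext(path))
  ok <- switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
    png = png::writePNG(img, path),
    stop_format(sprintf("unsupported image extension `.%s`", ext))
  )
  invisible(path)
}

#' Load a binary islet mask
#'
#' Any nonzero pixel marks the islet. The mask must match the dimensions of
#' its channel stack and must contain at least one islet pixel.
#'
#' @param path Single-plane TIFF or PNG path.
#' @param dims Expected `c(height, width)` in pixels.
#' @return An [islet_mask()].
#' @export
load_islet_mask <- function(path, dims) {
  g <- read_image_grid(path)
  if (length(dim(g)) == 3L) g <- g[, , 1]
  if (!identical(dim(g), as.integer(dims))) {
    stop_format(sprintf("mask is %d x %d but expected %d x %d: %s",
                        nrow(g), ncol(g), dims[1], dims[2], path))
  }
  islet_mask(g > 0)
}

#' Write an islet mask image
#'
#' @param islet An [islet_mask()].
#' @param path Output TIFF or PNG path.
#' @return `path`, invisibly.
#' @export
write_islet_mask <- function(islet, path) {
  stopifnot(inherits(islet, "islet_mask"))
  g <- matrix(as.numeric(islet$mask), nrow = nrow(islet$mask))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(g, path, bits.per.sample = 8L),
    png = png::writePNG(g, path),
    stop_format(sprintf("unsupported image extension `.%s`", ext))
  )
  invisible(path)
}
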