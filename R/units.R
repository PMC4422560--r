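#' Pixel / micron unit conversions
#'
#' The assay images at 4x magnification with 2.5 um/px, fixed by the
#' background-estimation geometry (80 um blocks spanning 32 px).  All
#' distance thresholds in the pipeline are stored in microns; these helpers
#' convert the pixel-denominated thresholds used at segmentation and
#' tracking time.
#'
#' @param px length or area in pixels.
#' @param um length in microns.
#' @param pixel_size microns per pixel (default 2.5).
#' @return converted numeric vector.
#' @examples
#' px_to_um(16)        # crowding threshold: 16 px = 40 um
#' px_to_um(4)         # minimum move for angle measurement: 4 px = 10 um
#' px_area_to_um2(75)  # upper area filter ~ 470 um^2
#' @export
px_to_um <- function(px, pixel_size = 2.5) px * pixel_size

#' @rdname px_to_um
#' @export
um_to_px <- function(um, pixel_size = 2.5) um / pixel_size

#' @rdname px_to_um
#' @export
px_area_to_um2 <- function(px, pixel_size = 2.5) px * pixel_size^2
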