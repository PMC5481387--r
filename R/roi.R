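#' Define an axis-aligned analysis region (ROI)
#'
#' An ROI is an axis-aligned box with its origin fixed at (0, 0, 0) and side
#' lengths `Lx`, `Ly`, `Lz` in nanometres. Coordinates inside an ROI follow
#' the half-open convention `[0, L)` on each axis, which makes the toroidal
#' wrap arithmetic used throughout the package exact.
#'
#' @param Lx,Ly,Lz Side lengths in nm; all must be strictly positive.
#'
#' @return An object of class `"roi"`: a list with elements `Lx`, `Ly`, `Lz`.
#' @examples
#' r <- roi(3000, 3000, 600)
#' roi_volume(r)  # 5.4e9 nm^3
#' @export
roi <- function(Lx, Ly, Lz) {
  dims <- c(Lx = Lx, Ly = Ly, Lz = Lz)
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    stop("ROI side lengths must be finite and strictly positive", call. = FALSE)
  }
  structure(list(Lx = Lx, Ly = Ly, Lz = Lz), class = "roi")
}

#' @describeIn roi Volume of the ROI in nm^3.
#' @param x An `roi` object.
#' @export
roi_volume <- function(x) {
  stopifnot(inherits(x, "roi"))
  x$Lx * x$Ly * x$Lz
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %g x %g x %g nm (V = %g nm^3)\n",
              x$Lx, x$Ly, x$Lz, roi_volume(x)))
  invisible(x)
}

roi_sides <- function(x) c(x$Lx, x$Ly, x$Lz)
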