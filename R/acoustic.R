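#' Specify the focused ultrasound source
#'
#' Parametric description of the in-plane focal zone of the 1.5-MHz focused
#' histotripsy source.  Only the -6 dB focal widths of the measured field are
#' published for the thrombosis transducer, so the field is modelled as a
#' separable elliptical Gaussian matched to those widths; a measured map can
#' be substituted via [read_pressure_matrix()].
#'
#' @param peak_negative_pressure Spatial-peak peak-negative pressure in MPa.
#' @param frequency Fundamental frequency in MHz (default 1.5).
#' @param axial_width_6dB Axial -6 dB focal width in mm (default 4.3).
#' @param lateral_width_6dB Lateral -6 dB focal width in mm (default 0.7).
#' @param focus Focus location `c(x, y)` in mm, or `NULL` to align with the
#'   thrombus centroid when the field is rendered onto a section.
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(peak_negative_pressure, frequency = 1.5,
                        axial_width_6dB = 4.3, lateral_width_6dB = 0.7,
                        focus = NULL) {
  if (peak_negative_pressure < 0) stop("'peak_negative_pressure' must be >= 0")
  if (axial_width_6dB <= 0 || lateral_width_6dB <= 0 || frequency <= 0)
    stop("widths and frequency must be positive")
  structure(list(peak_negative_pressure = peak_negative_pressure,
                 frequency = frequency,
                 axial_width_6dB = axial_width_6dB,
                 lateral_width_6dB = lateral_width_6dB,
                 focus = focus),
            class = "source_spec")
}

#' Render the peak-negative-pressure field onto a section grid
#'
#' Separable Gaussian focal model: the pressure is at its spatial peak at the
#' focus and falls to half its peak at half the -6 dB width along each axis.
#' Propagation is along the grid vertical (rows = axial direction).
#'
#' @param spec A [source_spec()].
#' @param section A [histology_section()] supplying the grid geometry.
#' @return An object of class `pressure_field`: list with `p_neg` (matrix,
#'   MPa, same dimensions as the section), `focus` (mm) and `spec`.
#' @examples
#' s <- generate_section(0.2, extent = 6, pixel_size = 30, seed = 2)
#' f <- pressure_field(source_spec(36), s)
#' max(f$p_neg)  # 36 at the focus pixel
#' @export
pressure_field <- function(spec, section) {
  stopifnot(inherits(spec, "source_spec"), inherits(section, "histology_section"))
  focus <- spec$focus %||% unname(section_centroid(section))
  ps <- section$pixel_size / 1000
  x <- (seq_len(ncol(section$labels)) - 0.5) * ps + section$origin[1]
  y <- (seq_len(nrow(section$labels)) - 0.5) * ps + section$origin[2]
  ## half maximum at +/- width/2 from the focus
  ax <- exp(-log(2) * ((y - focus[2]) / (spec$axial_width_6dB / 2))^2)
  lat <- exp(-log(2) * ((x - focus[1]) / (spec$lateral_width_6dB / 2))^2)
  p <- spec$peak_negative_pressure * outer(ax, lat)
  structure(list(p_neg = p, focus = focus, spec = spec),
            class = "pressure_field")
}

#' @export
print.pressure_field <- function(x, ...) {
  cat(sprintf("<pressure_field> %d x %d, peak %.3g MPa at (%.2f, %.2f) mm\n",
              nrow(x$p_neg), ncol(x$p_neg), max(x$p_neg),
              x$focus[1], x$focus[2]))
  invisible(x)
}

#' Import a measured pressure map
#'
#' Reads a whitespace-delimited matrix of peak negative pressures (MPa) and
#' wraps it as a `pressure_field` co-registered to a section grid.  The matrix
#' must match the section dimensions pixel-for-pixel.
#'
#' @param path Path to the delimited text matrix.
#' @param section The [histology_section()] the map is co-registered to.
#' @return A `pressure_field`.
#' @export
read_pressure_matrix <- function(path, section) {
  p <- as.matrix(read.table(path, header = FALSE))
  dimnames(p) <- NULL
  if (!identical(dim(p), dim(section$labels)))
    stop("pressure matrix dimensions do not match the section grid")
  if (any(p < 0)) stop("peak negative pressures must be >= 0 MPa")
  focus_idx <- which(p == max(p), arr.ind = TRUE)[1, ]
  ps <- section$pixel_size / 1000
  structure(list(p_neg = p,
                 focus = c((focus_idx[2] - 0.5) * ps + section$origin[1],
                           (focus_idx[1] - 0.5) * ps + section$origin[2]),
                 spec = NULL),
            class = "pressure_field")
}
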