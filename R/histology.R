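#' Construct a histology section
#'
#' A histology section is the spatial substrate for every calculation in the
#' package: a 2D grid of categorical labels (fibrin, red blood cell or
#' background) with a physical pixel size.  Sections are normally produced by
#' [generate_section()] or [read_label_mask()].
#'
#' @param labels Integer matrix of label codes (see [label_codes()]).  Rows are
#'   the vertical (axial) direction, columns horizontal (lateral).
#' @param pixel_size Edge length of one pixel in micrometres (default 7.4, the
#'   scale of a red blood cell).
#' @param origin Physical coordinate (mm) of the grid corner, `c(x, y)`.
#' @return An object of class `histology_section`.
#' @export
histology_section <- function(labels, pixel_size = 7.4, origin = c(0, 0)) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a single positive length in micrometres")
  bad <- setdiff(unique(as.vector(labels)), unname(label_codes()))
  if (length(bad))
    stop("unknown label code(s): ", paste(bad, collapse = ", "))
  if (!any(labels != LBL_BACKGROUND))
    stop("section contains no thrombus pixels")
  structure(
    list(labels = labels, pixel_size = pixel_size, origin = as.numeric(origin)),
    class = "histology_section")
}

#' @export
print.histology_section <- function(x, ...) {
  comp <- composition(x)
  cat(sprintf("<histology_section> %d x %d pixels @ %.3g um (%.2f x %.2f mm)\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size,
              nrow(x$labels) * x$pixel_size / 1000,
              ncol(x$labels) * x$pixel_size / 1000))
  cat(sprintf("  thrombus area %.2f mm^2, fibrin fraction %.3f (%s)\n",
              comp$thrombus_area, comp$fibrin_fraction, comp$subgroup))
  invisible(x)
}

#' @export
plot.histology_section <- function(x, ...) {
  pal <- c("white", "firebrick", "lightpink", "grey90")  # bg, rbc, fibrin, ablated
  z <- t(x$labels)[, rev(seq_len(nrow(x$labels)))]
  image(seq_len(nrow(z)) * x$pixel_size / 1000,
        seq_len(ncol(z)) * x$pixel_size / 1000,
        z, col = pal, zlim = c(-0.5, 3.5), asp = 1,
        xlab = "lateral (mm)", ylab = "axial (mm)", ...)
  invisible(x)
}

## Gaussian smoothing with periodic boundaries via FFT; sigma in pixels.
## Used to turn white noise into a spatially correlated texture.
smooth_field_fft <- function(z, sigma) {
  nr <- nrow(z); nc <- ncol(z)
  fr <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fc <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  gr <- exp(-2 * pi^2 * sigma^2 * fr^2)
  gc <- exp(-2 * pi^2 * sigma^2 * fc^2)
  Re(fft(fft(z) * outer(gr, gc), inverse = TRUE)) / (nr * nc)
}

#' Generate a synthetic thrombus section
#'
#' Emulates an annotated H&E thrombus cross-section: a compact, roughly
#' elliptical thrombus blob (about 70% of the field of view) whose interior is
#' partitioned into spatially clustered fibrin and red-blood-cell territories.
#' The texture is produced by thresholding an isotropically smoothed Gaussian
#' noise field at the quantile matching the requested fibrin fraction, so the
#' realized fraction tracks the target closely while the patches keep a single
#' interpretable correlation length.
#'
#' @param target_fibrin_fraction Desired fibrin fraction of the thrombus
#'   pixels, in `[0, 1]`.
#' @param clustering_scale Correlation length of the fibrin/RBC patches in mm
#'   (default 0.5; patches in real sections cluster at roughly 0.1--1 mm).
#' @param extent Physical side length of the (square) field of view in mm
#'   (default 10; must cover the focal zone, i.e. at least 5 mm).
#' @param pixel_size Pixel edge in micrometres (default 7.4).
#' @param seed Optional integer seed; identical seed and parameters reproduce
#'   the identical section bit-for-bit.
#' @return A [histology_section()].
#' @examples
#' s <- generate_section(0.5, extent = 6, pixel_size = 30, seed = 1)
#' composition(s)
#' @export
generate_section <- function(target_fibrin_fraction, clustering_scale = 0.5,
                             extent = 10, pixel_size = 7.4, seed = NULL) {
  if (!is.numeric(target_fibrin_fraction) || length(target_fibrin_fraction) != 1L ||
      is.na(target_fibrin_fraction) ||
      target_fibrin_fraction < 0 || target_fibrin_fraction > 1)
    stop("'target_fibrin_fraction' must be a single value in [0, 1]")
  if (clustering_scale <= 0 || extent <= 0 || pixel_size <= 0)
    stop("'clustering_scale', 'extent' and 'pixel_size' must be positive")
  if (!is.null(seed)) set.seed(seed)

  n <- max(8L, as.integer(round(extent * 1000 / pixel_size)))
  ## elliptical thrombus outline filling ~70% of the grid
  a <- 0.49 * n; b <- 0.455 * n
  rows <- seq_len(n) - (n + 1) / 2
  cols <- seq_len(n) - (n + 1) / 2
  inside <- outer(rows^2 / a^2, cols^2 / b^2, `+`) <= 1

  noise <- matrix(rnorm(n * n), n, n)
  sigma_px <- clustering_scale * 1000 / pixel_size
  field <- smooth_field_fft(noise, sigma_px)

  labels <- matrix(LBL_BACKGROUND, n, n)
  labels[inside] <- LBL_RBC
  if (target_fibrin_fraction >= 1) {
    labels[inside] <- LBL_FIBRIN
  } else if (target_fibrin_fraction > 0) {
    thr <- quantile(field[inside], probs = 1 - target_fibrin_fraction,
                    names = FALSE, type = 7)
    labels[inside & field >= thr] <- LBL_FIBRIN
  }
  histology_section(labels, pixel_size = pixel_size)
}

#' Summarise thrombus composition
#'
#' Fractions are computed over thrombus pixels only (fibrin plus red blood
#' cell; ablated pixels count as red blood cell material for composition
#' purposes since composition is a property of the untreated section).
#'
#' @param section A [histology_section()].
#' @return A list of class `composition_summary` with `fibrin_fraction`,
#'   `rbc_fraction`, `subgroup` and `thrombus_area` (mm^2).
#' @export
composition <- function(section) {
  stopifnot(inherits(section, "histology_section"))
  lab <- section$labels
  n_fib <- sum(lab == LBL_FIBRIN)
  n_rbc <- sum(lab == LBL_RBC | lab == LBL_ABLATED)
  n_tot <- n_fib + n_rbc
  if (n_tot == 0L) stop("section contains no thrombus pixels")
  ff <- n_fib / n_tot
  structure(
    list(fibrin_fraction = ff, rbc_fraction = n_rbc / n_tot,
         subgroup = classify_subgroup(ff),
         thrombus_area = n_tot * (section$pixel_size / 1000)^2),
    class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf("fibrin %.3f / RBC %.3f, %s, %.2f mm^2 thrombus\n",
              x$fibrin_fraction, x$rbc_fraction, x$subgroup, x$thrombus_area))
  invisible(x)
}

#' Classify a thrombus subgroup from its fibrin fraction
#'
#' Subgroups follow the conventional composition thresholds: strictly more
#' than 75% fibrin is fibrin-dominant (a proxy for chronic thrombus), strictly
#' more than 75% red blood cells is RBC-dominant (acute), and everything in
#' between -- including the boundary values 0.25 and 0.75 exactly -- is
#' Half-Half (subacute).
#'
#' @param fibrin_fraction Fibrin fraction in `[0, 1]` (vectorised).
#' @return Character vector: `"FIBRIN_DOMINANT"`, `"RBC_DOMINANT"` or
#'   `"HALF_HALF"`.
#' @export
classify_subgroup <- function(fibrin_fraction) {
  if (any(is.na(fibrin_fraction)) ||
      any(fibrin_fraction < 0 | fibrin_fraction > 1))
    stop("'fibrin_fraction' must be in [0, 1]")
  ifelse(fibrin_fraction > 0.75, "FIBRIN_DOMINANT",
         ifelse(fibrin_fraction < 0.25, "RBC_DOMINANT", "HALF_HALF"))
}

#' Read / write portable label masks
#'
#' Sections are stored as a whitespace-delimited integer matrix of label codes
#' with a plain key--value sidecar (`<path>.meta`) holding `pixel_size_um` and
#' the grid origin.  A write followed by a read reproduces the labels and
#' pixel size exactly.
#'
#' @param path File path for the matrix; the metadata sidecar is `<path>.meta`.
#' @param section A [histology_section()] (or, for ablation masks, any object
#'   with the same structure -- ablated pixels use code 3).
#' @return `read_label_mask()` returns a [histology_section()];
#'   `write_label_mask()` returns `path` invisibly.
#' @export
read_label_mask <- function(path) {
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path)) stop("missing metadata sidecar: ", meta_path)
  kv <- read.table(meta_path, header = FALSE, sep = "=", strip.white = TRUE,
                   col.names = c("key", "value"), stringsAsFactors = FALSE)
  meta <- stats::setNames(as.numeric(kv$value), kv$key)
  if (!"pixel_size_um" %in% names(meta))
    stop("metadata sidecar lacks 'pixel_size_um'")
  labels <- as.matrix(read.table(path, header = FALSE))
  dimnames(labels) <- NULL
  histology_section(labels, pixel_size = meta[["pixel_size_um"]],
                    origin = c(meta["origin_x_mm"] %||% 0,
                               meta["origin_y_mm"] %||% 0))
}

#' @rdname read_label_mask
#' @export
write_label_mask <- function(section, path) {
  stopifnot(inherits(section, "histology_section"))
  write.table(section$labels, path, row.names = FALSE, col.names = FALSE)
  writeLines(c(sprintf("pixel_size_um = %.17g", section$pixel_size),
               sprintf("origin_x_mm = %.17g", section$origin[1]),
               sprintf("origin_y_mm = %.17g", section$origin[2])),
             paste0(path, ".meta"))
  invisible(path)
}

#' Thrombus centroid in physical coordinates
#'
#' Centroid of all thrombus pixels (fibrin, RBC and ablated), in mm relative
#' to the grid origin.  Used to centre both the infusion catheter and the
#' default acoustic focus.
#'
#' @param section A [histology_section()].
#' @return Numeric `c(x, y)` in mm (x along columns, y along rows).
#' @export
section_centroid <- function(section) {
  lab <- section$labels
  idx <- which(lab != LBL_BACKGROUND, arr.ind = TRUE)
  ps <- section$pixel_size / 1000
  c(x = mean(idx[, 2] - 0.5) * ps + section$origin[1],
    y = mean(idx[, 1] - 0.5) * ps + section$origin[2])
}
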