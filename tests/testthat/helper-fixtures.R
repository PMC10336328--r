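## Shared fixtures: sections and fields built in code, plus an R-level
## reference implementation of the per-pulse Monte Carlo used to cross-check
## the compiled path draw-for-draw.

## Uniform peak-negative-pressure field on a section grid.
uniform_field <- function(p, section) {
  structure(list(p_neg = matrix(p, nrow(section$labels), ncol(section$labels)),
                 focus = unname(section_centroid(section)), spec = NULL),
            class = "pressure_field")
}

## Homogeneous elliptical section (single label) at a given pixel size.
ellipse_section <- function(extent_mm = 10, pixel_size = 29.6,
                            label = label_codes()[["RBC"]]) {
  n <- as.integer(round(extent_mm * 1000 / pixel_size))
  rows <- seq_len(n) - (n + 1) / 2
  inside <- outer(rows^2 / (0.49 * n)^2, rows^2 / (0.455 * n)^2, `+`) <= 1
  lab <- matrix(label_codes()[["BACKGROUND"]], n, n)
  lab[inside] <- label
  histology_section(lab, pixel_size = pixel_size)
}

## Reference single-pulse Monte Carlo: same candidate enumeration
## (column-major thrombus pixels with probability above the floor), one
## uniform draw per candidate, modulus averages on the pulse-start state,
## disk footprints over RBC pixels.  Mirrors the documented contract of the
## compiled kernel using only exported R functions.
ref_pulse <- function(labels, pneg, pixel_size, m = material_parameters(),
                      model = nucleation_model()) {
  nr <- nrow(labels)
  prob <- pnorm(pneg, model$threshold_mean, model$threshold_sd)
  cand <- which(labels != 0L & prob > 1e-12)
  u <- runif(length(cand))
  nuc <- cand[prob[cand] > u]
  snapshot <- histology_section(labels, pixel_size = pixel_size)
  out <- labels
  for (k in nuc) {
    i0 <- ((k - 1L) %% nr) + 1L
    j0 <- ((k - 1L) %/% nr) + 1L
    G <- tryCatch(local_shear_modulus(snapshot, c(i0, j0), m),
                  error = function(e) NA_real_)
    if (is.na(G)) next
    if (bubble_xi(pneg[k], G, m) <= 0) next
    rpx <- max_bubble_radius(pneg[k], G, m) / pixel_size
    ii <- max(1L, i0 - floor(rpx)):min(nr, i0 + floor(rpx))
    jj <- max(1L, j0 - floor(rpx)):min(ncol(labels), j0 + floor(rpx))
    sel <- outer((ii - i0)^2, (jj - j0)^2, `+`) <= rpx^2
    blk <- out[ii, jj, drop = FALSE]
    blk[sel & blk == 1L] <- 3L
    out[ii, jj] <- blk
  }
  out
}
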