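#' Configure a dose-response experiment
#'
#' Describes a cohort of sections and a pressure sweep for the serial
#' pipeline: Monte Carlo ablation, steady rt-PA transport, fibrinolysis, and
#' summary statistics.  The study-scale defaults are a 28--40 MPa sweep in
#' 2-MPa steps plus a 0-MPa baseline, 1000 pulses and 10 Monte Carlo repeats;
#' tests and examples use smaller values.
#'
#' @param sections A list of [histology_section()] objects, or a data frame /
#'   list of generator parameter lists for [generate_section()] (fields
#'   `target_fibrin_fraction` and optionally `clustering_scale`, `extent`,
#'   `pixel_size`).
#' @param pressures Peak negative pressures in MPa (default `c(0, 28--40)`;
#'   a 0-MPa baseline is required for relative FDP).
#' @param n_pulses Pulses per treatment (default 1000).
#' @param n_repeats Monte Carlo repeats (default 10).
#' @param material [material_parameters()].
#' @param nucleation [nucleation_model()].
#' @param transport [transport_parameters()].
#' @param kinetics [kinetic_parameters()].
#' @param grid_dr Radial step of the transport grid, cm (default 0.002).
#' @param fdp_repeats How many Monte Carlo repeats get a full transport +
#'   fibrinolysis evaluation (default 1; transport is deterministic given a
#'   mask, and mask-to-mask variability is small next to its cost).
#' @param seed Master seed for the whole experiment.
#' @param outdir Optional directory for result tables and mask/field exports.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(sections, pressures = c(0, seq(28, 40, by = 2)),
                              n_pulses = 1000, n_repeats = 10,
                              material = material_parameters(),
                              nucleation = nucleation_model(),
                              transport = transport_parameters(),
                              kinetics = kinetic_parameters(),
                              grid_dr = 0.002, fdp_repeats = 1,
                              seed = 1, outdir = NULL) {
  if (!length(pressures)) stop("'pressures' must be non-empty")
  structure(list(sections = sections, pressures = sort(unique(pressures)),
                 n_pulses = n_pulses, n_repeats = n_repeats,
                 material = material, nucleation = nucleation,
                 transport = transport, kinetics = kinetics,
                 grid_dr = grid_dr, fdp_repeats = fdp_repeats,
                 seed = seed, outdir = outdir),
            class = "experiment_config")
}

## Resolve the section cohort: pass histology_section objects through,
## generate from parameter lists otherwise (seeded off the master seed).
resolve_sections <- function(config) {
  secs <- config$sections
  if (inherits(secs, "histology_section")) secs <- list(secs)
  lapply(seq_along(secs), function(i) {
    s <- secs[[i]]
    if (inherits(s, "histology_section")) return(s)
    do.call(generate_section,
            modifyList(list(seed = config$seed + 1000L + i), as.list(s)))
  })
}

#' Run the serial histotripsy + thrombolysis pipeline
#'
#' For every section and every pressure in the sweep: run the Monte Carlo
#' treatment (no treatment at 0 MPa), solve the transport equation to steady
#' state on the resulting ablation mask, evaluate fibrinolysis over the
#' fibrin pixels, and collect one row per (section, pressure, repeat).  Each
#' stage is seeded deterministically from the master seed, so a rerun with an
#' identical configuration reproduces the identical table.  A failure in one
#' (section, pressure) cell is logged and skipped rather than aborting the
#' sweep.
#'
#' @param config An [experiment_config()].
#' @param verbose Print per-cell progress (default FALSE).
#' @return A data frame of class `dose_response` with columns `section`,
#'   `subgroup`, `fibrin_fraction`, `pressure_MPa`, `repeat_idx`,
#'   `ablation_area_mm2`, `hemoglobin_ng`, `hemoglobin_catheter_ng`,
#'   `fdp_total` and `relative_fdp` (FDP fields are per-pressure values,
#'   repeated across repeat rows; `NA` where not evaluated).
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  sections <- resolve_sections(config)
  rows <- list()
  for (si in seq_along(sections)) {
    sec <- sections[[si]]
    comp <- composition(sec)
    hb_cath <- catheter_hemolysis(sec, config$transport$catheter_radius)
    grid <- section_polar_grid(sec, config$transport, config$grid_dr)
    fdp_by_pressure <- rep(NA_real_, length(config$pressures))
    for (pi in seq_along(config$pressures)) {
      p <- config$pressures[pi]
      cell <- tryCatch({
        run_pipeline_cell(sec, p, config, grid, si, pi, verbose)
      }, error = function(e) {
        warning(sprintf("section %d, %g MPa failed: %s", si, p,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (is.null(cell)) next
      fdp_by_pressure[pi] <- cell$fdp_total
      rows[[length(rows) + 1L]] <- data.frame(
        section = si, subgroup = comp$subgroup,
        fibrin_fraction = comp$fibrin_fraction,
        pressure_MPa = p, repeat_idx = seq_len(max(1L, cell$n_repeats)),
        ablation_area_mm2 = cell$area,
        hemoglobin_ng = cell$hb,
        hemoglobin_catheter_ng = hb_cath,
        fdp_total = cell$fdp_total,
        relative_fdp = NA_real_)
    }
    base <- fdp_by_pressure[config$pressures == 0]
    if (length(base) == 1 && !is.na(base) && base > 0) {
      for (k in seq_along(rows)) {
        if (rows[[k]]$section[1] == si)
          rows[[k]]$relative_fdp <- rows[[k]]$fdp_total / base
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("dose_response", class(out))
  if (!is.null(config$outdir)) export_dose_response(out, config$outdir)
  out
}

## A transport grid sized to the section: outer radius at the farthest
## thrombus pixel from the centroid.
section_polar_grid <- function(section, transport, dr) {
  lab <- section$labels
  ps_cm <- section$pixel_size / 1e4
  ctr <- section_centroid(section) / 10
  idx <- which(lab != LBL_BACKGROUND, arr.ind = TRUE)
  x <- (idx[, 2] - 0.5) * ps_cm + section$origin[1] / 10 - ctr[1]
  y <- (idx[, 1] - 0.5) * ps_cm + section$origin[2] / 10 - ctr[2]
  r_max <- max(sqrt(x^2 + y^2)) + 2 * dr
  polar_grid(r_min = transport$catheter_radius / 10, r_max = r_max, dr = dr)
}

## One (section, pressure) cell of the sweep.
run_pipeline_cell <- function(sec, p, config, grid, si, pi, verbose) {
  cell_seed <- (config$seed + 7919L * si + 104729L * pi) %% .Machine$integer.max
  if (p > 0) {
    field <- pressure_field(source_spec(p), sec)
    tr <- run_treatment(sec, field, config$material, config$nucleation,
                        n_pulses = config$n_pulses,
                        n_repeats = config$n_repeats, seed = cell_seed)
    area <- tr$area_curve[nrow(tr$area_curve), ]
    hb <- tr$hemoglobin_histotripsy
    masks <- tr$masks[seq_len(min(config$fdp_repeats, length(tr$masks)))]
    n_repeats <- config$n_repeats
  } else {
    area <- rep(0, config$n_repeats)
    hb <- rep(0, config$n_repeats)
    masks <- list(NULL)
    n_repeats <- config$n_repeats
  }
  fdp_vals <- vapply(masks, function(mk) {
    fld <- solve_transport(config$transport, grid, section = sec,
                           ablated_mask = mk, duration = 60,
                           steady_tol = 1e-3)
    fdp_map(fld, sec, k = config$kinetics)$total
  }, numeric(1))
  if (verbose)
    message(sprintf("section %d @ %g MPa: area %.3g mm^2, FDP %.4g",
                    si, p, mean(area), mean(fdp_vals)))
  list(area = area, hb = hb, fdp_total = mean(fdp_vals),
       n_repeats = n_repeats)
}

## Delimited-text exports: one row per (section, pressure, repeat) plus a
## per-pressure FDP table.
export_dose_response <- function(tab, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write.table(tab, file.path(outdir, "dose_response.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(tab)
}

#' Summary statistics of a dose-response table
#'
#' Reproduces the study's statistical battery on a dose-response table:
#' subgroup-wise ANOVA/Tukey of final ablation area, Pearson correlation of
#' ablation area against pressure per subgroup, and the z-score linear
#' regression coefficient between hemoglobin and FDP per section.
#'
#' @param tab A [run_experiment()] result.
#' @return List with `anova` ([anova_tukey()] across subgroups at the top
#'   pressure), `pearson` (per-subgroup correlation of area vs pressure) and
#'   `lrc` (per-section coefficient; `NA` where hemoglobin does not vary).
#' @export
dose_response_stats <- function(tab) {
  treated <- tab[tab$pressure_MPa > 0, ]
  top <- treated[treated$pressure_MPa == max(treated$pressure_MPa), ]
  an <- if (length(unique(top$subgroup)) >= 2)
    anova_tukey(top$ablation_area_mm2, top$subgroup) else NULL
  pe <- lapply(split(treated, treated$subgroup), function(d) {
    agg <- stats::aggregate(ablation_area_mm2 ~ pressure_MPa + section, d, mean)
    if (sd(agg$ablation_area_mm2) == 0) return(NULL)
    pearson_correlation(agg$pressure_MPa, agg$ablation_area_mm2)
  })
  lrc <- vapply(split(treated, treated$section), function(d) {
    agg <- stats::aggregate(cbind(hemoglobin_ng, fdp_total) ~ pressure_MPa,
                            d, mean)
    if (nrow(agg) < 3) return(NA_real_)
    linear_regression_coefficient(agg$hemoglobin_ng, agg$fdp_total)
  }, numeric(1))
  list(anova = an, pearson = pe, lrc = lrc)
}
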