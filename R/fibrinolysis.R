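#' Fibrinolysis kinetic parameters
#'
#' Rate constants and concentrations of the closed-form two-step fibrinolysis
#' cascade: rt-PA converts plasminogen to plasmin (rate `k1`), plasmin cleaves
#' fibrin into fibrin degradation products (rate `k4`), and alpha-2
#' antiplasmin quenches plasmin (rate `k3`).  With plasmin at its fast
#' quasi-steady level the fibrin pool decays exponentially with rate
#' `k1 k4 C C_Pm / (k3 C_AP)`.
#'
#' @param C_FIB Initial fibrin concentration in fibrin pixels, nM
#'   (default 950; red-blood-cell pixels carry 0).
#' @param C_Pm Plasminogen concentration, uM (default 0.13).
#' @param C_AP Alpha-2 antiplasmin concentration, uM (default 0.44).
#' @param k1 Plasminogen-to-plasmin rate under rt-PA, 1/(uM s)
#'   (default 0.011).
#' @param k4 Fibrin-to-FDP rate under plasmin, 1/(uM s) (default 0.77).
#' @param k3 Plasmin quench rate under antiplasmin, 1/(uM s) (default 10).
#' @param exposure_time rt-PA exposure time, s (default 1200 = 20 min).
#' @return An object of class `kinetic_parameters`.
#' @export
kinetic_parameters <- function(C_FIB = 950, C_Pm = 0.13, C_AP = 0.44,
                               k1 = 0.011, k4 = 0.77, k3 = 10,
                               exposure_time = 1200) {
  if (any(c(C_FIB, C_Pm, C_AP, k1, k4, k3) < 0))
    stop("concentrations and rates must be >= 0")
  if (exposure_time <= 0) stop("'exposure_time' must be positive")
  structure(list(C_FIB = C_FIB, C_Pm = C_Pm, C_AP = C_AP, k1 = k1, k4 = k4,
                 k3 = k3, exposure_time = exposure_time),
            class = "kinetic_parameters")
}

#' Fibrin degradation product concentration
#'
#' Closed-form FDP concentration after exposure of fibrin to a local rt-PA
#' concentration `C` for time `t`:
#' `C_FDP = C_FIB (1 - exp(-(k1 k4 C C_Pm / (k3 C_AP)) t))`.
#' Monotone increasing in `C` and `t`, saturating at `C_FIB`.
#'
#' @param C_rtpa Local rt-PA concentration, nM (vectorised).
#' @param t Exposure time, s (default `k$exposure_time`).
#' @param k [kinetic_parameters()].
#' @return FDP concentration in nM.
#' @examples
#' fdp_concentration(700, 1200)  # ~180 nM at source strength for 20 min
#' @export
fdp_concentration <- function(C_rtpa, t = NULL, k = kinetic_parameters()) {
  t <- t %||% k$exposure_time
  if (any(C_rtpa < 0) || any(t < 0)) stop("'C_rtpa' and 't' must be >= 0")
  rate <- k$k1 * k$k4 * (C_rtpa / 1000) * k$C_Pm / (k$k3 * k$C_AP)  # 1/s
  k$C_FIB * (1 - exp(-rate * t))
}

#' Map fibrin degradation over a section
#'
#' Evaluates [fdp_concentration()] at every fibrin pixel of the section,
#' sampling the steady rt-PA field at the pixel's polar position (nearest
#' node; pixels inside the catheter lumen see the source concentration and
#' pixels beyond the solved annulus see zero).  Fibrin pixels inside ablated
#' zones retain their full fibrin pool: histotripsy alone degrades no fibrin.
#'
#' @param field A [solve_transport()] result at steady state.
#' @param section A [histology_section()].
#' @param ablated_mask Unused for fibrin bookkeeping (fibrin persists through
#'   ablation) but accepted for interface symmetry.
#' @param k [kinetic_parameters()].
#' @param t Exposure time, s (default `k$exposure_time`).
#' @return List with `map` (matrix of per-pixel FDP, nM, zero outside fibrin)
#'   and `total` (sum over fibrin pixels, nM pixel units; pixel area cancels
#'   in relative comparisons).
#' @export
fdp_map <- function(field, section, ablated_mask = NULL,
                    k = kinetic_parameters(), t = NULL) {
  stopifnot(inherits(field, "concentration_field"),
            inherits(section, "histology_section"))
  lab <- section$labels
  fib <- which(lab == LBL_FIBRIN, arr.ind = TRUE)
  map <- matrix(0, nrow(lab), ncol(lab))
  if (nrow(fib)) {
    ps_cm <- section$pixel_size / 1e4
    ctr <- section_centroid(section) / 10
    x <- (fib[, 2] - 0.5) * ps_cm + section$origin[1] / 10 - ctr[1]
    y <- (fib[, 1] - 0.5) * ps_cm + section$origin[2] / 10 - ctr[2]
    rr <- sqrt(x^2 + y^2)
    th <- atan2(y, x) %% (2 * pi)
    ir <- round((rr - field$grid$r_min) / field$grid$dr)
    it <- (round(th / field$grid$dtheta) %% length(field$theta)) + 1L
    Cloc <- numeric(nrow(fib))
    inside_cath <- ir < 1L
    in_domain <- ir >= 1L & ir <= length(field$r)
    Cloc[inside_cath] <- field$params$C_source
    Cloc[in_domain] <- field$C[cbind(ir[in_domain], it[in_domain])]
    map[fib] <- fdp_concentration(Cloc, t, k)
  }
  list(map = map, total = sum(map[fib]))
}

#' Relative fibrin degradation
#'
#' Ratio of the FDP total under a histotripsy exposure to the FDP total with
#' no histotripsy (0 MPa baseline).
#'
#' @param fdp_pnp FDP total at the treatment pressure.
#' @param fdp_baseline FDP total of the 0-MPa baseline (must be positive).
#' @return Dimensionless ratio.
#' @export
relative_fdp <- function(fdp_pnp, fdp_baseline) {
  if (any(fdp_baseline <= 0))
    stop("baseline FDP is zero; relative FDP undefined")
  fdp_pnp / fdp_baseline
}
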