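#' Material and bubble-model parameters
#'
#' Physical constants for the analytic Kelvin-Voigt maximum-bubble-radius
#' model and for the composition-dependent elastic modulus of thrombus.
#'
#' @param P0 Ambient pressure, MPa (default 0.1).
#' @param rho Density, kg/m^3 (default 1000).
#' @param R0 Intrinsic nucleus radius, nm (default 2.5).
#' @param G_fibrin Elastic modulus of fibrin, Pa (default 14e6).
#' @param G_rbc Elastic modulus of red-blood-cell regions, Pa (default 4e3).
#' @param G_ablated Elastic modulus assigned to liquefied (ablated) pixels,
#'   Pa (default 0: ablated thrombus behaves as fluid).
#' @param frequency Source frequency, MHz, used for the default tension
#'   duration (default 1.5).
#' @param tau Effective tension duration in seconds; defaults to the
#'   rarefactional half period `1/(2 f)`.
#' @param averaging_radius Radius (um) of the neighbourhood over which the
#'   local elastic modulus is averaged (default 500).
#' @return An object of class `material_parameters`.
#' @export
material_parameters <- function(P0 = 0.1, rho = 1000, R0 = 2.5,
                                G_fibrin = 14e6, G_rbc = 4e3, G_ablated = 0,
                                frequency = 1.5,
                                tau = 1 / (2 * frequency * 1e6),
                                averaging_radius = 500) {
  if (any(c(G_fibrin, G_rbc, G_ablated) < 0)) stop("elastic moduli must be >= 0")
  if (tau <= 0 || R0 <= 0 || P0 <= 0 || rho <= 0 || averaging_radius <= 0)
    stop("'P0', 'rho', 'R0', 'tau' and 'averaging_radius' must be positive")
  structure(list(P0 = P0, rho = rho, R0 = R0, G_fibrin = G_fibrin,
                 G_rbc = G_rbc, G_ablated = G_ablated, frequency = frequency,
                 tau = tau, averaging_radius = averaging_radius),
            class = "material_parameters")
}

#' Effective confining pressure ("Blake brake")
#'
#' The elastic modulus of the medium augments the ambient pressure that
#' arrests bubble growth: `p_EFF = P0 (1 + 4 G / (3 P0))`.
#'
#' @param G Elastic modulus in Pa (vectorised).
#' @param m [material_parameters()].
#' @return Effective pressure in MPa.
#' @export
effective_pressure <- function(G, m = material_parameters()) {
  if (any(G < 0)) stop("'G' must be >= 0")
  P0 <- m$P0 * 1e6
  (P0 * (1 + 4 * G / (3 * P0))) / 1e6
}

#' Dimensionless driving tension
#'
#' Net dimensionless tension available for bubble growth,
#' `xi = xi_HA - 6 G / P0`, where `xi_HA = (p_neg - P0) / P0` is the
#' dimensionless rarefactional tension of the acoustic pulse.  Negative values
#' mean the elastic brake has arrested growth before it starts.
#'
#' @param p_neg Peak negative pressure, MPa (vectorised).
#' @param G Elastic modulus, Pa.
#' @param m [material_parameters()].
#' @param xi_HA Optional function `(p_neg_MPa, m) -> dimensionless` replacing
#'   the default driving-tension definition.
#' @return Dimensionless tension (may be negative).
#' @export
bubble_xi <- function(p_neg, G, m = material_parameters(), xi_HA = NULL) {
  if (any(p_neg < 0)) stop("'p_neg' must be >= 0")
  drive <- if (is.null(xi_HA)) (p_neg - m$P0) / m$P0 else xi_HA(p_neg, m)
  drive - 6 * G / (m$P0 * 1e6)
}

#' Analytic maximum bubble radius in a Kelvin-Voigt medium
#'
#' Maximum radius reached by an intrinsic-threshold histotripsy bubble:
#' `R_MAX = R0 + sqrt(2 P0 xi / (9 rho)) * tau * (xi P0 / (3 p_EFF) + 1)^(1/3)`
#' for positive net tension `xi`, and `R_MAX = R0` (no growth) otherwise.
#' The square-root factor is the far-field growth velocity under tension, and
#' the cube-root factor accounts for inertial expansion after the pulse has
#' passed, against the effective confining pressure.
#'
#' @inheritParams bubble_xi
#' @return Maximum radius in micrometres (vectorised over `p_neg` / `G`).
#' @examples
#' max_bubble_radius(30, 4e3)   # ~124 um in RBC-rich thrombus
#' max_bubble_radius(30, 14e6)  # nucleus size: fibrin arrests growth
#' @export
max_bubble_radius <- function(p_neg, G, m = material_parameters(), xi_HA = NULL) {
  xi <- bubble_xi(p_neg, G, m, xi_HA)
  P0 <- m$P0 * 1e6
  R0_m <- m$R0 * 1e-9
  peff <- effective_pressure(G, m) * 1e6
  grown <- R0_m + sqrt(2 * P0 * pmax(xi, 0) / (9 * m$rho)) * m$tau *
    (pmax(xi, 0) * P0 / (3 * peff) + 1)^(1 / 3)
  ifelse(xi > 0, grown, R0_m) * 1e6
}

#' Locally averaged elastic modulus
#'
#' Arithmetic mean of per-pixel elastic moduli over a disk of radius
#' `m$averaging_radius` centred on a pixel: fibrin pixels contribute
#' `G_fibrin`, red-blood-cell pixels `G_rbc`, ablated (liquefied) pixels
#' `G_ablated`, and background pixels are excluded from the average.
#'
#' @param section A [histology_section()].
#' @param location Pixel index `c(row, col)`.
#' @param m [material_parameters()].
#' @param ablated_mask Optional logical matrix marking liquefied pixels
#'   (alternatively the section labels may already carry ablated codes).
#' @return Mean elastic modulus in Pa.
#' @export
local_shear_modulus <- function(section, location, m = material_parameters(),
                                ablated_mask = NULL) {
  lab <- section$labels
  if (!is.null(ablated_mask)) lab[ablated_mask & lab == LBL_RBC] <- LBL_ABLATED
  nr <- nrow(lab); nc <- ncol(lab)
  i0 <- location[1]; j0 <- location[2]
  if (i0 < 1 || i0 > nr || j0 < 1 || j0 > nc) stop("'location' outside the grid")
  rpx <- m$averaging_radius / section$pixel_size
  di <- max(i0 - floor(rpx), 1):min(i0 + floor(rpx), nr)
  dj <- max(j0 - floor(rpx), 1):min(j0 + floor(rpx), nc)
  sub <- lab[di, dj, drop = FALSE]
  dist2 <- outer((di - i0)^2, (dj - j0)^2, `+`)
  sel <- dist2 <= rpx^2 & sub != LBL_BACKGROUND
  if (!any(sel)) stop("no thrombus pixels within the averaging radius")
  gv <- c(NA, m$G_rbc, m$G_fibrin, m$G_ablated)[sub[sel] + 1L]
  mean(gv)
}
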