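#' Transport parameters for catheter-directed rt-PA infusion
#'
#' Physical parameters of the perfusion--diffusion calculation.  Intact
#' thrombus is a porous medium with longitudinal/transverse dispersion
#' coefficients `a_I`/`a_II`; ablated (liquefied) regions are fluid with
#' diffusion coefficient `D_ablate`.  Advection is a flux-conserving radial
#' outflow `v(r) = U r_min / r` matching the printed fluid speed `U` at the
#' catheter surface, and rt-PA is quenched at first-order rate `k2 * C_p` by
#' PAI-1.
#'
#' `C_p` has no published value; the default 0.7 uM (the order of
#' platelet-released PAI-1 inside thrombus) is calibrated so the steady
#' penetration depth of rt-PA in intact thrombus is about 2 mm, and is
#' exposed here for sensitivity analysis.
#'
#' @param Q Infusion volumetric rate, mL/s (default [infusion_rate()] of
#'   12.5 mL/h).
#' @param n Thrombus porosity (default 0.15).
#' @param U Fluid speed at the catheter surface, cm/s (default 0.87).
#' @param D_clot Diffusion coefficient of intact thrombus, cm^2/s
#'   (default 2.5e-6).
#' @param D_ablate Diffusion coefficient of ablated thrombus, cm^2/s
#'   (default 25e-6, a ten-fold increase).
#' @param d Particulate diameter, cm (default 1e-4, the weighted average of
#'   fibrin bundle and red-cell diameters).
#' @param a_I,a_II Longitudinal and transverse dispersion coefficients,
#'   cm^2/s (defaults 9.4e-6 and 3.4e-6).
#' @param k2 rt-PA/PAI-1 interaction rate, 1/(uM s) (default 29).
#' @param C_p PAI-1 concentration, uM (default 0.7; see Details).
#' @param C_source rt-PA concentration at the catheter surface, nM
#'   (default 700).
#' @param catheter_radius Catheter radius, mm (default 0.84).
#' @return An object of class `transport_parameters`; the effective
#'   catheter-to-edge distance `B = Q / (2 pi n U r_min)` (cm) is derived for
#'   internal consistency with the printed `U`.
#' @export
transport_parameters <- function(Q = infusion_rate(12.5), n = 0.15, U = 0.87,
                                 D_clot = 2.5e-6, D_ablate = 25e-6, d = 1e-4,
                                 a_I = 9.4e-6, a_II = 3.4e-6, k2 = 29,
                                 C_p = 0.7, C_source = 700,
                                 catheter_radius = 0.84) {
  if (any(c(Q, n, U, D_clot, D_ablate, d, a_I, a_II, k2, C_p, C_source) < 0))
    stop("transport rates, coefficients and concentrations must be >= 0")
  if (D_ablate <= D_clot) stop("'D_ablate' must exceed 'D_clot'")
  if (catheter_radius <= 0) stop("'catheter_radius' must be positive")
  r_min <- catheter_radius / 10  # cm
  structure(list(Q = Q, n = n, U = U, D_clot = D_clot, D_ablate = D_ablate,
                 d = d, a_I = a_I, a_II = a_II, k2 = k2, C_p = C_p,
                 C_source = C_source, catheter_radius = catheter_radius,
                 B = if (n * U * r_min > 0) Q / (2 * pi * n * U * r_min) else NA_real_),
            class = "transport_parameters")
}

#' Convert an infusion rate from mL/h to mL/s
#'
#' @param mL_per_h Infusion rate in mL/h (the typical catheter-directed rt-PA
#'   protocol infuses 12.5 mL/h).
#' @return Rate in mL/s (12.5 mL/h is about 0.0035 mL/s).
#' @export
infusion_rate <- function(mL_per_h = 12.5) mL_per_h / 3600

#' Peclet number of intra-thrombus transport
#'
#' Ratio of advective to diffusive transport, `Pe = U d / (n D_clot)`; about
#' 232 for the default parameter set.
#'
#' @param params [transport_parameters()].
#' @return Dimensionless Peclet number.
#' @export
peclet <- function(params = transport_parameters()) {
  if (params$D_clot <= 0) stop("'D_clot' must be positive")
  params$U * params$d / (params$n * params$D_clot)
}

#' Longitudinal and transverse dispersion coefficients
#'
#' In `"printed"` mode (the default used everywhere in the pipeline) returns
#' the tabulated coefficients `a_I`/`a_II`.  In `"correlation"` mode evaluates
#' the standard porous-media power law relative to molecular diffusion,
#' `a_I = 0.5 D_clot Pe^1.2`, `a_II = 0.025 D_clot Pe^1.1`; this mode exists
#' for sensitivity analysis of the particulate diameter `d` and is not used
#' for headline results because no argument convention reproduces the
#' tabulated values exactly.
#'
#' @param params [transport_parameters()].
#' @param mode `"printed"` or `"correlation"`.
#' @return Named numeric `c(a_I =, a_II =)` in cm^2/s.
#' @export
dispersion_coefficients <- function(params = transport_parameters(),
                                    mode = c("printed", "correlation")) {
  mode <- match.arg(mode)
  if (mode == "printed") return(c(a_I = params$a_I, a_II = params$a_II))
  Pe <- peclet(params)
  c(a_I = 0.5 * params$D_clot * Pe^1.2,
    a_II = 0.025 * params$D_clot * Pe^1.1)
}

#' Annular polar grid around the infusion catheter
#'
#' @param r_min Inner radius (catheter surface), cm (default 0.084).
#' @param r_max Outer radius, cm (default 0.8; when a section is supplied to
#'   [build_coefficients()] the outer edge is taken from the thrombus).
#' @param dr Radial step, cm (default 0.002 = 0.02 mm, the desk-scale grid;
#'   set 1e-4 for the fine-grid configuration).
#' @param dtheta Azimuthal step, radian (default `pi/25`).
#' @param dt Optional fixed time step, s; by default derived from
#'   [stability_timestep()].
#' @return An object of class `polar_grid` with node radii `r` (interior
#'   nodes; Dirichlet boundaries sit at `r_min` and `r_max`) and angles
#'   `theta`.
#' @export
polar_grid <- function(r_min = 0.084, r_max = 0.8, dr = 0.002,
                       dtheta = pi / 25, dt = NULL) {
  if (r_min <= 0 || r_max <= r_min) stop("need 0 < r_min < r_max")
  if (dr <= 0 || dtheta <= 0) stop("'dr' and 'dtheta' must be positive")
  nr <- as.integer(round((r_max - r_min) / dr)) - 1L
  if (nr < 3L) stop("grid has too few radial nodes; decrease 'dr'")
  ntheta <- as.integer(round(2 * pi / dtheta))
  structure(list(r_min = r_min, r_max = r_min + (nr + 1) * dr, dr = dr,
                 dtheta = 2 * pi / ntheta, dt = dt,
                 r = r_min + seq_len(nr) * dr,
                 theta = (seq_len(ntheta) - 1) * (2 * pi / ntheta)),
            class = "polar_grid")
}

## Map polar nodes to section pixels (nearest neighbour) and classify each
## node as "intact", "ablated" or "outside".  The grid is centred on the
## thrombus centroid (where the catheter sits).
polar_node_regions <- function(section, ablated_mask, grid) {
  lab <- section$labels
  if (!is.null(ablated_mask)) {
    if (!identical(dim(ablated_mask), dim(lab)))
      stop("'ablated_mask' is not co-registered with the section")
    if (is.matrix(ablated_mask) && !is.logical(ablated_mask))
      ablated_mask <- ablated_mask == LBL_ABLATED
    lab[ablated_mask & lab == LBL_RBC] <- LBL_ABLATED
  }
  ctr <- section_centroid(section) / 10  # cm
  ps_cm <- section$pixel_size / 1e4
  nr <- length(grid$r); nth <- length(grid$theta)
  x <- outer(grid$r, cos(grid$theta)) + (ctr[1] - section$origin[1] / 10)
  y <- outer(grid$r, sin(grid$theta)) + (ctr[2] - section$origin[2] / 10)
  col <- pmin(pmax(ceiling(x / ps_cm), 1L), ncol(lab))
  row <- pmin(pmax(ceiling(y / ps_cm), 1L), nrow(lab))
  outside <- x < 0 | y < 0 | x > ncol(lab) * ps_cm | y > nrow(lab) * ps_cm
  code <- matrix(lab[cbind(as.vector(row), as.vector(col))], nr, nth)
  code[outside] <- LBL_BACKGROUND
  region <- matrix("intact", nr, nth)
  region[code == LBL_ABLATED] <- "ablated"
  region[code == LBL_BACKGROUND] <- "outside"
  region
}

#' Region labels of polar nodes from a Cartesian mask
#'
#' Nearest-neighbour lookup of the section/ablation mask at each polar node's
#' physical position, with the grid centred on the thrombus centroid.
#'
#' @param mask Label matrix (ablated pixels coded 3) or logical ablation mask,
#'   or `NULL` for no ablation.
#' @param section A [histology_section()].
#' @param grid A [polar_grid()].
#' @return Character matrix (`length(grid$r)` x `length(grid$theta)`) with
#'   entries `"intact"`, `"ablated"` or `"outside"`.
#' @export
cartesian_to_polar <- function(mask, section, grid) {
  polar_node_regions(section, mask, grid)
}

#' Per-node transport coefficients
#'
#' Builds the spatially varying coefficient fields of the perfusion--diffusion
#' equation: intact (porous) nodes carry radial/azimuthal dispersion
#' `a_I`/`a_II`, ablated (fluid) nodes carry `D_ablate` in both directions;
#' the advective velocity `v(r) = U r_min / r` is continuous across the
#' interface, and the PAI-1 quench rate `k2 C_p` applies everywhere inside
#' the thrombus.
#'
#' @param section Optional [histology_section()]; `NULL` gives a homogeneous
#'   annulus (all nodes intact, or all ablated with `all_ablated = TRUE`).
#' @param ablated_mask Optional label/logical matrix of liquefied pixels.
#' @param grid A [polar_grid()].
#' @param params [transport_parameters()].
#' @param all_ablated With `section = NULL`, treat the whole annulus as
#'   liquefied fluid.
#' @return A list of class `coefficient_fields` with matrices `D_r`,
#'   `D_theta`, `v`, `quench`, logical `active`, character `region`.
#' @export
build_coefficients <- function(section = NULL, ablated_mask = NULL, grid,
                               params = transport_parameters(),
                               all_ablated = FALSE) {
  nr <- length(grid$r); nth <- length(grid$theta)
  region <- if (is.null(section)) {
    matrix(if (all_ablated) "ablated" else "intact", nr, nth)
  } else {
    polar_node_regions(section, ablated_mask, grid)
  }
  disp <- dispersion_coefficients(params, "printed")
  D_r <- matrix(disp[["a_I"]], nr, nth)
  D_th <- matrix(disp[["a_II"]], nr, nth)
  abl <- region == "ablated"
  D_r[abl] <- params$D_ablate
  D_th[abl] <- params$D_ablate
  v <- matrix(params$U * grid$r_min / grid$r, nr, nth)
  quench <- matrix(params$k2 * params$C_p, nr, nth)
  active <- region != "outside"
  D_r[!active] <- 0; D_th[!active] <- 0; v[!active] <- 0; quench[!active] <- 0
  structure(list(D_r = D_r, D_theta = D_th, v = v, quench = quench,
                 active = active, region = region),
            class = "coefficient_fields")
}

#' Largest stable explicit time step
#'
#' Courant--Friedrichs--Lewy-type bound for the explicit scheme: the forward
#' Euler update is stable (and sign-preserving) when
#' `dt * (2 D_r / dr^2 + 2 D_theta / (r dtheta)^2 + v / dr + k) <= 1` at
#' every node, so the step is the safety factor over the maximum combined
#' rate.  This is never larger than the individual diffusive bound
#' `dr^2 / (2 (D_r + D_theta (dr / (r dtheta))^2))` or the advective bound
#' `dr / max(v)`.  [solve_transport()] refuses a larger step.
#'
#' @param grid A [polar_grid()].
#' @param coeffs A [build_coefficients()] result.
#' @param safety Fraction of the bound actually used (default 0.8).
#' @return Time step in seconds.
#' @export
stability_timestep <- function(grid, coeffs, safety = 0.8) {
  r <- grid$r
  rate <- 2 * (coeffs$D_r / grid$dr^2 +
                 sweep(coeffs$D_theta, 1, (r * grid$dtheta)^2, `/`)) +
    coeffs$v / grid$dr + coeffs$quench
  safety / max(rate)
}

#' Solve the perfusion--diffusion equation for infused rt-PA
#'
#' Explicit time-marching finite-difference solution of
#' `dC/dt = D_r d2C/dr2 + (D_theta / r^2) d2C/dtheta2 - v(r) dC/dr - k2 C_p C`
#' on the annular polar grid around the catheter: forward Euler in time,
#' central differences for diffusion, first-order upwind for the (outward)
#' advection.  Boundary conditions: `C = C_source` on the catheter surface,
#' `C = 0` at the thrombus outer edge (flowing blood clears drug), periodic
#' in theta.  The scheme preserves `0 <= C <= C_source` under the
#' [stability_timestep()] bound.
#'
#' @param params [transport_parameters()].
#' @param grid A [polar_grid()].
#' @param section,ablated_mask Optional section and ablation mask defining
#'   per-node regions (see [build_coefficients()]).
#' @param coeffs Optional precomputed [build_coefficients()]; overrides
#'   `section`/`ablated_mask`.
#' @param duration Maximum simulated time, s (default 1200 = 20 min).
#' @param steady_tol Steady-state criterion: stop once the maximum
#'   concentration change per second drops below `steady_tol * C_source`
#'   (default 1e-3; `NULL` disables early stopping).
#' @param quench_on Include the PAI-1 quench term (default TRUE).
#' @param dt Time step, s; defaults to [stability_timestep()].  A value above
#'   the stability bound is an error.
#' @param track_mass Accumulate the discrete boundary fluxes and quench loss
#'   so mass conservation can be audited (homogeneous grids only).
#' @return An object of class `concentration_field`: matrix `C` (nM, nodes
#'   `r` x `theta`), elapsed time `t`, `steady_time` (NA if the criterion was
#'   never met), the grid, parameters, and (if tracked) a `mass` list with
#'   `inflow`, `outflow`, `quench_loss`, `mass` and `residual` (all in
#'   nM cm^3 per unit porosity-weighted volume).
#' @export
solve_transport <- function(params = transport_parameters(),
                            grid = polar_grid(),
                            section = NULL, ablated_mask = NULL, coeffs = NULL,
                            duration = 1200, steady_tol = 1e-3,
                            quench_on = TRUE, dt = NULL, track_mass = FALSE) {
  if (is.null(coeffs))
    coeffs <- build_coefficients(section, ablated_mask, grid, params)
  if (!quench_on) coeffs$quench[] <- 0
  dt_max <- stability_timestep(grid, coeffs, safety = 1)
  if (is.null(dt)) dt <- grid$dt %||% stability_timestep(grid, coeffs)
  if (dt > dt_max)
    stop(sprintf("dt = %.3g s violates the stability bound %.3g s", dt, dt_max))

  nr <- length(grid$r); nth <- length(grid$theta)
  r <- grid$r; dr <- grid$dr; dth <- grid$dtheta
  Cs <- params$C_source
  C <- matrix(0, nr, nth)
  active <- coeffs$active
  ## source ring is only live where the adjacent node is inside the thrombus
  src <- rep(Cs, nth) * as.numeric(active[1, ])
  iL <- c(nth, seq_len(nth - 1)); iR <- c(seq_len(nth)[-1], 1)
  Dr_dr2 <- coeffs$D_r / dr^2
  Dth_r2dth2 <- sweep(coeffs$D_theta, 1, (r * dth)^2, `/`)
  v_dr <- coeffs$v / dr
  q <- coeffs$quench

  n_steps <- ceiling(duration / dt)
  steady_time <- NA_real_
  inflow <- outflow <- quench_loss <- 0
  gam <- params$U * grid$r_min
  t <- 0
  for (s in seq_len(n_steps)) {
    Cup <- rbind(src, C[-nr, , drop = FALSE])       # node i-1
    Cdn <- rbind(C[-1, , drop = FALSE], rep(0, nth))  # node i+1
    lap_r <- Dr_dr2 * (Cdn - 2 * C + Cup)
    lap_th <- Dth_r2dth2 * (C[, iL, drop = FALSE] + C[, iR, drop = FALSE] - 2 * C)
    adv <- v_dr * (C - Cup)
    if (track_mass) {
      quench_loss <- quench_loss + dt * sum(q * C * r) * dr * dth
      inflow <- inflow + dt * dth *
        (gam * sum(src) +
           coeffs$D_r[1, 1] / dr * sum(r[1] * src - grid$r_min * C[1, ]))
      outflow <- outflow + dt * dth *
        (gam * sum(C[nr, ]) +
           coeffs$D_r[nr, 1] / dr * (r[nr] + dr) * sum(C[nr, ]))
    }
    Cnew <- C + dt * (lap_r + lap_th - adv - q * C)
    Cnew[!active] <- 0
    t <- t + dt
    if (!is.null(steady_tol) && max(abs(Cnew - C)) / (Cs * dt) < steady_tol) {
      C <- Cnew
      steady_time <- t
      break
    }
    C <- Cnew
  }
  mass <- NULL
  if (track_mass) {
    M <- sum(C * r) * dr * dth
    mass <- list(inflow = inflow, outflow = outflow,
                 quench_loss = quench_loss, mass = M,
                 residual = inflow - outflow - quench_loss - M)
  }
  structure(list(C = C, r = r, theta = grid$theta, t = t,
                 steady_time = steady_time, grid = grid, params = params,
                 region = coeffs$region, mass = mass),
            class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf("<concentration_field> %d x %d nodes, t = %.3g s%s\n",
              length(x$r), length(x$theta), x$t,
              if (is.na(x$steady_time)) "" else
                sprintf(" (steady at %.3g s)", x$steady_time)))
  cat(sprintf("  C in [%.3g, %.3g] nM; penetration %.2f mm\n",
              min(x$C), max(x$C), penetration_depth(x)))
  invisible(x)
}

#' Radial penetration depth of infused drug
#'
#' Largest radial distance beyond the catheter surface at which the
#' angle-maximum concentration still exceeds a fraction of the source
#' concentration.
#'
#' @param field A [solve_transport()] result (normally at steady state).
#' @param fraction Threshold fraction of `C_source` (default 0.01).
#' @return Depth in mm (0 if the whole field is below threshold).
#' @export
penetration_depth <- function(field, fraction = 0.01) {
  stopifnot(inherits(field, "concentration_field"))
  m <- apply(field$C, 1, max)
  idx <- which(m > fraction * field$params$C_source)
  if (!length(idx)) return(0)
  (field$r[max(idx)] - field$grid$r_min) * 10
}
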