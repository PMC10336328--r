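test_that("Peclet number follows U d / (n D) and is ~232 at defaults", {
  expect_equal(peclet(), 232, tolerance = 0.002)
  expect_equal(peclet(transport_parameters(U = 0)), 0)
  p1 <- transport_parameters(d = 1e-4)
  p2 <- transport_parameters(d = 2e-4)
  expect_equal(peclet(p2), 2 * peclet(p1))
  expect_error(peclet(structure(list(U = 1, d = 1, n = 1, D_clot = 0),
                                class = "transport_parameters")), "positive")
})

test_that("the typical infusion protocol converts to ~0.0035 mL/s", {
  expect_equal(infusion_rate(12.5), 12.5 / 3600)
  expect_equal(infusion_rate(12.5), 0.0035, tolerance = 0.01)
})

test_that("dispersion is anisotropic with longitudinal exceeding transverse", {
  printed <- dispersion_coefficients(mode = "printed")
  expect_equal(unname(printed), c(9.4e-6, 3.4e-6))
  corr <- dispersion_coefficients(mode = "correlation")
  expect_gt(printed[["a_I"]], printed[["a_II"]])
  expect_gt(corr[["a_I"]], corr[["a_II"]])
  expect_error(dispersion_coefficients(mode = "guess"))
})

test_that("steady field is insensitive to particulate diameter in correlation mode", {
  g <- polar_grid(r_min = 0.084, r_max = 0.5, dr = 0.002)
  fields <- lapply(c(1e-5, 1e-4), function(d) {
    p <- transport_parameters(d = d)
    ab <- dispersion_coefficients(p, "correlation")
    p2 <- transport_parameters(d = d, a_I = ab[["a_I"]], a_II = ab[["a_II"]])
    solve_transport(p2, g, steady_tol = 1e-4)
  })
  rel <- max(abs(fields[[1]]$C - fields[[2]]$C)) / 700
  expect_lt(rel, 0.05)
})

test_that("coefficient fields distinguish intact and ablated regions", {
  g <- polar_grid(r_min = 0.084, r_max = 0.4, dr = 0.002)
  p <- transport_parameters()
  intact <- build_coefficients(grid = g, params = p)
  expect_true(all(intact$D_r == p$a_I))
  expect_true(all(intact$D_theta == p$a_II))
  expect_true(all(intact$region == "intact"))
  fluid <- build_coefficients(grid = g, params = p, all_ablated = TRUE)
  expect_true(all(fluid$D_r == 25e-6))
  ## advective velocity is U at the catheter surface and decays as 1/r
  expect_equal(intact$v[1, 1], p$U * g$r_min / g$r[1])
  expect_equal(p$U * g$r_min / g$r_min, 0.87)
  expect_equal(intact$quench[5, 5], 29 * 0.7)
})

test_that("stability bound reproduces the fine-grid time step and its scalings", {
  p <- transport_parameters()
  ## fine grid, dr = 0.001 mm: the advective bound dr/v is ~1.1e-4 s, the
  ## same order as the 0.1-ms step of the reference configuration, and the
  ## returned step never exceeds it
  g <- polar_grid(r_min = 0.084, r_max = 0.09, dr = 1e-4)
  co <- build_coefficients(grid = g, params = p)
  co$quench[] <- 0
  adv_bound <- g$dr / max(co$v)
  expect_equal(adv_bound, 1e-4 / 0.87 * (g$r[1] / g$r_min), tolerance = 1e-6)
  dt <- stability_timestep(g, co, safety = 1)
  expect_lte(dt, adv_bound)
  diff_bound <- g$dr^2 /
    (2 * max(co$D_r + co$D_theta[1, 1] * (g$dr / (g$r[1] * g$dtheta))^2))
  expect_lte(dt, diff_bound)
  ## halving dr halves the advective bound
  g2 <- polar_grid(r_min = 0.084, r_max = 0.09, dr = 5e-5)
  co2 <- build_coefficients(grid = g2, params = p)
  expect_equal((g2$dr / max(co2$v)) / adv_bound, 0.5, tolerance = 0.01)
  expect_lt(stability_timestep(g2, co2), dt)
  ## pure diffusion: the step is exactly the combined diffusive rate bound
  pd <- transport_parameters(U = 0, a_I = 1e-5, a_II = 1e-5)
  cod <- build_coefficients(grid = g, params = pd)
  cod$quench[] <- 0
  dtd <- stability_timestep(g, cod, safety = 1)
  expect_equal(dtd, 1 / (2 * (1e-5 / (1e-4)^2 + 1e-5 / (g$r[1] * g$dtheta)^2)),
               tolerance = 1e-10)
})

test_that("solver refuses an unstable time step", {
  g <- polar_grid(r_min = 0.084, r_max = 0.3, dr = 0.002)
  expect_error(solve_transport(grid = g, dt = 1), "stability")
})

test_that("zero source concentration gives an identically zero field", {
  p <- transport_parameters(C_source = 0)
  g <- polar_grid(r_min = 0.084, r_max = 0.2, dr = 0.002)
  fld <- solve_transport(p, g, duration = 0.5, steady_tol = NULL)
  expect_true(all(fld$C == 0))
})

test_that("FDTD steady state matches the closed-form annulus solution", {
  ## advection-dispersion without quench at moderate Peclet so the grid
  ## resolves the radial boundary layer; closed form for v = gamma / r:
  ## C = Cs (1 - (r^(a+1) - rmin^(a+1)) / (rmax^(a+1) - rmin^(a+1))),
  ## a = gamma / D
  p <- transport_parameters(U = 5e-3, a_I = 1e-4, a_II = 1e-4, C_p = 0)
  g <- polar_grid(r_min = 0.084, r_max = 0.4, dr = 0.001)
  fld <- solve_transport(p, g, duration = 1000, steady_tol = 1e-6,
                         quench_on = FALSE)
  alpha <- p$U * g$r_min / 1e-4
  r <- fld$r; rmin <- g$r_min; rmax <- g$r_max
  num <- exp((alpha + 1) * log(r / rmax)) - exp((alpha + 1) * log(rmin / rmax))
  den <- 1 - exp((alpha + 1) * log(rmin / rmax))
  C_exact <- p$C_source * (1 - num / den)
  expect_lt(max(abs(fld$C[, 1] - C_exact)) / p$C_source, 0.02)
})

test_that("mass is conserved to within 1% without quench", {
  g <- polar_grid(r_min = 0.084, r_max = 0.3, dr = 0.002)
  fld <- solve_transport(grid = g, duration = 2, steady_tol = NULL,
                         quench_on = FALSE, track_mass = TRUE)
  expect_lt(abs(fld$mass$residual) / fld$mass$inflow, 0.01)
  ## and with quench on, the quench sink closes the budget
  fld2 <- solve_transport(grid = g, duration = 2, steady_tol = NULL,
                          track_mass = TRUE)
  expect_lt(abs(fld2$mass$residual) / fld2$mass$inflow, 0.01)
  expect_gt(fld2$mass$quench_loss, 0)
})

test_that("concentrations stay within [0, C_source] and decay radially", {
  g <- polar_grid(r_min = 0.084, r_max = 0.8, dr = 0.002)
  fld <- solve_transport(grid = g, duration = 30)
  expect_gte(min(fld$C), 0)
  expect_lte(max(fld$C), 700 * (1 + 1e-12))
  profile <- apply(fld$C, 1, max)
  expect_true(all(diff(profile) <= 1e-9))
})

test_that("quenched infusion reaches steady state within ~10 s", {
  g <- polar_grid(r_min = 0.084, r_max = 0.8, dr = 0.002)
  fld <- solve_transport(grid = g, duration = 60, steady_tol = 1e-3)
  expect_false(is.na(fld$steady_time))
  expect_lte(fld$steady_time, 10)
})

test_that("penetration depth reports the 1% contour distance", {
  g <- polar_grid(r_min = 0.084, r_max = 0.3, dr = 0.002)
  p <- transport_parameters()
  fake <- structure(list(C = matrix(700, length(g$r), length(g$theta)),
                         r = g$r, grid = g, params = p),
                    class = "concentration_field")
  expect_equal(penetration_depth(fake), (g$r[length(g$r)] - g$r_min) * 10)
  fake$C[] <- 0
  expect_equal(penetration_depth(fake), 0)
})

test_that("rt-PA penetrates no more than ~2 mm into intact thrombus", {
  g <- polar_grid(r_min = 0.084, r_max = 0.8, dr = 0.002)
  fld <- solve_transport(grid = g, duration = 60)
  expect_lte(penetration_depth(fld, 0.01), 2)
  expect_gt(penetration_depth(fld, 0.01), 0.5)
})

test_that("halving the radial step changes penetration by less than 5%", {
  f1 <- solve_transport(grid = polar_grid(r_min = 0.084, r_max = 0.8,
                                          dr = 0.002), duration = 60)
  f2 <- solve_transport(grid = polar_grid(r_min = 0.084, r_max = 0.8,
                                          dr = 0.001), duration = 60)
  d1 <- penetration_depth(f1); d2 <- penetration_depth(f2)
  expect_lt(abs(d1 - d2) / d2, 0.05)
})

test_that("polar node regions follow the Cartesian mask geometry", {
  s <- ellipse_section(extent_mm = 8, pixel_size = 40)
  g <- polar_grid(r_min = 0.084, r_max = 0.3, dr = 0.002)
  reg <- cartesian_to_polar(NULL, s, g)
  expect_true(all(reg == "intact"))

  ## half-plane ablated: nodes split by angle at the horizontal boundary
  codes <- label_codes()
  mask <- matrix(FALSE, nrow(s$labels), ncol(s$labels))
  mask[seq_len(nrow(mask) / 2), ] <- TRUE  # y below centre
  reg2 <- cartesian_to_polar(mask, s, g)
  th <- g$theta
  upper <- th > g$dtheta & th < pi - g$dtheta        # y > 0 quadrant-pair
  lower <- th > pi + g$dtheta & th < 2 * pi - g$dtheta
  expect_true(all(reg2[, lower] == "ablated"))
  expect_true(all(reg2[, upper] == "intact"))

  ## ablated disk of known radius: weighted node area matches annulus area
  ctr <- section_centroid(s)
  ps <- s$pixel_size / 1000
  x <- (seq_len(ncol(s$labels)) - 0.5) * ps
  y <- (seq_len(nrow(s$labels)) - 0.5) * ps
  disk <- outer((y - ctr[2])^2, (x - ctr[1])^2, `+`) <= 1.5^2  # 1.5 mm disk
  g3 <- polar_grid(r_min = 0.084, r_max = 0.3, dr = 0.001)
  reg3 <- cartesian_to_polar(disk, s, g3)
  w <- matrix(g3$r, length(g3$r), length(g3$theta)) * g3$dr * g3$dtheta
  area_nodes <- sum(w[reg3 == "ablated"])       # cm^2
  area_true <- pi * (0.15^2 - g3$r_min^2)       # annulus catheter -> 1.5 mm
  expect_equal(area_nodes, area_true, tolerance = 0.05)
})
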