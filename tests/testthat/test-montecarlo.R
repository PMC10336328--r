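test_that("nucleation probability is the intrinsic-threshold sigmoid", {
  expect_equal(nucleation_probability(26.8), 0.5)
  expect_lt(nucleation_probability(0), 1e-10)
  expect_equal(nucleation_probability(30.4), 0.99865, tolerance = 1e-4)
  p <- nucleation_probability(seq(20, 40, by = 0.5))
  expect_true(all(diff(p) >= 0))
  expect_true(all(diff(p[p > 1e-6 & p < 1 - 1e-6]) > 0))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(nucleation_probability(-1), ">= 0")
})

test_that("a zero-pressure pulse leaves the state unchanged", {
  s <- ellipse_section(extent_mm = 5, pixel_size = 50)
  f <- uniform_field(0, s)
  set.seed(1)
  expect_identical(apply_pulse(s$labels, f, s), s$labels)
})

test_that("all-fibrin sections are never ablated", {
  s <- ellipse_section(extent_mm = 5, pixel_size = 50,
                       label = label_codes()[["FIBRIN"]])
  tr <- run_treatment(s, uniform_field(40, s), n_pulses = 5, n_repeats = 2,
                      seed = 4)
  expect_true(all(tr$area_curve == 0))
  expect_true(all(tr$hemoglobin_histotripsy == 0))
})

test_that("compiled pulse kernel replays the R reference draw-for-draw", {
  codes <- label_codes()
  ## heterogeneous 40x40 grid: RBC with fibrin block and background margin
  lab <- matrix(codes[["RBC"]], 40, 40)
  lab[1:6, ] <- codes[["BACKGROUND"]]
  lab[20:28, 8:30] <- codes[["FIBRIN"]]
  s <- histology_section(lab, pixel_size = 50)
  for (p in c(25, 27, 30)) {
    f <- uniform_field(p, s)
    set.seed(1234 + p)
    got <- apply_pulse(s$labels, f, s)
    set.seed(1234 + p)
    want <- ref_pulse(s$labels, f$p_neg, s$pixel_size)
    expect_identical(got, want)
  }
  ## and on a state that already contains ablated pixels
  set.seed(77)
  state <- apply_pulse(s$labels, uniform_field(30, s), s)
  set.seed(88)
  got <- apply_pulse(state, uniform_field(27, s), s)
  set.seed(88)
  want <- ref_pulse(state, uniform_field(27, s)$p_neg, s$pixel_size)
  expect_identical(got, want)
})

test_that("expected single-pulse ablation matches exact enumeration", {
  ## small all-RBC grid under a uniform field: the ablation probability of a
  ## pixel is 1 - (1 - p)^(number of sites within the bubble radius), which
  ## is computable exactly and independently of the simulation path
  codes <- label_codes()
  s <- histology_section(matrix(codes[["RBC"]], 20, 20), pixel_size = 50)
  p_mpa <- 25
  prob <- nucleation_probability(p_mpa)
  rpx <- max_bubble_radius(p_mpa, 4e3) / s$pixel_size
  idx <- expand.grid(i = 1:20, j = 1:20)
  n_sites <- vapply(seq_len(nrow(idx)), function(k) {
    sum((idx$i - idx$i[k])^2 + (idx$j - idx$j[k])^2 <= rpx^2)
  }, numeric(1))
  expected_px <- sum(1 - (1 - prob)^n_sites)

  f <- uniform_field(p_mpa, s)
  set.seed(2024)
  counts <- replicate(400, sum(apply_pulse(s$labels, f, s) == codes[["ABLATED"]]))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected_px), 4 * se + 1e-9)
})

test_that("treatments are reproducible and ablate only original RBC pixels", {
  s <- generate_section(0.3, extent = 6, pixel_size = 50, seed = 5)
  f <- pressure_field(source_spec(34), s)
  a <- run_treatment(s, f, n_pulses = 30, n_repeats = 3, seed = 11)
  b <- run_treatment(s, f, n_pulses = 30, n_repeats = 3, seed = 11)
  expect_identical(a$masks, b$masks)
  expect_identical(a$area_curve, b$area_curve)
  codes <- label_codes()
  expect_true(all(apply(a$area_curve, 2, function(x) all(diff(x) >= 0))))
  for (mk in a$masks) {
    ablated <- mk == codes[["ABLATED"]]
    expect_true(all(s$labels[ablated] == codes[["RBC"]]))
    ## fibrin and background are untouched
    expect_identical(mk[s$labels == codes[["FIBRIN"]]],
                     s$labels[s$labels == codes[["FIBRIN"]]])
    expect_identical(mk[s$labels == codes[["BACKGROUND"]]],
                     s$labels[s$labels == codes[["BACKGROUND"]]])
  }
})

test_that("zero-pulse treatments produce no ablation", {
  s <- ellipse_section(extent_mm = 5, pixel_size = 50)
  tr <- run_treatment(s, uniform_field(40, s), n_pulses = 0, n_repeats = 2,
                      seed = 1)
  expect_true(all(tr$area_curve == 0))
  expect_equal(normalized_hemoglobin(tr), c(0, 0))
})

test_that("hemoglobin bookkeeping scales with pixel area", {
  expect_equal(hemoglobin_total(0), 0)
  expect_equal(hemoglobin_total(100, 7.4), 3.0)
  expect_equal(hemoglobin_total(1, 14.8), 0.12)
  mask <- matrix(c(3L, 3L, 1L, 0L), 2)
  expect_equal(hemoglobin_total(mask, 7.4), 0.06)
})

test_that("catheter insertion hemolysis counts RBC pixels in the lumen disk", {
  s <- ellipse_section(extent_mm = 8, pixel_size = 20)
  hb <- catheter_hemolysis(s)
  expected_px <- pi * 840^2 / 20^2  # disk area over pixel area
  expect_equal(hb / (0.03 * (20 / 7.4)^2), expected_px, tolerance = 0.01)
  fib <- ellipse_section(extent_mm = 8, pixel_size = 20,
                         label = label_codes()[["FIBRIN"]])
  expect_equal(catheter_hemolysis(fib), 0)
  ## a finely mixed 50/50 section releases about half the all-RBC value
  mixed <- generate_section(0.5, clustering_scale = 0.05, extent = 8,
                            pixel_size = 20, seed = 8)
  expect_equal(catheter_hemolysis(mixed) / hb, 0.5, tolerance = 0.1)
})

test_that("normalized hemoglobin exceeds one for RBC-dominant thrombus at 40 MPa", {
  s <- generate_section(0.15, extent = 10, pixel_size = 29.6, seed = 11)
  tr <- run_treatment(s, pressure_field(source_spec(40), s),
                      n_pulses = 1000, n_repeats = 3, seed = 7)
  expect_true(all(normalized_hemoglobin(tr) > 1))
})
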