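test_that("shell geometry follows the area-to-radius construction", {
  comp <- composition_section(lean_interior_area = 100 * pi, vf_area = 0,
                              sf_area = 0, muscle_thickness = 2)
  sh <- shells_from_composition(comp)
  expect_equal(sh$r_interior, 10)
  expect_equal(sh$r_muscle_out, 12)
  expect_equal(sh$r_outer, 12)  # zero SF collapses the outer annulus
  expect_equal(sh$wc_cm, 2 * pi * 12, tolerance = 1e-10)
  expect_equal(sh$wc_cm, 75.40, tolerance = 1e-3)

  # adding visceral fat pushes every radius outward
  comp2 <- composition_section(100 * pi, 50, 80, 2)
  comp3 <- composition_section(100 * pi, 120, 80, 2)
  s2 <- shells_from_composition(comp2)
  s3 <- shells_from_composition(comp3)
  expect_true(s3$r_interior > s2$r_interior)
  expect_true(s3$r_muscle_out > s2$r_muscle_out)
  expect_true(s3$r_outer > s2$r_outer)
})

test_that("conductivity dispersion is linear with a >10x lean/fat contrast", {
  mp <- muscle_params(); fp <- fat_params()
  expect_equal(tissue_conductivity(mp, 100), 0.40)
  expect_equal(tissue_conductivity(fp, 100), 0.035)
  f <- seq(50, 500, by = 10)
  expect_true(all(tissue_conductivity(mp, f) >
                    10 * tissue_conductivity(fp, f)))
  flat <- tissue_params(0.2, 0)
  expect_equal(tissue_conductivity(flat, 60), 0.2)
  expect_equal(tissue_conductivity(flat, 400), 0.2)
  expect_warning(tissue_conductivity(mp, 30), "validity")
})

test_that("interior conductivity is an area-weighted mixture between endpoints", {
  lean_only <- composition_section(200, 0, 0, 2)
  fat_only <- composition_section(0, 200, 0, 2)
  mixed <- composition_section(120, 80, 0, 2)
  f <- 103
  lo <- interior_conductivity(fat_only, f)
  hi <- interior_conductivity(lean_only, f)
  expect_equal(hi, tissue_conductivity(muscle_params(), f))
  expect_equal(lo, tissue_conductivity(fat_params(), f))
  mid <- interior_conductivity(mixed, f)
  expect_true(mid > lo && mid < hi)
  expect_equal(mid, 0.6 * hi + 0.4 * lo, tolerance = 1e-12)
  empty <- composition_section(0, 0, 10, 1)
  expect_error(interior_conductivity(empty, f), "empty interior")
})

test_that("shell-sum loss equals numerical radial quadrature", {
  # homogeneous cylinder: lean fills everything, muscle/fat shells are
  # zero-width, so one conductivity spans the whole radius
  homog <- shells_from_composition(composition_section(300, 0, 0, 0))
  # layered default anatomy
  layered <- shells_from_composition(reference_composition())
  for (sh in list(homog, layered)) {
    for (f in c(103, 140, 185)) {
      expect_equal(section_loss(sh, f), quadrature_loss(sh, f) * 2 / pi,
                   tolerance = 1e-10)
    }
  }
  # degenerate limit: no excitation, no loss
  expect_equal(suppressWarnings(section_loss(layered, 0)), 0)
})

test_that("splitting a shell at constant conductivity leaves the loss unchanged", {
  # with fat given the muscle's conductivity, muscle+SF act as one annulus;
  # compare against a single thicker muscle shell of equal outer radius
  tiss_same <- default_tissues()
  tiss_same$fat <- muscle_params()
  comp_split <- composition_section(250, 90, 150, 2.2)
  sh_split <- shells_from_composition(comp_split, tiss_same,
                                      check_contrast = FALSE)
  t_total <- sh_split$r_outer - sh_split$r_interior
  comp_one <- composition_section(250, 90, 0, t_total)
  sh_one <- shells_from_composition(comp_one, tiss_same,
                                    check_contrast = FALSE)
  expect_equal(sh_one$r_outer, sh_split$r_outer, tolerance = 1e-12)
  for (f in c(103, 185)) {
    expect_equal(section_loss(sh_one, f), section_loss(sh_split, f),
                 tolerance = 1e-12)
  }
})

test_that("voltage changes scale with gain and grow with frequency", {
  comp <- reference_composition()
  d1 <- drive_config(1)
  d2 <- drive_config(2)
  v1 <- forward_voltage_change(comp, study_freqs(), d1)
  v2 <- forward_voltage_change(comp, study_freqs(), d2)
  expect_equal(v2, 2 * v1)
  expect_true(v1[["dv_high"]] > v1[["dv_low"]])
  expect_equal(noise_free_m_loss(comp, study_freqs(), d2),
               2 * noise_free_m_loss(comp, study_freqs(), d1))
})

test_that("gain calibration anchors the reference anatomy at the target rate", {
  drive <- calibrate_gain(target_m_loss = 0.6)
  expect_equal(noise_free_m_loss(reference_composition(), study_freqs(),
                                 drive), 0.6, tolerance = 1e-12)
  d2 <- calibrate_gain(target_m_loss = 1.2)
  expect_equal(d2$gain, 2 * drive$gain, tolerance = 1e-12)
  expect_error(calibrate_gain(target_m_loss = 0), "positive")
})

test_that("noise-free rate rises monotonically with visceral fat", {
  drive <- calibrate_gain()
  vf_grid <- seq(0, 300, by = 20)
  m <- vapply(vf_grid, function(v) {
    noise_free_m_loss(composition_section(250, v, 150, 2.2), study_freqs(),
                      drive)
  }, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("the rate is far less sensitive to subcutaneous than visceral fat", {
  drive <- calibrate_gain()
  h <- 5
  base <- reference_composition()
  m_at <- function(vf, sf) {
    noise_free_m_loss(composition_section(base$lean_interior_area, vf, sf,
                                          base$muscle_thickness),
                      study_freqs(), drive)
  }
  d_vf <- (m_at(90 + h, 150) - m_at(90 - h, 150)) / (2 * h)
  d_sf <- (m_at(90, 150 + h) - m_at(90, 150 - h)) / (2 * h)
  expect_lt(d_sf / d_vf, 0.3)
  expect_gt(d_sf, 0)  # still positive, merely minor
})

test_that("a thin muscle sheath suppresses the rate for the same visceral fat", {
  drive <- calibrate_gain()
  thin <- noise_free_m_loss(composition_section(250, 250, 150, 0.3),
                            study_freqs(), drive)
  normal <- noise_free_m_loss(composition_section(250, 250, 150, 2.2),
                              study_freqs(), drive)
  expect_lt(thin, normal)
  expect_lt(thin / normal, 0.75)
})

test_that("skin depth validates the quasi-static assumption", {
  delta <- skin_depth_m(tissue_conductivity(muscle_params(), 185), 185)
  expect_gt(delta, 1)  # metres
  r_outer_m <- shells_from_composition(reference_composition())$r_outer / 100
  expect_gt(delta, 10 * r_outer_m)
})
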