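test_that("analytic truth matches the closed forms", {
  tr <- analytic_truth(phantom_spec())
  expect_equal(tr$edv_ml, (2 / 3) * pi * 2.5 * 2.5 * 8, tolerance = 1e-12)
  expect_equal(tr$edv_ml, 104.7198, tolerance = 1e-4)
  expect_equal(tr$myocardial_mass_g,
               1.05 * (2 / 3) * pi * (3.5 * 3.5 * 9 - 2.5 * 2.5 * 8),
               tolerance = 1e-12)
  expect_equal(tr$myocardial_mass_g, 132.4967, tolerance = 1e-4)
  # hemisphere: concentric shells of radii 4 and 3
  hs <- analytic_truth(phantom_spec(endo_long_cm = 3, endo_b_cm = 3,
                                    endo_c_cm = 3))
  expect_equal(hs$myocardial_mass_g, 1.05 * (2 / 3) * pi * (4^3 - 3^3),
               tolerance = 1e-12)
  # zero wall: zero mass
  expect_equal(analytic_truth(phantom_spec(wall_cm = 0))$myocardial_mass_g, 0)
  cyl <- analytic_truth(phantom_spec("cylinder_flat_cap", endo_b_cm = 2,
                                     endo_c_cm = 2))
  expect_equal(cyl$edv_ml, pi * 4 * 8, tolerance = 1e-12)
  expect_equal(cyl$myocardial_mass_g, 1.05 * (pi * 5 * 8 + pi * 9),
               tolerance = 1e-12)
})

test_that("septal bulge extra volume matches a numeric double integral", {
  p <- phantom_spec("septal_bulge", endo_b_cm = 2, endo_c_cm = 2,
                    bulge_extra_cm = 0.8)
  base <- phantom_spec("cylinder_flat_cap", endo_b_cm = 2, endo_c_cm = 2)
  extra <- (analytic_truth(p)$myocardial_mass_g -
              analytic_truth(base)$myocardial_mass_g) / 1.05
  # independent oracle: brute-force integration of int[R*Delta + Delta^2/2]
  R <- 3; E <- 0.8; al <- p$bulge_angle_rad; w <- p$bulge_extent_cm
  th <- seq(-al, al, length.out = 4001)
  zz <- seq(-w, w, length.out = 4001)
  g <- cos(pi * th / (2 * al))^2
  f <- cos(pi * zz / (2 * w))^2
  dth <- diff(th)[1]; dz <- diff(zz)[1]
  num <- sum(outer(f, g, function(fi, gi) R * E * fi * gi +
                     (E * fi * gi)^2 / 2)) * dth * dz
  expect_equal(extra, num, tolerance = 1e-5)
})

test_that("rendered measurements are consistent with the geometry", {
  # cylinder: concentric circles
  m <- render_measurements(phantom_spec("cylinder_flat_cap", endo_b_cm = 2,
                                        endo_c_cm = 2))
  expect_equal(m$sax$a2_cm2, 4 * pi, tolerance = 1e-12)
  expect_equal(m$sax$a1_cm2, 9 * pi, tolerance = 1e-12)
  expect_equal(mean_wall_thickness(m$sax), 1.0, tolerance = 1e-12)
  expect_equal(m$linear$lvid_cm, 4)
  expect_equal(m$linear$ivs_cm, 1)

  # hemi-ellipsoid: endocardial SAX radius is b*sqrt(1 - (z0/L)^2)
  p <- phantom_spec()
  mh <- render_measurements(p)
  z0 <- 0.4 * 8
  rb <- 2.5 * sqrt(1 - (z0 / 8)^2)
  expect_equal(mh$sax$a2_cm2, pi * rb^2, tolerance = 1e-12)
  expect_equal(mh$linear$lvid_cm, 2 * rb, tolerance = 1e-12)
  Rb <- 3.5 * sqrt(1 - (z0 / 9)^2)
  expect_equal(mh$linear$ivs_cm, Rb - rb, tolerance = 1e-12)
  expect_equal(mh$long_axis$a_cm, 8 - z0)
  expect_equal(mh$long_axis$d_cm, z0)

  # septal bulge centred on the SAX plane: IVS carries the bulge, PWT not
  mb <- render_measurements(phantom_spec("septal_bulge", endo_b_cm = 2,
                                         endo_c_cm = 2, bulge_extra_cm = 0.8))
  expect_equal(mb$linear$ivs_cm, 1 + 0.8, tolerance = 1e-12)
  expect_equal(mb$linear$pwt_cm, 1)
  expect_gt(mb$sax$a1_cm2, 9 * pi)

  expect_error(phantom_spec(sax_level_fraction = 1.2),
               class = "echolvm_domain_error")
  expect_error(phantom_spec("septal_bulge", endo_b_cm = 2, endo_c_cm = 2,
                            bulge_extent_cm = 5),
               class = "echolvm_geometry_error")
})

test_that("perturb is the identity at zero noise and reproducible by seed", {
  m <- render_measurements(phantom_spec())
  m0 <- perturb(m, noise_model())
  expect_equal(m0$linear, m$linear)
  expect_equal(m0$sax, m$sax)
  expect_equal(m0$disc_stack$semi_axes, m$disc_stack$semi_axes)

  nm <- noise_model(linear_sd_cm = 0.05, area_rel_sd = 0.03,
                    contour_rel_sd = 0.03, seed = 17)
  a <- perturb(m, nm)
  b <- perturb(m, nm)
  expect_identical(a$linear, b$linear)
  expect_identical(a$sax, b$sax)
  expect_identical(a$disc_stack$semi_axes, b$disc_stack$semi_axes)
  expect_false(identical(a$linear$lvid_cm, m$linear$lvid_cm))
})

test_that("perturbed LVID has the configured spread", {
  m <- render_measurements(phantom_spec())
  nm <- noise_model(linear_sd_cm = 0.05)
  set.seed(12)
  lvids <- vapply(1:1000, function(i) perturb(m, nm)$linear$lvid_cm,
                  numeric(1))
  expect_equal(sd(lvids), 0.05, tolerance = 0.1)
  expect_equal(mean(lvids), m$linear$lvid_cm, tolerance = 0.01)
})

test_that("simulate_cohort produces a deterministic tidy table", {
  p <- phantom_spec()
  quiet_cohort <- simulate_cohort(p, noise_model(seed = 4), sessions = 2)
  expect_equal(nrow(quiet_cohort), 2)
  # zero noise: the two sessions are identical apart from the session column
  expect_identical(quiet_cohort$stack_json[1], quiet_cohort$stack_json[2])
  expect_identical(quiet_cohort$ivs_cm[1], quiet_cohort$ivs_cm[2])

  specs <- replicate(20, phantom_spec(), simplify = FALSE)
  nm <- noise_model(linear_sd_cm = 0.05, contour_rel_sd = 0.03, seed = 9)
  co <- simulate_cohort(specs, nm, sessions = 2)
  expect_equal(nrow(co), 40)
  expect_setequal(unique(co$session), c(1, 2))

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(simulate_cohort(specs, nm, sessions = 2), f1, row.names = FALSE)
  write.csv(simulate_cohort(specs, nm, sessions = 2), f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("sliced contours reproduce the analytic cavity volume", {
  for (shape in c("hemi_ellipsoid", "cylinder_flat_cap")) {
    p <- phantom_spec(shape)
    m <- render_measurements(p)
    st <- contours_to_discstack(m$contour_4ch, m$contour_2ch, n = 30)
    truth <- analytic_truth(p)$edv_ml
    expect_lt(abs(biplane_edv(st) - truth) / truth, 0.005)
    # and matches the directly rendered stack closely
    expect_equal(biplane_edv(st), biplane_edv(m$disc_stack), tolerance = 1e-3)
  }
})

test_that("on the septal-bulge phantom the disc-expansion method beats the
           cube formula", {
  p <- phantom_spec("septal_bulge", endo_b_cm = 2, endo_c_cm = 2,
                    bulge_extra_cm = 0.8)
  truth <- analytic_truth(p)$myocardial_mass_g
  m <- render_measurements(p)
  nov <- novel_lvm(m$disc_stack, m$sax)$lvm_g
  dev <- devereux_lvm(m$linear)
  expect_lt(abs(nov - truth), abs(dev - truth))
})

test_that("noiseless phantom errors are scale invariant", {
  # the cube formula is affine (additive 0.6 g), so its relative error is
  # only scale invariant after removing that constant
  rel_errors <- function(s) {
    p <- phantom_spec(endo_long_cm = 8 * s, endo_b_cm = 2.5 * s,
                      endo_c_cm = 2.5 * s, wall_cm = s)
    truth <- analytic_truth(p)$myocardial_mass_g
    m <- render_measurements(p)
    c(novel = novel_lvm(m$disc_stack, m$sax)$lvm_g,
      dev = devereux_lvm(m$linear) - 0.6,
      al = area_length_lvm(m$sax, m$long_axis),
      te = truncated_ellipsoid_lvm(m$sax, m$long_axis)) / truth - 1
  }
  expect_equal(rel_errors(1), rel_errors(1.6), tolerance = 1e-9)
})
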