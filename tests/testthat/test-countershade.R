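# Countershading module: optimal reflectance, re-rendering, apparent
# shading, and the orientation-departure shading curves.

test_that("leaf reference radiance is Lambertian and linear in albedo", {
  iso <- isotropic_sky(1)
  expect_equal(leaf_reference_radiance(iso, 1), 1, tolerance = 2e-3)
  a1 <- leaf_reference_radiance(sky_model(), 1)
  expect_equal(leaf_reference_radiance(sky_model(), 0.5), a1 / 2,
               tolerance = 1e-12)
  # composition: albedo x irradiance(up) / pi from the parts
  sky <- sky_model()
  expect_equal(leaf_reference_radiance(sky, 0.5),
               0.5 * irradiance(sky, c(0, 0, 1)) / pi)
  expect_error(leaf_reference_radiance(sky, 0), "leaf_albedo")
})

test_that("optimal reflectance inverts the irradiance pattern", {
  mesh <- make_ellipsoid(subdivision = 2)
  q <- quad_fast()
  # isotropic environment: irr = pi L0 everywhere, albedo 1 for rhl = L0
  iso <- isotropic_sky(1)
  r_iso <- suppressWarnings(optimal_reflectance(mesh, iso, 1, q))
  expect_true(all(abs(r_iso$albedo - 1) < 0.02))  # 16 x 8 rule accuracy
  # linearity in the target radiance
  sky <- sky_model()
  rhl <- leaf_reference_radiance(sky, 0.5, q)
  r1 <- suppressWarnings(optimal_reflectance(mesh, sky, rhl, q))
  r2 <- suppressWarnings(optimal_reflectance(mesh, sky, 2 * rhl, q))
  expect_equal(r2$albedo, 2 * r1$albedo)
  # countershading direction: sunlit-side faces are painted darker, and
  # the albedo ratio equals the inverse irradiance ratio
  irr <- irradiance(sky, mesh$normals, q)
  up <- mesh$normals[, 3] > 0.7
  down <- mesh$normals[, 3] < -0.7
  expect_lt(mean(r1$albedo[up]), mean(r1$albedo[down]))
  i <- which.max(irr); j <- which.min(irr)
  expect_equal(r1$albedo[j] / r1$albedo[i], irr[i] / irr[j],
               tolerance = 1e-9)
  # clamped mode caps at 1
  rc <- optimal_reflectance(mesh, sky, rhl, q, clamp = TRUE)
  expect_true(all(rc$albedo <= 1))
})

test_that("unlit faces make the optimum unattainable", {
  mesh <- make_ellipsoid(subdivision = 2)
  sun_only <- sky_model(zenith_radiance = 0, sun_irradiance = 5,
                        ground_albedo = 0)
  expect_error(optimal_reflectance(mesh, sun_only, 1, quad_fast()),
               "zero irradiance")
})

test_that("the optimal body renders perfectly flat at the reference pose", {
  mesh <- make_ellipsoid(subdivision = 2)
  sky <- sky_model()
  q <- quad_fast()
  rhl <- leaf_reference_radiance(sky, 0.5, q)
  refl <- suppressWarnings(optimal_reflectance(mesh, sky, rhl, q))
  view <- render_view(mesh, refl, sky, orientation(), quad = q)
  expect_lt(stats::sd(view$radiance) / mean(view$radiance), 1e-10)
  expect_equal(mean(view$radiance), rhl, tolerance = 1e-9)
  expect_lt(apparent_shading(view), 0.01 * rhl)
  expect_lt(apparent_shading(view, visible_only = FALSE), 0.01 * rhl)
})

test_that("a uniform body under an isotropic environment is uniformly lit", {
  mesh <- make_ellipsoid(subdivision = 2)
  iso <- isotropic_sky(2)
  view <- render_view(mesh, 0.4, iso, orientation(30, 45, -60),
                      quad = quad_fast())
  expect_equal(view$radiance, rep(0.4 * 2, length(view$radiance)),
               tolerance = 5e-3)
  # synthetic constant view has exactly zero apparent shading
  view$radiance[] <- 3
  expect_identical(apparent_shading(view), 0)
})

test_that("re-rendering at a new pose matches the two-irradiance formula", {
  mesh <- make_ellipsoid(subdivision = 2)
  sky <- sky_model()
  q <- quad_fast()
  rhl <- leaf_reference_radiance(sky, 0.5, q)
  refl <- suppressWarnings(optimal_reflectance(mesh, sky, rhl, q))
  o <- orientation(roll = 90)
  view <- render_view(mesh, refl, sky, o, quad = q)
  # spot-check 5 faces: radiance = rhl * irr(R n) / irr0(n), rotating the
  # normals by hand
  R <- countershade:::rotation_matrix(o)
  irr0 <- irradiance(sky, mesh$normals, q)
  for (k in c(1, 77, 150, 271, 320)) {
    n_rot <- drop(R %*% mesh$normals[k, ])
    expect_equal(view$radiance[k],
                 rhl * irradiance(sky, n_rot, q) / irr0[k],
                 tolerance = 1e-6)
  }
  expect_error(render_view(mesh, refl$albedo[-1], sky), "faces")
})

test_that("visibility flags follow the back-face test", {
  mesh <- make_ellipsoid(subdivision = 2)
  view <- render_view(mesh, 0.5, isotropic_sky(), quad = quad_fast())
  expect_identical(view$visible, drop(view$mesh$normals %*% c(1, 0, 0)) < 0)
  expect_true(any(view$visible) && any(!view$visible))
})

test_that("shading curves rise from zero and normalize to a unit maximum", {
  mesh <- make_ellipsoid(subdivision = 2)
  sky <- sky_model()
  q <- quad_fast()
  rhl <- leaf_reference_radiance(sky, 0.5, q)
  refl <- suppressWarnings(optimal_reflectance(mesh, sky, rhl, q))
  cur <- shading_curves(mesh, refl, sky, quad = q)
  expect_identical(max(cur$normalized), 1)
  expect_true(all(cur$normalized >= 0 & cur$normalized <= 1))
  # identical configuration at level 0 on every axis
  lvl0 <- cur$raw[cur$angle == 0]
  expect_equal(lvl0, rep(lvl0[1], 3))
  # monotone growth away from the reference orientation
  for (ax in c("pitch", "roll", "yaw")) {
    s <- cur$normalized[cur$axis == ax][order(cur$angle[cur$axis == ax])]
    expect_true(all(diff(s) >= 0))
  }
  # scale invariance: light-field magnitude cancels in normalized curves
  sky2 <- sky_model(zenith_radiance = 3 * sky$zenith_radiance,
                    sun_irradiance = 3 * sky$sun_irradiance)
  cur2 <- shading_curves(mesh, refl, sky2, quad = q)
  expect_equal(cur2$normalized, cur$normalized, tolerance = 1e-9)
  # lookup helper returns level-named normalized values
  s <- shading_lookup(cur, "yaw")
  expect_named(s, c("0", "15", "30", "45", "90"))
  expect_identical(unname(s[5]), 1)
})

test_that("countershading beats uniform coloration at the reference pose", {
  mesh <- make_ellipsoid(subdivision = 2)
  sky <- sky_model()
  q <- quad_fast()
  rhl <- leaf_reference_radiance(sky, 0.5, q)
  refl <- suppressWarnings(optimal_reflectance(mesh, sky, rhl, q))
  s_cs <- apparent_shading(render_view(mesh, refl, sky, quad = q))
  s_un <- apparent_shading(render_view(mesh, 0.5, sky, quad = q))
  expect_lt(s_cs, 0.01 * s_un)
})
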