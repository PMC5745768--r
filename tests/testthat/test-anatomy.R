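test_that("axis builders pass through their landmarks with stated orientation", {
  tpl <- make_template_ankle()

  # construction examples
  lm <- tpl
  lm <- cflsim:::set_landmark(lm, "medial_malleolus_inferior", "fibula", c(0, 0, -35))
  lm <- cflsim:::set_landmark(lm, "lateral_malleolus_inferior", "fibula", c(0, 0, 35))
  tc <- build_talocrural_axis(lm)
  expect_equal(tc$direction, c(0, 0, 1))            # medial -> lateral
  expect_equal(cflsim:::point_axis_distance(c(0, 0, 0), tc), 0, tolerance = 1e-12)

  lm2 <- cflsim:::set_landmark(lm, "calcaneal_tuberosity_lateral", "calcaneus",
                               c(-60, -30, 10))
  lm2 <- cflsim:::set_landmark(lm2, "talar_head_midpoint", "talus", c(20, 0, 0))
  st <- build_subtalar_axis(lm2)
  expect_equal(st$direction, c(80, 30, -10) / sqrt(sum(c(80, 30, -10)^2)))

  # incidence: template axes contain both defining landmarks
  for (build in list(build_talocrural_axis, build_subtalar_axis,
                     build_fibula_long_axis)) {
    ax <- build(tpl)
    expect_s3_class(ax, "axis_line")
  }
  expect_equal(cflsim:::point_axis_distance(
    landmark_point(tpl, "medial_malleolus_inferior"), build_talocrural_axis(tpl)), 0,
    tolerance = 1e-9)
  expect_equal(cflsim:::point_axis_distance(
    landmark_point(tpl, "talar_head_midpoint"), build_subtalar_axis(tpl)), 0,
    tolerance = 1e-9)
  expect_equal(cflsim:::point_axis_distance(
    landmark_point(tpl, "fibula_shaft_proximal"), build_fibula_long_axis(tpl)), 0,
    tolerance = 1e-9)
  # fibular direction points proximal -> distal
  expect_lt(build_fibula_long_axis(tpl)$direction[2], 0)

  # coincident landmarks are rejected
  bad <- cflsim:::set_landmark(lm, "medial_malleolus_inferior", "fibula", c(0, 0, 35))
  expect_error(build_talocrural_axis(bad), "degenerate axis")
})

test_that("running angle round-trips the generator and is rigid-transform invariant", {
  tpl <- make_template_ankle()
  m35 <- ankle_model(make_cfl_at_angle(tpl, 35))
  expect_equal(cfl_running_angle(m35), 35, tolerance = 1e-6)

  # collinear and perpendicular limit cases, built directly
  d <- build_fibula_long_axis(tpl)$direction
  origin <- landmark_point(tpl, "cfl_origin")
  lm <- cflsim:::set_landmark(tpl, "cfl_insertion", "calcaneus", origin + 20 * d)
  expect_equal(cfl_running_angle(ankle_model(lm)), 0, tolerance = 1e-9)
  perp <- c(-d[2], d[1], 0); perp <- perp / sqrt(sum(perp^2))
  lm <- cflsim:::set_landmark(tpl, "cfl_insertion", "calcaneus", origin + 20 * perp)
  expect_equal(cfl_running_angle(ankle_model(lm)), 90, tolerance = 1e-9)

  set.seed(303)
  for (i in 1:20) {
    tr <- random_rigid()
    moved <- transform_landmarks(make_cfl_at_angle(tpl, 42.5), tr$R, tr$t)
    expect_equal(cfl_running_angle(ankle_model(moved)), 42.5, tolerance = 1e-9)
  }
})

test_that("classification covers [20,60) half-open by bundle count and errors elsewhere", {
  expect_identical(classify_cfl(35, 1), "CFL30")
  expect_identical(classify_cfl(29.9, 1), "CFL20")
  expect_identical(classify_cfl(30.0, 1), "CFL30")
  expect_identical(classify_cfl(20, 1), "CFL20")
  expect_identical(classify_cfl(59.999, 1), "CFL50")
  for (a in c(10, 35, 75, 170)) expect_identical(classify_cfl(a, 2), "CFL2")
  expect_error(classify_cfl(10, 1), "unclassifiable")
  expect_error(classify_cfl(60, 1), "unclassifiable")
  expect_error(classify_cfl(-5, 1), "0, 180")
  # totality on a fine sweep of the covered domain
  for (a in seq(20, 59.99, by = 0.37)) {
    expect_true(classify_cfl(a, 1) %in% cfl_categories())
  }
})

test_that("category census reproduces the reference proportions", {
  cats <- rep(cfl_categories(), c(14, 22, 29, 15, 1))
  cp <- category_proportions(cats)
  expect_identical(cp$n, c(14L, 22L, 29L, 15L, 1L))
  expect_identical(cp$pct, c(17.3, 27.2, 35.8, 18.5, 1.2))
  expect_lt(abs(sum(cp$pct) - 100), 0.3)

  one <- category_proportions(rep("CFL40", 5))
  expect_identical(one$pct[one$category == "CFL40"], 100)
  even <- category_proportions(cfl_categories())
  expect_identical(even$pct, rep(20, 5))
  expect_error(category_proportions(character(0)), "empty input")
})

test_that("chi-squared homogeneity matches the Pearson formula and is permutation invariant", {
  # identical rows: no association at all
  same <- rbind(c(5, 10, 15), c(5, 10, 15))
  r0 <- chi_squared_homogeneity(same)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # hand-computed 2x2: expected all 5, statistic 4 * (10-5)^2/5 = 20
  r1 <- suppressWarnings(chi_squared_homogeneity(rbind(c(10, 0), c(0, 10))))
  expect_equal(r1$statistic, 20)
  expect_identical(r1$df, 1L)

  # reference sex table against the independent Pearson oracle
  sex <- reference_counts("sex")
  r2 <- suppressWarnings(chi_squared_homogeneity(sex))
  o2 <- oracle_pearson(sex)
  expect_equal(r2$statistic, o2$statistic, tolerance = 1e-12)
  expect_identical(r2$df, as.integer(o2$df))
  expect_equal(r2$p_value,
               stats::pchisq(o2$statistic, o2$df, lower.tail = FALSE),
               tolerance = 1e-12)

  # permutation invariance
  set.seed(404)
  perm <- suppressWarnings(chi_squared_homogeneity(sex[c(2, 1), sample(5)]))
  expect_equal(perm$statistic, r2$statistic, tolerance = 1e-12)

  # zero margins rejected, small expected counts warn
  expect_error(chi_squared_homogeneity(rbind(c(0, 0), c(3, 4))), "margin")
  expect_warning(chi_squared_homogeneity(rbind(c(1, 2), c(2, 1))),
                 "expected counts")
})

test_that("projected running-angle variant agrees with geometry in the lateral plane", {
  tpl <- make_template_ankle(template_config(cfl_plane_tilt_deg = 0,
                                             medial_malleolus_offset = c(0, 0),
                                             fibula_shaft_anterior_offset = 0))
  # with no out-of-plane tilt and a pure mediolateral hinge, the projected
  # and 3D angles coincide
  m <- ankle_model(make_cfl_at_angle(tpl, 40))
  expect_equal(cfl_running_angle(m, projected = TRUE), 40, tolerance = 1e-9)
  # with tilt, the projected (goniometer-style) angle is smaller than 3D
  tilted <- ankle_model(make_cfl_at_angle(make_template_ankle(), 40))
  expect_lt(cfl_running_angle(tilted, projected = TRUE), 40)
})
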