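test_that("a fronto-parallel plane renders at its exact depth everywhere", {
  intr <- small_intr()
  f <- render_frame(plane(c(0, 0, 1000)), intr)
  expect_true(all(f$depth == 1000))
  expect_true(all(f$label == 1L))
})

test_that("a sphere's principal-point depth is center depth minus radius", {
  f <- render_frame(sphere(c(0, 0, 600), 25), default_intr())
  expect_equal(f$depth[241, 321], 575)
})

test_that("depth silhouette area approximates the projected disc area", {
  # r*fx/Zc >= 20 px so the quantized silhouette tracks pi*R^2 within 5%
  for (case in list(c(r = 25, Z = 600), c(r = 25, Z = 400),
                    c(r = 40, Z = 900))) {
    f <- render_frame(sphere(c(0, 0, case["Z"]), case["r"]), default_intr())
    R <- case["r"] * 600 / case["Z"]
    expect_gte(R, 20)
    expect_equal(sum(f$depth > 0), pi * R^2, tolerance = 0.05,
                 ignore_attr = TRUE)
  }
})

test_that("the label mask covers the depth silhouette and its fringe", {
  f <- render_frame(sphere(c(0, 0, 500), 10), default_intr())
  on_depth <- f$depth > 0
  expect_true(all(f$label[on_depth] == 1L))
  expect_gte(sum(f$label == 1L), sum(on_depth))
})

test_that("rendering is deterministic", {
  sc <- list(sphere(c(20, 0, 500), 25), plane(c(0, 0, 1500)))
  f1 <- render_frame(sc, small_intr())
  f2 <- render_frame(sc, small_intr())
  expect_identical(f1$depth, f2$depth)
  expect_identical(f1$label, f2$label)
})

test_that("an identity sensor profile leaves in-range depths untouched", {
  f <- render_frame(plane(c(0, 0, 800)), small_intr())
  prof <- sensor_profile("identity", range = c(100, 5000))
  out <- apply_sensor(f, prof, "sunrise", seed = 1)
  expect_identical(out$depth, f$depth)
})

test_that("apply_sensor is deterministic given the seed", {
  f <- render_frame(plane(c(0, 0, 800)), small_intr())
  prof <- sensor_profile("noisy", range = c(100, 5000),
                         noise_family = "linear", noise_coef = 0.01,
                         base_dropout = 0.2, outlier_rate = 0.01)
  a <- apply_sensor(f, prof, "overcast", seed = 99)
  b <- apply_sensor(f, prof, "overcast", seed = 99)
  cdiff <- apply_sensor(f, prof, "overcast", seed = 100)
  expect_identical(a$depth, b$depth)
  expect_false(identical(a$depth, cdiff$depth))
})

test_that("dropout zeroes the injected fraction of an in-range plane", {
  intr <- camera_intrinsics(300, 300, 100, 100, 200, 200)
  f <- render_frame(plane(c(0, 0, 800)), intr)
  prof <- sensor_profile("drop", range = c(100, 5000), base_dropout = 0.3)
  out <- apply_sensor(f, prof, "sunrise", seed = 5)
  se <- sqrt(0.3 * 0.7 / (200 * 200))
  expect_lt(abs(mean(out$depth == 0) - 0.3), 3 * se)
})

test_that("lux band raises dropout by the profile slope", {
  intr <- camera_intrinsics(300, 300, 100, 100, 200, 200)
  f <- render_frame(plane(c(0, 0, 800)), intr)
  prof <- sensor_profile("lux", range = c(100, 5000), base_dropout = 0.1,
                         lux_dropout_slope = 0.2)
  out <- apply_sensor(f, prof, "direct_sunlight", seed = 6)  # 0.1 + 3*0.2
  se <- sqrt(0.7 * 0.3 / (200 * 200))
  expect_lt(abs(mean(out$depth == 0) - 0.7), 3 * se)
})

test_that("depths beyond the working range are reported as missing", {
  f <- render_frame(plane(c(0, 0, 2500)), small_intr())
  prof <- sensor_profile("sr300_like", range = c(300, 2000))
  out <- apply_sensor(f, prof, "sunrise", seed = 1)
  expect_true(all(out$depth == 0))
})

test_that("profile constructor rejects invalid probabilities and ranges", {
  expect_error(sensor_profile("bad", range = c(500, 100)))
  expect_error(sensor_profile("bad", base_dropout = 1.5), "probabilities")
  expect_error(apply_sensor(render_frame(plane(c(0, 0, 500)), small_intr()),
                            list(), "sunrise", seed = 1), "config error")
})

test_that("the experiment scene builder follows the outdoor protocol", {
  scenes <- make_experiment_scene()
  expect_length(scenes, 7)
  for (sc in scenes) {
    balls <- sc$objects$true_size_mm[sc$objects$class == "ball"]
    expect_equal(sort(balls), c(7.8, 50))
  }
  expect_error(make_experiment_scene(distances = numeric()), "config error")
  expect_error(make_experiment_scene(distances = -5), "config error")
  expect_error(make_experiment_scene(ball_diameters = numeric(), n_stems = 0),
               "config error")
})

test_that("rendered sphere diameters converge with resolution", {
  # relative error shrinks as pixel pitch falls (same scene, finer camera)
  est_err <- vapply(c(300, 600, 1200), function(fx) {
    intr <- camera_intrinsics(fx, fx, 320, 240, 640, 480)
    f <- render_frame(sphere(c(0, 0, 500), 25), intr)
    m <- f$label == 1
    est <- estimate_diameter(intr, f$depth, select_perimeter_pairs(m),
                             mask = m)
    abs(est$value - 50) / 50
  }, numeric(1))
  expect_lt(est_err[3], 0.02)
  expect_lt(est_err[3], est_err[1] + 0.005)
})
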