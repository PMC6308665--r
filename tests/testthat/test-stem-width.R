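test_that("cropping keeps rasters aligned and records the offset", {
  f <- render_frame(list(sphere(c(0, 0, 500), 20), plane(c(0, 0, 1200))),
                    small_intr())
  full <- crop_detection(f, c(0, 0, 319, 239))
  expect_identical(full$depth, f$depth)
  cr <- crop_detection(f, c(10, 20, 19, 29))
  expect_equal(dim(cr$depth), c(10, 10))
  expect_equal(dim(cr$color), c(10, 10, 3))
  expect_equal(cr$depth[3, 4], f$depth[3 + 20, 4 + 10])
  expect_equal(cr$offset, c(x = 10, y = 20))
  expect_error(crop_detection(f, c(300, 0, 340, 50)), "outside")
  expect_error(crop_detection(f, c(10, 10, 5, 20)), "x0 < x1")
})

test_that("orientation is the incline of the extreme-pixel line", {
  m <- matrix(FALSE, 50, 50); m[10:40, 25] <- TRUE
  expect_equal(estimate_orientation(m), 0)
  m45 <- matrix(FALSE, 50, 50)
  for (i in 0:30) m45[10 + i, 10 + i] <- TRUE
  expect_equal(estimate_orientation(m45), 45)
  single <- matrix(FALSE, 10, 10); single[4, 2:8] <- TRUE
  expect_error(estimate_orientation(single), "orientation error")
})

test_that("orientation of rendered inclined stems is recovered within 2 degrees", {
  for (th in c(-30, -15, 0, 10, 25, 30)) {
    f <- stem_frame(500, th)
    mask <- f$label == 1
    expect_gte(diff(range(which(rowSums(mask) > 0))), 100)
    got <- estimate_orientation(mask)
    # the camera-frame X axis is mirrored in pixel x, flipping the sign
    expect_lt(abs(abs(got) - abs(th)), 2)
  }
})

test_that("rotation is canvas-preserving, approximately invertible, and never blends depths", {
  f <- stem_frame(500, 20)
  cr <- crop_detection(f, c(200, 100, 439, 379))
  expect_identical(rotate_to_vertical(cr, 0), cr)
  rot <- rotate_to_vertical(cr, 20)
  back <- rotate_to_vertical(rot, -20)
  interior_r <- 60:220; interior_c <- 60:180
  # double bilinear resampling only smears the stem edges a little
  expect_lt(mean(abs(back$color[interior_r, interior_c, ] -
                       cr$color[interior_r, interior_c, ])), 0.02)
  expect_true(all(rot$depth %in% c(0, cr$depth)))
  expect_equal(dim(rot$depth), dim(cr$depth))
  expect_error(rotate_to_vertical(cr, 95), "angle")
})

test_that("canonization brings an inclined stem upright", {
  f <- stem_frame(500, 25)
  det <- detect_from_labels(f, "stem")
  cr <- crop_detection(f, c(det$x0, det$y0, det$x1, det$y1))
  seg <- label_segmenter(1)
  ang <- estimate_orientation(seg(cr))
  rot <- rotate_to_vertical(cr, ang)
  expect_lt(abs(estimate_orientation(seg(rot))), 2)
})

test_that("width lines span leftmost to rightmost over the middle third", {
  m <- matrix(FALSE, 20, 20)
  m[6:14, 8:12] <- TRUE                      # 9 rows, constant width 5
  ln <- extract_width_lines(m)
  expect_equal(nrow(ln), 3)
  expect_equal(ln$npix, rep(5L, 3))
  expect_equal(ln$left, rep(7L, 3))          # 0-based
  expect_equal(ln$right, rep(11L, 3))

  m[10, ] <- FALSE; m[10, 9] <- TRUE         # single-pixel row
  ln2 <- extract_width_lines(m)
  expect_equal(ln2$npix[ln2$row == 9], 1L)

  mh <- matrix(FALSE, 20, 20); mh[6:14, 8:12] <- TRUE
  mh[10, 10] <- FALSE                        # interior hole
  ln3 <- extract_width_lines(mh)
  expect_equal(ln3$npix[ln3$row == 9], 5L)   # hole ignored

  flat <- matrix(FALSE, 10, 10); flat[4:5, 2:8] <- TRUE
  expect_error(extract_width_lines(flat), "measurement error")
})

test_that("the 3-SD line filter follows its defining arithmetic", {
  mk <- function(lens) data.frame(row = seq_along(lens) - 1L, left = 0L,
                                  right = lens - 1L, npix = lens)
  expect_equal(nrow(filter_lines(mk(rep(10L, 5)))), 5)
  expect_equal(nrow(filter_lines(mk(c(8L, 10L, 12L)))), 3)
  lens <- c(rep(10L, 50), 60L)
  kept <- filter_lines(mk(lens))
  expect_equal(nrow(kept), 50)
  expect_false(60L %in% kept$npix)
  set.seed(51)
  for (rep in 1:30) {
    lens <- sample(3:60, sample(1:40, 1), TRUE)
    kept <- filter_lines(mk(lens))
    expect_equal(kept$npix, lens[oracle_filter_lines(lens)])
    expect_lte(nrow(kept), length(lens))
    if (length(lens) > 1 && sd(lens) > 0)
      expect_lte(abs(mean(kept$npix) - mean(lens)), 3 * sd(lens))
  }
})

test_that("identical kept lines give the line's own metric length", {
  intr <- default_intr()
  img <- matrix(900, 480, 640)
  lines <- data.frame(row = c(50L, 51L, 52L), left = 100L, right = 120L,
                      npix = 21L)
  w <- measure_stem_width(intr, img, lines)
  expect_equal(as.numeric(w), 900 * 20 / 600)
  expect_equal(attr(w, "n_lines"), 3L)
})

test_that("the pipeline measures noise-free stems and isolates failures", {
  intr <- default_intr()
  sc <- make_experiment_scene(distances = 500, n_stems = 3)[[1]]
  f <- render_frame(sc$scene, intr)
  dets <- detect_from_labels(f, "stem")
  expect_equal(nrow(dets), 3)
  res <- run_pipeline(f, dets, label_segmenter(dets$id))
  expect_s3_class(res, "stem_measurements")
  expect_true(all(res$status == "ok"))
  expect_equal(res$width_mm, rep(8, 3), tolerance = 0.05)

  # a detection over empty background fails alone
  dets2 <- rbind(dets, data.frame(id = 99L, x0 = 0L, y0 = 0L,
                                  x1 = 30L, y1 = 60L))
  res2 <- run_pipeline(f, dets2, label_segmenter(dets$id))
  expect_equal(sum(res2$status == "ok"), 3)
  expect_match(res2$status[res2$id == 99], "error")

  expect_equal(nrow(run_pipeline(f, dets[0, ], label_segmenter(1))), 0)
  res3 <- run_pipeline(f, dets, label_segmenter(dets$id))
  expect_identical(res$width_mm, res3$width_mm)
})

test_that("width is stable under inclination after canonization", {
  ws <- vapply(c(0, 10, 20, 30), function(th) {
    f <- stem_frame(500, th)
    res <- run_pipeline(f, detect_from_labels(f, "stem"), label_segmenter(1))
    res$width_mm
  }, numeric(1))
  expect_true(all(abs(ws - 8) / 8 < 0.05))
})

test_that("Monte-Carlo mean width under 2 mm depth noise is unbiased", {
  intr <- default_intr()
  f <- stem_frame(500, 0)
  prof <- sensor_profile("sigma2", range = c(100, 5000),
                         noise_family = "constant", noise_coef = 2)
  det <- detect_from_labels(f, "stem")
  seg <- label_segmenter(1)
  base <- run_pipeline(f, det, seg)$width_mm   # quantization-limited truth
  ws <- vapply(1:200, function(i) {
    fn <- apply_sensor(f, prof, "sunrise", seed = 7000 + i)
    fn$label <- f$label; fn$objects <- f$objects
    run_pipeline(fn, det, seg)$width_mm
  }, numeric(1))
  se <- sd(ws) / sqrt(length(ws))
  expect_lt(abs(mean(ws) - base), max(2 * se, 0.05))
})
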