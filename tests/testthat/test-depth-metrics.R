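test_that("the 3-SD validity rule keeps non-zero in-band pixels", {
  img <- matrix(0, 10, 10)
  roi <- matrix(FALSE, 10, 10); roi[1, 1:10] <- TRUE
  img[1, 1:6] <- 1000                       # 6 valid, 4 missing
  expect_equal(sum(valid_mask(img, roi)), 6)
  expect_equal(fill_rate(img, roi), 0.6)

  img2 <- matrix(0, 10, 10); roi2 <- matrix(TRUE, 10, 10)
  img2[] <- 1000; img2[5, 5] <- 5000        # 99 at 1000 mm, 1 outlier
  vm <- valid_mask(img2, roi2)
  expect_false(vm[5, 5])
  expect_equal(sum(vm), 99)
  expect_equal(fill_rate(img2, roi2), 0.99)

  img3 <- matrix(0, 4, 4)
  expect_equal(sum(valid_mask(img3, matrix(TRUE, 4, 4))), 0)
  expect_error(valid_mask(img, matrix(FALSE, 10, 10)), "at least one pixel")
})

test_that("fill rate equals one minus the realized dropout on constant depth", {
  # constant in-range depth: the 3-SD rule degenerates to the non-zero test,
  # so the fill rate must match the realized zero fraction exactly
  intr <- camera_intrinsics(300, 300, 100, 100, 200, 200)
  f <- render_frame(plane(c(0, 0, 900)), intr)
  prof <- sensor_profile("drop", range = c(100, 5000), base_dropout = 0.3)
  out <- apply_sensor(f, prof, "sunrise", seed = 21)
  roi <- matrix(TRUE, 200, 200)
  expect_equal(fill_rate(out$depth, roi), 1 - mean(out$depth == 0))
})

test_that("fill rate agrees with the counting oracle and never rises under zeroing", {
  set.seed(31)
  for (rep in 1:20) {
    img <- matrix(sample(c(0, 800, 820, 3000), 400, TRUE,
                         prob = c(0.2, 0.4, 0.3, 0.1)), 20, 20)
    roi <- matrix(runif(400) < 0.6, 20, 20)
    if (!any(roi)) roi[1, 1] <- TRUE
    fr <- fill_rate(img, roi)
    expect_equal(fr, oracle_fill_rate(img, roi))
    expect_gte(fr, 0); expect_lte(fr, 1)
    img_z <- img
    kill <- which(roi & img > 0)
    if (length(kill)) {
      img_z[sample(kill, ceiling(length(kill) / 3))] <- 0
      expect_lte(fill_rate(img_z, roi), fr + 1e-12)
    }
  }
})

test_that("lux bands follow the published boundaries and tile [0, Inf)", {
  expect_equal(as.character(categorize_lux(500)), "sunrise")
  expect_equal(as.character(categorize_lux(15000)), "full_daylight")
  expect_equal(as.character(categorize_lux(32000)), "direct_sunlight")
  expect_equal(as.character(categorize_lux(c(0, 999, 1000, 9999, 10000, 1e6))),
               c("sunrise", "sunrise", "overcast", "overcast",
                 "full_daylight", "direct_sunlight"))
  set.seed(32)
  lx <- c(0, 10^runif(500, 0, 6))
  expect_false(anyNA(categorize_lux(lx)))
  expect_error(categorize_lux(-1), "non-negative")
})

test_that("background removal keeps the in-band object and rescues holes", {
  h <- 60; w <- 60
  col <- array(runif(h * w * 3), dim = c(h, w, 3))
  depth <- matrix(1000, h, w)
  expect_equal(remove_background(col, depth, 1000), col)

  # object disc at 1000 mm on a 2000 mm backdrop, > 10 px apart
  depth2 <- matrix(2000, h, w)
  obj <- disc_mask(h, w, 30, 30, 12)
  depth2[obj] <- 1000
  out <- remove_background(col, depth2, 1000)
  border <- disc_mask(h, w, 30, 30, 23) & !disc_mask(h, w, 30, 30, 22)
  expect_true(all(out[, , 1][!disc_mask(h, w, 30, 30, 23)] == 0))
  expect_equal(out[, , 1][obj], col[, , 1][obj])

  # a missing-depth pixel 5 px inside the object is rescued by neighbours
  depth3 <- depth2
  depth3[31, 31] <- 0
  out3 <- remove_background(col, depth3, 1000)
  expect_equal(out3[31, 31, ], col[31, 31, ])
})

test_that("background removal never blackens an in-band pixel", {
  set.seed(33)
  for (rep in 1:10) {
    depth <- matrix(sample(c(0, 900, 1000, 1100, 2500), 900, TRUE), 30, 30)
    col <- array(runif(900 * 3, min = 0.1), dim = c(30, 30, 3))
    out <- remove_background(col, depth, 1000)
    inband <- depth >= 750 & depth <= 1250
    expect_equal(out[, , 2][inband], col[, , 2][inband])
  }
})

test_that("fill-rate aggregation means match a naive per-group average", {
  one <- data.frame(sensor = "a", object = "ball", fill_rate = 0.37)
  expect_equal(aggregate_fill(one, "sensor")$mean_fill_rate, 0.37)
  two <- data.frame(sensor = c("a", "a"), fill_rate = c(0.4, 0.6))
  expect_equal(aggregate_fill(two, "sensor")$mean_fill_rate, 0.5)
  set.seed(34)
  rec <- data.frame(sensor = sample(letters[1:3], 200, TRUE),
                    object = sample(c("ball", "stem"), 200, TRUE),
                    distance_mm = sample(c(400, 800), 200, TRUE),
                    fill_rate = runif(200))
  agg <- aggregate_fill(rec, c("sensor", "object"))
  for (i in seq_len(nrow(agg))) {
    sel <- rec$sensor == agg$sensor[i] & rec$object == agg$object[i]
    expect_equal(agg$mean_fill_rate[i], mean(rec$fill_rate[sel]))
    expect_equal(agg$n[i], sum(sel))
  }
  expect_error(aggregate_fill(rec, "nope"), "unknown grouping key")
  expect_error(aggregate_fill(rec[0, ], "sensor"), "non-empty")
})
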