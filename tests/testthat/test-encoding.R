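test_that("distance encoding matches analytic values", {
  cs <- click_set(3, 4, "positive")
  g <- encode_distance(cs, c(8, 8))
  expect_s3_class(g, "guidance_map")
  expect_identical(g$encoding, "distance")
  expect_false(g$empty_flag)
  expect_equal(g$values[3, 4], 0)
  expect_equal(g$values[3, 5], 1)
  expect_equal(g$values[6, 8], 5)       # 3-4-5 triangle
  cs2 <- click_set(c(1, 4), c(1, 5), "positive")
  g2 <- encode_distance(cs2, c(8, 8))
  expect_equal(g2$values[4, 1], 3)      # min(3, 4)
})

test_that("distance clipping bounds the map", {
  cs <- click_set(1, 1, "positive")
  g <- encode_distance(cs, c(64, 64), clip = 10)
  expect_equal(max(g$values), 10)
  expect_true(all(g$values >= 0))
})

test_that("gaussian encoding matches the closed form", {
  cs <- click_set(6, 6, "positive")
  g <- encode_gaussian(cs, c(12, 12), sigma = 1)
  expect_equal(g$values[6, 6], 1)
  expect_equal(g$values[6, 7], exp(-0.5))
  expect_equal(g$values[7, 7], exp(-1))
})

test_that("empty click sets give blank maps with the empty flag", {
  for (enc in list(encode_distance, encode_gaussian)) {
    g <- enc(click_set(), c(16, 16))
    expect_true(g$empty_flag)
    expect_true(all(g$values == 0))
  }
})

test_that("clicks outside the image are rejected", {
  expect_error(encode_distance(click_set(20, 2, "positive"), c(16, 16)),
               "bounds")
  expect_error(encode_gaussian(click_set(0, 2, "positive"), c(16, 16)),
               "bounds")
})

test_that("both encoders agree with brute-force oracles on random instances", {
  set.seed(7)
  for (rep in 1:50) {
    k <- sample(1:20, 1)
    shape <- c(sample(20:40, 1), sample(20:40, 1))
    cs <- click_set(sample.int(shape[1], k, replace = TRUE),
                    sample.int(shape[2], k, replace = TRUE), "positive")
    sigma <- runif(1, 0.5, 8)
    expect_equal(encode_distance(cs, shape)$values,
                 brute_distance_map(cs, shape), tolerance = 1e-12)
    expect_equal(encode_gaussian(cs, shape, sigma)$values,
                 brute_gaussian_map(cs, shape, sigma), tolerance = 1e-12)
  }
})

test_that("one extra brute-force check at the larger grid size", {
  set.seed(8)
  cs <- click_set(sample.int(64, 20, replace = TRUE),
                  sample.int(64, 20, replace = TRUE), "positive")
  expect_equal(encode_distance(cs, c(64, 64))$values,
               brute_distance_map(cs, c(64, 64)), tolerance = 1e-12)
})

test_that("adding a click moves maps monotonically", {
  set.seed(9)
  for (rep in 1:50) {
    shape <- c(24, 24)
    k <- sample(1:8, 1)
    cs <- click_set(sample.int(shape[1], k, replace = TRUE),
                    sample.int(shape[2], k, replace = TRUE), "positive")
    extra <- click_set(sample.int(shape[1], 1), sample.int(shape[2], 1),
                       "positive")
    both <- append_clicks(cs, extra)
    d0 <- encode_distance(cs, shape)$values
    d1 <- encode_distance(both, shape)$values
    expect_true(all(d1 <= d0 + 1e-12))
    g0 <- encode_gaussian(cs, shape, 3)$values
    g1 <- encode_gaussian(both, shape, 3)$values
    expect_true(all(g1 >= g0 - 1e-12))
  }
})

test_that("encodings are invariant to click order", {
  set.seed(10)
  shape <- c(30, 30)
  cs <- click_set(sample.int(30, 6), sample.int(30, 6), "positive")
  perm <- cs[sample.int(nrow(cs)), ]
  class(perm) <- class(cs)
  expect_equal(encode_distance(cs, shape)$values,
               encode_distance(perm, shape)$values)
  expect_equal(encode_gaussian(cs, shape, 2)$values,
               encode_gaussian(perm, shape, 2)$values)
})

test_that("a two-click gaussian map is the max of the single-click maps", {
  shape <- c(20, 20)
  a <- click_set(4, 5, "positive"); b <- click_set(15, 11, "positive")
  both <- append_clicks(a, b)
  expect_equal(encode_gaussian(both, shape, 2)$values,
               pmax(encode_gaussian(a, shape, 2)$values,
                    encode_gaussian(b, shape, 2)$values))
})

test_that("full-image window cropping is the identity", {
  sc <- tiny_scene(2)
  box <- c(1, 64, 1, 64)
  out <- crop_to_window(box, scene = sc)
  expect_identical(out$instance_mask, sc$instance_mask)
  mask <- sc$instance_mask == 1
  expect_identical(restore_from_window(mask, out$placement), mask)
})

test_that("windowed predictions restore with zeros outside the box", {
  sc <- generate_scene(scene_config(height = 120, width = 140, seed = 3))
  box <- c(11, 74, 21, 84)
  cs <- click_set(40, 50, "positive")
  pg <- encode_gaussian(cs, c(120, 140), 5)
  out <- crop_to_window(box, scene = sc, pos_guidance = pg, clicks = cs)
  expect_identical(dim(out$instance_mask), c(64L, 64L))
  expect_identical(dim(out$pos_guidance$values), c(64L, 64L))
  pred <- out$instance_mask > 0
  full <- restore_from_window(pred, out$placement)
  expect_identical(dim(full), c(120L, 140L))
  expect_true(all(!full[-(11:74), ]))
  expect_true(all(!full[, -(21:84)]))
})

test_that("IoU computed after restoration equals IoU inside the window", {
  sc <- generate_scene(scene_config(height = 120, width = 140, seed = 5))
  # pick an object and a box that contains it entirely
  obj <- sc$instance_mask == 1
  rows <- range(which(rowSums(obj) > 0)); cols <- range(which(colSums(obj) > 0))
  box <- c(max(1, rows[1] - 5), min(120, rows[2] + 5),
           max(1, cols[1] - 5), min(140, cols[2] + 5))
  out <- crop_to_window(box, scene = sc)
  pred_win <- out$instance_mask == 1      # a perfect windowed prediction
  gt_win <- out$instance_mask == 1
  expect_equal(iou(restore_from_window(pred_win, out$placement), obj),
               iou(pred_win, gt_win))
})

test_that("a box excluding a positive click is rejected", {
  cs <- click_set(c(5, 50), c(5, 50), c("positive", "negative"))
  sc <- tiny_scene(2)
  expect_error(crop_to_window(c(10, 60, 10, 60), scene = sc, clicks = cs),
               "positive click")
  # negative clicks may fall outside; they are dropped from the window
  out <- crop_to_window(c(1, 40, 1, 40), scene = sc, clicks = cs)
  expect_equal(nrow(out$clicks), 1)
  expect_equal(out$clicks$polarity, "positive")
})
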