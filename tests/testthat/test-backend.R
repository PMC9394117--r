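make_input <- function(sc, clicks, prior_channel = NULL,
                       cfg = sim_config()) {
  shape <- dim(sc$instance_mask)
  if (is.null(prior_channel)) prior_channel <- blank_prior(shape)
  backend_input(sc$image,
                encode_gaussian(filter_clicks(clicks, "positive"), shape,
                                cfg$sigma),
                encode_gaussian(filter_clicks(clicks, "negative"), shape,
                                cfg$sigma),
                prior_channel, clicks = clicks)
}

test_that("backend inputs enforce shape agreement", {
  sc <- tiny_scene(1)
  g <- encode_gaussian(click_set(3, 3, "positive"), c(64, 64))
  bad <- encode_gaussian(click_set(3, 3, "positive"), c(32, 32))
  expect_error(backend_input(sc$image, bad, g, blank_prior(c(64, 64))),
               "shape")
  expect_error(backend_input(sc$image, g, g, blank_prior(c(32, 32))),
               "shape")
})

test_that("the oracle backend reproduces the clicked object's mask", {
  sc <- tiny_scene(2)
  px <- which(sc$instance_mask == 2)[5]
  cs <- click_set(((px - 1) %% 64) + 1, ((px - 1) %/% 64) + 1, "positive")
  b <- backend_bind(oracle_backend(), sc)
  out <- backend_predict(b, make_input(sc, cs))
  expect_identical(out$mask, sc$instance_mask == 2)
  expect_error(backend_predict(oracle_backend(), make_input(sc, cs)),
               "bound")
})

test_that("the empty backend predicts nothing", {
  sc <- tiny_scene(3)
  out <- backend_predict(empty_backend(),
                         make_input(sc, click_set(5, 5, "positive")))
  expect_true(all(!out$mask))
  expect_true(all(out$prob == 0))
})

test_that("baseline with a zero-noise prior equals the clicked component", {
  sc <- tiny_scene(4)
  pr <- make_prior(sc, prior_noise())
  px <- which(sc$instance_mask == 1)[20]
  cs <- click_set(((px - 1) %% 64) + 1, ((px - 1) %/% 64) + 1, "positive")
  sel <- select_channel(pr, cs)
  # oracle: flood fill over the selected channel's >= 0.5 pixels,
  # keep the component under the click
  lab <- flood_fill_label(sel$channel >= 0.5)
  want <- lab == lab[cs$row[1], cs$col[1]] & lab > 0
  out <- backend_predict(threshold_backend(), make_input(sc, cs, sel$channel))
  expect_identical(out$mask, want)
  expect_equal(iou(out$mask, sc$instance_mask == 1), 1)
})

test_that("negative-only components are removed by the baseline", {
  # four objects over two classes: the selected class channel holds two
  # components; the positively clicked one stays, the negatively
  # clicked one goes
  sc <- generate_scene(scene_config(height = 96, width = 96, n_objects = 4,
                                    n_classes = 2, seed = 19))
  pr <- make_prior(sc, prior_noise())
  same_class <- which(sc$object_classes == sc$object_classes[1])
  other <- setdiff(same_class, 1)[1]
  p1 <- which(sc$instance_mask == 1)[10]
  p2 <- which(sc$instance_mask == other)[10]
  cs <- click_set(((c(p1, p2) - 1) %% 96) + 1, ((c(p1, p2) - 1) %/% 96) + 1,
                  c("positive", "negative"))
  sel <- select_channel(pr, cs)
  input <- backend_input(sc$image,
                         encode_gaussian(filter_clicks(cs, "positive"),
                                         c(96, 96)),
                         encode_gaussian(filter_clicks(cs, "negative"),
                                         c(96, 96)),
                         sel$channel, clicks = cs)
  out <- backend_predict(threshold_backend(), input)
  expect_identical(out$mask, sc$instance_mask == 1)
})

test_that("the clicks-only path grows a region containing the click", {
  sc <- tiny_scene(5)
  px <- which(sc$instance_mask == 1)[15]
  cs <- click_set(((px - 1) %% 64) + 1, ((px - 1) %/% 64) + 1, "positive")
  out <- backend_predict(threshold_backend(), make_input(sc, cs))
  expect_true(out$mask[cs$row[1], cs$col[1]])
  # grown region is dominated by the clicked object's pixels
  expect_gt(mean(sc$instance_mask[out$mask] == 1), 0.8)
})

test_that("bootstrapped CE reduces to plain CE at fraction one", {
  set.seed(41)
  p <- matrix(runif(64, 0.01, 0.99), 8, 8)
  y <- random_binary_mask(8, 8)
  plain <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(bootstrapped_ce_loss(p, y, fraction = 1), plain)
})

test_that("a perfect prediction has loss at the clamp floor", {
  y <- random_binary_mask(8, 8)
  expect_lt(bootstrapped_ce_loss(y * 1, y, fraction = 1), 1e-6)
})

test_that("the top-k mean matches a hand-computed case", {
  # per-pixel CE values {0.1, 0.2, 0.7, 1.4} via p = exp(-ce), y = 1
  ce <- c(0.1, 0.2, 0.7, 1.4)
  p <- matrix(exp(-ce), 2, 2)
  y <- matrix(1, 2, 2)
  expect_equal(bootstrapped_ce_loss(p, y, fraction = 0.5), (0.7 + 1.4) / 2,
               tolerance = 1e-9)
  # fraction small enough to keep only the single hardest pixel
  expect_equal(bootstrapped_ce_loss(p, y, fraction = 0.25), 1.4,
               tolerance = 1e-9)
})

test_that("the learning-rate schedule follows exponential decay with a floor", {
  cfg <- train_config()
  expect_equal(learning_rate(0, cfg), 1e-4)
  expect_equal(learning_rate(5, cfg), 9e-5)
  expect_equal(learning_rate(10, cfg), 8.1e-5)
  expect_equal(learning_rate(4, cfg), 1e-4)    # within the first interval
  expect_equal(learning_rate(1000, cfg), 5e-7)
  expect_true(all(learning_rate(0:2000, cfg) >= 5e-7))
})

test_that("probability-one prior reset always feeds a blank prior", {
  scenes <- lapply(1:3, function(i) tiny_scene(i + 50))
  seen <- list()
  train_backend(scenes,
                train_config(epochs = 1, initial_lr = 0.01,
                             prior_reset_prob = 1, seed = 2),
                instrument = function(pc) seen[[length(seen) + 1]] <<- pc)
  expect_gt(length(seen), 0)
  expect_true(all(vapply(seen, function(pc) all(pc == 0), logical(1))))
})

test_that("training runs deterministically and logs the schedule", {
  scenes <- lapply(1:4, function(i) tiny_scene(i + 60))
  cfg <- train_config(epochs = 2, initial_lr = 0.02, seed = 5)
  a <- train_backend(scenes, cfg)
  b <- train_backend(scenes, cfg)
  expect_identical(a$par, b$par)
  expect_identical(a$log, b$log)
  expect_equal(a$log$epoch, 1:2)
  expect_equal(a$log$lr, rep(0.02, 2))
  expect_true(all(is.finite(a$log$loss)))
})

test_that("model checkpoints round-trip through JSON", {
  scenes <- lapply(1:2, function(i) tiny_scene(i + 70))
  m <- train_backend(scenes, train_config(epochs = 1, initial_lr = 0.02,
                                          seed = 3))
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_seg_model(m, f)
  m2 <- read_seg_model(f)
  expect_equal(m2$par, m$par, tolerance = 1e-12)
  sc <- tiny_scene(77)
  cs <- click_set(32, 32, "positive")
  expect_equal(backend_predict(m, make_input(sc, cs))$prob,
               backend_predict(m2, make_input(sc, cs))$prob,
               tolerance = 1e-12)
})

test_that("the backend registry exposes the built-ins", {
  expect_true(all(c("oracle", "empty", "threshold", "pixelmlp") %in%
                    list_backends()))
  expect_s3_class(make_backend("threshold"), "threshold_backend")
  expect_error(make_backend("nope"), "unknown backend")
})
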