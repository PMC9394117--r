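test_that("initial sampling spends exactly the click budget", {
  for (seed in 1:6) {
    sc <- tiny_scene(seed)
    cs <- sample_initial(sc, 1, sim_config(), seed = seed * 13)
    expect_equal(nrow(cs), 20)
    expect_gte(n_clicks(cs, "positive"), 1)
  }
})

test_that("all positive clicks lie on the object of interest", {
  sc <- tiny_scene(4)
  for (k in seq_along(sc$object_classes)) {
    cs <- sample_initial(sc, k, sim_config(), seed = k)
    pos <- filter_clicks(cs, "positive")
    expect_true(all(sc$instance_mask[cbind(pos$row, pos$col)] == k))
    neg <- filter_clicks(cs, "negative")
    expect_true(all(sc$instance_mask[cbind(neg$row, neg$col)] != k))
  }
})

test_that("positive clicks respect the d_step spacing", {
  sc <- tiny_scene(8)
  cfg <- sim_config(d_step = 7)
  cs <- sample_initial(sc, 1, cfg, seed = 5)
  pos <- filter_clicks(cs, "positive")
  if (nrow(pos) > 1) {
    d <- as.matrix(stats::dist(cbind(pos$row, pos$col)))
    diag(d) <- Inf
    expect_gte(min(d), cfg$d_step)
  }
})

test_that("negative clicks sit on nearby objects or in the surrounding ring", {
  sc <- tiny_scene(10)
  cfg <- sim_config()
  cs <- sample_initial(sc, 2, cfg, seed = 3)
  neg <- filter_clicks(cs, "negative")
  obj <- sc$instance_mask == 2
  # brute-force distance of each negative click to the object
  obj_px <- which(obj, arr.ind = TRUE)
  for (i in seq_len(nrow(neg))) {
    d <- min(sqrt((obj_px[, 1] - neg$row[i])^2 +
                    (obj_px[, 2] - neg$col[i])^2))
    on_other <- sc$instance_mask[neg$row[i], neg$col[i]] > 0
    ok <- (on_other && d <= cfg$d_near) ||
      (d >= cfg$ring_inner && d <= cfg$ring_outer)
    expect_true(ok, info = sprintf("negative click %d at distance %.1f", i, d))
  }
})

test_that("initial sampling is deterministic given a seed", {
  sc <- tiny_scene(5)
  a <- sample_initial(sc, 1, sim_config(), seed = 99)
  b <- sample_initial(sc, 1, sim_config(), seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("a missing object is reported", {
  sc <- tiny_scene(5)
  expect_error(sample_initial(sc, 42, sim_config()), "absent")
})

test_that("identical masks yield no error regions", {
  m <- random_binary_mask(16, 16)
  expect_length(find_error_regions(m, m), 0)
})

test_that("separated missing corners become separate unit regions", {
  gt <- matrix(FALSE, 9, 9); gt[3:7, 3:7] <- TRUE
  pred <- gt; pred[3, 3] <- FALSE; pred[7, 7] <- FALSE
  regs <- find_error_regions(pred, gt)
  expect_length(regs, 2)
  expect_true(all(vapply(regs, `[[`, character(1), "kind") ==
                    "false_negative"))
  expect_true(all(vapply(regs, `[[`, numeric(1), "size") == 1))
})

test_that("error regions match an independent flood fill and conserve pixels", {
  set.seed(17)
  for (rep in 1:20) {
    pred <- random_binary_mask(32, 32, 0.4)
    gt <- random_binary_mask(32, 32, 0.4)
    regs <- find_error_regions(pred, gt)
    # conservation: region sizes partition the symmetric difference
    expect_equal(sum(vapply(regs, `[[`, numeric(1), "size")),
                 sum(xor(pred, gt)))
    # oracle: flood-fill components of each error kind
    for (kind in c("false_negative", "false_positive")) {
      err <- if (kind == "false_negative") gt & !pred else pred & !gt
      lab <- flood_fill_label(err)
      mine <- regs[vapply(regs, `[[`, character(1), "kind") == kind]
      expect_length(mine, max(lab))
      got <- lapply(mine, function(r)
        sort((r$pixels[, 2] - 1L) * 32L + r$pixels[, 1]))
      want <- lapply(seq_len(max(lab)), function(k) sort(which(lab == k)))
      expect_setequal(vapply(got, paste, character(1), collapse = ","),
                      vapply(want, paste, character(1), collapse = ","))
    }
  }
})

test_that("shape mismatch is an error", {
  expect_error(find_error_regions(matrix(TRUE, 3, 3), matrix(TRUE, 4, 4)),
               "identical shapes")
})

test_that("a single region with budget one yields one click inside it", {
  gt <- matrix(FALSE, 12, 12); gt[4:8, 4:8] <- TRUE
  regs <- find_error_regions(matrix(FALSE, 12, 12), gt)
  expect_length(regs, 1)
  cs <- sample_corrections(regs, 19, sim_config(), seed = 1)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$polarity, "positive")
  expect_true(gt[cs$row, cs$col])
})

test_that("false positives draw negative corrections", {
  pred <- matrix(FALSE, 10, 10); pred[2:4, 2:4] <- TRUE
  regs <- find_error_regions(pred, matrix(FALSE, 10, 10))
  cs <- sample_corrections(regs, 0, sim_config(), seed = 2)
  expect_equal(cs$polarity, "negative")
  expect_true(pred[cs$row, cs$col])
})

test_that("region choice is proportional to region size", {
  # two regions of 90 and 10 pixels; P(select first) = 0.9
  gt <- matrix(FALSE, 30, 30)
  gt[1:9, 1:10] <- TRUE          # 90 px
  gt[20:29, 25] <- TRUE          # 10 px
  regs <- find_error_regions(matrix(FALSE, 30, 30), gt)
  expect_length(regs, 2)
  sizes <- vapply(regs, `[[`, numeric(1), "size")
  big <- which.max(sizes)
  n <- 10000
  hits <- 0
  set.seed(123)
  for (i in seq_len(n)) {
    cs <- sample_corrections(regs, 19, sim_config())
    if (gt[cs$row, cs$col] && regs[[big]]$size == 90 &&
        cs$row <= 9) hits <- hits + 1
  }
  # binomial: 0.9 +/- 3.5 sd = 0.9 +/- 0.0105
  expect_gt(hits / n, 0.9 - 0.0105)
  expect_lt(hits / n, 0.9 + 0.0105)
})

test_that("corrections never exceed the click cap and stay in regions", {
  set.seed(19)
  for (rep in 1:25) {
    pred <- random_binary_mask(24, 24, 0.35)
    gt <- random_binary_mask(24, 24, 0.35)
    regs <- find_error_regions(pred, gt)
    if (length(regs) == 0) next
    existing <- sample(0:19, 1)
    cfg <- sim_config(R_max = sample(1:4, 1))
    cs <- sample_corrections(regs, existing, cfg)
    expect_lte(existing + nrow(cs), cfg$cap)
    expect_lte(nrow(cs), min(cfg$R_max, length(regs)))
    all_px <- do.call(rbind, lapply(regs, function(r)
      cbind(r$pixels, fn = r$kind == "false_negative")))
    for (i in seq_len(nrow(cs))) {
      hit <- all_px[all_px[, 1] == cs$row[i] & all_px[, 2] == cs$col[i], ,
                    drop = FALSE]
      expect_equal(nrow(hit), 1)
      expect_equal(cs$polarity[i] == "positive", unname(hit[1, 3] == 1))
    }
  }
})

test_that("an exhausted budget is an error", {
  gt <- matrix(FALSE, 8, 8); gt[2:4, 2:4] <- TRUE
  regs <- find_error_regions(matrix(FALSE, 8, 8), gt)
  expect_error(sample_corrections(regs, 20, sim_config()), "budget")
  expect_error(sample_corrections(list(), 0, sim_config()), "no error")
})

test_that("a perfect backend ends the session at one click", {
  sc <- tiny_scene(20)
  rec <- simulate_session(sc, 1, oracle_backend(), sim_config(), seed = 1)
  expect_equal(rec$clicks_to_target, 1L)
  expect_true(rec$reached)
  expect_equal(rec$steps$iou[1], 1)
})

test_that("a hopeless backend runs to the cap", {
  sc <- tiny_scene(21)
  rec <- simulate_session(sc, 1, empty_backend(), sim_config(), seed = 1)
  expect_equal(rec$clicks_to_target, 20L)
  expect_false(rec$reached)
  expect_true(all(diff(rec$steps$clicks) > 0))
  expect_lte(max(rec$steps$clicks), 20)
})

test_that("sessions are reproducible under a fixed seed", {
  sc <- tiny_scene(22)
  pr <- make_prior(sc, prior_noise(0.5, 2, 0.02, seed = 3))
  a <- simulate_session(sc, 2, threshold_backend(), sim_config(),
                        prior = pr, seed = 7)
  b <- simulate_session(sc, 2, threshold_backend(), sim_config(),
                        prior = pr, seed = 7)
  expect_identical(a$steps, b$steps)
  expect_identical(as.data.frame(a$clicks), as.data.frame(b$clicks))
  expect_identical(a$clicks_to_target, b$clicks_to_target)
})

test_that("session clicks stay in bounds and counts stay in [1, cap]", {
  for (seed in 1:4) {
    sc <- tiny_scene(seed + 30)
    pr <- make_prior(sc, prior_noise(0.5, 2, 0.05, seed = seed))
    rec <- simulate_session(sc, 1, threshold_backend(), sim_config(),
                            prior = pr, seed = seed)
    expect_gte(rec$clicks_to_target, 1)
    expect_lte(rec$clicks_to_target, 20)
    expect_true(all(rec$clicks$row >= 1 & rec$clicks$row <= 64 &
                      rec$clicks$col >= 1 & rec$clicks$col <= 64))
    expect_true(all(rec$steps$iou >= 0 & rec$steps$iou <= 1))
  }
})
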