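#' Configuration for simulated-user interaction
#'
#' Bundles the interaction protocol's parameters: the total click budget
#' (cap), the minimum spacing between sampled positive clicks, the IoU
#' target that ends a session, and how many error regions receive a
#' corrective click per refinement round.
#'
#' @param cap total click budget per object (default 20).
#' @param d_step minimum Euclidean spacing in pixels between sampled
#'   positive clicks (default 10).
#' @param iou_target session success threshold (default 0.85).
#' @param R_max maximum number of error regions corrected per round
#'   (default 1: the evaluation protocol adds one click per iteration;
#'   training uses larger values).
#' @param d_near radius in pixels defining "close to or touching" other
#'   objects for negative-click placement (default 10).
#' @param ring_inner,ring_outer the ring around the target object, in
#'   pixels of distance to the object, where remaining negative clicks
#'   are placed (defaults 5 and 30).
#' @param encoder guidance encoding fed to backends, `"gaussian"`
#'   (default) or `"distance"`.
#' @param sigma Gaussian encoding bandwidth (pixels).
#' @param clip distance encoding clip.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(cap = 20L, d_step = 10, iou_target = 0.85,
                       R_max = 1L, d_near = 10, ring_inner = 5,
                       ring_outer = 30,
                       encoder = c("gaussian", "distance"),
                       sigma = 10, clip = 255) {
  encoder <- match.arg(encoder)
  stopifnot(cap >= 1, d_step >= 1, iou_target > 0, iou_target <= 1,
            R_max >= 1, ring_inner >= 0, ring_outer > ring_inner)
  structure(list(cap = as.integer(cap), d_step = d_step,
                 iou_target = iou_target, R_max = as.integer(R_max),
                 d_near = d_near, ring_inner = ring_inner,
                 ring_outer = ring_outer, encoder = encoder,
                 sigma = sigma, clip = clip),
            class = "sim_config")
}

# Most interior pixel(s) of a logical mask: maxima of the distance
# transform to the mask's complement; one is drawn at random among
# co-maximal pixels.
most_interior <- function(mask) {
  stopifnot(any(mask))
  dm <- EBImage::distmap(mask * 1)
  mx <- max(dm)
  cand <- which(dm == mx)
  px <- if (length(cand) == 1) cand else sample(cand, 1)
  c(row = ((px - 1) %% nrow(mask)) + 1L,
    col = ((px - 1) %/% nrow(mask)) + 1L)
}

# Euclidean distance from every pixel to the nearest TRUE pixel of mask.
dist_to_mask <- function(mask) {
  EBImage::distmap((!mask) * 1)
}

#' Sample the initial click budget on an object
#'
#' Draws `n` positive and `m = cap - n` negative clicks (`n` uniform on
#' 1..cap) until the total budget is spent. The first positive click is
#' taken in the object's centre (a maximum of the interior distance
#' transform); later positives are uniform over object pixels at least
#' `d_step` away from all previously sampled positives. Negative clicks
#' go first onto other objects close to or touching the target (within
#' `d_near` of it), and the remainder into a ring around the object
#' between `ring_inner` and `ring_outer` pixels of distance. When one
#' polarity runs out of feasible placements its shortfall is reallocated
#' to the other, so exactly `cap` clicks are returned unless both
#' feasible sets are exhausted.
#'
#' @param scene a [generate_scene()] scene.
#' @param object_id id of the object of interest in `instance_mask`.
#' @param cfg a [sim_config()].
#' @param seed optional integer seed for reproducible sampling.
#' @return a [click_set()]; every positive click lies on the object.
#' @export
sample_initial <- function(scene, object_id, cfg = sim_config(),
                           seed = NULL) {
  obj <- scene$instance_mask == object_id
  if (!any(obj)) stop(sprintf("object %s absent from scene", object_id),
                      call. = FALSE)
  with_seed(seed, {
    n <- sample.int(cfg$cap, 1)                 # positives; n >= 1
    m <- cfg$cap - n
    pos <- sample_positives(obj, n, cfg$d_step)
    m <- m + (n - nrow(pos))                    # reallocate shortfall
    neg <- sample_negatives(scene, object_id, m, cfg)
    # negatives exhausted: try to refill with more positives
    short <- m - nrow(neg)
    if (short > 0) {
      extra <- sample_positives(obj, nrow(pos) + short, cfg$d_step,
                                already = pos)
      pos <- extra
    }
    click_set(c(pos$row, neg$row), c(pos$col, neg$col),
              c(rep("positive", nrow(pos)), rep("negative", nrow(neg))))
  })
}

# positives: centre-first then d_step-separated uniform draws
sample_positives <- function(obj, n, d_step, already = NULL) {
  h <- nrow(obj); w <- ncol(obj)
  rows <- integer(0); cols <- integer(0)
  mind <- matrix(Inf, h, w)                    # min distance to chosen positives
  if (!is.null(already) && nrow(already) > 0) {
    rows <- already$row; cols <- already$col
    for (i in seq_along(rows))
      mind <- pmin(mind, sqrt(.d2_to_click(c(h, w), rows[i], cols[i])))
  }
  while (length(rows) < n) {
    if (length(rows) == 0) {
      p <- most_interior(obj)
    } else {
      cand <- which(obj & mind >= d_step)
      if (length(cand) == 0) break
      px <- if (length(cand) == 1) cand else sample(cand, 1)
      p <- c(((px - 1) %% h) + 1L, ((px - 1) %/% h) + 1L)
    }
    rows <- c(rows, p[1]); cols <- c(cols, p[2])
    mind <- pmin(mind, sqrt(.d2_to_click(c(h, w), p[1], p[2])))
  }
  data.frame(row = rows, col = cols)
}

sample_negatives <- function(scene, object_id, m, cfg) {
  if (m <= 0) return(data.frame(row = integer(0), col = integer(0)))
  obj <- scene$instance_mask == object_id
  d2o <- dist_to_mask(obj)
  near <- which(scene$instance_mask > 0 & !obj & d2o <= cfg$d_near)
  ring <- which(!obj & d2o >= cfg$ring_inner & d2o <= cfg$ring_outer)
  ring <- setdiff(ring, near)
  take <- function(cand, k) {
    if (k <= 0 || length(cand) == 0) return(integer(0))
    if (length(cand) == 1) return(if (k >= 1) cand else integer(0))
    sample(cand, min(k, length(cand)))
  }
  sel <- take(near, m)
  sel <- c(sel, take(ring, m - length(sel)))
  h <- nrow(obj)
  data.frame(row = ((sel - 1) %% h) + 1L, col = ((sel - 1) %/% h) + 1L)
}

#' Partition prediction errors into connected regions
#'
#' Incorrect pixels are grouped into 4-connected components, separately
#' for false negatives (object pixels the prediction missed) and false
#' positives (predicted pixels outside the object). The union of all
#' region pixel sets is exactly the symmetric difference of the masks.
#'
#' @param pred,gt binary (logical or 0/1) matrices of identical shape.
#' @return a list of error regions, each a list with `kind`
#'   (`"false_negative"` or `"false_positive"`), `pixels` (an `n x 2`
#'   matrix of row/col coordinates) and `size`.
#' @export
find_error_regions <- function(pred, gt) {
  stop_if_not_matrix_pair(pred, gt)
  pred <- pred > 0; gt <- gt > 0
  regions_of <- function(mask, kind) {
    if (!any(mask)) return(list())
    lab <- EBImage::bwlabel(mask * 1)
    lapply(seq_len(max(lab)), function(k) {
      px <- which(lab == k)
      coords <- cbind(row = ((px - 1) %% nrow(mask)) + 1L,
                      col = ((px - 1) %/% nrow(mask)) + 1L)
      list(kind = kind, pixels = coords, size = nrow(coords))
    })
  }
  c(regions_of(gt & !pred, "false_negative"),
    regions_of(pred & !gt, "false_positive"))
}

#' Sample corrective clicks on error regions
#'
#' Draws `R` regions without replacement with probability proportional
#' to region size (`R` at most `R_max`, the number of regions, and the
#' remaining click budget), then places one click in each selected
#' region at its most interior pixel (ties broken at random). Missed
#' object regions receive positive clicks; spurious prediction regions
#' receive negative clicks. The total click count never exceeds the cap.
#'
#' @param regions output of [find_error_regions()]; must be non-empty.
#' @param existing_n number of clicks already placed (must be < cap).
#' @param cfg a [sim_config()].
#' @param seed optional integer seed.
#' @param existing optional [click_set()] of clicks already placed;
#'   already-clicked pixels are avoided so refinement always adds new
#'   information.
#' @return a [click_set()] of the added clicks (length `K = R`, one per
#'   selected region, every click inside its region).
#' @export
sample_corrections <- function(regions, existing_n, cfg = sim_config(),
                               seed = NULL, existing = NULL) {
  if (length(regions) == 0) stop("no error regions to correct", call. = FALSE)
  budget <- cfg$cap - existing_n
  if (budget < 1) stop("click budget exhausted", call. = FALSE)
  with_seed(seed, {
    R <- min(cfg$R_max, length(regions), budget)
    sizes <- vapply(regions, `[[`, numeric(1), "size")
    idx <- if (length(regions) == 1) 1L
           else sample.int(length(regions), R, prob = sizes)
    rows <- integer(0); cols <- integer(0); pol <- character(0)
    for (i in seq_len(R)) {
      reg <- regions[[idx[i]]]
      # most interior pixel of the region among pixels not yet clicked,
      # random among co-maximal
      hs <- max(reg$pixels[, 1]) - min(reg$pixels[, 1]) + 3L
      ws <- max(reg$pixels[, 2]) - min(reg$pixels[, 2]) + 3L
      r0 <- min(reg$pixels[, 1]) - 2L; c0 <- min(reg$pixels[, 2]) - 2L
      m <- matrix(FALSE, hs, ws)
      m[cbind(reg$pixels[, 1] - r0, reg$pixels[, 2] - c0)] <- TRUE
      dm <- EBImage::distmap(m * 1)
      if (!is.null(existing) && nrow(existing) > 0) {
        er <- existing$row - r0; ec <- existing$col - c0
        ok <- er >= 1 & er <= hs & ec >= 1 & ec <= ws
        dm[cbind(er[ok], ec[ok])] <- 0
      }
      if (max(dm) == 0) next                  # region fully clicked already
      cand <- which(dm == max(dm))
      px <- if (length(cand) == 1) cand else sample(cand, 1)
      rows <- c(rows, ((px - 1) %% hs) + 1L + r0)
      cols <- c(cols, ((px - 1) %/% hs) + 1L + c0)
      pol <- c(pol, if (reg$kind == "false_negative") "positive"
                    else "negative")
    }
    click_set(rows, cols, pol)
  })
}

#' Run a full simulated interactive-refinement session
#'
#' Starts from a single positive click at the object's centre, predicts,
#' then alternates corrective-click sampling on the current error
#' regions with re-prediction, until the IoU target is reached or the
#' click budget is spent. IoU is always computed at full frame. Guidance
#' maps use the configured encoder; when the negative click set is
#' empty the backend receives a blank negative map.
#'
#' @param scene a [generate_scene()] scene.
#' @param object_id the object of interest.
#' @param backend a backend object (see [backend_predict()]); it is
#'   bound to the scene first.
#' @param cfg a [sim_config()].
#' @param prior a [make_prior()] `semantic_prior`, or `NULL` to run
#'   without a prior (the backend then receives [blank_prior()]).
#' @param seed optional integer seed; a fixed seed, scene and backend
#'   give an identical session.
#' @return an object of class `session_record`: list with `object_id`,
#'   `steps` (data frame of cumulative `clicks`, `iou`, `pred_hash`),
#'   `clicks_to_target` (capped at `cfg$cap`) and `reached`.
#' @export
simulate_session <- function(scene, object_id, backend,
                             cfg = sim_config(), prior = NULL,
                             seed = NULL) {
  backend <- backend_bind(backend, scene)
  gt <- scene$instance_mask == object_id
  if (!any(gt)) stop(sprintf("object %s absent from scene", object_id),
                     call. = FALSE)
  shape <- dim(gt)
  with_seed(seed, {
    clicks <- {
      p <- most_interior(gt)
      click_set(p[1], p[2], "positive")
    }
    steps <- data.frame(clicks = integer(0), iou = numeric(0),
                        pred_hash = character(0))
    repeat {
      prior_channel <- if (is.null(prior)) blank_prior(shape)
                       else select_channel(prior, clicks)$channel
      pred <- predict_for_clicks(backend, scene, clicks, prior_channel, cfg)
      cur_iou <- iou(pred, gt)
      steps <- rbind(steps, data.frame(
        clicks = nrow(clicks), iou = cur_iou,
        pred_hash = cheap_hash(pred)))
      if (cur_iou >= cfg$iou_target || nrow(clicks) >= cfg$cap) break
      regions <- find_error_regions(pred, gt)
      if (length(regions) == 0) break
      add <- sample_corrections(regions, nrow(clicks), cfg,
                                existing = clicks)
      if (nrow(add) == 0) break              # every error pixel clicked
      clicks <- append_clicks(clicks, add)
    }
    first <- which(steps$iou >= cfg$iou_target)
    reached <- length(first) > 0
    structure(list(object_id = object_id,
                   steps = steps,
                   clicks = clicks,
                   clicks_to_target = if (reached)
                     as.integer(steps$clicks[first[1]]) else cfg$cap,
                   reached = reached,
                   cfg = cfg),
              class = "session_record")
  })
}

# encode the current click set and query the backend; returns the binary mask
predict_for_clicks <- function(backend, scene, clicks, prior_channel, cfg) {
  shape <- dim(scene$instance_mask)
  pos <- filter_clicks(clicks, "positive")
  neg <- filter_clicks(clicks, "negative")
  enc <- function(cs) {
    if (cfg$encoder == "gaussian") encode_gaussian(cs, shape, cfg$sigma)
    else encode_distance(cs, shape, cfg$clip)
  }
  input <- backend_input(image = scene$image,
                         pos_guidance = enc(pos), neg_guidance = enc(neg),
                         prior_channel = prior_channel, clicks = clicks,
                         clip = cfg$clip)
  backend_predict(backend, input)$mask
}

cheap_hash <- function(mask) {
  v <- which(mask > 0)
  sprintf("%d-%.0f-%.0f", length(v), sum(v), sum(as.double(v) * seq_along(v)) %% 1e9)
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> object %s: %s at %d clicks (final IoU %.3f)\n",
              x$object_id,
              if (x$reached) "target reached" else "target not reached",
              x$clicks_to_target, utils::tail(x$steps$iou, 1)))
  invisible(x)
}
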