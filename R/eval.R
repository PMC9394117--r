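#' Intersection over union
#'
#' `|pred & gt| / |pred | gt|` between two binary masks. Both empty
#' masks give 1 (nothing to segment, nothing segmented); exactly one
#' empty mask gives 0.
#'
#' @param pred,gt binary (logical or 0/1) matrices of identical shape.
#' @return a number in \[0, 1\]; symmetric in its arguments.
#' @examples
#' iou(matrix(c(1, 1, 0, 0), 2), matrix(c(0, 1, 1, 1), 2))  # 1/4
#' @export
iou <- function(pred, gt) {
  stop_if_not_matrix_pair(pred, gt)
  pred <- pred > 0; gt <- gt > 0
  u <- sum(pred | gt)
  if (u == 0) return(1)
  sum(pred & gt) / u
}

#' Mean clicks to an IoU threshold
#'
#' For each session, the first cumulative click count whose IoU meets
#' the threshold; sessions that never meet it count the cap. The
#' arithmetic mean over sessions is the protocol's headline number
#' (clicks@threshold).
#'
#' @param records a list of `session_record`s (see
#'   [simulate_session()]); must be non-empty.
#' @param threshold IoU threshold (default 0.85).
#' @param cap click cap (default 20).
#' @return the mean click count, in \[1, cap\].
#' @export
clicks_at_threshold <- function(records, threshold = 0.85, cap = 20L) {
  if (length(records) == 0) stop("no session records", call. = FALSE)
  per <- vapply(records, function(r) {
    hit <- which(r$steps$iou >= threshold)
    if (length(hit) > 0) as.numeric(r$steps$clicks[hit[1]]) else as.numeric(cap)
  }, numeric(1))
  mean(per)
}

#' Mean-IoU-versus-clicks curve
#'
#' For each click count `k` in `1..cap`, the mean over sessions of the
#' IoU achieved with at most `k` clicks, carrying a session's last
#' value forward once it stops adding clicks. Sessions record at least
#' the single-click step, so the curve is defined everywhere.
#'
#' @inheritParams clicks_at_threshold
#' @return a data frame with columns `clicks` and `mean_iou`.
#' @export
miou_curve <- function(records, cap = 20L) {
  if (length(records) == 0) stop("no session records", call. = FALSE)
  per <- vapply(records, function(r) {
    vapply(seq_len(cap), function(k) {
      i <- which(r$steps$clicks <= k)
      if (length(i) == 0) 0 else r$steps$iou[max(i)]
    }, numeric(1))
  }, numeric(cap))
  data.frame(clicks = seq_len(cap),
             mean_iou = if (is.matrix(per)) rowMeans(per) else per)
}

#' Evaluate a backend over every object of a scene set
#'
#' Runs a [simulate_session()] for every object of every scene and
#' assembles the protocol report: all session records, the mean clicks
#' to the IoU threshold, and the mIoU-versus-clicks curve.
#'
#' @param scenes list of [generate_scene()] scenes.
#' @param backend a backend object.
#' @param cfg a [sim_config()].
#' @param prior_mode `"with_prior"` (priors built from each scene with
#'   `noise`) or `"blank"` (every object runs on [blank_prior()]).
#' @param noise a [prior_noise()] used when `prior_mode = "with_prior"`.
#' @param seed base seed; object `k` of scene `i` uses a seed derived
#'   from it, so two runs (or two arms sharing `seed`) see identical
#'   randomness.
#' @return an object of class `eval_report`: list with `records`,
#'   `mean_clicks`, `curve` and `config` (threshold, cap, prior mode,
#'   seed).
#' @export
evaluate_backend <- function(scenes, backend, cfg = sim_config(),
                             prior_mode = c("with_prior", "blank"),
                             noise = prior_noise(softness = 0.5, jitter = 2,
                                                 confusion = 0.02),
                             seed = 1L) {
  prior_mode <- match.arg(prior_mode)
  stopifnot(length(scenes) >= 1)
  records <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    prior <- if (prior_mode == "with_prior")
      make_prior(sc, prior_noise(noise$softness, noise$jitter,
                                 noise$confusion, child_seed(seed, i)))
    else NULL
    for (k in seq_along(sc$object_classes)) {
      rec <- simulate_session(sc, k, backend, cfg, prior = prior,
                              seed = child_seed(seed, i * 1000L + k))
      rec$scene <- i
      records[[length(records) + 1L]] <- rec
    }
  }
  structure(list(records = records,
                 mean_clicks = clicks_at_threshold(records,
                                                   cfg$iou_target, cfg$cap),
                 curve = miou_curve(records, cfg$cap),
                 config = list(threshold = cfg$iou_target, cap = cfg$cap,
                               prior_mode = prior_mode, seed = seed)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> %d sessions, prior mode '%s': ",
                     "mean clicks @ IoU>=%.2f = %.2f\n"),
              length(x$records), x$config$prior_mode, x$config$threshold,
              x$mean_clicks))
  invisible(x)
}

#' Plot the mIoU-versus-clicks curve
#' @param x an `eval_report`.
#' @param ... passed to [plot()].
#' @export
plot.eval_report <- function(x, ...) {
  plot(x$curve$clicks, x$curve$mean_iou, type = "b", pch = 16,
       xlab = "number of clicks", ylab = "mean IoU",
       ylim = c(0, 1), ...)
  graphics::abline(h = x$config$threshold, lty = 2, col = "grey50")
  invisible(x)
}

#' Paired comparison of prior modes
#'
#' Evaluates the same scenes and backend twice — once with semantic
#' priors, once with the blank prior — under common random numbers
#' (identical derived seeds in both arms), and pairs the per-object
#' click counts. This isolates the effect of the semantic prior on the
#' number of clicks required.
#'
#' @inheritParams evaluate_backend
#' @return an object of class `prior_mode_comparison`: list with the
#'   two `eval_report`s (`with_prior`, `blank`), a `paired` data frame
#'   (scene, object, clicks in each arm) and the two means.
#' @export
compare_prior_modes <- function(scenes, backend, cfg = sim_config(),
                                noise = prior_noise(softness = 0.5,
                                                    jitter = 2,
                                                    confusion = 0.02),
                                seed = 1L) {
  with_rep <- evaluate_backend(scenes, backend, cfg, "with_prior", noise,
                               seed)
  blank_rep <- evaluate_backend(scenes, backend, cfg, "blank", noise, seed)
  stopifnot(length(with_rep$records) == length(blank_rep$records))
  paired <- data.frame(
    scene = vapply(with_rep$records, `[[`, numeric(1), "scene"),
    object = vapply(with_rep$records, function(r) as.numeric(r$object_id),
                    numeric(1)),
    clicks_with_prior = vapply(with_rep$records, `[[`, numeric(1),
                               "clicks_to_target"),
    clicks_blank = vapply(blank_rep$records, `[[`, numeric(1),
                          "clicks_to_target"))
  structure(list(with_prior = with_rep, blank = blank_rep, paired = paired,
                 mean_with_prior = with_rep$mean_clicks,
                 mean_blank = blank_rep$mean_clicks),
            class = "prior_mode_comparison")
}

#' @export
print.prior_mode_comparison <- function(x, ...) {
  cat(sprintf(paste0("<prior_mode_comparison> %d paired sessions: mean ",
                     "clicks with prior %.2f vs blank %.2f\n"),
              nrow(x$paired), x$mean_with_prior, x$mean_blank))
  invisible(x)
}
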