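#' Training configuration for the trainable backend
#'
#' Defaults mirror the full-scale training recipe: 50 epochs, batch
#' size 5, initial learning rate 1e-4 with exponential decay of 0.9
#' every 5 epochs floored at 5e-7, random reset of the prior channel to
#' a blank mask, a bootstrapped cross-entropy loss over the hardest
#' pixels, and iterative refreshing of the simulated clicks against the
#' model's own predictions. The desk-scale reference backend is a small
#' per-pixel network (see [train_backend()]) and is typically trained
#' with a larger `initial_lr` suited to its scale.
#'
#' @param epochs number of passes over the training scenes.
#' @param batch_size samples per gradient step.
#' @param initial_lr initial learning rate.
#' @param lr_decay_rate multiplicative decay applied once per
#'   `lr_decay_interval` epochs.
#' @param lr_decay_interval epochs between decay steps.
#' @param lr_floor minimum learning rate.
#' @param prior_reset_prob probability of replacing a sample's prior
#'   channel with a blank (all-zero) mask, keeping the model usable
#'   without semantic information.
#' @param bootstrap_fraction fraction of hardest pixels kept by the
#'   bootstrapped cross-entropy loss (0 < f <= 1).
#' @param correction_iterations corrective-click rounds per sample.
#' @param hidden_units width of the network's hidden layer.
#' @param seed integer seed; training is deterministic on one thread.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 5L, initial_lr = 1e-4,
                         lr_decay_rate = 0.9, lr_decay_interval = 5L,
                         lr_floor = 5e-7, prior_reset_prob = 0.3,
                         bootstrap_fraction = 0.25,
                         correction_iterations = 3L, hidden_units = 12L,
                         seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, initial_lr > 0,
            lr_decay_rate > 0, lr_decay_rate <= 1, lr_decay_interval >= 1,
            lr_floor >= 0, prior_reset_prob >= 0, prior_reset_prob <= 1,
            bootstrap_fraction > 0, bootstrap_fraction <= 1,
            correction_iterations >= 0, hidden_units >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, lr_decay_rate = lr_decay_rate,
                 lr_decay_interval = as.integer(lr_decay_interval),
                 lr_floor = lr_floor, prior_reset_prob = prior_reset_prob,
                 bootstrap_fraction = bootstrap_fraction,
                 correction_iterations = as.integer(correction_iterations),
                 hidden_units = as.integer(hidden_units),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' Exponential decay by `lr_decay_rate` once per `lr_decay_interval`
#' epochs, floored at `lr_floor`. Epochs are 0-based, so epoch 0 runs at
#' `initial_lr`.
#'
#' @param epoch 0-based epoch index (vectorised).
#' @param cfg a [train_config()].
#' @return the learning rate(s).
#' @examples
#' learning_rate(c(0, 5, 10), train_config())
#' @export
learning_rate <- function(epoch, cfg = train_config()) {
  pmax(cfg$initial_lr * cfg$lr_decay_rate^(epoch %/% cfg$lr_decay_interval),
       cfg$lr_floor)
}

#' Bootstrapped binary cross-entropy
#'
#' Mean of the per-pixel binary cross-entropy over the
#' `ceiling(fraction * N)` highest-loss pixels. Probabilities are
#' clamped to `[eps, 1 - eps]` so the loss is always finite. With
#' `fraction = 1` this is the plain mean binary cross-entropy.
#'
#' @param prob predicted probabilities (any numeric array).
#' @param gt binary ground truth of identical shape.
#' @param fraction bootstrap fraction in (0, 1].
#' @param eps clamp (default 1e-7).
#' @return a scalar loss.
#' @export
bootstrapped_ce_loss <- function(prob, gt, fraction = 0.25, eps = 1e-7) {
  stopifnot(fraction > 0, fraction <= 1, length(prob) == length(gt),
            length(prob) > 0)
  p <- pmin(pmax(as.numeric(prob), eps), 1 - eps)
  y <- as.numeric(gt > 0)
  ce <- -(y * log(p) + (1 - y) * log(1 - p))
  k <- ceiling(fraction * length(ce))
  mean(sort(ce, decreasing = TRUE)[seq_len(k)])
}

# ---------------------------------------------------------------------
# Pixel-MLP reference backend: a small fully convolutional model whose
# only learned layers are 1x1 (a per-pixel MLP over fixed multi-scale
# colour features plus the guidance and prior channels).

N_COLOR_FEATS <- 6L   # RGB at two smoothing scales
N_FEATS <- N_COLOR_FEATS + 3L   # + pos guidance, neg guidance, prior

color_features <- function(image, sigmas = c(1, 4)) {
  f <- lapply(sigmas, function(s) {
    sm <- smooth_image(image, s)
    cbind(as.vector(sm[, , 1]), as.vector(sm[, , 2]), as.vector(sm[, , 3]))
  })
  do.call(cbind, f)
}

assemble_features <- function(color_f, pos_scaled, neg_scaled, prior_channel) {
  cbind(color_f, as.vector(pos_scaled), as.vector(neg_scaled),
        as.vector(prior_channel))
}

mlp_init <- function(n_feats, hidden, seed) {
  with_seed(seed, list(
    W1 = matrix(rnorm(n_feats * hidden, sd = 0.3), n_feats, hidden),
    b1 = rep(0, hidden),
    W2 = matrix(rnorm(hidden, sd = 0.3), hidden, 1),
    b2 = 0))
}

mlp_forward <- function(par, X) {
  z1 <- sweep(X %*% par$W1, 2, par$b1, "+")
  h <- tanh(z1)
  z2 <- as.vector(h %*% par$W2) + par$b2
  p <- 1 / (1 + exp(-z2))
  list(h = h, p = p)
}

# gradient of the bootstrapped CE wrt parameters (top-k selection fixed)
mlp_backward <- function(par, X, fwd, y, fraction, eps = 1e-7) {
  p <- pmin(pmax(fwd$p, eps), 1 - eps)
  ce <- -(y * log(p) + (1 - y) * log(1 - p))
  k <- ceiling(fraction * length(ce))
  sel <- order(ce, decreasing = TRUE)[seq_len(k)]
  dz2 <- numeric(length(p))
  dz2[sel] <- (fwd$p[sel] - y[sel]) / k
  dW2 <- crossprod(fwd$h, dz2)
  db2 <- sum(dz2)
  dh <- outer(dz2, as.vector(par$W2))       # N x H
  dz1 <- dh * (1 - fwd$h^2)
  list(W1 = crossprod(X, dz1), b1 = colSums(dz1),
       W2 = dW2, b2 = db2, loss = mean(ce[sel]))
}

adam_init <- function(par) {
  list(m = lapply(par, function(x) x * 0), v = lapply(par, function(x) x * 0),
       t = 0L)
}

adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in c("W1", "b1", "W2", "b2")) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grad[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

#' Train the pixel-MLP reference backend
#'
#' Iterative training with simulated users: for each sample an object
#' is drawn, a small random initial click budget is sampled with
#' [sample_initial()], and for `correction_iterations` rounds the
#' current model's prediction is corrected with [sample_corrections()]
#' and the encoded clicks refreshed; with probability
#' `prior_reset_prob` the sample's prior channel is replaced by zeros.
#' One gradient of the bootstrapped cross-entropy per sample is
#' accumulated over `batch_size` samples before an Adam step at the
#' scheduled learning rate. Fully deterministic given `cfg$seed` on one
#' thread.
#'
#' The model itself is a small fully convolutional network whose
#' learned layers are 1x1: a per-pixel MLP (one tanh hidden layer) over
#' fixed multi-scale smoothed colour features, the two guidance
#' channels and the prior channel.
#'
#' @param scenes a list of [generate_scene()] scenes.
#' @param cfg a [train_config()].
#' @param noise a [prior_noise()] describing the corruption of the
#'   training priors (emulating an imperfect offline semantic model).
#' @param sim a [sim_config()] used for click simulation during
#'   training (the click cap stays 20; several regions may be corrected
#'   per round).
#' @param trace print a line per epoch.
#' @param instrument optional function called per sample with the
#'   prior channel actually fed to the model (used to verify the random
#'   prior reset).
#' @return an object of class `c("seg_model", "backend")` with the
#'   learned parameters, `cfg`, and `log` (data frame with one row per
#'   epoch: `epoch`, `lr`, `loss`).
#' @export
train_backend <- function(scenes, cfg = train_config(),
                          noise = prior_noise(softness = 0.5, jitter = 2,
                                              confusion = 0.02),
                          sim = sim_config(R_max = 3L), trace = FALSE,
                          instrument = NULL) {
  stopifnot(length(scenes) >= 1)
  shape <- dim(scenes[[1]]$instance_mask)
  color_f <- lapply(scenes, function(s) color_features(s$image))
  priors <- lapply(seq_along(scenes), function(i)
    make_prior(scenes[[i]], prior_noise(noise$softness, noise$jitter,
                                        noise$confusion,
                                        child_seed(noise$seed, i))))
  par <- mlp_init(N_FEATS, cfg$hidden_units, cfg$seed)
  opt <- adam_init(par)
  log <- data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0))
  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- learning_rate(epoch - 1L, cfg)
      ord <- sample(seq_along(scenes))
      acc <- NULL; n_acc <- 0L; epoch_losses <- numeric(0)
      for (i in ord) {
        sc <- scenes[[i]]
        obj <- sample(seq_along(sc$object_classes), 1)
        gt <- as.numeric(sc$instance_mask == obj)
        use_prior <- runif(1) >= cfg$prior_reset_prob
        # small random initial budget leaves headroom for corrections
        init_cap <- sample(2:6, 1)
        clicks <- sample_initial(sc, obj,
                                 modifyList2(sim, list(cap = init_cap)))
        for (it in seq_len(cfg$correction_iterations)) {
          prior_channel <- training_prior_channel(priors[[i]], clicks,
                                                  use_prior, shape)
          X <- training_features(sc, color_f[[i]], clicks, prior_channel, sim)
          pred <- mlp_forward(par, X)$p >= 0.5
          regions <- find_error_regions(matrix(pred, shape[1], shape[2]),
                                        matrix(gt, shape[1], shape[2]))
          if (length(regions) == 0 || nrow(clicks) >= sim$cap) break
          add <- sample_corrections(regions, nrow(clicks), sim,
                                    existing = clicks)
          if (nrow(add) == 0) break
          clicks <- append_clicks(clicks, add)
        }
        prior_channel <- training_prior_channel(priors[[i]], clicks,
                                                use_prior, shape)
        if (!is.null(instrument)) instrument(prior_channel)
        X <- training_features(sc, color_f[[i]], clicks, prior_channel, sim)
        fwd <- mlp_forward(par, X)
        grad <- mlp_backward(par, X, fwd, gt, cfg$bootstrap_fraction)
        if (!is.finite(grad$loss))
          stop(sprintf("non-finite loss at epoch %d, scene %d", epoch, i),
               call. = FALSE)
        epoch_losses <- c(epoch_losses, grad$loss)
        acc <- if (is.null(acc)) grad
               else Map(function(a, b) a + b, acc, grad)
        n_acc <- n_acc + 1L
        if (n_acc == cfg$batch_size) {
          step <- adam_step(par, lapply(acc[c("W1", "b1", "W2", "b2")],
                                        function(g) g / n_acc),
                            opt, lr)
          par <- step$par; opt <- step$state
          acc <- NULL; n_acc <- 0L
        }
      }
      if (n_acc > 0) {
        step <- adam_step(par, lapply(acc[c("W1", "b1", "W2", "b2")],
                                      function(g) g / n_acc), opt, lr)
        par <- step$par; opt <- step$state
      }
      log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                   loss = mean(epoch_losses)))
      if (trace)
        message(sprintf("epoch %d/%d  lr %.3g  loss %.4f", epoch,
                        cfg$epochs, lr, mean(epoch_losses)))
    }
  })
  structure(list(par = par, cfg = cfg, sim = sim, noise = noise, log = log),
            class = c("seg_model", "backend"))
}

# prior channel for one training sample: blank on reset, else selected
training_prior_channel <- function(prior, clicks, use_prior, shape) {
  if (!use_prior) return(blank_prior(shape))
  sel <- select_channel(prior, clicks)
  sel$channel
}

training_features <- function(sc, color_f, clicks, prior_channel, sim) {
  shape <- dim(sc$instance_mask)
  pos <- filter_clicks(clicks, "positive")
  neg <- filter_clicks(clicks, "negative")
  enc <- function(cs) {
    g <- if (sim$encoder == "gaussian") encode_gaussian(cs, shape, sim$sigma)
         else encode_distance(cs, shape, sim$clip)
    scale_guidance(g, sim$clip)
  }
  assemble_features(color_f, enc(pos), enc(neg), prior_channel)
}

# modifyList for classed config lists, preserving the class
modifyList2 <- function(x, val) {
  out <- utils::modifyList(unclass(x), val)
  class(out) <- class(x)
  out
}

#' @export
backend_predict.seg_model <- function(backend, input, ...) {
  shape <- dim(input$image)[1:2]
  X <- assemble_features(color_features(input$image),
                         input$pos_scaled, input$neg_scaled,
                         input$prior_channel)
  p <- mlp_forward(backend$par, X)$p
  finish_prediction(matrix(p, shape[1], shape[2]))
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf(paste0("<seg_model> pixel-MLP backend: %d features, %d hidden",
                     " units; trained %d epochs (final loss %.4f)\n"),
              nrow(x$par$W1), ncol(x$par$W1), nrow(x$log),
              utils::tail(x$log$loss, 1)))
  invisible(x)
}

#' Save / load a trained backend
#'
#' Checkpoints are plain JSON (weights, config, seed manifest and the
#' training log), so they survive text-only pipelines.
#'
#' @param model a `seg_model`.
#' @param path file path.
#' @return `read_seg_model()` returns the restored `seg_model`.
#' @export
write_seg_model <- function(model, path) {
  obj <- list(par = lapply(model$par, function(x) {
                if (is.matrix(x)) list(dim = dim(x), data = as.vector(x))
                else list(dim = NULL, data = as.vector(x))
              }),
              cfg = unclass(model$cfg), sim = unclass(model$sim),
              noise = unclass(model$noise), log = model$log)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_seg_model
#' @export
read_seg_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  par <- lapply(obj$par, function(p) {
    if (length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  cfg <- structure(as.list(obj$cfg), class = "train_config")
  sim <- structure(as.list(obj$sim), class = "sim_config")
  structure(list(par = par, cfg = cfg, sim = sim,
                 noise = structure(as.list(obj$noise), class = "prior_noise"),
                 log = as.data.frame(obj$log)),
            class = c("seg_model", "backend"))
}

# training log export: epoch, lr, loss
#' Write the training log as CSV
#' @param model a `seg_model`.
#' @param path CSV path.
#' @export
write_training_log <- function(model, path) {
  utils::write.csv(model$log, path, row.names = FALSE)
  invisible(path)
}
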