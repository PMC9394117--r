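#' Assemble a backend input
#'
#' Every segmentation backend honours one contract: it receives the RGB
#' image, per-polarity click-guidance maps, and a single (possibly
#' blank) semantic-prior channel, all with equal spatial shape and
#' guidance/prior values in \[0, 1\] after scaling; it returns a
#' per-pixel object probability. The raw click set travels along for
#' backends (such as test doubles and the component-based baseline)
#' that need exact click pixels.
#'
#' @param image `H x W x 3` array in \[0, 1\].
#' @param pos_guidance,neg_guidance `guidance_map`s (see [guidance]).
#' @param prior_channel `H x W` prior matrix, possibly [blank_prior()].
#' @param clicks the [click_set()] the guidance encodes.
#' @param placement optional `window_placement` when inputs are cropped.
#' @param clip distance-encoding clip used for \[0, 1\] scaling.
#' @return an object of class `backend_input`.
#' @export
backend_input <- function(image, pos_guidance, neg_guidance, prior_channel,
                          clicks = NULL, placement = NULL, clip = 255) {
  shape <- dim(image)[1:2]
  for (g in list(pos_guidance, neg_guidance))
    if (!all(dim(g$values) == shape))
      stop("guidance shape does not match image", call. = FALSE)
  if (!all(dim(prior_channel) == shape))
    stop("prior channel shape does not match image", call. = FALSE)
  structure(list(image = image,
                 pos_guidance = pos_guidance, neg_guidance = neg_guidance,
                 pos_scaled = scale_guidance(pos_guidance, clip),
                 neg_scaled = scale_guidance(neg_guidance, clip),
                 prior_channel = prior_channel,
                 clicks = clicks, placement = placement),
            class = "backend_input")
}

#' Backend prediction contract
#'
#' `backend_predict()` maps a backend and a [backend_input()] to a list
#' with `prob` (`H x W` probabilities in \[0, 1\]) and `mask` (logical,
#' `prob >= 0.5`). Predictions are deterministic for fixed weights and
#' input. `backend_bind()` gives scene-aware backends (such as the
#' ground-truth oracle) access to the current scene; the default method
#' returns the backend unchanged.
#'
#' @param backend a backend object.
#' @param input a [backend_input()].
#' @param scene a [generate_scene()] scene.
#' @param ... unused.
#' @return `backend_predict()`: list with `prob` and `mask`;
#'   `backend_bind()`: a (possibly scene-bound) backend.
#' @export
backend_predict <- function(backend, input, ...) UseMethod("backend_predict")

#' @rdname backend_predict
#' @export
backend_bind <- function(backend, scene, ...) UseMethod("backend_bind")

#' @export
backend_bind.default <- function(backend, scene, ...) backend

finish_prediction <- function(prob, threshold = 0.5) {
  list(prob = prob, mask = prob >= threshold)
}

# ---------------------------------------------------------------------
# Ground-truth oracle backend (test double): returns the ground-truth
# mask of the object under the first positive click.

#' Reference backends
#'
#' Three fixed backends exercise the contract end-to-end:
#'
#' * `oracle_backend()` — a test double that, once bound to a scene,
#'   returns the ground-truth mask of the object under the first
#'   positive click. Any evaluation run with it yields
#'   `clicks_to_target = 1`.
#' * `empty_backend()` — always predicts the empty mask; every session
#'   runs to the click cap.
#' * `threshold_backend()` — the component-based baseline. With a
#'   non-blank prior it thresholds the selected prior channel at
#'   `prior_level`, labels the 4-connected components, keeps the
#'   components containing a positive click and removes components that
#'   contain a negative click and no positive one. With a blank prior it
#'   falls back to clicks-only seeded region growing on the (lightly
#'   smoothed) image: from each positive click it grows over
#'   4-connected pixels whose colour stays within `color_tol` of the
#'   seed's local mean colour, and removes the analogous growth from
#'   negative clicks.
#'
#' @param prior_level threshold on the prior channel (default 0.5).
#' @param color_tol Euclidean RGB tolerance of the region growing
#'   (default 0.12; conservative growth keeps the baseline refinable).
#' @param blur_sigma Gaussian smoothing applied to the image before
#'   region growing (pixels).
#' @return a backend object.
#' @name backends
NULL

#' @rdname backends
#' @export
oracle_backend <- function() {
  structure(list(scene = NULL), class = c("oracle_backend", "backend"))
}

#' @export
backend_bind.oracle_backend <- function(backend, scene, ...) {
  backend$scene <- scene
  backend
}

#' @export
backend_predict.oracle_backend <- function(backend, input, ...) {
  if (is.null(backend$scene))
    stop("oracle backend must be bound to a scene", call. = FALSE)
  pos <- filter_clicks(input$clicks, "positive")
  if (nrow(pos) == 0) stop("oracle backend needs a positive click",
                           call. = FALSE)
  id <- backend$scene$instance_mask[pos$row[1], pos$col[1]]
  prob <- (backend$scene$instance_mask == id & id > 0) * 1
  finish_prediction(prob)
}

#' @rdname backends
#' @export
empty_backend <- function() {
  structure(list(), class = c("empty_backend", "backend"))
}

#' @export
backend_predict.empty_backend <- function(backend, input, ...) {
  finish_prediction(matrix(0, dim(input$image)[1], dim(input$image)[2]))
}

#' @rdname backends
#' @export
threshold_backend <- function(prior_level = 0.5, color_tol = 0.12,
                              blur_sigma = 1) {
  structure(list(prior_level = prior_level, color_tol = color_tol,
                 blur_sigma = blur_sigma),
            class = c("threshold_backend", "backend"))
}

#' @export
backend_predict.threshold_backend <- function(backend, input, ...) {
  pos <- filter_clicks(input$clicks, "positive")
  neg <- filter_clicks(input$clicks, "negative")
  if (nrow(pos) == 0) stop("baseline backend needs a positive click",
                           call. = FALSE)
  shape <- dim(input$image)[1:2]
  mask <- matrix(FALSE, shape[1], shape[2])
  if (!is_blank_prior(input$prior_channel)) {
    cand <- input$prior_channel >= backend$prior_level
    mask <- keep_clicked_components(cand, pos, neg)
  }
  # positive clicks the prior route does not cover fall back to
  # colour-based region growing (this is the whole mask when no prior)
  outside <- pos[!mask[cbind(pos$row, pos$col)], , drop = FALSE]
  if (nrow(outside) > 0)
    mask <- mask | grow_from_clicks(input$image, outside,
                                    backend$color_tol, backend$blur_sigma)
  if (nrow(neg) > 0) {
    bad <- grow_from_clicks(input$image, neg, backend$color_tol,
                            backend$blur_sigma)
    if (any(mask & bad)) {
      mask <- mask & !bad
      # removal may disconnect; keep only parts still holding a positive
      mask <- keep_clicked_components(mask, pos, click_set())
    }
  }
  finish_prediction(mask * 1)
}

# components of cand containing a positive click, minus components that
# contain a negative click and no positive one
keep_clicked_components <- function(cand, pos, neg) {
  if (!any(cand)) return(matrix(FALSE, nrow(cand), ncol(cand)))
  lab <- EBImage::bwlabel(cand * 1)
  pos_labs <- unique(lab[cbind(pos$row, pos$col)])
  pos_labs <- pos_labs[pos_labs > 0]
  neg_labs <- if (nrow(neg) > 0) {
    nl <- unique(lab[cbind(neg$row, neg$col)])
    setdiff(nl[nl > 0], pos_labs)
  } else integer(0)
  keep <- setdiff(pos_labs, neg_labs)
  matrix(lab %in% keep, nrow(cand), ncol(cand))
}

smooth_image <- function(image, sigma) {
  if (sigma <= 0) return(image)
  out <- image
  for (ch in seq_len(dim(image)[3]))
    out[, , ch] <- EBImage::gblur(image[, , ch], sigma = sigma)
  out
}

# BFS colour region growing from click seeds (4-connected)
grow_from_clicks <- function(image, clicks, tol, blur_sigma) {
  img <- smooth_image(image, blur_sigma)
  h <- dim(img)[1]; w <- dim(img)[2]
  out <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(clicks))) {
    r0 <- clicks$row[i]; c0 <- clicks$col[i]
    # seed reference colour: 3x3 local mean
    rs <- max(1, r0 - 1):min(h, r0 + 1); cs <- max(1, c0 - 1):min(w, c0 + 1)
    ref <- apply(img[rs, cs, , drop = FALSE], 3, mean)
    dist2 <- (img[, , 1] - ref[1])^2 + (img[, , 2] - ref[2])^2 +
      (img[, , 3] - ref[3])^2
    ok <- dist2 <= tol^2
    ok[r0, c0] <- TRUE
    if (!any(ok)) next
    lab <- EBImage::bwlabel(ok * 1)
    out <- out | (lab == lab[r0, c0] & lab[r0, c0] > 0)
  }
  out
}

# ---------------------------------------------------------------------
# Backend registry: plug in alternative architectures by name.

backend_registry <- new.env(parent = emptyenv())

#' Backend registry
#'
#' Backends are pluggable: alternative architectures register a
#' constructor under a name and are instantiated with `make_backend()`.
#' The built-in entries are `"oracle"`, `"empty"`, `"threshold"` and
#' `"pixelmlp"` (the trainable reference backend; its constructor is
#' [train_backend()] and requires a training set).
#'
#' @param name backend name.
#' @param constructor a function returning a backend object.
#' @param ... passed to the constructor.
#' @return `make_backend()` returns a backend; `list_backends()` the
#'   registered names.
#' @export
register_backend <- function(name, constructor) {
  stopifnot(is.character(name), is.function(constructor))
  assign(name, constructor, envir = backend_registry)
  invisible(name)
}

#' @rdname register_backend
#' @export
list_backends <- function() sort(ls(backend_registry))

#' @rdname register_backend
#' @export
make_backend <- function(name, ...) {
  if (!exists(name, envir = backend_registry, inherits = FALSE))
    stop(sprintf("unknown backend '%s'; see list_backends()", name),
         call. = FALSE)
  get(name, envir = backend_registry)(...)
}
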