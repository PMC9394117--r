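#' Configuration for the synthetic scene generator
#'
#' Describes a synthetic multi-class instance scene in the style of in
#' vitro plant tissue culture imagery: a handful of tissue objects
#' (callus-, shoot- or stem-like regions) on a plain background, each
#' object belonging to one of `n_classes` tissue classes with a distinct
#' base colour plus additive pixel noise.
#'
#' @param height,width canvas size in pixels (>= 32).
#' @param n_objects number of objects to place (>= 1).
#' @param n_classes number of tissue classes C (>= 1); objects are
#'   assigned classes round-robin so that with `n_objects == n_classes`
#'   every object has its own class.
#' @param min_object_area minimum pixel area per object (>= 16).
#' @param shape_family `"blob"` (smooth random outline), `"lobed"`
#'   (adds higher-frequency lobes, callus-like) or `"elongated"`
#'   (stem-like anisotropy).
#' @param overlap_allowed may objects overlap? When `FALSE` (default)
#'   placements that overlap an existing object are rejected; touching is
#'   allowed.
#' @param noise_sd standard deviation of the additive Gaussian image
#'   noise (image values live in \[0, 1\]).
#' @param seed integer seed; scene generation is fully deterministic
#'   given the config.
#' @return an object of class `scene_config`.
#' @seealso [generate_scene()]
#' @export
scene_config <- function(height = 96, width = 96, n_objects = 3,
                         n_classes = 3, min_object_area = 64,
                         shape_family = c("blob", "lobed", "elongated"),
                         overlap_allowed = FALSE, noise_sd = 0.08,
                         seed = 1) {
  shape_family <- match.arg(shape_family)
  stopifnot(height >= 32, width >= 32, n_objects >= 1, n_classes >= 1,
            min_object_area >= 16, noise_sd >= 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_objects = as.integer(n_objects),
                 n_classes = as.integer(n_classes),
                 min_object_area = as.integer(min_object_area),
                 shape_family = shape_family,
                 overlap_allowed = isTRUE(overlap_allowed),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_config")
}

#' Deterministic class colour palette
#'
#' Class 1..3 use the tissue colours conventional in regeneration
#' imagery (stem blue-ish, callus red-ish, shoot green-ish); further
#' classes get deterministic distinct hues. Row 1 is the background
#' colour.
#'
#' @param n_classes number of tissue classes.
#' @return a `(n_classes + 1) x 3` matrix of RGB values in \[0, 1\];
#'   row `c + 1` is the colour of class `c`.
#' @export
class_palette <- function(n_classes) {
  base <- rbind(c(0.16, 0.16, 0.18),           # background
                c(0.25, 0.35, 0.80),           # stem
                c(0.80, 0.30, 0.22),           # callus
                c(0.25, 0.70, 0.30))           # shoot
  if (n_classes + 1 <= nrow(base)) return(base[seq_len(n_classes + 1), , drop = FALSE])
  extra <- t(sapply(seq_len(n_classes - 3), function(i) {
    grDevices::col2rgb(grDevices::hsv((0.11 + i * 0.381966) %% 1, 0.6, 0.8))[, 1] / 255
  }))
  rbind(base, extra)
}

default_class_names <- function(n_classes) {
  nm <- c("background", "stem", "callus", "shoot")
  if (n_classes + 1 <= length(nm)) return(nm[seq_len(n_classes + 1)])
  c(nm, paste0("class", 4:(n_classes)))
}

# Rasterize a star-convex outline: radius(theta) = r0 * modulation.
# Returns a logical matrix (the largest 4-connected component), or NULL
# if the shape is degenerate.
rasterize_shape <- function(h, w, cr, cc, r0, family) {
  # low-order Fourier modulation keeps outlines smooth and star-convex
  a <- runif(2, 0.05, 0.20); ph <- runif(2, 0, 2 * pi)
  lobe_amp <- if (family == "lobed") runif(1, 0.15, 0.30) else 0
  lobe_k <- sample(4:6, 1); lobe_ph <- runif(1, 0, 2 * pi)
  stretch <- if (family == "elongated") runif(1, 1.8, 2.6) else 1
  ang0 <- runif(1, 0, pi)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- rows - cr; dx <- cols - cc
  # rotate then stretch (elongation along a random axis)
  u <- cos(ang0) * dx + sin(ang0) * dy
  v <- -sin(ang0) * dx + cos(ang0) * dy
  u <- u / stretch; v <- v * sqrt(stretch)
  d <- sqrt(u^2 + v^2)
  th <- atan2(v, u)
  rad <- r0 * (1 + a[1] * sin(2 * th + ph[1]) + a[2] * sin(3 * th + ph[2]) +
                 lobe_amp * sin(lobe_k * th + lobe_ph))
  m <- d <= rad
  if (!any(m)) return(NULL)
  lab <- EBImage::bwlabel(m * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  lab == keep
}

#' Generate a synthetic multi-class instance scene
#'
#' Places `n_objects` random smooth tissue-like shapes on a canvas,
#' producing the ground-truth instance mask, semantic class mask and an
#' RGB rendering in which each class has a distinct base colour plus
#' additive Gaussian noise (so a trainable backend can learn class
#' appearance). Each object is a single 4-connected region of at least
#' `min_object_area` pixels.
#'
#' @param config a [scene_config()].
#' @param max_attempts placement attempts per object before giving up.
#' @return an object of class `scene`: a list with `image`
#'   (`H x W x 3` array in \[0, 1\]), `instance_mask` (`H x W` integer
#'   matrix, 0 = background), `semantic_mask` (`H x W` integer matrix of
#'   class ids, 0 = background), `object_classes` (named integer vector
#'   mapping object id to class id), `class_names`, and `config`.
#' @examples
#' sc <- generate_scene(scene_config(seed = 7))
#' table(sc$instance_mask)
#' @export
generate_scene <- function(config = scene_config(), max_attempts = 60) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, {
    h <- config$height; w <- config$width
    inst <- matrix(0L, h, w)
    sem <- matrix(0L, h, w)
    classes <- ((seq_len(config$n_objects) - 1L) %% config$n_classes) + 1L
    r_lo <- sqrt(2 * config$min_object_area / pi)
    r_hi <- max(r_lo + 1, min(h, w) / 6)
    for (k in seq_len(config$n_objects)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        r0 <- runif(1, r_lo, r_hi)
        margin <- ceiling(r0 * 1.8) + 1
        if (2 * margin >= min(h, w)) margin <- floor(min(h, w) / 2) - 1
        cr <- sample(seq(margin, h - margin), 1)
        cc <- sample(seq(margin, w - margin), 1)
        m <- rasterize_shape(h, w, cr, cc, r0, config$shape_family)
        if (is.null(m) || sum(m) < config$min_object_area) next
        if (!config$overlap_allowed && any(inst[m] > 0)) next
        inst[m] <- k
        sem[m] <- classes[k]
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf("could not place object %d (area >= %d) after %d attempts",
                     k, config$min_object_area, max_attempts), call. = FALSE)
    }
    # overlap_allowed scenes may bury an earlier object entirely
    for (k in seq_len(config$n_objects))
      if (!any(inst == k))
        stop(sprintf("object %d vanished under later placements", k),
             call. = FALSE)
    pal <- class_palette(config$n_classes)
    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      base <- matrix(pal[sem + 1L, ch], h, w)
      img[, , ch] <- pmin(1, pmax(0, base + rnorm(h * w, sd = config$noise_sd)))
    }
    structure(list(image = img, instance_mask = inst, semantic_mask = sem,
                   object_classes = stats::setNames(classes,
                                                    seq_len(config$n_objects)),
                   class_names = default_class_names(config$n_classes),
                   config = config),
              class = "scene")
  })
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %dx%d, %d objects, %d tissue classes (%s)\n",
              nrow(x$instance_mask), ncol(x$instance_mask),
              length(x$object_classes), x$config$n_classes,
              paste(x$class_names[-1], collapse = ", ")))
  invisible(x)
}

#' Corruption model for synthetic semantic priors
#'
#' Parameters emulating the imperfections of priors produced by an
#' offline semantic segmentation model: `softness` softens the one-hot
#' class encoding (per-pixel softmax temperature; argmax is preserved),
#' `jitter` displaces class boundaries by up to the given radius in
#' pixels, and `confusion` flips each pixel's class channel to a random
#' other class with the given probability.
#'
#' @param softness softmax temperature tau >= 0 (0 = hard one-hot).
#' @param jitter boundary-jitter radius in pixels (>= 0).
#' @param confusion per-pixel channel-confusion rate in \[0, 1\].
#' @param seed integer seed for the jitter/confusion randomness.
#' @return an object of class `prior_noise`.
#' @export
prior_noise <- function(softness = 0, jitter = 0, confusion = 0, seed = 1) {
  stopifnot(softness >= 0, jitter >= 0, confusion >= 0, confusion <= 1)
  structure(list(softness = softness, jitter = jitter,
                 confusion = confusion, seed = as.integer(seed)),
            class = "prior_noise")
}

#' Build a (possibly corrupted) semantic prior from a scene
#'
#' Emulates the multi-channel class probability maps of an offline
#' semantic model by corrupting the ground-truth semantic mask: boundary
#' jitter, channel confusion, then a per-pixel softmax softening. With
#' all noise parameters zero the per-pixel argmax over channels equals
#' `semantic_mask` exactly and channels are an exact one-hot encoding.
#'
#' @param scene a [generate_scene()] scene.
#' @param noise a [prior_noise()] specification.
#' @return an object of class `semantic_prior`: list with `channels`
#'   (`H x W x (C+1)` array, channel 1 = background, channel `c + 1` =
#'   class `c`, values in \[0, 1\]) and `class_names`.
#' @export
make_prior <- function(scene, noise = prior_noise()) {
  stopifnot(inherits(scene, "scene"), inherits(noise, "prior_noise"))
  sem <- scene$semantic_mask
  h <- nrow(sem); w <- ncol(sem)
  C1 <- scene$config$n_classes + 1L
  with_seed(noise$seed, {
    lab <- sem
    if (noise$jitter > 0) {
      # iid displacement uniform in a disc of the jitter radius: a pixel's
      # label can only change if a different class lies within that radius
      n <- h * w
      ang <- runif(n, 0, 2 * pi)
      rad <- noise$jitter * sqrt(runif(n))
      ri <- pmin(h, pmax(1, round(row(sem) + rad * sin(ang))))
      ci <- pmin(w, pmax(1, round(col(sem) + rad * cos(ang))))
      lab <- matrix(sem[cbind(as.vector(ri), as.vector(ci))], h, w)
    }
    if (noise$confusion > 0) {
      flip <- which(runif(h * w) < noise$confusion)
      if (length(flip) > 0) {
        # replace with a uniformly drawn *other* label in 0..C
        off <- sample.int(C1 - 1L, length(flip), replace = TRUE)
        lab[flip] <- (lab[flip] + off) %% C1
      }
    }
    ch <- array(0, dim = c(h, w, C1))
    for (k in seq_len(C1)) ch[, , k] <- (lab == (k - 1L)) * 1
    hi <- if (noise$softness > 0) exp(1 / noise$softness) else Inf
    if (is.finite(hi)) {
      # softmax of one-hot / tau: argmax preserved, values strictly in (0,1)
      lo <- 1
      denom <- hi + (C1 - 1) * lo
      ch <- ch * (hi - lo) / denom + lo / denom
    }
    structure(list(channels = ch, class_names = scene$class_names),
              class = "semantic_prior")
  })
}

#' @export
print.semantic_prior <- function(x, ...) {
  d <- dim(x$channels)
  cat(sprintf("<semantic_prior> %dx%d, %d channels (%s)\n", d[1], d[2], d[3],
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}
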