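#' Click-guidance maps
#'
#' The interactive backend consumes user clicks as per-polarity
#' real-valued guidance maps. Two encodings are provided:
#'
#' * **distance**: `u[x, y] = min` over click points of the Euclidean
#'   distance between the pixel and the click, clipped at `clip`. Value
#'   is exactly 0 at every click pixel.
#' * **gaussian**: per-pixel maximum over per-click Gaussian bumps
#'   `exp(-d^2 / (2 sigma^2))`; value is exactly 1 at every click pixel.
#'
#' An empty click set of a polarity yields a blank (all-zero) map with
#' `empty_flag = TRUE` — the "no information" convention for missing
#' negative clicks.
#'
#' @name guidance
NULL

new_guidance_map <- function(values, encoding, empty_flag) {
  structure(list(values = values, encoding = encoding,
                 empty_flag = isTRUE(empty_flag)),
            class = "guidance_map")
}

#' @export
print.guidance_map <- function(x, ...) {
  cat(sprintf("<guidance_map> %s, %dx%d%s, range [%.3g, %.3g]\n",
              x$encoding, nrow(x$values), ncol(x$values),
              if (x$empty_flag) " (blank)" else "",
              min(x$values), max(x$values)))
  invisible(x)
}

# squared Euclidean distance from every pixel to one click
.d2_to_click <- function(shape, r, c) {
  outer((seq_len(shape[1]) - r)^2, (seq_len(shape[2]) - c)^2, "+")
}

#' Minimum-distance click encoding
#'
#' @param clicks a [click_set()], normally already filtered to one
#'   polarity; all clicks present are used as the point set.
#' @param shape integer `c(H, W)`.
#' @param clip distance clip (> 0); default 255.
#' @return a `guidance_map` (see [guidance]).
#' @rdname guidance
#' @export
encode_distance <- function(clicks, shape, clip = 255) {
  stopifnot(length(shape) == 2, all(shape >= 1), clip > 0)
  check_clicks_in_bounds(clicks, shape)
  if (nrow(clicks) == 0)
    return(new_guidance_map(matrix(0, shape[1], shape[2]), "distance", TRUE))
  d2 <- Reduce(pmin, lapply(seq_len(nrow(clicks)), function(i)
    .d2_to_click(shape, clicks$row[i], clicks$col[i])))
  new_guidance_map(pmin(sqrt(d2), clip), "distance", FALSE)
}

#' Gaussian click encoding
#'
#' @param sigma Gaussian bandwidth in pixels (> 0); default 10.
#' @rdname guidance
#' @export
encode_gaussian <- function(clicks, shape, sigma = 10) {
  stopifnot(length(shape) == 2, all(shape >= 1), sigma > 0)
  check_clicks_in_bounds(clicks, shape)
  if (nrow(clicks) == 0)
    return(new_guidance_map(matrix(0, shape[1], shape[2]), "gaussian", TRUE))
  g <- Reduce(pmax, lapply(seq_len(nrow(clicks)), function(i)
    exp(-.d2_to_click(shape, clicks$row[i], clicks$col[i]) / (2 * sigma^2))))
  new_guidance_map(g, "gaussian", FALSE)
}

#' Scale a guidance map to the backend's [0, 1] input range
#'
#' Distance maps are divided by their clip; Gaussian maps are already in
#' range and returned unchanged.
#'
#' @param g a `guidance_map`.
#' @param clip the clip used at encoding time (distance maps only).
#' @return an `H x W` numeric matrix in \[0, 1\].
#' @export
scale_guidance <- function(g, clip = 255) {
  stopifnot(inherits(g, "guidance_map"))
  if (g$encoding == "distance") g$values / clip else g$values
}

#' Window (bounding-box) cropping with inverse placement
#'
#' Large images are segmented inside a user-drawn bounding box; all
#' backend inputs are cropped identically and the windowed prediction is
#' later re-embedded at full resolution with zeros outside the box.
#'
#' @param box integer `c(rmin, rmax, cmin, cmax)`, 1-based inclusive.
#' @param scene a [generate_scene()] scene (or `NULL`).
#' @param prior_channel single-channel prior matrix (or `NULL`).
#' @param pos_guidance,neg_guidance `guidance_map`s (or `NULL`).
#' @param clicks a [click_set()] (or `NULL`); every *positive* click must
#'   fall inside the box; clicks are shifted to window coordinates.
#' @return a list with the cropped `image`, `instance_mask`,
#'   `semantic_mask`, `prior_channel`, `pos_guidance`, `neg_guidance`,
#'   `clicks`, and `placement` (class `window_placement`) for
#'   [restore_from_window()].
#' @export
crop_to_window <- function(box, scene = NULL, prior_channel = NULL,
                           pos_guidance = NULL, neg_guidance = NULL,
                           clicks = NULL) {
  box <- as.integer(box)
  stopifnot(length(box) == 4, box[1] >= 1, box[3] >= 1,
            box[2] >= box[1], box[4] >= box[3])
  shape <- NULL
  if (!is.null(scene)) shape <- dim(scene$instance_mask)
  else if (!is.null(prior_channel)) shape <- dim(prior_channel)
  else if (!is.null(pos_guidance)) shape <- dim(pos_guidance$values)
  if (is.null(shape)) stop("nothing to crop", call. = FALSE)
  if (box[2] > shape[1] || box[4] > shape[2])
    stop("box exceeds image bounds", call. = FALSE)
  if (!is.null(clicks)) {
    pos <- filter_clicks(clicks, "positive")
    if (nrow(pos) > 0 && any(pos$row < box[1] | pos$row > box[2] |
                             pos$col < box[3] | pos$col > box[4]))
      stop("bounding box excludes a positive click", call. = FALSE)
  }
  rs <- box[1]:box[2]; cs <- box[3]:box[4]
  crop_mat <- function(m) if (is.null(m)) NULL else m[rs, cs, drop = FALSE]
  crop_g <- function(g) {
    if (is.null(g)) return(NULL)
    new_guidance_map(g$values[rs, cs, drop = FALSE], g$encoding, g$empty_flag)
  }
  out_clicks <- NULL
  if (!is.null(clicks)) {
    inside <- clicks$row >= box[1] & clicks$row <= box[2] &
      clicks$col >= box[3] & clicks$col <= box[4]
    kept <- clicks[inside, , drop = FALSE]
    out_clicks <- click_set(kept$row - box[1] + 1L, kept$col - box[3] + 1L,
                            kept$polarity)
  }
  list(image = if (is.null(scene)) NULL else
         scene$image[rs, cs, , drop = FALSE],
       instance_mask = if (is.null(scene)) NULL else
         crop_mat(scene$instance_mask),
       semantic_mask = if (is.null(scene)) NULL else
         crop_mat(scene$semantic_mask),
       prior_channel = crop_mat(prior_channel),
       pos_guidance = crop_g(pos_guidance),
       neg_guidance = crop_g(neg_guidance),
       clicks = out_clicks,
       placement = structure(list(box = box, full_shape = shape),
                             class = "window_placement"))
}

#' Re-embed a windowed prediction at full resolution
#'
#' @param mask a binary (logical or 0/1) matrix with the window's shape.
#' @param placement the `window_placement` from [crop_to_window()].
#' @return a full-resolution matrix, zero (FALSE) outside the window.
#' @export
restore_from_window <- function(mask, placement) {
  stopifnot(inherits(placement, "window_placement"))
  box <- placement$box
  if (!all(dim(mask) == c(box[2] - box[1] + 1L, box[4] - box[3] + 1L)))
    stop("mask shape does not match window", call. = FALSE)
  full <- matrix(vector(mode = typeof(mask), 1), placement$full_shape[1],
                 placement$full_shape[2])
  full[box[1]:box[2], box[3]:box[4]] <- mask
  full
}
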