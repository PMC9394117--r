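#' Class/object hierarchy
#'
#' The annotation hierarchy: an ordered list of classes (id, name,
#' colour) and objects with their member class ids. Colours are the
#' deterministic palette used by the label-mask writers; the hierarchy
#' is persisted as JSON.
#'
#' @param class_names character vector of tissue class names (without
#'   background).
#' @param objects optional list of `list(id, name, classes)` entries.
#' @param colors optional `(C + 1) x 3` RGB matrix in \[0, 1\]
#'   (background first); defaults to [class_palette()].
#' @return an object of class `hierarchy`.
#' @export
hierarchy <- function(class_names, objects = list(), colors = NULL) {
  C <- length(class_names)
  if (is.null(colors)) colors <- class_palette(C)
  stopifnot(nrow(colors) == C + 1, ncol(colors) == 3)
  colors <- round(colors * 255) / 255     # snap to the 8-bit PNG grid
  key <- apply(round(colors * 255), 1, paste, collapse = ",")
  if (anyDuplicated(key)) stop("hierarchy colours collide", call. = FALSE)
  cls <- data.frame(id = 0:C,
                    name = c("background", class_names),
                    stringsAsFactors = FALSE)
  for (ob in objects) {
    if (!all(ob$classes %in% cls$id))
      stop("object references an unknown class id", call. = FALSE)
  }
  structure(list(classes = cls, colors = colors, objects = objects),
            class = "hierarchy")
}

#' Hierarchy of a scene
#' @param scene a [generate_scene()] scene.
#' @return the scene's [hierarchy()] (one object entry per instance).
#' @export
scene_hierarchy <- function(scene) {
  hierarchy(scene$class_names[-1],
            objects = lapply(seq_along(scene$object_classes), function(k)
              list(id = k, name = paste0("object", k),
                   classes = as.integer(scene$object_classes[k]))))
}

#' Read/write a hierarchy as JSON
#' @param h a [hierarchy()].
#' @param path file path.
#' @return `read_hierarchy()` returns the restored [hierarchy()].
#' @export
write_hierarchy <- function(h, path) {
  jsonlite::write_json(
    list(classes = h$classes,
         colors = round(h$colors * 255),
         objects = h$objects),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_hierarchy
#' @export
read_hierarchy <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  objects <- list()
  if (length(obj$objects) > 0) {
    objects <- if (is.data.frame(obj$objects))
      lapply(seq_len(nrow(obj$objects)), function(i)
        list(id = obj$objects$id[i], name = obj$objects$name[i],
             classes = unlist(obj$objects$classes[i])))
    else obj$objects
  }
  hierarchy(obj$classes$name[-1], objects = objects,
            colors = as.matrix(obj$colors) / 255)
}

# deterministic distinct colour for an arbitrary integer id (> 0)
id_color <- function(id) {
  cbind((37 * id + 71) %% 256, (101 * id + 13) %% 256,
        (151 * id + 29) %% 256) / 255
}

#' Write / read label masks as colour PNG
#'
#' Masks are written as RGB PNGs with a deterministic colour table and
#' decoded back exactly:
#'
#' * `by_class` — each class id painted with the hierarchy colour.
#' * `by_object` — each object id painted with a deterministic
#'   id-derived colour (requires `instance_mask`).
#' * `nested` — each distinct (object, class) pair painted with a
#'   deterministic colour, so two objects sharing a class decode to
#'   distinct ids.
#'
#' @param semantic_mask `H x W` class-id matrix.
#' @param h the [hierarchy()] describing classes and colours.
#' @param path PNG path.
#' @param mode `"by_class"`, `"by_object"` or `"nested"`.
#' @param instance_mask `H x W` object-id matrix (object/nested modes).
#' @return `read_label_png()` returns the decoded mask (`by_class`: the
#'   class mask; `by_object`: the object mask; `nested`: a list with
#'   both).
#' @export
write_label_png <- function(semantic_mask, h, path,
                            mode = c("by_class", "by_object", "nested"),
                            instance_mask = NULL) {
  mode <- match.arg(mode)
  C <- nrow(h$classes) - 1L
  if (max(semantic_mask) > C)
    stop("mask label not covered by hierarchy", call. = FALSE)
  hh <- nrow(semantic_mask); ww <- ncol(semantic_mask)
  img <- array(0, dim = c(hh, ww, 3))
  if (mode == "by_class") {
    for (ch in 1:3) img[, , ch] <- matrix(h$colors[semantic_mask + 1L, ch],
                                          hh, ww)
  } else {
    if (is.null(instance_mask))
      stop("instance_mask required for object/nested modes", call. = FALSE)
    stop_if_not_matrix_pair(semantic_mask, instance_mask)
    code <- if (mode == "by_object") instance_mask
            else instance_mask * (C + 1L) + semantic_mask
    cols <- id_color(0:max(code))
    cols[1, ] <- h$colors[1, ]                # background keeps its colour
    for (ch in 1:3) img[, , ch] <- matrix(cols[code + 1L, ch], hh, ww)
  }
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname write_label_png
#' @param max_id largest object id expected when decoding object/nested
#'   modes.
#' @export
read_label_png <- function(path, h, mode = c("by_class", "by_object",
                                             "nested"), max_id = 255L) {
  mode <- match.arg(mode)
  img <- png::readPNG(path)
  key <- function(colmat) apply(round(colmat * 255), 1, paste, collapse = ",")
  px <- paste(round(img[, , 1] * 255), round(img[, , 2] * 255),
              round(img[, , 3] * 255), sep = ",")
  C <- nrow(h$classes) - 1L
  if (mode == "by_class") {
    lut <- stats::setNames(h$classes$id, key(h$colors))
    out <- lut[px]
    if (any(is.na(out))) stop("unknown colour in label PNG", call. = FALSE)
    return(matrix(as.integer(out), dim(img)[1], dim(img)[2]))
  }
  codes <- 0:(if (mode == "by_object") max_id else (max_id + 1L) * (C + 1L))
  cols <- id_color(codes)
  cols[1, ] <- h$colors[1, ]
  lut <- stats::setNames(codes, key(cols))
  out <- lut[px]
  if (any(is.na(out))) stop("unknown colour in label PNG", call. = FALSE)
  code <- matrix(as.integer(out), dim(img)[1], dim(img)[2])
  if (mode == "by_object") return(code)
  list(instance_mask = code %/% (C + 1L), semantic_mask = code %% (C + 1L))
}

#' Write / read an instance mask as PNG
#'
#' Object ids up to 65535 are stored losslessly by splitting each id
#' into a high and a low byte carried in the red and green channels of
#' an 8-bit RGB PNG.
#'
#' @param instance_mask `H x W` non-negative integer matrix.
#' @param path PNG path.
#' @return `read_instance_png()` returns the integer mask.
#' @export
write_instance_png <- function(instance_mask, path) {
  if (max(instance_mask) > 65535L)
    stop("instance ids exceed 16-bit range", call. = FALSE)
  hh <- nrow(instance_mask); ww <- ncol(instance_mask)
  img <- array(0, dim = c(hh, ww, 3))
  img[, , 1] <- (instance_mask %/% 256L) / 255
  img[, , 2] <- (instance_mask %% 256L) / 255
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname write_instance_png
#' @export
read_instance_png <- function(path) {
  img <- png::readPNG(path)
  matrix(as.integer(round(img[, , 1] * 255) * 256L +
                      round(img[, , 2] * 255)),
         dim(img)[1], dim(img)[2])
}

#' Write / read a semantic prior as multi-channel 32-bit TIFF
#'
#' One TIFF directory per channel with 32-bit samples; values must lie
#' in \[0, 1\] (the prior convention) and round-trip at a resolution of
#' 2^-32, far below any probability difference of interest. Channel
#' names are persisted in a JSON sidecar (`<path>.json`) and must match
#' the channel count on read.
#'
#' @param prior a [make_prior()] `semantic_prior`.
#' @param path TIFF path.
#' @return `read_prior_tiff()` returns the restored `semantic_prior`.
#' @export
write_prior_tiff <- function(prior, path) {
  stopifnot(inherits(prior, "semantic_prior"))
  ch <- lapply(seq_len(dim(prior$channels)[3]), function(k)
    prior$channels[, , k])
  tiff::writeTIFF(ch, path, bits.per.sample = 32L)
  jsonlite::write_json(list(class_names = prior$class_names),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_prior_tiff
#' @export
read_prior_tiff <- function(path) {
  ch <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing channel-name sidecar: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (length(meta$class_names) != length(ch))
    stop("sidecar names do not match channel count", call. = FALSE)
  arr <- array(0, dim = c(dim(ch[[1]]), length(ch)))
  for (k in seq_along(ch)) arr[, , k] <- ch[[k]]
  structure(list(channels = arr, class_names = meta$class_names),
            class = "semantic_prior")
}

#' Export a guidance map as 32-bit TIFF (values scaled to \[0, 1\])
#' @param g a `guidance_map`.
#' @param path TIFF path.
#' @export
write_guidance_tiff <- function(g, path) {
  stopifnot(inherits(g, "guidance_map"))
  v <- g$values
  if (g$encoding == "distance" && max(v) > 1) v <- v / max(v)
  tiff::writeTIFF(v, path, bits.per.sample = 32L)
  invisible(path)
}

#' Export a scene to disk
#'
#' Writes `image.png` (RGB), `instance.png` (16-bit ids over two 8-bit
#' channels), `semantic.png` (class-coloured), `hierarchy.json` and
#' `prior.tif` (+ sidecar) for an optionally supplied prior.
#'
#' @param scene a [generate_scene()] scene.
#' @param dir output directory (created if needed).
#' @param prior optional `semantic_prior` to write alongside.
#' @return the directory, invisibly.
#' @export
write_scene <- function(scene, dir, prior = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  png::writePNG(scene$image, file.path(dir, "image.png"))
  write_instance_png(scene$instance_mask, file.path(dir, "instance.png"))
  h <- scene_hierarchy(scene)
  write_label_png(scene$semantic_mask, h, file.path(dir, "semantic.png"),
                  "by_class")
  write_hierarchy(h, file.path(dir, "hierarchy.json"))
  if (!is.null(prior)) write_prior_tiff(prior, file.path(dir, "prior.tif"))
  invisible(dir)
}

#' Serialize session records to JSON
#'
#' Sessions round-trip losslessly. Click coordinates inside the JSON
#' are 0-based `(row, col)` with origin at the top-left, the package's
#' on-disk convention; in-memory objects stay 1-based.
#'
#' @param records list of `session_record`s (or one record).
#' @param path JSON path.
#' @return `read_sessions_json()` returns the list of records.
#' @export
write_sessions_json <- function(records, path) {
  if (inherits(records, "session_record")) records <- list(records)
  obj <- lapply(records, function(r) {
    cl <- if (!is.null(r$clicks))
      data.frame(row = r$clicks$row - 1L, col = r$clicks$col - 1L,
                 polarity = r$clicks$polarity)
    else NULL
    out <- list(object_id = r$object_id, steps = r$steps, clicks = cl,
                clicks_to_target = r$clicks_to_target, reached = r$reached,
                scene = r$scene,
                threshold = r$cfg$iou_target, cap = r$cfg$cap)
    out[!vapply(out, is.null, logical(1))]
  })
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sessions_json
#' @export
read_sessions_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(obj)), function(i) {
    clicks <- NULL
    if ("clicks" %in% names(obj) && !is.null(obj$clicks[[i]])) {
      cl <- as.data.frame(obj$clicks[[i]])
      clicks <- click_set(cl$row + 1L, cl$col + 1L, cl$polarity)
    }
    structure(list(object_id = obj$object_id[i],
                   steps = as.data.frame(obj$steps[[i]]),
                   clicks = clicks,
                   clicks_to_target = as.integer(obj$clicks_to_target[i]),
                   reached = obj$reached[i],
                   scene = if (is.atomic(obj[["scene"]]))
                     obj[["scene"]][i] else NULL,
                   cfg = sim_config(cap = obj$cap[i],
                                    iou_target = obj$threshold[i])),
              class = "session_record")
  })
}

#' Write an evaluation report (JSON + curve CSV)
#'
#' @param report an `eval_report`.
#' @param path JSON path; the curve additionally goes to `curve_path`.
#' @param curve_path CSV path for the `(clicks, mean_iou)` curve.
#' @return `read_report_json()` returns a list with `mean_clicks`,
#'   `curve` and `config`.
#' @export
write_report_json <- function(report, path, curve_path = NULL) {
  obj <- list(mean_clicks = report$mean_clicks, config = report$config,
              curve = report$curve,
              sessions = lapply(report$records, function(r)
                list(object_id = r$object_id, scene = r$scene,
                     clicks_to_target = r$clicks_to_target,
                     reached = r$reached, steps = r$steps)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  if (!is.null(curve_path))
    utils::write.csv(report$curve, curve_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
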