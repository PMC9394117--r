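#' Per-class pixel areas of a semantic mask
#'
#' `Area_c = sum over pixels of 1[class(pixel) == c]`, the pixel count
#' of each class. Classes absent from the mask report 0; the counts
#' over all classes including background always sum to `H * W`.
#'
#' @param semantic_mask `H x W` integer matrix of class ids (0 =
#'   background).
#' @param n_classes number of tissue classes C; defaults to the largest
#'   id present.
#' @return a named integer vector of length C + 1 (`background`,
#'   `class1..C` or the supplied names).
#' @param class_names optional names of length C + 1.
#' @export
area_per_class <- function(semantic_mask, n_classes = NULL,
                           class_names = NULL) {
  vals <- as.integer(semantic_mask)
  if (any(is.na(vals) | vals < 0))
    stop("semantic mask holds unknown (negative or NA) labels",
         call. = FALSE)
  if (is.null(n_classes)) n_classes <- max(vals, 0L)
  if (max(vals) > n_classes)
    stop("semantic mask holds a label outside 0..n_classes", call. = FALSE)
  counts <- tabulate(vals + 1L, nbins = n_classes + 1L)
  names(counts) <- if (!is.null(class_names)) class_names
                   else default_class_names(n_classes)
  counts
}

#' Relative tissue areas
#'
#' `RArea_c = Area_c / sum over tissue classes of Area_c`: each tissue
#' class's share of all tissue pixels. Background is excluded from both
#' numerator and denominator. With no tissue pixels at all, every
#' relative area is 0.
#'
#' @param areas output of [area_per_class()] (background first).
#' @return a named numeric vector over the tissue classes; sums to 1
#'   whenever any tissue pixel exists.
#' @export
relative_area <- function(areas) {
  tissue <- areas[-1]
  tot <- sum(tissue)
  if (tot == 0) return(tissue * 0)
  tissue / tot
}

#' Count isolated clusters of a class
#'
#' The number of 4-connected components formed by the pixels of one
#' class — the "isolated clusters" statistic of the annotated-mask
#' summaries.
#'
#' @param semantic_mask `H x W` integer matrix of class ids.
#' @param class_id the class to count (> 0).
#' @return a non-negative integer.
#' @export
cluster_count <- function(semantic_mask, class_id) {
  stopifnot(length(class_id) == 1, class_id >= 1)
  m <- semantic_mask == class_id
  if (!any(m)) return(0L)
  max(EBImage::bwlabel(m * 1))
}

#' Trait table for a set of semantic masks
#'
#' Computes, per image: per-class pixel area, relative tissue area,
#' fraction of all image pixels, and isolated-cluster count; plus
#' dataset-level averages of the image-pixel percentage and cluster
#' count per class. An optional grouping vector (e.g. replicate id)
#' adds group means of every numeric trait, the form consumed by
#' downstream association studies.
#'
#' @param masks a list of `H x W` semantic masks (or a single mask).
#' @param n_classes number of tissue classes C (required if not
#'   deducible).
#' @param class_names optional length C + 1 names.
#' @param ids optional image ids (default `seq_along(masks)`).
#' @param group optional grouping vector, one entry per mask.
#' @return an object of class `trait_table`: list with `per_image` (one
#'   row per image and class), `summary` (per-class means of
#'   percent-of-image pixels and cluster counts), and optionally
#'   `by_group`.
#' @export
summarize_dataset <- function(masks, n_classes = NULL, class_names = NULL,
                              ids = NULL, group = NULL) {
  if (is.matrix(masks)) masks <- list(masks)
  if (length(masks) == 0) stop("no masks supplied", call. = FALSE)
  if (is.null(n_classes))
    n_classes <- max(vapply(masks, max, numeric(1)), 1)
  if (is.null(ids)) ids <- seq_along(masks)
  rows <- list()
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    areas <- area_per_class(m, n_classes, class_names)
    rel <- relative_area(areas)
    npx <- length(m)
    for (cl in seq_len(n_classes)) {
      rows[[length(rows) + 1L]] <- data.frame(
        image = ids[i],
        class_id = cl,
        class = names(areas)[cl + 1],
        area_px = as.integer(areas[cl + 1]),
        relative_area = as.numeric(rel[cl]),
        pct_of_image = 100 * areas[cl + 1] / npx,
        clusters = cluster_count(m, cl),
        stringsAsFactors = FALSE)
    }
  }
  per_image <- do.call(rbind, rows)
  rownames(per_image) <- NULL
  summary <- do.call(rbind, lapply(seq_len(n_classes), function(cl) {
    sub <- per_image[per_image$class_id == cl, ]
    data.frame(class_id = cl, class = sub$class[1],
               mean_pct_of_image = mean(sub$pct_of_image),
               mean_clusters = mean(sub$clusters),
               mean_relative_area = mean(sub$relative_area),
               stringsAsFactors = FALSE)
  }))
  by_group <- NULL
  if (!is.null(group)) {
    stopifnot(length(group) == length(masks))
    per_image$group <- group[match(per_image$image, ids)]
    agg <- stats::aggregate(
      per_image[, c("area_px", "relative_area", "pct_of_image", "clusters")],
      by = list(group = per_image$group, class_id = per_image$class_id),
      FUN = mean)
    by_group <- agg[order(agg$group, agg$class_id), ]
    rownames(by_group) <- NULL
  }
  structure(list(per_image = per_image, summary = summary,
                 by_group = by_group),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("<trait_table> %d images x %d classes\n",
              length(unique(x$per_image$image)), nrow(x$summary)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a trait table to CSV
#'
#' Writes the per-image rows followed by per-class `summary:` rows, or
#' the two tables to separate files when `summary_path` is given.
#'
#' @param traits a `trait_table`.
#' @param path CSV path for the per-image table.
#' @param summary_path optional CSV path for the summary table; when
#'   `NULL` the summary is appended to `path` with `image = "summary"`.
#' @export
write_trait_csv <- function(traits, path, summary_path = NULL) {
  per <- traits$per_image
  if (is.null(summary_path)) {
    s <- data.frame(image = "summary", class_id = traits$summary$class_id,
                    class = traits$summary$class, area_px = NA,
                    relative_area = traits$summary$mean_relative_area,
                    pct_of_image = traits$summary$mean_pct_of_image,
                    clusters = traits$summary$mean_clusters)
    if ("group" %in% names(per)) s$group <- NA
    per$image <- as.character(per$image)
    utils::write.csv(rbind(per, s), path, row.names = FALSE)
  } else {
    utils::write.csv(per, path, row.names = FALSE)
    utils::write.csv(traits$summary, summary_path, row.names = FALSE)
  }
  invisible(path)
}
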