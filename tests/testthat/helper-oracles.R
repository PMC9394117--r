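# Independent brute-force oracles used across tests. These deliberately
# avoid the package's implementation paths (and EBImage): plain loops
# and stack-based flood fill only.

# O(H*W*|P|) per-pixel minimum distance to a click set
brute_distance_map <- function(clicks, shape, clip = 255) {
  out <- matrix(0, shape[1], shape[2])
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2])) {
    d <- Inf
    for (k in seq_len(nrow(clicks)))
      d <- min(d, sqrt((clicks$row[k] - i)^2 + (clicks$col[k] - j)^2))
    out[i, j] <- min(d, clip)
  }
  out
}

brute_gaussian_map <- function(clicks, shape, sigma) {
  out <- matrix(0, shape[1], shape[2])
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2])) {
    g <- 0
    for (k in seq_len(nrow(clicks)))
      g <- max(g, exp(-((clicks$row[k] - i)^2 + (clicks$col[k] - j)^2) /
                        (2 * sigma^2)))
    out[i, j] <- g
  }
  out
}

# stack-based 4-connected flood fill labelling
flood_fill_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    while (length(stack) > 0) {
      px <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- ((px - 1) %% h) + 1L; c <- ((px - 1) %/% h) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w) {
          q <- (cc - 1L) * h + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- nxt
            stack <- c(stack, q)
          }
        }
      }
    }
  }
  lab
}

brute_iou <- function(pred, gt) {
  a <- which(pred > 0); b <- which(gt > 0)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

random_binary_mask <- function(h, w, p = 0.3) {
  matrix(runif(h * w) < p, h, w)
}

# small scene used widely in tests
tiny_scene <- function(seed = 1, ...) {
  generate_scene(scene_config(height = 64, width = 64, seed = seed, ...))
}

# hand-built semantic prior from an explicit channel array
manual_prior <- function(channels, class_names = NULL) {
  if (is.null(class_names))
    class_names <- c("background", paste0("class", seq_len(dim(channels)[3] - 1)))
  structure(list(channels = channels, class_names = class_names),
            class = "semantic_prior")
}
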