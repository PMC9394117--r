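#' Blank semantic-prior channel
#'
#' When no semantic prior is available the backend receives an all-zero
#' channel; by definition it behaves as "no information", and a backend
#' given the blank channel must produce the same prediction as one given
#' a prior of all zeros.
#'
#' @param shape integer `c(H, W)`.
#' @return an `H x W` zero matrix with attribute `blank = TRUE`.
#' @seealso [select_channel()]
#' @export
blank_prior <- function(shape) {
  stopifnot(length(shape) == 2, all(shape >= 1))
  structure(matrix(0, shape[1], shape[2]), blank = TRUE)
}

#' Is this prior channel the blank (absent-prior) channel?
#' @param x a prior channel matrix.
#' @return logical.
#' @export
is_blank_prior <- function(x) {
  isTRUE(attr(x, "blank")) || (is.matrix(x) && all(x == 0))
}

#' Select the semantic-prior channel for the object of interest
#'
#' The user always places at least one positive click on the object of
#' interest; the channel handed to the backend is the tissue class whose
#' probability, summed over all positive-click pixels, is maximal.
#' The background channel (channel 1) is never selectable, and ties
#' break toward the lowest class index. Summation over clicks is the
#' package's order-invariant aggregate. With a single click the
#' selection is invariant to any strictly monotone per-pixel transform
#' applied to all channels simultaneously, so storing logits instead of
#' probabilities cannot change it; with several clicks the same holds
#' for positive affine transforms.
#'
#' @param prior a [make_prior()] `semantic_prior` (channels
#'   `H x W x (C+1)`, channel 1 = background).
#' @param clicks a [click_set()]; only its positive clicks are used and
#'   at least one is required.
#' @return a list with `class_id` (1..C), `channel` (the `H x W` map for
#'   that class) and `scores` (the per-class click-pixel sums).
#' @export
select_channel <- function(prior, clicks) {
  stopifnot(inherits(prior, "semantic_prior"))
  pos <- filter_clicks(clicks, "positive")
  if (nrow(pos) == 0)
    stop("channel selection requires at least one positive click",
         call. = FALSE)
  d <- dim(prior$channels)
  check_clicks_in_bounds(pos, d[1:2])
  C <- d[3] - 1L
  if (C < 1) stop("prior must hold background plus at least one class",
                  call. = FALSE)
  scores <- vapply(seq_len(C), function(cl)
    sum(prior$channels[cbind(pos$row, pos$col, cl + 1L)]), numeric(1))
  names(scores) <- if (length(prior$class_names) == d[3])
    prior$class_names[-1] else paste0("class", seq_len(C))
  cl <- which.max(scores)          # ties break toward the lowest index
  list(class_id = as.integer(cl),
       channel = prior$channels[, , cl + 1L],
       scores = scores)
}
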