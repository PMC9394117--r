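#' Point annotations for interactive segmentation
#'
#' A click set is an ordered sequence of positive (inside the object of
#' interest) and negative (outside) point annotations in pixel
#' coordinates. Order is interaction order; adjacent exact duplicates are
#' collapsed. Coordinates are 1-based `(row, col)` with origin at the
#' top-left pixel, the R matrix convention.
#'
#' @param row,col integer pixel coordinates (1-based).
#' @param polarity `"positive"` or `"negative"`, recycled to the length of
#'   `row`.
#' @return An object of class `click_set`: a data frame with columns
#'   `row`, `col`, `polarity`.
#' @examples
#' cs <- click_set(c(5, 9), c(5, 2), c("positive", "negative"))
#' n_clicks(cs)
#' @export
click_set <- function(row = integer(), col = integer(),
                      polarity = character()) {
  row <- as.integer(row); col <- as.integer(col)
  if (length(row) != length(col))
    stop("row and col must have the same length", call. = FALSE)
  if (length(row) > 0) {
    polarity <- match.arg(rep_len(as.character(polarity), length(row)),
                          c("positive", "negative"), several.ok = TRUE)
  } else polarity <- character()
  cs <- data.frame(row = row, col = col, polarity = polarity,
                   stringsAsFactors = FALSE)
  class(cs) <- c("click_set", "data.frame")
  collapse_adjacent(cs)
}

# drop adjacent exact duplicates (same pixel, same polarity back-to-back)
collapse_adjacent <- function(cs) {
  if (nrow(cs) < 2) return(cs)
  keep <- c(TRUE, !(cs$row[-1] == cs$row[-nrow(cs)] &
                    cs$col[-1] == cs$col[-nrow(cs)] &
                    cs$polarity[-1] == cs$polarity[-nrow(cs)]))
  out <- cs[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("click_set", "data.frame")
  out
}

#' Number of clicks in a click set
#' @param clicks a [click_set()].
#' @param polarity optional `"positive"` or `"negative"` to count one
#'   polarity only.
#' @return integer count.
#' @export
n_clicks <- function(clicks, polarity = NULL) {
  if (is.null(polarity)) nrow(clicks)
  else sum(clicks$polarity == match.arg(polarity, c("positive", "negative")))
}

#' Filter a click set to a single polarity
#' @inheritParams n_clicks
#' @return a [click_set()] holding only the requested polarity, order kept.
#' @export
filter_clicks <- function(clicks, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  out <- clicks[clicks$polarity == polarity, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("click_set", "data.frame")
  out
}

#' Append clicks to a click set
#' @param clicks,more two [click_set()] objects.
#' @return the concatenation, with adjacent duplicates collapsed.
#' @export
append_clicks <- function(clicks, more) {
  out <- rbind(as.data.frame(clicks), as.data.frame(more))
  class(out) <- c("click_set", "data.frame")
  collapse_adjacent(out)
}

#' @export
print.click_set <- function(x, ...) {
  cat(sprintf("<click_set> %d clicks (%d positive, %d negative)\n",
              nrow(x), sum(x$polarity == "positive"),
              sum(x$polarity == "negative")))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

check_clicks_in_bounds <- function(clicks, shape) {
  if (nrow(clicks) == 0) return(invisible(TRUE))
  if (any(clicks$row < 1 | clicks$row > shape[1] |
          clicks$col < 1 | clicks$col > shape[2]))
    stop("click outside image bounds", call. = FALSE)
  invisible(TRUE)
}
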