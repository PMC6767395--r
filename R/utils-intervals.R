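#' Interval table helpers
#'
#' Event epochs throughout the package are plain data frames with numeric
#' `start` and `end` columns (seconds). These helpers keep interval algebra in
#' one place: merging, intersection, duration and point membership.
#'
#' @param iv,a,b interval data frames with `start` and `end` columns
#' @param gap intervals separated by less than `gap` seconds are merged
#' @name intervals
NULL

#' @rdname intervals
#' @export
iv_new <- function(start = numeric(0), end = numeric(0)) {
  stopifnot(length(start) == length(end))
  if (any(end < start)) stop("interval end before start")
  data.frame(start = as.numeric(start), end = as.numeric(end))
}

#' @rdname intervals
#' @export
iv_merge <- function(iv, gap = 0) {
  if (nrow(iv) == 0) return(iv_new())
  iv <- iv[order(iv$start), , drop = FALSE]
  start <- iv$start[1]; end <- iv$end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= end + gap) {
      end <- max(end, iv$end[i])
    } else {
      out_s <- c(out_s, start); out_e <- c(out_e, end)
      start <- iv$start[i]; end <- iv$end[i]
    }
  }
  iv_new(c(out_s, start), c(out_e, end))
}

#' @rdname intervals
#' @export
iv_intersect <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(iv_new())
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(a))) {
    s <- pmax(a$start[i], b$start)
    e <- pmin(a$end[i], b$end)
    keep <- e > s
    out_s <- c(out_s, s[keep]); out_e <- c(out_e, e[keep])
  }
  iv_merge(iv_new(out_s, out_e))
}

#' @rdname intervals
#' @export
iv_duration <- function(iv) sum(iv$end - iv$start)

#' @rdname intervals
#' @param t numeric vector of times
#' @return `iv_contains`: logical vector, TRUE where `t` falls inside any interval.
#' @export
iv_contains <- function(iv, t) {
  if (nrow(iv) == 0) return(rep(FALSE, length(t)))
  iv <- iv[order(iv$start), , drop = FALSE]
  idx <- findInterval(t, iv$start)
  idx > 0 & t <= iv$end[pmax(idx, 1)]
}

#' Count spikes of several units in a set of time windows
#'
#' @param spike_times list of numeric vectors (spike times per unit, sorted)
#' @param win_start,win_end window boundaries (half-open `[start, end)`)
#' @return integer matrix, windows x units
#' @export
count_in_windows <- function(spike_times, win_start, win_end) {
  stopifnot(length(win_start) == length(win_end))
  n_w <- length(win_start)
  out <- matrix(0L, n_w, length(spike_times))
  for (j in seq_along(spike_times)) {
    st <- sort(spike_times[[j]])
    out[, j] <- findInterval(win_end, st, left.open = TRUE) -
      findInterval(win_start, st, left.open = TRUE)
  }
  out
}

#' Non-overlapping windows tiling a set of intervals
#'
#' Windows are aligned to each interval's start; a trailing remainder shorter
#' than `width` is dropped.
#'
#' @param iv interval data frame
#' @param width window length (s)
#' @param step optional step (s); defaults to `width` (non-overlapping)
#' @return data frame with `start`, `end`, `center`
#' @export
iv_windows <- function(iv, width, step = width) {
  out_s <- numeric(0)
  for (i in seq_len(nrow(iv))) {
    span <- iv$end[i] - iv$start[i]
    if (span < width) next
    k <- floor((span - width) / step)
    out_s <- c(out_s, iv$start[i] + step * (0:k))
  }
  data.frame(start = out_s, end = out_s + width, center = out_s + width / 2)
}
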