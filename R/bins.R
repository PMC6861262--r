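#' Probability answer bins for a swarm session
#'
#' The swarm chooses among a small set of contiguous probability ranges;
#' each bin's representative value is its midpoint, used as the answer
#' value in squared-impulse interpolation. The default scheme is the
#' five-range layout used in the chest-radiograph reader study:
#' 0-5%, 5-25%, 25-65%, 65-85%, 85-100%, with midpoints 0.025, 0.15,
#' 0.45, 0.75, 0.925. Bin targets sit at equally spaced angles on the
#' unit circle of the simulated answer board.
#'
#' @param breaks increasing numeric vector of bin edges starting at 0 and
#'   ending at 1.
#' @return A `bin_scheme`: data frame with `lower`, `upper`, `midpoint`,
#'   `angle` (radians, target position on the unit circle).
#' @examples
#' bin_scheme()$midpoint
#' @export
bin_scheme <- function(breaks = c(0, 0.05, 0.25, 0.65, 0.85, 1)) {
  if (breaks[1L] != 0 || breaks[length(breaks)] != 1 ||
      any(diff(breaks) <= 0))
    stop("breaks must increase from 0 to 1", call. = FALSE)
  k <- length(breaks) - 1L
  if (k < 2L) stop("need at least 2 bins", call. = FALSE)
  lower <- breaks[-length(breaks)]
  upper <- breaks[-1L]
  out <- data.frame(lower = lower, upper = upper,
                    midpoint = (lower + upper) / 2,
                    angle = pi / 2 - (seq_len(k) - 1L) * 2 * pi / k)
  class(out) <- c("bin_scheme", "data.frame")
  out
}

#' Map probabilities to answer bins
#'
#' Bins are lower-inclusive, upper-exclusive, except the last which is
#' closed at 1.
#'
#' @param p numeric vector of probabilities in \[0, 1\].
#' @param scheme a [bin_scheme()].
#' @return integer bin indices.
#' @export
prob_bin <- function(p, scheme = bin_scheme()) {
  if (any(p < 0 | p > 1)) stop("probabilities outside [0,1]", call. = FALSE)
  breaks <- c(scheme$lower, 1)
  findInterval(p, breaks, rightmost.closed = TRUE)
}

bin_targets <- function(scheme) {
  cbind(cos(scheme$angle), sin(scheme$angle))
}
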