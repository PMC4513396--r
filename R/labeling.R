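#' Build a Gaussian smoothing mask
#'
#' Precomputed Gaussian weights \eqn{g(x) = (2\pi\sigma^2)^{-1/2}
#' \exp\{-(x-\mu)^2 / 2\sigma^2\}} centered at the mask midpoint. The mask
#' width is about 7 standard deviations (essentially all of the Gaussian's
#' mass), rounded to the nearest odd integer so the mask has a center.
#'
#' @param sigma Standard deviation, in positions; > 0.
#' @return Object of class \code{gaussian_mask}: \code{sigma},
#'   \code{half_width} h, and \code{weights} (length 2h+1, symmetric,
#'   maximal at the center).
#' @export
gaussian_mask <- function(sigma) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  width <- round(7 * sigma)
  if (width %% 2 == 0) width <- width + 1
  h <- (width - 1) / 2
  x <- -h:h
  weights <- stats::dnorm(x, mean = 0, sd = sigma)
  structure(list(sigma = sigma, half_width = h, weights = weights),
            class = "gaussian_mask")
}

#' Smooth a score track with a Gaussian mask
#'
#' Each position becomes the mask-weighted mean of the scores it covers.
#' Near the sequence ends the mask is truncated to in-bounds positions and
#' the divisor is the truncated weight sum, so constants are preserved
#' exactly everywhere, boundaries included.
#'
#' @param scores Numeric score track.
#' @param mask A [gaussian_mask()].
#' @return Numeric smoothed track, same length.
#' @export
smooth_track <- function(scores, mask) {
  n <- length(scores)
  if (n == 0L) return(scores)
  h <- mask$half_width
  w <- mask$weights
  # exact windowed sums via stats::filter on zero-padded input; the
  # denominator is the same filter applied to an indicator of in-bounds
  # positions, which renormalizes the truncated mask at the ends
  pad <- function(x) c(numeric(h), x, numeric(h))
  num <- stats::filter(pad(scores), w, method = "convolution", sides = 2)
  den <- stats::filter(pad(rep(1, n)), w, method = "convolution", sides = 2)
  as.numeric(num[(h + 1):(h + n)] / den[(h + 1):(h + n)])
}

#' Discrete first- and second-derivative approximations
#'
#' First derivative: sum of the w scores preceding a position minus the sum
#' of the w scores following it. Second derivative: sum of both flanking
#' windows minus 2w times the central score. Positions within w of either
#' end are undefined (NA) and excluded from the maxima test.
#'
#' @param smoothed Numeric smoothed track.
#' @param w Flank window length in positions, >= 1 (default 10).
#' @return List with numeric tracks \code{first} and \code{second}, each the
#'   length of the input with NA at undefined positions.
#' @export
track_derivatives <- function(smoothed, w = 10L) {
  w <- as.integer(w)
  if (w < 1L) stop("w must be >= 1")
  n <- length(smoothed)
  first <- rep(NA_real_, n)
  second <- rep(NA_real_, n)
  if (n >= 2L * w + 1L) {
    cs <- c(0, cumsum(smoothed))
    i <- (w + 1L):(n - w)
    pre <- cs[i] - cs[i - w]          # scores i-w .. i-1
    post <- cs[i + w + 1L] - cs[i + 1L]  # scores i+1 .. i+w
    first[i] <- pre - post
    second[i] <- pre + post - 2 * w * smoothed[i]
  }
  list(first = first, second = second)
}

#' Locate local maxima by the second-derivative test
#'
#' A maximum is declared where the sign of the first derivative changes
#' between two consecutive defined positions (the zero crossing) and the
#' second derivative there is negative. Of the two positions flanking a
#' crossing, the one with the more negative second derivative is reported
#' (the left one on ties).
#'
#' @param smoothed Numeric smoothed track.
#' @param w Derivative window, as in [track_derivatives()].
#' @return Integer vector of maxima positions (1-based), strictly
#'   increasing.
#' @export
local_maxima <- function(smoothed, w = 10L) {
  d <- track_derivatives(smoothed, w)
  f1 <- d$first
  f2 <- d$second
  n <- length(smoothed)
  if (n < 2L) return(integer())
  s <- sign(f1)
  i <- seq_len(n - 1L)
  # an exact zero counts as a sign change on both sides, so a perfectly
  # symmetric peak (f' hits 0 at the apex) is still a single crossing
  cross <- which(!is.na(s[i]) & !is.na(s[i + 1L]) & s[i] != s[i + 1L])
  if (!length(cross)) return(integer())
  left_f2 <- f2[cross]
  right_f2 <- f2[cross + 1L]
  at <- ifelse(left_f2 <= right_f2, cross, cross + 1L)
  keep <- f2[at] < 0
  sort(unique(at[keep]))
}

#' Delineate candidate repetitive and potential non-repetitive regions
#'
#' Candidate cores are maximal runs of smoothed scores at or above the
#' threshold \code{t}; cores separated by a sub-threshold gap shorter than
#' the mask width are bridged into one candidate, and a candidate is kept
#' only if it contains at least one detected local maximum. Potential
#' non-repetitive regions are the sub-threshold runs, outside candidates,
#' of length at least the mask width. Short ambiguous leftovers belong to
#' neither list.
#'
#' @param smoothed Numeric smoothed track.
#' @param maxima Positions from [local_maxima()] on the same track.
#' @param t Low-score threshold (> 1; it doubles as the HMM's log base).
#' @param mask_width Width of the smoothing mask (2h+1), used as the
#'   bridging and minimum-non-repeat length.
#' @param seq_name Sequence name stamped on the output regions.
#' @return List of class \code{labeled_regions}: \code{candidates} and
#'   \code{nonrepeats} (regions data.frames, 0-based half-open) and
#'   \code{maxima}.
#' @export
delineate_regions <- function(smoothed, maxima, t = 2, mask_width = 41L,
                              seq_name = "seq") {
  if (t <= 1) stop("t must be > 1 (it is also the HMM log base)")
  n <- length(smoothed)
  high <- smoothed >= t
  r <- rle(high)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hi <- which(r$values)
  cand <- empty_regions()
  if (length(hi)) {
    # bridge high runs separated by short low gaps
    cs <- starts[hi]; ce <- ends[hi]
    new_grp <- c(TRUE, cs[-1] - ce[-length(ce)] - 1L >= mask_width)
    grp_end <- c(which(new_grp[-1]) , length(cs))
    merged <- cbind(cs[new_grp], ce[grp_end])
    mx <- sort(maxima)
    has_max <- findInterval(merged[, 2], mx) >
      findInterval(merged[, 1] - 1L, mx)
    merged <- merged[has_max, , drop = FALSE]
    if (nrow(merged)) {
      cand <- regions(seq_name, merged[, 1] - 1L, merged[, 2])
    }
  }
  # complement of the candidates, restricted to sub-threshold runs of
  # at least mask_width positions
  covered <- logical(n)
  for (j in seq_len(nrow(cand))) {
    covered[(cand$start[j] + 1L):cand$end[j]] <- TRUE
  }
  free_low <- !covered & !high
  rl <- rle(free_low)
  e2 <- cumsum(rl$lengths)
  s2 <- e2 - rl$lengths + 1L
  keep <- which(rl$values & rl$lengths >= mask_width)
  nonrep <- if (length(keep)) {
    regions(seq_name, s2[keep] - 1L, e2[keep])
  } else {
    empty_regions()
  }
  structure(list(candidates = cand, nonrepeats = nonrep, maxima = maxima),
            class = "labeled_regions")
}
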