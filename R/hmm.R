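ceil_tol <- function(x, tol = 1e-9) ceiling(x - tol)

#' Logarithmic output level of a score
#'
#' Maps a score to its HMM output level: \code{ceiling(log_t(s))} for
#' positive scores (floored at level 0 for fractional scores below 1), and
#' 0 for scores at or below 0. Every state of the segmentation HMM emits
#' exactly one level, so output probabilities are always 1.
#'
#' @param score Numeric score(s).
#' @param t Log base (> 1); the same value as the labeling low-score
#'   threshold.
#' @return Integer level(s), >= 0.
#' @export
output_level <- function(score, t) {
  if (t <= 1) stop("t must be > 1")
  lev <- integer(length(score))
  pos <- which(score > 0)
  if (length(pos)) {
    lev[pos] <- pmax(as.integer(ceil_tol(log(score[pos]) / log(t))), 0L)
  }
  lev
}

#' Build an untrained segmentation HMM
#'
#' Two parallel state tracks — non-repeat and repeat — each with one state
#' per output level \code{0..L}, where \code{L = ceiling(log_t(max_score))}
#' (at least 1 for any positive maximum score, so the smallest non-degenerate
#' model has the didactic four states; a genome with an all-zero score track
#' yields the two level-0 states only). States are indexed non-repeat
#' first, lower level first. Priors and transitions start as add-one
#' pseudocount mass.
#'
#' @param max_score Largest score observed in the genome.
#' @param t Log base (> 1).
#' @return Object of class \code{repeat_hmm}: \code{t}, \code{n_levels},
#'   \code{n_states}, \code{priors}, \code{transitions}, \code{trained}.
#' @export
build_hmm <- function(max_score, t = 2) {
  if (t <= 1) stop("t must be > 1")
  n_levels <- if (max_score <= 0) 1L else {
    as.integer(max(1, ceil_tol(log(max_score) / log(t)))) + 1L
  }
  n_states <- 2L * n_levels
  structure(list(t = t, n_levels = n_levels, n_states = n_states,
                 priors = rep(1 / n_states, n_states),
                 transitions = matrix(1 / n_states, n_states, n_states),
                 trained = FALSE),
            class = "repeat_hmm")
}

# state id for (track, level): non-repeat track = 0, repeat track = 1;
# id = track * n_levels + level + 1
state_id <- function(track, level, n_levels) {
  track * n_levels + level + 1L
}

state_track <- function(id, n_levels) as.integer(id > n_levels)
state_level <- function(id, n_levels) as.integer((id - 1L) %% n_levels)

# state sequence of one labeled region
region_states <- function(scores, start, end, track, model) {
  lev <- pmin(output_level(scores[(start + 1L):end], model$t),
              model$n_levels - 1L)
  state_id(track, lev, model$n_levels)
}

# per-position state ids of a whole track under both labels, computed once
track_states <- function(scores, model) {
  lev <- pmin(output_level(scores, model$t), model$n_levels - 1L)
  list(nonrep = lev + 1L, rep = model$n_levels + lev + 1L)
}

#' Train the segmentation HMM on auto-labeled regions
#'
#' Priors are the add-one-smoothed frequencies of the first state of every
#' labeled region. Transitions are the add-one-smoothed frequencies of
#' successive state pairs within each region, plus one transition between
#' the adjoining states of each pair of consecutive labeled regions on the
#' same sequence — without those cross-boundary counts the repeat/non-repeat
#' switching probabilities would be pure pseudocount.
#'
#' @param model A [build_hmm()] model.
#' @param tracks Named list of numeric score tracks (raw scores, one per
#'   sequence).
#' @param labels Named list of [delineate_regions()] results aligned with
#'   \code{tracks}.
#' @return The model with \code{priors} and \code{transitions} estimated;
#'   each row of \code{transitions} and the priors sum to 1.
#' @export
train_hmm <- function(model, tracks, labels) {
  S <- model$n_states
  first_states <- integer(0)
  from_states <- integer(0)
  to_states <- integer(0)
  n_regions <- 0L
  for (nm in names(tracks)) {
    lab <- labels[[nm]]
    cand <- lab$candidates
    nonr <- lab$nonrepeats
    reg <- rbind(
      if (nrow(cand)) cbind(cand[c("start", "end")], track = 1L),
      if (nrow(nonr)) cbind(nonr[c("start", "end")], track = 0L)
    )
    if (is.null(reg) || nrow(reg) == 0L) next
    reg <- reg[order(reg$start), , drop = FALSE]
    n_regions <- n_regions + nrow(reg)
    ts <- track_states(tracks[[nm]], model)
    sts <- lapply(seq_len(nrow(reg)), function(j) {
      idx <- (reg$start[j] + 1L):reg$end[j]
      if (reg$track[j] == 1L) ts$rep[idx] else ts$nonrep[idx]
    })
    first_states <- c(first_states, vapply(sts, `[`, 0L, 1L))
    # within-region successive pairs, plus one cross-boundary transition
    # between each pair of adjoining labeled regions
    from_states <- c(from_states,
                     unlist(lapply(sts, function(s) s[-length(s)])),
                     vapply(sts[-length(sts)], function(s) s[length(s)], 0L))
    to_states <- c(to_states,
                   unlist(lapply(sts, `[`, -1L)),
                   vapply(sts[-1L], `[`, 0L, 1L))
  }
  if (n_regions == 0L) {
    stop("no labeled regions to train on; review the labeling parameters ",
         "(threshold t, mask width)")
  }
  prior_counts <- 1 + tabulate(first_states, S)  # add-one pseudocounts
  trans_counts <- matrix(
    1 + tabulate((to_states - 1L) * S + from_states, S * S), S, S)
  model$priors <- prior_counts / sum(prior_counts)
  model$transitions <- trans_counts / rowSums(trans_counts)
  model$trained <- TRUE
  model
}

#' Viterbi decoding of a score track
#'
#' Finds the maximum-probability state path. Because each state emits
#' exactly one output level, the path is constrained at every position to
#' the two states (non-repeat and repeat) matching that position's level;
#' the dynamic program therefore carries just two live states. Computed in
#' log space; ties broken toward the lower state index (non-repeat, then
#' lower level), so decoding is deterministic.
#'
#' @param model A trained [build_hmm()] model (any stochastic priors and
#'   transitions are accepted).
#' @param scores Numeric score track.
#' @return Integer vector of state ids, one per position.
#' @export
viterbi <- function(model, scores) {
  n <- length(scores)
  if (n == 0L) return(integer())
  L1 <- model$n_levels
  S <- model$n_states
  lev <- pmin(output_level(scores, model$t), L1 - 1L)
  lp <- log(model$priors)
  lt <- log(model$transitions)  # column-major; (a,b) at a + (b-1)*S
  nr <- lev + 1L        # non-repeat state per position
  rp <- L1 + lev + 1L   # repeat state per position
  back <- matrix(0L, 2L, n)
  v1 <- lp[nr[1L]]
  v2 <- lp[rp[1L]]
  for (i in 2:n) {
    p1 <- nr[i - 1L]; p2 <- rp[i - 1L]
    c1 <- nr[i]; c2 <- rp[i]
    a <- v1 + lt[p1 + (c1 - 1L) * S]
    b <- v2 + lt[p2 + (c1 - 1L) * S]
    if (a >= b) { nv1 <- a; back[1L, i] <- 1L } else { nv1 <- b; back[1L, i] <- 2L }
    a <- v1 + lt[p1 + (c2 - 1L) * S]
    b <- v2 + lt[p2 + (c2 - 1L) * S]
    if (a >= b) { nv2 <- a; back[2L, i] <- 1L } else { nv2 <- b; back[2L, i] <- 2L }
    v1 <- nv1; v2 <- nv2
  }
  track <- integer(n)
  track[n] <- if (v1 >= v2) 1L else 2L
  if (n > 1L) {
    for (i in n:2) track[i - 1L] <- back[track[i], i]
  }
  ifelse(track == 1L, nr, rp)
}

#' Final repeat regions from a decoded state path
#'
#' Maximal runs of repeat-track states become regions; each region's end is
#' extended by k-1 positions (the right k-1 nucleotides belong to the final
#' k-mer of the region), clipped to the sequence length, and regions that
#' abut or overlap after extension are merged.
#'
#' @param path Integer state ids from [viterbi()].
#' @param k Word length used for scoring.
#' @param n_levels The model's number of levels (to tell the tracks apart).
#' @param seq_name Name stamped on the regions.
#' @param seq_len Sequence length for clipping; defaults to the path length.
#' @return Regions data.frame (0-based half-open).
#' @export
decode_regions <- function(path, k, n_levels, seq_name = "seq",
                           seq_len = length(path)) {
  rep_state <- path > n_levels
  r <- rle(rep_state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values)
  if (!length(hit)) return(empty_regions())
  out <- regions(seq_name, starts[hit] - 1L,
                 pmin(ends[hit] + k - 1L, seq_len))
  merge_regions(out)
}

#' @export
print.repeat_hmm <- function(x, ...) {
  cat("Segmentation HMM: ", x$n_states, " states (2 tracks x ",
      x$n_levels, " levels), log base t = ", x$t,
      if (x$trained) ", trained" else ", untrained", "\n", sep = "")
  invisible(x)
}
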