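#' Fit a self-training repeat detector to a genome
#'
#' The full training pipeline: count every k-mer of the genome, adjust the
#' counts against a Markov background chain trained on the same genome,
#' score every position with the adjusted count of the k-mer starting
#' there, smooth the score track with a Gaussian mask, auto-label candidate
#' repetitive regions (smoothed runs above \code{t} containing a
#' second-derivative local maximum) and potential non-repetitive regions,
#' and train the two-track logarithmic-level HMM on those labels. The
#' entire fit is deterministic: no randomness anywhere in detection.
#'
#' Multi-record inputs are treated as one genome for counting, background
#' training and HMM training; score tracks and regions remain per record.
#'
#' @param genome Named character vector of DNA strings, or the path to a
#'   FASTA file.
#' @param k Word length; default \code{floor(log4(valid bases))} clamped to
#'   \[8, 16\] (see [default_k()]).
#' @param order Background chain order (default 6; must be < k).
#' @param sigma Gaussian mask standard deviation in positions; the default
#'   40/7 gives the canonical mask width of about 40.
#' @param w Derivative window length (default 10).
#' @param t Low-score threshold and HMM log base (default 2).
#' @param mode \code{"genome"} for assembled input; \code{"reads"} for
#'   unassembled short reads. The machinery is identical — k is derived
#'   from the pooled base count across reads and every read is scored
#'   independently — the flag is recorded so downstream reports can state
#'   how the model was trained.
#' @param max_table Capacity cap on the dense k-mer table.
#' @return Object of class \code{repeat_detector} with components
#'   \code{k}, \code{order}, \code{t}, \code{sigma}, \code{w},
#'   \code{table} (adjusted k-mer table), \code{background}, \code{hmm}
#'   (trained), \code{genome}, \code{tracks} (raw score tracks),
#'   \code{labels} (per-sequence auto-labels), \code{mask_width}.
#' @seealso [predict.repeat_detector()] to decode repeats, [mask_repeats()]
#'   for the one-call pipeline.
#' @examples
#' g <- c(chr = paste(c(rep("ACGTTGCA", 30),
#'                      rep(strrep("GATTACAT", 40), 1)), collapse = ""))
#' fit <- repeat_detector(g, k = 8, order = 2)
#' fit
#' @export
repeat_detector <- function(genome, k = NULL, order = 6L, sigma = 40 / 7,
                            w = 10L, t = 2, mode = c("genome", "reads"),
                            max_table = 4^12) {
  mode <- match.arg(mode)
  cl <- match.call()
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome)) &&
      file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  if (is.null(names(genome)) || anyNA(names(genome))) {
    stop("genome sequences must be named")
  }
  if (t <= 1) stop("t must be > 1")
  if (is.null(k)) k <- default_k(genome, max_table)
  k <- as.integer(k)
  order <- as.integer(order)
  if (order >= k) stop("background order (", order, ") must be < k (", k, ")")

  observed <- count_kmers(genome, k, max_table)
  background <- train_background(genome, order)
  table <- adjust_counts(observed, background)

  mask <- gaussian_mask(sigma)
  mask_width <- length(mask$weights)
  tracks <- lapply(genome, score_sequence, table = table)
  labels <- lapply(names(genome), function(nm) {
    sm <- smooth_track(tracks[[nm]], mask)
    mx <- local_maxima(sm, w)
    delineate_regions(sm, mx, t = t, mask_width = mask_width, seq_name = nm)
  })
  names(labels) <- names(genome)

  max_score <- max(0, vapply(tracks, function(x) if (length(x)) max(x) else 0, 0))
  hmm <- build_hmm(max_score, t)
  hmm <- train_hmm(hmm, tracks, labels)

  structure(list(call = cl, k = k, order = order, sigma = sigma, w = w,
                 t = t, mode = mode, mask_width = mask_width,
                 table = table, background = background, hmm = hmm,
                 genome = genome, tracks = tracks, labels = labels),
            class = "repeat_detector")
}

#' Decode repeat regions with a fitted detector
#'
#' Scores the sequences with the fitted adjusted k-mer table, Viterbi-decodes
#' each score track with the trained HMM, and converts maximal runs of
#' repeat-track states into regions, extending each region's end by k-1
#' positions.
#'
#' @param object A [repeat_detector()] fit.
#' @param newdata Optional genome (named character vector or FASTA path) to
#'   scan; defaults to the training genome, whose score tracks are reused.
#' @param type \code{"regions"} (default) returns the final repeat regions;
#'   \code{"path"} returns the per-sequence state paths.
#' @param ... Unused.
#' @return Regions data.frame (0-based half-open), or a named list of state
#'   paths.
#' @export
predict.repeat_detector <- function(object, newdata = NULL,
                                    type = c("regions", "path"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (is.null(object$genome)) {
      stop("this model carries no training genome; supply newdata")
    }
    seqs <- object$genome
    tracks <- object$tracks
  } else {
    if (is.character(newdata) && length(newdata) == 1L &&
        is.null(names(newdata)) && file.exists(newdata)) {
      newdata <- read_fasta(newdata)
    }
    seqs <- newdata
    tracks <- lapply(seqs, score_sequence, table = object$table)
  }
  paths <- lapply(tracks, viterbi, model = object$hmm)
  if (type == "path") return(paths)
  out <- empty_regions()
  for (nm in names(paths)) {
    out <- rbind(out, decode_regions(paths[[nm]], object$k,
                                     object$hmm$n_levels, seq_name = nm,
                                     seq_len = nchar(seqs[[nm]])))
  }
  rownames(out) <- NULL
  sort_regions(out)
}

#' One-call repeat masking pipeline
#'
#' Fits [repeat_detector()], decodes the final repeats, and masks them.
#'
#' @inheritParams repeat_detector
#' @param mask_mode \code{"soft"} (lowercase, the default) or \code{"hard"}
#'   (N) masking.
#' @param ... Passed to [repeat_detector()].
#' @return List with \code{model}, \code{repeats} (regions data.frame) and
#'   \code{masked} (masked sequences).
#' @export
mask_repeats <- function(genome, mask_mode = c("soft", "hard"), ...) {
  mask_mode <- match.arg(mask_mode)
  fit <- repeat_detector(genome, ...)
  reps <- predict(fit)
  masked <- mask_sequences(fit$genome, reps, mask_mode)
  list(model = fit, repeats = reps, masked = masked)
}

#' @export
print.repeat_detector <- function(x, ...) {
  n_cand <- sum(vapply(x$labels, function(l) nrow(l$candidates), 0L))
  n_non <- sum(vapply(x$labels, function(l) nrow(l$nonrepeats), 0L))
  cat("Self-training repeat detector\n")
  cat("  genome: ", length(x$genome), " sequence(s), ",
      format(sum(nchar(x$genome)), big.mark = ","), " bp\n", sep = "")
  cat("  k = ", x$k, ", background order = ", x$order,
      ", sigma = ", signif(x$sigma, 4), ", w = ", x$w, ", t = ", x$t,
      ", mode = ", x$mode, "\n", sep = "")
  cat("  auto-labels: ", n_cand, " candidate region(s), ", n_non,
      " non-repetitive region(s)\n", sep = "")
  cat("  HMM: ", x$hmm$n_states, " states (", x$hmm$n_levels,
      " levels per track)\n", sep = "")
  invisible(x)
}

#' @export
summary.repeat_detector <- function(object, ...) {
  cand_bp <- sum(vapply(object$labels, function(l) {
    sum(l$candidates$end - l$candidates$start)
  }, 0))
  non_bp <- sum(vapply(object$labels, function(l) {
    sum(l$nonrepeats$end - l$nonrepeats$start)
  }, 0))
  total_bp <- sum(nchar(object$genome))
  n_hot <- sum(object$table$values > 0)
  structure(list(fit = object, cand_bp = cand_bp, non_bp = non_bp,
                 total_bp = total_bp, n_repetitive_words = n_hot,
                 max_score = max(object$table$values)),
            class = "summary.repeat_detector")
}

#' @export
print.summary.repeat_detector <- function(x, ...) {
  print(x$fit)
  cat("  repetitive words (adjusted count > 0): ",
      format(x$n_repetitive_words, big.mark = ","), " of 4^", x$fit$k,
      "; max adjusted count ", signif(x$max_score, 5), "\n", sep = "")
  cat(sprintf("  candidate coverage: %.2f%%; non-repetitive coverage: %.2f%%\n",
              100 * x$cand_bp / x$total_bp, 100 * x$non_bp / x$total_bp))
  invisible(x)
}

#' @export
coef.repeat_detector <- function(object, ...) {
  list(priors = object$hmm$priors, transitions = object$hmm$transitions)
}

#' Plot the smoothed score track and labels of one sequence
#'
#' @param x A [repeat_detector()] fit.
#' @param seq Sequence name or index to plot.
#' @param xlim Optional position range.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.repeat_detector <- function(x, seq = 1L, xlim = NULL, ...) {
  nm <- if (is.character(seq)) seq else names(x$genome)[seq]
  sm <- smooth_track(x$tracks[[nm]], gaussian_mask(x$sigma))
  pos <- seq_along(sm)
  if (is.null(xlim)) xlim <- range(pos)
  graphics::plot(pos, sm, type = "l", xlab = "position",
                 ylab = "smoothed score", xlim = xlim, main = nm, ...)
  graphics::abline(h = x$t, lty = 2, col = "grey40")
  lab <- x$labels[[nm]]
  if (nrow(lab$candidates)) {
    graphics::rect(lab$candidates$start + 1, graphics::par("usr")[3],
                   lab$candidates$end, 0, col = "#d6604d80", border = NA)
  }
  if (length(lab$maxima)) {
    graphics::points(lab$maxima, sm[lab$maxima], pch = 3, col = "#b2182b")
  }
  invisible(x)
}

#' Simulate output-level sequences from the fitted HMM
#'
#' Samples state paths from the trained priors and transitions and reports
#' the emitted output levels (each state emits its level with probability
#' 1). Useful for inspecting what score structure the trained model
#' believes in.
#'
#' @param object A [repeat_detector()] fit.
#' @param nsim Number of sequences.
#' @param seed Optional RNG seed.
#' @param n Length of each simulated sequence.
#' @param ... Unused.
#' @return List of integer level vectors; each carries the sampled state
#'   path as attribute \code{"states"}.
#' @export
simulate.repeat_detector <- function(object, nsim = 1, seed = NULL,
                                     n = 1000L, ...) {
  hmm <- object$hmm
  with_seed(seed, {
    lapply(seq_len(nsim), function(j) {
      states <- integer(n)
      states[1L] <- sample.int(hmm$n_states, 1L, prob = hmm$priors)
      for (i in seq_len(n - 1L)) {
        states[i + 1L] <- sample.int(hmm$n_states, 1L,
                                     prob = hmm$transitions[states[i], ])
      }
      structure(state_level(states, hmm$n_levels), states = states)
    })
  })
}
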