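#' Quaternary index of a k-mer
#'
#' Maps a DNA word to its table index by reading the bases A, C, G, T as the
#' base-4 digits 0, 1, 2, 3, leftmost base most significant:
#' \eqn{index = \sum_i d_i 4^{k-1-i}}. The mapping is a bijection between
#' the 4^k words of length k and the integers \code{[0, 4^k)}.
#'
#' @param word A single DNA string (case-insensitive).
#' @return The index as a double (indices exceed .Machine$integer.max for
#'   k > 15), or \code{NA} if the word contains any non-A/C/G/T base.
#' @examples
#' encode_kmer("AAA")  # 0
#' encode_kmer("CGT")  # 1*16 + 2*4 + 3 = 27
#' @export
encode_kmer <- function(word) {
  d <- seq_codes(word)
  if (anyNA(d)) return(NA_real_)
  sum(d * 4^(rev(seq_along(d)) - 1))
}

#' Rolling k-mer indices of a sequence
#'
#' Computes the quaternary index of every k-window of a sequence
#' incrementally by Horner's rule: \code{next = (prev mod 4^(k-1)) * 4 +
#' digit}. Windows containing any invalid (non-A/C/G/T) base yield
#' \code{NA} and the rolling computation restarts after the invalid base.
#'
#' @param seq A DNA string, or an integer code vector from an internal call.
#' @param k Word length, >= 1.
#' @return Numeric vector of length \code{nchar(seq) - k + 1} (empty if the
#'   sequence is shorter than k): the index of the window starting at each
#'   position, \code{NA} for invalid windows.
#' @export
rolling_indices <- function(seq, k) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  d <- if (is.character(seq)) seq_codes(seq) else as.integer(seq)
  n <- length(d)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  # Horner evaluation, vectorized over all window starts; NA codes
  # propagate so any window touching an invalid base comes out NA.
  idx <- as.numeric(d[seq_len(m)])
  if (k > 1L) {
    for (j in 2:k) idx <- idx * 4 + d[j:(j + m - 1L)]
  }
  idx
}

#' Count all k-mers of a genome
#'
#' Single pass over every record, forward strand only. The table is dense:
#' entry \code{i + 1} holds the observed count of the word with quaternary
#' index \code{i}.
#'
#' @param seqs Named character vector of DNA strings.
#' @param k Word length.
#' @param max_table Capacity cap on the dense table (number of entries).
#' @return Object of class \code{kmer_table}: list with \code{k},
#'   \code{counts} (length 4^k), and \code{n_windows} (total valid windows,
#'   which equals \code{sum(counts)}).
#' @export
count_kmers <- function(seqs, k, max_table = 4^12) {
  k <- as.integer(k)
  if (4^k > max_table) {
    stop("4^k = ", format(4^k, scientific = FALSE), " exceeds the table ",
         "capacity cap (", format(max_table, scientific = FALSE),
         "); use a smaller k or raise max_table")
  }
  counts <- integer(4^k)
  for (s in seqs) {
    idx <- rolling_indices(s, k)
    idx <- idx[!is.na(idx)]
    if (length(idx)) {
      counts <- counts + tabulate(as.integer(idx) + 1L, nbins = 4^k)
    }
  }
  if (sum(counts) == 0) stop("no valid k-window in the input")
  structure(list(k = k, counts = counts, n_windows = sum(counts)),
            class = "kmer_table")
}

#' Train a Markov-chain background on a genome
#'
#' Maximum-likelihood conditional base frequencies given each preceding
#' context of length \code{order}, estimated over valid (A/C/G/T) stretches
#' of all records. Contexts never observed fall back to the uniform
#' distribution. The trained chain supplies the expected count that
#' repetition is measured against, so compositional bias (including whole
#' genome duplication / polyploidy, which an order-6 chain can capture) is
#' subtracted out of the score.
#'
#' @param seqs Named character vector of DNA strings.
#' @param order Chain order, >= 0.
#' @return Object of class \code{markov_background}: \code{order},
#'   \code{cond} (4^(order+1) conditional probabilities, context-major),
#'   \code{ctx_freq} (4^order empirical context frequencies), and
#'   \code{total_positions} (valid windows of length order+1 seen).
#' @export
train_background <- function(seqs, order) {
  order <- as.integer(order)
  if (order < 0L) stop("order must be >= 0")
  joint <- integer(4^(order + 1L))
  for (s in seqs) {
    idx <- rolling_indices(s, order + 1L)
    idx <- idx[!is.na(idx)]
    if (length(idx)) {
      joint <- joint + tabulate(as.integer(idx) + 1L, nbins = 4^(order + 1L))
    }
  }
  total <- sum(joint)
  if (total == 0) stop("no valid stretch longer than the chain order")
  # joint is context-major: index = ctx*4 + base, so base varies fastest
  ctx_tot <- colSums(matrix(joint, nrow = 4L))
  cond <- joint / rep(ctx_tot, each = 4L)
  cond[rep(ctx_tot == 0, each = 4L)] <- 0.25
  ctx_freq <- ctx_tot / total
  structure(list(order = order, cond = cond, ctx_freq = ctx_freq,
                 total_positions = total),
            class = "markov_background")
}

# Chain probability of each word given by its quaternary index.
# P(word) = P(leading order-context) * prod_j P(base_j | context_j).
word_probability <- function(idx, k, background) {
  o <- background$order
  if (k <= o) stop("word length k must exceed the background order")
  prefix <- idx %/% 4^(k - o)
  p <- background$ctx_freq[prefix + 1]
  for (j in o:(k - 1L)) {
    sub <- (idx %/% 4^(k - 1L - j)) %% 4^(o + 1L)
    p <- p * background$cond[sub + 1]
  }
  p
}

#' Expected genome-wide count of a word under the background chain
#'
#' The expectation is \code{n_windows * P(word)} where \code{P(word)} is the
#' chain probability of the word: the empirical frequency of its leading
#' \code{order}-context times the product of the trained conditional
#' probabilities of each following base.
#'
#' @param word A DNA string, or a numeric vector of quaternary indices (in
#'   which case \code{k} must be given).
#' @param background A [train_background()] fit.
#' @param n_windows Number of valid k-windows to scale by; defaults to the
#'   background's \code{total_positions}.
#' @param k Word length when \code{word} is a vector of indices.
#' @return Non-negative expected count(s).
#' @export
expected_count <- function(word, background, n_windows = NULL, k = NULL) {
  if (is.character(word)) {
    k <- nchar(word)
    idx <- encode_kmer(word)
  } else {
    if (is.null(k)) stop("k must be supplied with numeric word indices")
    idx <- word
  }
  if (is.null(n_windows)) n_windows <- background$total_positions
  n_windows * word_probability(idx, k, background)
}

#' The count-adjustment rule
#'
#' A word's adjusted count is 0 if it was observed at most twice (screening
#' out single-copy sequence and ordinary duplications), 0 if its observed
#' count does not exceed its background expectation, and
#' \code{observed - expected} otherwise.
#'
#' @param observed Observed count(s).
#' @param expected Expected count(s) under the background chain.
#' @return Adjusted count(s); non-negative, never larger than observed.
#' @export
adjusted_count <- function(observed, expected) {
  ifelse(observed <= 2, 0, pmax(0, observed - expected))
}

#' Adjust a k-mer count table against a background chain
#'
#' Applies [adjusted_count()] to every word, computing expectations (scaled
#' by the table's own number of valid windows) only for the words whose
#' observed count is at least 3 — all others are 0 by rule.
#'
#' @param observed A [count_kmers()] table.
#' @param background A [train_background()] fit on the same genome, with
#'   \code{order < k}.
#' @return Object of class \code{kmer_table} with numeric \code{values}
#'   (adjusted counts) alongside the original \code{counts}.
#' @export
adjust_counts <- function(observed, background) {
  k <- observed$k
  if (background$order >= k) stop("background order must be < k")
  values <- numeric(length(observed$counts))
  hot <- which(observed$counts >= 3L)
  if (length(hot)) {
    exp_hot <- expected_count(hot - 1, background,
                              n_windows = observed$n_windows, k = k)
    values[hot] <- pmax(0, observed$counts[hot] - exp_hot)
  }
  structure(list(k = k, counts = observed$counts, values = values,
                 n_windows = observed$n_windows),
            class = "kmer_table")
}

#' Score a sequence with an adjusted k-mer table
#'
#' The score of a position is the adjusted count of the k-mer starting
#' there; positions where no valid k-window starts (the last k-1 positions,
#' or any window touching an invalid base) score 0.
#'
#' @param seq A DNA string.
#' @param table An [adjust_counts()] table.
#' @return Numeric score track with one value per sequence position.
#' @export
score_sequence <- function(seq, table) {
  if (is.null(table$values)) stop("table has not been adjusted")
  n <- nchar(seq)
  k <- table$k
  scores <- numeric(n)
  if (n >= k) {
    idx <- rolling_indices(seq, k)
    v <- table$values[idx + 1]
    v[is.na(v)] <- 0
    scores[seq_along(v)] <- v
  }
  scores
}

#' Default word length for a genome
#'
#' \code{floor(log4(total valid bases))}, clamped to \[8, 16\] and to the
#' largest k the table capacity allows. At this k the expected count of a
#' random word is about 1, so genuine repetition stands out from noise.
#'
#' @param seqs Named character vector of DNA strings.
#' @param max_table Table capacity cap.
#' @return Integer word length.
#' @export
default_k <- function(seqs, max_table = 4^12) {
  valid <- sum(vapply(seqs, function(s) sum(valid_mask(s)), 0))
  k <- floor(log(max(valid, 2), base = 4))
  k <- min(max(k, 8L), 16L)
  min(k, floor(log(max_table, base = 4)))
}
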