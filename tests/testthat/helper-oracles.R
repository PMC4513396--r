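# Independent brute-force oracles used against the package implementation.

# random A/C/G/T text
random_text <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# direct per-window quaternary encoding via string arithmetic (no Horner)
oracle_encode <- function(word) {
  strtoi(chartr("ACGT", "0123", word), base = 4L)
}

oracle_window_indices <- function(text, k) {
  n <- nchar(text)
  if (n < k) return(numeric(0))
  words <- substring(text, 1:(n - k + 1L), k:n)
  out <- suppressWarnings(strtoi(chartr("ACGT", "0123", words), base = 4L))
  out[grepl("[^ACGT]", words)] <- NA
  as.numeric(out)
}

# per-position weighted mean, straight from the definition
oracle_smooth <- function(scores, weights) {
  n <- length(scores)
  h <- (length(weights) - 1L) / 2L
  vapply(seq_len(n), function(i) {
    j <- (i - h):(i + h)
    ok <- j >= 1L & j <= n
    sum(scores[j[ok]] * weights[ok]) / sum(weights[ok])
  }, 0)
}

# exhaustive maximum-probability path over the two level-consistent states
# per position
oracle_viterbi <- function(model, scores) {
  n <- length(scores)
  L1 <- model$n_levels
  lev <- pmin(output_level(scores, model$t), L1 - 1L)
  choices <- expand.grid(rep(list(0:1), n))  # track per position
  best_lp <- -Inf
  best <- NULL
  for (r in seq_len(nrow(choices))) {
    tr <- as.integer(choices[r, ])
    st <- tr * L1 + lev + 1L
    lp <- log(model$priors[st[1L]])
    if (n > 1L) {
      lp <- lp + sum(log(model$transitions[cbind(st[-n], st[-1L])]))
    }
    if (lp > best_lp + 1e-12) { best_lp <- lp; best <- st }
  }
  list(path = best, logp = best_lp)
}

# per-base bitmap interval arithmetic
oracle_bitmap <- function(r, seq_names, lens) {
  out <- lapply(seq_along(seq_names), function(i) logical(lens[i]))
  names(out) <- seq_names
  for (i in seq_len(nrow(r))) {
    sn <- r$seq_name[i]
    out[[sn]][(r$start[i] + 1):r$end[i]] <- TRUE
  }
  out
}

oracle_overlap_bp <- function(a, b, seq_names, lens) {
  ba <- oracle_bitmap(a, seq_names, lens)
  bb <- oracle_bitmap(b, seq_names, lens)
  sum(vapply(seq_names, function(sn) sum(ba[[sn]] & bb[[sn]]), 0))
}

# base composition helpers for statistical checks
base_freqs <- function(seq) {
  tabulate(seq_codes(seq) + 1L, 4L) / nchar(seq)
}

dinuc_freqs <- function(seq) {
  idx <- rolling_indices(seq, 2L)
  tabulate(as.integer(idx) + 1L, 16L) / length(idx)
}

seq_codes <- repdetect:::seq_codes
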