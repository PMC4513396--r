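# Intersection length of two sorted non-overlapping interval sets
# (vectors of starts/ends), by a two-pointer sweep.
sweep_overlap <- function(s1, e1, s2, e2) {
  i <- 1L; j <- 1L; total <- 0
  n1 <- length(s1); n2 <- length(s2)
  while (i <= n1 && j <= n2) {
    lo <- max(s1[i], s2[j])
    hi <- min(e1[i], e2[j])
    if (hi > lo) total <- total + (hi - lo)
    if (e1[i] <= e2[j]) i <- i + 1L else j <- j + 1L
  }
  total
}

#' Base-pair overlap between two region sets
#'
#' Total length of the intersection, per sequence, after merging each set's
#' overlapping intervals. This is the shared primitive O of the sensitivity
#' and specificity measures.
#'
#' @param a,b Regions data.frames.
#' @return Total intersected length in bp.
#' @export
overlap_bp <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  a <- merge_regions(a)
  b <- merge_regions(b)
  total <- 0
  for (sn in intersect(unique(a$seq_name), unique(b$seq_name))) {
    x <- a[a$seq_name == sn, ]
    y <- b[b$seq_name == sn, ]
    total <- total + sweep_overlap(x$start, x$end, y$start, y$end)
  }
  total
}

region_bp <- function(r) {
  if (nrow(r) == 0L) return(0)
  m <- merge_regions(r)
  sum(m$end - m$start)
}

#' Sensitivity to annotated repeats
#'
#' \eqn{SN = 100 \times O / R}: the percentage of annotated repeat bases
#' (optionally of one class) covered by the predictions. Classes that
#' overlap are pooled by interval union, never by summing lengths.
#'
#' @param pred Predicted regions.
#' @param truth Annotated regions; a \code{class} column supports
#'   class-restricted sensitivity.
#' @param class Optional class tag (e.g. \code{"te"}, \code{"tr"},
#'   \code{"low"}, \code{"other"}); \code{NULL} pools all classes.
#' @return Percentage in \[0, 100\], or \code{NA} if the (filtered) truth is
#'   empty — undefined, not zero.
#' @export
sensitivity <- function(pred, truth, class = NULL) {
  if (!is.null(class) && "class" %in% names(truth)) {
    truth <- truth[truth$class %in% class, , drop = FALSE]
  } else if (!is.null(class)) {
    truth <- truth[0, , drop = FALSE]
  }
  R <- region_bp(truth)
  if (R == 0) return(NA_real_)
  100 * overlap_bp(pred, truth) / R
}

#' Exon-avoidance specificity
#'
#' \eqn{SP = 100 - 100 \times O / E}: the percentage of coding bases the
#' detector avoids calling repetitive.
#'
#' @param pred Predicted regions.
#' @param exons Exon regions.
#' @return Percentage, or \code{NA} if there are no exon bases.
#' @export
specificity_exon <- function(pred, exons) {
  E <- region_bp(exons)
  if (E == 0) return(NA_real_)
  100 - 100 * overlap_bp(pred, exons) / E
}

#' Percentage of the genome predicted repetitive
#'
#' @param pred Predicted regions.
#' @param seqs Named character vector of genome sequences; the denominator
#'   is the number of valid (A/C/G/T) bases.
#' @return Percentage in \[0, 100\].
#' @export
percentage_predicted <- function(pred, seqs) {
  valid <- sum(vapply(seqs, function(s) sum(valid_mask(s)), 0))
  if (valid == 0) stop("genome has no valid bases")
  100 * region_bp(pred) / valid
}

#' Generate a composition-matched random genome
#'
#' For each input sequence, trains an order-\code{order} Markov chain on
#' that sequence and samples a synthetic sequence of the same length from
#' it, so the random genome matches the real one in local composition but
#' carries none of its repeat structure beyond what the chain encodes. The
#' chain is seeded with the sequence's first \code{order} valid bases, so a
#' degenerate input (e.g. all A) reproduces itself exactly.
#'
#' @param seqs Named character vector of DNA strings.
#' @param order Chain order (default 6).
#' @param seed RNG seed; the output is byte-reproducible for a fixed seed.
#' @return Named character vector of synthetic sequences, same names and
#'   lengths.
#' @export
random_genome <- function(seqs, order = 6L, seed = NULL) {
  order <- as.integer(order)
  with_seed(seed, {
    out <- vapply(names(seqs), function(nm) {
      s <- seqs[[nm]]
      bg <- train_background(s, order)
      init <- seq_codes(substr(s, 1L, order))
      if (order > 0L && anyNA(init)) init <- NULL
      sample_markov_chain(nchar(s), bg, init)
    }, "")
    names(out) <- names(seqs)
    out
  })
}

# Sample n bases from a trained chain. init: integer codes of the starting
# context (length order), or NULL to draw the context from ctx_freq.
sample_markov_chain <- function(n, background, init = NULL) {
  o <- background$order
  cond <- matrix(background$cond, nrow = 4L)  # base x context
  cum1 <- cond[1L, ]
  cum2 <- cum1 + cond[2L, ]
  cum3 <- cum2 + cond[3L, ]
  if (o == 0L) {
    u <- stats::runif(n)
    b <- (u > cum1[1L]) + (u > cum2[1L]) + (u > cum3[1L])
    return(codes_to_seq(b))
  }
  ctx <- if (!is.null(init)) {
    sum(init * 4^(rev(seq_along(init)) - 1))
  } else {
    sample.int(4^o, 1L, prob = background$ctx_freq) - 1L
  }
  u <- stats::runif(n)
  out <- integer(n)
  roll <- 4^(o - 1L)
  for (i in seq_len(n)) {
    r <- ctx + 1
    b <- (u[i] > cum1[r]) + (u[i] > cum2[r]) + (u[i] > cum3[r])
    out[i] <- b
    ctx <- (ctx %% roll) * 4 + b
  }
  codes_to_seq(out)
}

#' False-positive length
#'
#' Total length of detections on a random (repeat-free by construction)
#' genome, minus any bases overlapping a caller-supplied annotation of
#' repeats that survive in the random genome. Without a filter the value is
#' the unfiltered FPL.
#'
#' @param pred Regions detected on the random genome.
#' @param truth_filter Optional regions to subtract (e.g. a reference
#'   masker's calls on the same random genome).
#' @return Base pairs.
#' @export
false_positive_length <- function(pred, truth_filter = NULL) {
  total <- region_bp(pred)
  if (is.null(truth_filter) || nrow(truth_filter) == 0L) return(total)
  total - overlap_bp(pred, truth_filter)
}

#' Potential-repeat content
#'
#' Predicted bases not covered by the reference annotation.
#'
#' @param pred Predicted regions.
#' @param truth Reference annotation.
#' @return Base pairs.
#' @export
potential_repeats <- function(pred, truth) {
  region_bp(pred) - overlap_bp(pred, truth)
}

#' Full evaluation report
#'
#' Class-wise and overall sensitivity, exon specificity, percentage
#' predicted, false-positive length and potential-repeat content in one
#' row, mirroring the standard masking-benchmark table.
#'
#' @param pred Predicted regions.
#' @param truth Reference repeat annotation with a \code{class} column over
#'   \code{te}, \code{tr}, \code{low}, \code{other}.
#' @param exons Optional exon regions.
#' @param seqs Optional genome sequences (for PP).
#' @param fpl Optional precomputed FPL value.
#' @return One-row data.frame with columns SN_te, SN_tr, SN_low, SN_other,
#'   SN_all, SP_exon, PP, FPL, PR.
#' @export
evaluation_report <- function(pred, truth, exons = NULL, seqs = NULL,
                              fpl = NA_real_) {
  data.frame(
    SN_te = sensitivity(pred, truth, "te"),
    SN_tr = sensitivity(pred, truth, "tr"),
    SN_low = sensitivity(pred, truth, "low"),
    SN_other = sensitivity(pred, truth, "other"),
    SN_all = sensitivity(pred, truth),
    SP_exon = if (is.null(exons)) NA_real_ else specificity_exon(pred, exons),
    PP = if (is.null(seqs)) NA_real_ else percentage_predicted(pred, seqs),
    FPL = fpl,
    PR = potential_repeats(pred, truth)
  )
}
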