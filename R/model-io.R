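MODEL_FORMAT_VERSION <- 1L

#' Save a fitted detector to a JSON model file
#'
#' Stores everything `scan` needs to reproduce `mask` bit-for-bit on new
#' sequences: k, background order, t, the HMM (levels, priors,
#' transitions), and the nonzero entries of the adjusted k-mer table.
#'
#' @param object A [repeat_detector()] fit.
#' @param path Output path.
#' @export
write_model <- function(object, path) {
  nz <- which(object$table$values > 0)
  payload <- list(
    format_version = MODEL_FORMAT_VERSION,
    k = object$k,
    order = object$order,
    sigma = object$sigma,
    w = object$w,
    t = object$t,
    mode = object$mode,
    n_levels = object$hmm$n_levels,
    priors = object$hmm$priors,
    transitions = as.numeric(object$hmm$transitions),  # column-major
    table_n_windows = object$table$n_windows,
    table_index = nz - 1,       # quaternary indices of nonzero words
    table_value = object$table$values[nz]
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a detector model saved by [write_model()]
#'
#' @param path Path to the JSON model file.
#' @return A \code{repeat_detector} object usable with
#'   [predict.repeat_detector()] (it carries no training genome, so
#'   \code{newdata} is required).
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(m$format_version) || m$format_version > MODEL_FORMAT_VERSION) {
    stop("unsupported model format in ", path)
  }
  S <- 2L * m$n_levels
  values <- numeric(4^m$k)
  values[m$table_index + 1] <- m$table_value
  hmm <- structure(list(t = m$t, n_levels = as.integer(m$n_levels),
                        n_states = S, priors = m$priors,
                        transitions = matrix(m$transitions, S, S),
                        trained = TRUE),
                   class = "repeat_hmm")
  table <- structure(list(k = as.integer(m$k), counts = NULL,
                          values = values, n_windows = m$table_n_windows),
                     class = "kmer_table")
  structure(list(call = NULL, k = as.integer(m$k),
                 order = as.integer(m$order), sigma = m$sigma, w = m$w,
                 t = m$t, mode = m$mode, mask_width = NULL, table = table,
                 background = NULL, hmm = hmm, genome = NULL,
                 tracks = NULL, labels = NULL),
            class = "repeat_detector")
}
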