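#' Read DNA sequences from a FASTA file
#'
#' Reads every record of a FASTA file into a named character vector of
#' uppercase residue strings. Ambiguity codes (including \code{N}) are kept
#' in the text but are excluded from k-mer counting via [valid_mask()].
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase string per record, in file
#'   order. Names are the first whitespace-delimited token of each header.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s", "acgtn"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path, " (line 1)")
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA header in ", path, " (line ", first,
         "): expected '>'")
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  seqs
}

#' Validity mask of a DNA string
#'
#' @param seq A single uppercase DNA string.
#' @return Logical vector, one element per position, \code{TRUE} iff the
#'   residue is one of A, C, G, T. All other IUPAC codes (and anything else)
#'   are invalid: no k-mer window overlapping them is counted or scored.
#' @export
valid_mask <- function(seq) {
  !is.na(seq_codes(seq))
}

# Integer codes A,C,G,T -> 0,1,2,3; anything else -> NA.
# The quaternary digit mapping that underlies all k-mer indexing.
seq_codes <- function(seq) {
  code_lut <- rep(NA_integer_, 256L)
  code_lut[utf8ToInt("A")] <- 0L
  code_lut[utf8ToInt("C")] <- 1L
  code_lut[utf8ToInt("G")] <- 2L
  code_lut[utf8ToInt("T")] <- 3L
  code_lut[utf8ToInt("a")] <- 0L
  code_lut[utf8ToInt("c")] <- 1L
  code_lut[utf8ToInt("g")] <- 2L
  code_lut[utf8ToInt("t")] <- 3L
  code_lut[utf8ToInt(seq)]
}

codes_to_seq <- function(codes) {
  intToUtf8(utf8ToInt("ACGT")[codes + 1L])
}

#' Construct a set of genomic regions
#'
#' Regions are half-open, 0-based intervals \code{[start, end)} on named
#' sequences, the package's internal convention and the on-disk BED
#' convention.
#'
#' @param seq_name Character vector of sequence names.
#' @param start,end Numeric vectors; 0-based start (inclusive) and end
#'   (exclusive).
#' @param class Optional character vector of class tags (recycled).
#' @return A data.frame with columns \code{seq_name}, \code{start},
#'   \code{end} and, if given, \code{class}.
#' @export
regions <- function(seq_name = character(), start = numeric(),
                    end = numeric(), class = NULL) {
  if (length(start) && any(start < 0 | end <= start)) {
    stop("regions require 0 <= start < end")
  }
  df <- data.frame(seq_name = as.character(seq_name),
                   start = as.numeric(start), end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (!is.null(class) && nrow(df)) df$class <- rep_len(as.character(class), nrow(df))
  df
}

empty_regions <- function() regions()

# Sort regions by sequence then start.
sort_regions <- function(r) {
  if (nrow(r) == 0L) return(r)
  r[order(r$seq_name, r$start, r$end), , drop = FALSE]
}

# Merge overlapping or abutting intervals within each sequence.
merge_regions <- function(r) {
  if (nrow(r) <= 1L) return(r[, c("seq_name", "start", "end"), drop = FALSE])
  r <- sort_regions(r)
  # a new group starts when an interval begins past every earlier end
  # (within the same sequence)
  run_max <- stats::ave(r$end, r$seq_name, FUN = cummax)
  new_grp <- c(TRUE, r$start[-1] > run_max[-nrow(r)] |
                 r$seq_name[-1] != r$seq_name[-nrow(r)])
  grp <- cumsum(new_grp)
  out <- data.frame(
    seq_name = r$seq_name[new_grp],
    start = r$start[new_grp],
    end = as.numeric(tapply(r$end, grp, max)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Apply repeat masking to sequences
#'
#' @param seqs Named character vector of uppercase DNA strings.
#' @param repeats Regions data.frame (see [regions()]).
#' @param mode \code{"soft"} lowercases masked positions; \code{"hard"}
#'   replaces them with \code{N}.
#' @return The masked sequences, same names, same lengths.
#' @export
mask_sequences <- function(seqs, repeats, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  unknown <- setdiff(unique(repeats$seq_name), names(seqs))
  if (length(unknown)) {
    stop("regions reference unknown sequence name(s): ",
         paste(unknown, collapse = ", "))
  }
  out <- seqs
  for (i in seq_len(nrow(repeats))) {
    sn <- repeats$seq_name[i]
    len <- nchar(out[[sn]])
    if (repeats$end[i] > len) {
      stop("region [", repeats$start[i], ",", repeats$end[i],
           ") exceeds length of sequence ", sn)
    }
    from <- repeats$start[i] + 1L
    to <- repeats$end[i]
    piece <- substr(out[[sn]], from, to)
    piece <- if (mode == "soft") tolower(piece) else
      strrep("N", to - from + 1L)
    substr(out[[sn]], from, to) <- piece
  }
  out
}

#' Write sequences to FASTA, optionally masking repeats
#'
#' @inheritParams mask_sequences
#' @param path Output file path.
#' @param width Line wrap width.
#' @return Invisibly, the (masked) sequences.
#' @export
write_masked_fasta <- function(seqs, repeats = empty_regions(),
                               mode = c("soft", "hard"), path, width = 60L) {
  mode <- match.arg(mode)
  masked <- mask_sequences(seqs, repeats, mode)
  set <- Biostrings::BStringSet(masked)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(masked)
}

#' Write regions to disk
#'
#' @param r Regions data.frame.
#' @param path Output path.
#' @param dialect \code{"bed"} writes 3-column (or 4 with a class column)
#'   BED, 0-based half-open; \code{"coords"} writes human-readable
#'   \code{name:start-end} lines with 1-based inclusive coordinates.
#' @export
write_regions <- function(r, path, dialect = c("bed", "coords")) {
  dialect <- match.arg(dialect)
  if (nrow(r) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  if (dialect == "bed") {
    cols <- r[, intersect(c("seq_name", "start", "end", "class"), names(r)),
              drop = FALSE]
    cols$start <- format(cols$start, scientific = FALSE, trim = TRUE)
    cols$end <- format(cols$end, scientific = FALSE, trim = TRUE)
    utils::write.table(cols, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    writeLines(sprintf("%s:%d-%d", r$seq_name, as.integer(r$start) + 1L,
                       as.integer(r$end)), path)
  }
  invisible(path)
}

#' Read a BED file of regions
#'
#' @param path A 3+ column BED file; a 4th column, when present, is kept as
#'   the region class.
#' @return Regions data.frame.
#' @export
read_regions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_regions())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(parts))
  if (ncol_min < 3L) stop("BED file needs at least 3 columns: ", path)
  r <- regions(vapply(parts, `[`, "", 1L),
               as.numeric(vapply(parts, `[`, "", 2L)),
               as.numeric(vapply(parts, `[`, "", 3L)),
               class = if (ncol_min >= 4L) vapply(parts, `[`, "", 4L))
  sort_regions(r)
}

# Run RNG-dependent code under a seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  force(code)
}
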