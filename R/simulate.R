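#' Specify a synthetic genome
#'
#' Describes a seeded synthetic genome: an order-\code{background_order}
#' Markov background, planted interspersed repeat families (a random
#' consensus, mutated per copy), planted tandem arrays, and unique "exon"
#' stretches, with ground-truth intervals recorded exactly as placed. The
#' defaults describe the package's standard 1-Mb study genome: an order-3
#' background, one family of 200 copies of a 500-bp consensus at 5\%
#' divergence, 50 tandem arrays, and 20 unique exons.
#'
#' @param genome_length Genome length in bp.
#' @param background_order Order of the background chain.
#' @param gc GC fraction of the background composition.
#' @param concentration Dirichlet concentration for the per-context
#'   conditional distributions; smaller values give stronger local
#'   compositional structure.
#' @param families List of family specs, each a list with \code{length}
#'   (consensus bp), \code{copies}, \code{divergence} (per-base
#'   substitution probability), \code{indel_rate}, \code{class}.
#' @param tandems List with \code{count}, \code{motif_length} (range),
#'   \code{copies} (range per array), \code{divergence}; or \code{NULL}.
#' @param exons List with \code{count} and \code{length} (range); or
#'   \code{NULL}.
#' @param seed Integer seed; the simulation is fully determined by it.
#' @return Object of class \code{simulation_spec}.
#' @export
simulation_spec <- function(genome_length = 1e6,
                            background_order = 3L,
                            gc = 0.5,
                            concentration = 50,
                            families = list(list(length = 500L,
                                                 copies = 200L,
                                                 divergence = 0.05,
                                                 indel_rate = 0.001,
                                                 class = "te")),
                            tandems = list(count = 50L,
                                           motif_length = c(2L, 8L),
                                           copies = c(20L, 100L),
                                           divergence = 0.02),
                            exons = list(count = 20L,
                                         length = c(300L, 1500L)),
                            seed = 1L) {
  spec <- list(genome_length = as.numeric(genome_length),
               background_order = as.integer(background_order),
               gc = gc, concentration = concentration,
               families = families, tandems = tandems, exons = exons,
               seed = as.integer(seed))
  class(spec) <- "simulation_spec"
  spec
}

#' Mutate a sequence copy
#'
#' Per-base substitutions with the stated probability (uniform over the
#' three alternative bases) and, at the stated per-base rate, indels whose
#' lengths are geometric (mean 2); insertions and deletions are equally
#' likely.
#'
#' @param seq A DNA string.
#' @param divergence Substitution probability per base, in \[0, 1).
#' @param indel_rate Indel initiation probability per base, in \[0, 1).
#' @param seed Optional seed; otherwise the caller's RNG stream is used.
#' @return The mutated DNA string.
#' @export
mutate_sequence <- function(seq, divergence, indel_rate = 0, seed = NULL) {
  if (divergence < 0 || divergence >= 1) stop("divergence must be in [0, 1)")
  if (indel_rate < 0 || indel_rate >= 1) stop("indel_rate must be in [0, 1)")
  with_seed(seed, {
    d <- seq_codes(seq)
    n <- length(d)
    hit <- which(stats::runif(n) < divergence)
    if (length(hit)) {
      d[hit] <- (d[hit] + sample.int(3L, length(hit), replace = TRUE)) %% 4L
    }
    if (indel_rate > 0) {
      sites <- which(stats::runif(n) < indel_rate)
      # apply right to left so earlier coordinates stay valid
      for (i in rev(sites)) {
        len <- stats::rgeom(1L, 0.5) + 1L
        if (stats::runif(1L) < 0.5) {
          d <- d[-(i:min(i + len - 1L, length(d)))]        # deletion
        } else {
          ins <- sample.int(4L, len, replace = TRUE) - 1L  # insertion
          d <- append(d, ins, after = i)
        }
      }
    }
    codes_to_seq(d)
  })
}

random_dna <- function(n, comp = rep(0.25, 4)) {
  codes_to_seq(sample.int(4L, n, replace = TRUE, prob = comp) - 1L)
}

# Place elements (character vector) at uniform non-overlapping starts on
# [0, genome_length). Returns data.frame(start, end) in input order.
place_elements <- function(lengths, genome_length, what = "element",
                           tries = 2000L) {
  if (sum(lengths) >= genome_length) {
    stop("infeasible packing: planted ", what, " material (",
         sum(lengths), " bp) does not fit in ", genome_length, " bp")
  }
  occ_s <- numeric(0)
  occ_e <- numeric(0)
  starts <- numeric(length(lengths))
  for (i in seq_along(lengths)) {
    len <- lengths[i]
    ok <- FALSE
    for (try in seq_len(tries)) {
      s <- floor(stats::runif(1L, 0, genome_length - len))
      if (!any(s < occ_e & s + len > occ_s)) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("infeasible packing: could not place ", what, " #", i,
           " of length ", len)
    }
    starts[i] <- s
    occ_s <- c(occ_s, s); occ_e <- c(occ_e, s + len)
  }
  data.frame(start = starts, end = starts + lengths)
}

#' Simulate a genome with planted repeats and ground truth
#'
#' Samples the background from an order-\code{background_order} chain whose
#' per-context conditional distributions are Dirichlet draws around the
#' stated composition, then overwrites uniform-random non-overlapping
#' positions with mutated family copies, tandem arrays, and unique exon
#' stretches. Every planted interval is returned as ground truth.
#'
#' @param spec A [simulation_spec()].
#' @return List with \code{seqs} (named character vector of one sequence,
#'   \code{"sim1"}), \code{truth} (regions with \code{class} in
#'   \code{te}/\code{tr}), and \code{exons} (regions with class
#'   \code{exon}).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    o <- spec$background_order
    comp <- c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2, (1 - spec$gc) / 2)
    # order-o background chain: Dirichlet conditional per context
    n_ctx <- 4^o
    cond <- matrix(0, 4L, n_ctx)
    for (cx in seq_len(n_ctx)) {
      g <- stats::rgamma(4L, shape = spec$concentration * comp)
      cond[, cx] <- g / sum(g)
    }
    bg_chain <- structure(list(order = o, cond = as.numeric(cond),
                               ctx_freq = rep(1 / n_ctx, n_ctx),
                               total_positions = spec$genome_length),
                          class = "markov_background")
    genome <- sample_markov_chain(spec$genome_length, bg_chain)

    elements <- character(0)
    classes <- character(0)
    for (fam in spec$families) {
      consensus <- random_dna(fam$length)
      copies <- vapply(seq_len(fam$copies), function(i) {
        mutate_sequence(consensus, fam$divergence, fam$indel_rate)
      }, "")
      elements <- c(elements, copies)
      classes <- c(classes, rep(fam$class, fam$copies))
    }
    if (!is.null(spec$tandems) && spec$tandems$count > 0) {
      td <- spec$tandems
      arrays <- vapply(seq_len(td$count), function(i) {
        ml <- sample(td$motif_length[1]:td$motif_length[2], 1L)
        nc <- sample(td$copies[1]:td$copies[2], 1L)
        mutate_sequence(strrep(random_dna(ml), nc), td$divergence)
      }, "")
      elements <- c(elements, arrays)
      classes <- c(classes, rep("tr", td$count))
    }
    exon_seqs <- character(0)
    if (!is.null(spec$exons) && spec$exons$count > 0) {
      probe <- 15L  # uniqueness probe word length
      consensus_words <- unlist(lapply(elements, function(e) {
        if (nchar(e) >= probe) {
          idx <- rolling_indices(e, probe)
          idx[!is.na(idx)]
        }
      }))
      for (i in seq_len(spec$exons$count)) {
        repeat {
          ex <- random_dna(sample(spec$exons$length[1]:spec$exons$length[2], 1L))
          widx <- rolling_indices(ex, probe)
          if (!anyDuplicated(widx) && !any(widx %in% consensus_words)) break
        }
        exon_seqs <- c(exon_seqs, ex)
      }
    }

    all_el <- c(elements, exon_seqs)
    placed <- place_elements(nchar(all_el), spec$genome_length,
                             what = "planted element")
    for (i in seq_along(all_el)) {
      substr(genome, placed$start[i] + 1L, placed$end[i]) <- all_el[i]
    }
    n_rep <- length(elements)
    truth <- if (n_rep) {
      sort_regions(regions("sim1", placed$start[seq_len(n_rep)],
                           placed$end[seq_len(n_rep)], class = classes))
    } else {
      empty_regions()
    }
    exons <- if (length(exon_seqs)) {
      sort_regions(regions("sim1", placed$start[n_rep + seq_along(exon_seqs)],
                           placed$end[n_rep + seq_along(exon_seqs)],
                           class = "exon"))
    } else {
      empty_regions()
    }
    list(seqs = c(sim1 = genome), truth = truth, exons = exons)
  })
}

#' Standard study spec scaled to a genome length
#'
#' The package's standard synthetic study conditions (order-3 background,
#' a 500-bp family at 5\% divergence covering ~10\% of the genome, tandem
#' arrays and unique exons) with planting density held constant as the
#' genome length varies: copy numbers and counts scale linearly with
#' length relative to the 1-Mb defaults.
#'
#' @param genome_length Genome length in bp.
#' @param seed Integer seed.
#' @param background_order Background chain order.
#' @return A [simulation_spec()].
#' @export
scaled_simulation_spec <- function(genome_length, seed = 1L,
                                   background_order = 3L) {
  scale <- genome_length / 1e6
  simulation_spec(
    genome_length = genome_length,
    background_order = background_order,
    families = list(list(length = 500L,
                         copies = max(1L, round(200 * scale)),
                         divergence = 0.05, indel_rate = 0.001,
                         class = "te")),
    tandems = list(count = max(1L, round(50 * scale)),
                   motif_length = c(2L, 8L), copies = c(20L, 100L),
                   divergence = 0.02),
    exons = list(count = max(1L, round(20 * scale)),
                 length = c(300L, 1500L)),
    seed = seed)
}
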