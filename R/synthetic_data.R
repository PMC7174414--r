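#' Synthetic fragment configuration
#'
#' Describes the generative model for synthetic oriC-positive and
#' seed-matched negative fragments.  Positives carry the functional grammar
#' of a replication origin planted on i.i.d. background: an AT-rich DNA
#' unwinding element (DUE), high-affinity DnaA boxes, DnaA-trio repeats and
#' the anchoring seed 9-mer at the exact fragment center.  Negatives share
#' the length and central seed but none of the other grammar, so any
#' classifier signal must come from the planted elements -- the module's
#' central guarantee.
#'
#' @param n_pos,n_neg Numbers of positive / negative fragments (>= 1).
#' @param fragment_length Fragment length in bases (default 1250).
#' @param background_gc Background GC content in (0, 1) (default 0.5).
#' @param seed Central seed 9-mer (default the DnaA-box consensus
#'   TTATCCACA).
#' @param planted_elements List of `list(motif, copies, placement)`;
#'   `placement` is `"uniform"` or a fixed 0-based offset.  Defaults: 3
#'   DnaA boxes (TTATCCACA) and 2 DnaA-trio copies (TAATAATAA), uniformly
#'   placed outside the DUE.
#' @param due_window `list(offset, length, at_fraction)`: AT-rich window
#'   (default 300 bp at offset 100 with A+T probability 0.9).
#' @param rng_seed Integer seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pos = 200L, n_neg = 200L,
                             fragment_length = 1250L, background_gc = 0.5,
                             seed = "TTATCCACA",
                             planted_elements = list(
                               list(motif = "TTATCCACA", copies = 3L,
                                    placement = "uniform"),
                               list(motif = "TAATAATAA", copies = 2L,
                                    placement = "uniform")),
                             due_window = list(offset = 100L, length = 300L,
                                               at_fraction = 0.9),
                             rng_seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L)
  if (!(background_gc > 0 && background_gc < 1))
    stop("background_gc must lie in the open interval (0, 1)")
  seed <- toupper(seed)
  if (grepl("[^ACGT]", seed)) stop("seed must be over {A,C,G,T}")
  stopifnot(fragment_length >= nchar(seed))
  if (due_window$offset + due_window$length > fragment_length)
    stop("DUE window does not fit in the fragment")
  for (el in planted_elements) {
    if (grepl("[^ACGT]", el$motif)) stop("planted motifs must be over {A,C,G,T}")
    if (is.numeric(el$placement)) {
      if (el$placement < 0 || el$placement + nchar(el$motif) > fragment_length)
        stop("fixed placement of '", el$motif, "' does not fit the fragment")
      due_lo <- due_window$offset; due_hi <- due_window$offset + due_window$length
      if (el$placement < due_hi && el$placement + nchar(el$motif) > due_lo)
        stop("fixed placement of '", el$motif, "' overlaps the DUE window")
    }
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 fragment_length = as.integer(fragment_length),
                 background_gc = background_gc, seed = seed,
                 planted_elements = planted_elements,
                 due_window = due_window, rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

# Run expr with the current RNG stream when rng_seed is NULL, else under a
# local seed (callers that seed once get sequential determinism).
with_rng <- function(rng_seed, expr) {
  if (is.null(rng_seed)) expr
  else withr::with_seed(rng_seed, expr)
}

#' Random i.i.d. DNA background
#'
#' Bases drawn i.i.d. with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1 - gc)/2`.
#'
#' @param length Sequence length.
#' @param gc GC content in the open interval (0, 1).
#' @param rng_seed Integer seed, or `NULL` to consume the current RNG
#'   stream.
#' @return A sequence string.
#' @export
generate_background <- function(length, gc = 0.5, rng_seed = NULL) {
  if (!(gc > 0 && gc < 1)) stop("gc must lie in the open interval (0, 1)")
  with_rng(rng_seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  })
}

splice_at <- function(seq, piece, offset0) {
  paste0(substr(seq, 1L, offset0), piece,
         substr(seq, offset0 + nchar(piece) + 1L, nchar(seq)))
}

# Sample non-overlapping placements for planted elements outside forbidden
# intervals (0-based half-open data.frame(start, end)).
place_elements <- function(config, forbidden) {
  F <- config$fragment_length
  occupied <- logical(F)
  for (i in seq_len(nrow(forbidden)))
    occupied[(forbidden$start[i] + 1L):forbidden$end[i]] <- TRUE
  placements <- list()
  for (el in config$planted_elements) {
    w <- nchar(el$motif)
    for (cp in seq_len(el$copies)) {
      if (is.numeric(el$placement)) {
        p <- as.integer(el$placement)
        if (any(occupied[(p + 1L):(p + w)]))
          stop("fixed placement of '", el$motif, "' collides with another element")
      } else {
        csum <- c(0L, cumsum(occupied))
        starts <- 0:(F - w)
        ok <- starts[csum[starts + w + 1L] - csum[starts + 1L] == 0L]
        if (length(ok) == 0L)
          stop("no room to place '", el$motif, "' (fragment too crowded)")
        p <- ok[sample.int(length(ok), 1L)]
      }
      occupied[(p + 1L):(p + w)] <- TRUE
      placements[[length(placements) + 1L]] <- list(motif = el$motif, start = p)
    }
  }
  placements
}

#' Generate one synthetic oriC-positive fragment
#'
#' Background of `fragment_length` bases with the DUE window resampled
#' AT-rich, the planted elements at their placements (uniform placements
#' avoid the DUE, the central seed and each other) and the seed 9-mer
#' written at the exact fragment center, `(F - 9) %/% 2`.
#'
#' @param config A [synthetic_config()].
#' @param rng_seed Integer seed, or `NULL` to consume the current stream.
#' @return A sequence string of length `config$fragment_length`.
#' @export
generate_positive <- function(config, rng_seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  with_rng(rng_seed, {
    F <- config$fragment_length
    s <- generate_background(F, config$background_gc)
    due <- config$due_window
    at <- due$at_fraction
    due_seq <- paste(sample(c("A", "T", "C", "G"), due$length, replace = TRUE,
                            prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
                     collapse = "")
    s <- splice_at(s, due_seq, due$offset)
    sl <- nchar(config$seed)
    c0 <- (F - sl) %/% 2L
    forbidden <- data.frame(start = c(due$offset, c0),
                            end = c(due$offset + due$length, c0 + sl))
    for (pl in place_elements(config, forbidden)) {
      s <- splice_at(s, pl$motif, pl$start)
    }
    splice_at(s, config$seed, c0)
  })
}

#' Generate one seed-matched negative fragment
#'
#' Pure background of `fragment_length` bases with only the seed at the
#' exact center -- identical to positives in length and central seed.
#'
#' @inheritParams generate_positive
#' @return A sequence string.
#' @export
generate_negative <- function(config, rng_seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  with_rng(rng_seed, {
    F <- config$fragment_length
    s <- generate_background(F, config$background_gc)
    splice_at(s, config$seed, (F - nchar(config$seed)) %/% 2L)
  })
}

#' Generate a labelled set of positive and negative fragments
#'
#' @param config A [synthetic_config()]; `config$rng_seed` makes the whole
#'   set reproducible.
#' @return `data.frame(id, class, sequence)` with `config$n_pos` positives
#'   (`class = "pos"`) followed by `config$n_neg` negatives.
#' @export
generate_fragment_set <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$rng_seed, {
    pos <- vapply(seq_len(config$n_pos), function(i)
      generate_positive(config), "")
    neg <- vapply(seq_len(config$n_neg), function(i)
      generate_negative(config), "")
    data.frame(id = c(sprintf("pos_%d", seq_along(pos)),
                      sprintf("neg_%d", seq_along(neg))),
               class = c(rep("pos", length(pos)), rep("neg", length(neg))),
               sequence = c(pos, neg), stringsAsFactors = FALSE)
  })
}

#' Generate a GC-skewed circular chromosome with a planted origin
#'
#' On the arc running from the origin to its antipode the background is
#' G-enriched (`P(G) = gc/2 + skew_strength`, `P(C) = gc/2 - skew_strength`);
#' on the complementary arc the bias is reversed.  The cumulative GC-skew of
#' such a chromosome attains its minimum at the origin and its maximum near
#' the antipode -- the V shape used to locate real origins.  A
#' [generate_positive()] fragment is spliced in at `origin_position`.
#'
#' @param length Chromosome length (>= `config$fragment_length`).
#' @param origin_position 0-based position of the planted origin.
#' @param skew_strength Per-base G/C probability shift in (0, 0.2].
#' @param config A [synthetic_config()] describing the planted fragment.
#' @param rng_seed Integer seed.
#' @return List with `record` (circular [genome_record()]) and `truth`
#'   (`data.frame(record_id, planted_start, planted_end)`).
#' @export
generate_skewed_chromosome <- function(length, origin_position,
                                       skew_strength = 0.1,
                                       config = synthetic_config(),
                                       rng_seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!(skew_strength > 0 && skew_strength <= 0.2))
    stop("skew_strength must lie in (0, 0.2]")
  if (origin_position < 0 || origin_position >= length)
    stop("origin_position must lie in [0, length)")
  if (config$fragment_length > length)
    stop("chromosome shorter than the planted fragment")
  gc <- config$background_gc
  if (gc / 2 - skew_strength <= 0)
    stop("skew_strength too large for background_gc")
  with_rng(rng_seed, {
    pos <- 0:(length - 1L)
    on_leading <- ((pos - origin_position) %% length) < (length %/% 2L)
    bases <- character(length)
    p_at <- (1 - gc) / 2
    n_lead <- sum(on_leading)
    bases[on_leading] <- sample(c("A", "T", "G", "C"), n_lead, replace = TRUE,
                                prob = c(p_at, p_at, gc / 2 + skew_strength,
                                         gc / 2 - skew_strength))
    bases[!on_leading] <- sample(c("A", "T", "G", "C"), length - n_lead,
                                 replace = TRUE,
                                 prob = c(p_at, p_at, gc / 2 - skew_strength,
                                          gc / 2 + skew_strength))
    chrom <- paste(bases, collapse = "")
    frag <- generate_positive(config)
    F <- config$fragment_length
    if (origin_position + F <= length) {
      chrom <- splice_at(chrom, frag, origin_position)
    } else {
      tail_n <- length - origin_position
      chrom <- splice_at(chrom, substr(frag, 1L, tail_n), origin_position)
      chrom <- splice_at(chrom, substr(frag, tail_n + 1L, F), 0L)
    }
    rec <- genome_record(sprintf("synthetic_chromosome_seed%s",
                                 as.character(rng_seed %||% "NA")),
                         chrom, topology = "circular")
    list(record = rec,
         truth = data.frame(record_id = rec$id,
                            planted_start = origin_position,
                            planted_end = origin_position + F,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a multi-taxon labelled fragment set with private motifs
#'
#' Each taxon's fragments are [generate_positive()] outputs carrying, in
#' addition to the shared origin grammar, two uniformly placed copies of a
#' taxon-private motif; taxa therefore differ only in that motif.  Labels
#' are emitted at one taxonomic level.
#'
#' @param n_taxa Number of taxa (must match `length(private_motifs)`).
#' @param per_taxon_n Fragments per taxon.
#' @param private_motifs Character vector of equal-length motifs, pairwise
#'   Hamming distance >= 3; `NULL` draws `n_taxa` motifs from a built-in
#'   pool of six.
#' @param config A [synthetic_config()].
#' @param level Level at which labels are emitted (default `"order"`).
#' @param rng_seed Integer seed.
#' @return List with `fragments` (`data.frame(id, sequence)`) and
#'   `label_table` (`data.frame(sequence_id, order, family, genus)`).
#' @export
generate_taxon_dataset <- function(n_taxa = 3L, per_taxon_n = 40L,
                                   private_motifs = NULL,
                                   config = synthetic_config(),
                                   level = c("order", "family", "genus"),
                                   rng_seed = 1L) {
  level <- match.arg(level)
  if (is.null(private_motifs)) {
    pool <- c("AGGCTTGACC", "CTTGAGGCAT", "GCCAATCGTG", "TACGGTCAGT",
              "CGTACTGTCA", "GTCAGCATGG")
    if (n_taxa > length(pool))
      stop("supply private_motifs explicitly for more than ", length(pool),
           " taxa")
    private_motifs <- pool[seq_len(n_taxa)]
  }
  stopifnot(length(private_motifs) == n_taxa)
  w <- unique(nchar(private_motifs))
  if (length(w) != 1L) stop("private motifs must share one length")
  for (i in seq_len(n_taxa)) for (j in seq_len(n_taxa)) {
    if (i < j) {
      h <- sum(strsplit(private_motifs[i], "")[[1]] !=
                 strsplit(private_motifs[j], "")[[1]])
      if (h < 3L) stop("private motifs ", i, " and ", j,
                       " are closer than Hamming distance 3")
    }
  }
  withr::with_seed(rng_seed, {
    ids <- character(0); seqs <- character(0); taxa <- character(0)
    for (t in seq_len(n_taxa)) {
      cfg_t <- config
      cfg_t$planted_elements <- c(config$planted_elements,
                                  list(list(motif = private_motifs[t],
                                            copies = 2L,
                                            placement = "uniform")))
      for (i in seq_len(per_taxon_n)) {
        ids <- c(ids, sprintf("taxon%d_frag%d", t, i))
        seqs <- c(seqs, generate_positive(cfg_t))
        taxa <- c(taxa, sprintf("taxon_%d", t))
      }
    }
    lt <- data.frame(sequence_id = ids, order = NA_character_,
                     family = NA_character_, genus = NA_character_,
                     stringsAsFactors = FALSE)
    lt[[level]] <- taxa
    list(fragments = data.frame(id = ids, sequence = seqs,
                                stringsAsFactors = FALSE),
         label_table = lt)
  })
}
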