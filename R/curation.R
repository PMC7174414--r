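#' Cumulative GC-skew profile
#'
#' Per-base cumulative sum of the GC skew: `+1` for `G`, `-1` for `C`, `0`
#' otherwise.  On bacterial chromosomes this curve typically assumes a V (or
#' inverted V) shape whose minimum marks the replication origin, which is the
#' anchor of the semi-automated curation procedure.
#'
#' @param sequence A [genome_record()] or sequence string (non-empty).
#' @return An object of class `skew_profile`: list with `values` (numeric,
#'   one per base), `argmin` and `argmax` (0-based positions; smallest index
#'   attaining the extremum) and `total` (final cumulative value).
#' @examples
#' cumulative_gc_skew("CCCCGGGG")$argmin  # 3
#' @export
cumulative_gc_skew <- function(sequence) {
  s <- seq_of(sequence)
  if (!nzchar(s)) stop("empty sequence")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  step <- (ch == "G") - (ch == "C")
  v <- cumsum(step)
  structure(list(values = v,
                 argmin = which.min(v) - 1L,
                 argmax = which.max(v) - 1L,
                 total = v[length(v)]),
            class = "skew_profile")
}

#' @export
print.skew_profile <- function(x, ...) {
  cat(sprintf("<skew_profile> %d bp, argmin=%d argmax=%d total=%d\n",
              length(x$values), x$argmin, x$argmax, x$total))
  invisible(x)
}

#' Export a skew profile as TSV
#'
#' Columns `position` (0-based) and `cumulative_skew`.
#'
#' @param profile A [cumulative_gc_skew()] profile.
#' @param path Output path.
#' @export
write_skew_profile <- function(profile, path) {
  stopifnot(inherits(profile, "skew_profile"))
  write.table(data.frame(position = seq_along(profile$values) - 1L,
                         cumulative_skew = profile$values),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fixed-length windows centered on intergenic regions
#'
#' Splits a chromosome into windows of `window_length` (default 2.5 kb), one
#' per maximal intergenic interval, centered on the interval midpoint.
#' Boundary and circularity handling follow [extract_candidates()]: windows
#' running off a linear record are discarded, windows on circular records
#' wrap.  With no genes at all, the whole record is intergenic and one
#' window centered at `L %/% 2` is returned.
#'
#' @param record A [genome_record()].
#' @param gene_intervals `data.frame(start, end)` of gene intervals, 0-based
#'   half-open (see [read_gene_intervals()]); overlapping genes are merged.
#' @param window_length Window width in bases (default 2500).
#' @param circular Override topology.
#' @return Candidate-style data frame (`source_id`, `start`, `end`, `strand`,
#'   `seed`, `wrap`, `sequence`); `seed` holds the central 9-mer.
#' @export
intergenic_windows <- function(record, gene_intervals, window_length = 2500L,
                               circular = NULL) {
  s <- seq_of(record)
  id <- if (inherits(record, "genome_record")) record$id else "seq"
  if (is.null(circular))
    circular <- inherits(record, "genome_record") && record$topology == "circular"
  L <- nchar(s)
  gaps <- intergenic_intervals(gene_intervals, L, circular)
  if (nrow(gaps) == 0L) {
    warning("record '", id, "': no intergenic interval")
    return(window_frame(character(0)))
  }
  centers <- (gaps$start + gaps$end) %/% 2L %% L
  make_centered_windows(s, id, centers, window_length, circular)
}

# Maximal intergenic intervals on [0, L); on circular records the interval
# across the coordinate origin is represented with end > L.
intergenic_intervals <- function(gene_intervals, L, circular) {
  g <- as.data.frame(gene_intervals)[, c("start", "end")]
  g <- g[g$end > g$start, , drop = FALSE]
  if (nrow(g) == 0L) {
    return(data.frame(start = 0L, end = L))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = g$start + 1L, end = g$end))
  gap_ir <- IRanges::gaps(ir, start = 1L, end = L)
  gaps <- data.frame(start = BiocGenerics::start(gap_ir) - 1L,
                     end = BiocGenerics::end(gap_ir))
  if (circular && nrow(gaps) >= 1L) {
    first_at_zero <- nrow(gaps) > 0 && gaps$start[1] == 0L
    last_at_L <- nrow(gaps) > 0 && gaps$end[nrow(gaps)] == L
    if (first_at_zero && last_at_L && nrow(gaps) > 1L) {
      # join the two arcs flanking the coordinate origin
      gaps$end[nrow(gaps)] <- L + gaps$end[1]
      gaps <- gaps[-1L, , drop = FALSE]
    }
  }
  gaps[gaps$end > gaps$start, , drop = FALSE]
}

make_centered_windows <- function(s, id, centers, window_length, circular) {
  L <- nchar(s)
  if (window_length > L) {
    warning("record '", id, "' shorter than window_length; no windows")
    return(window_frame(character(0)))
  }
  start <- centers - window_length %/% 2L
  end <- start + window_length
  inb <- start >= 0L & end <= L
  keep <- if (circular) rep(TRUE, length(centers)) else inb
  start <- start[keep]; end <- end[keep]; inb <- inb[keep]
  if (length(start) == 0L) return(window_frame(character(0)))
  seqs <- vapply(seq_along(start),
                 function(i) substr_wrap(s, start[i], end[i]), "")
  central9 <- substr(seqs, (window_length - 9L) %/% 2L + 1L,
                     (window_length - 9L) %/% 2L + 9L)
  out <- data.frame(source_id = id, start = ((start %% L) + L) %% L,
                    stringsAsFactors = FALSE)
  out$end <- out$start + window_length
  out$strand <- "+"
  out$seed <- central9
  out$wrap <- !inb
  out$sequence <- seqs
  out
}

window_frame <- function(x) {
  data.frame(source_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), seed = character(0), wrap = logical(0),
             sequence = character(0), stringsAsFactors = FALSE)
}

#' Keep windows near the cumulative GC-skew minimum
#'
#' Retains windows whose center lies within `max_distance` bases of the
#' profile's argmin (circular distance on circular records).  "Close to the
#' minimum" is not sharply defined in the curation literature; the default of
#' 5% of the chromosome length is this package's declared choice.
#'
#' @param windows Window data frame ([intergenic_windows()] output).
#' @param profile The chromosome's [cumulative_gc_skew()] profile.
#' @param max_distance Maximum center-to-argmin distance in bases (default
#'   `0.05 * length`).
#' @param circular Use circular distance (default `TRUE`: chromosomes are
#'   circular).
#' @return The retained subset of `windows`.
#' @export
near_minimum_filter <- function(windows, profile,
                                max_distance = NULL, circular = TRUE) {
  stopifnot(inherits(profile, "skew_profile"))
  L <- length(profile$values)
  if (is.null(max_distance)) max_distance <- 0.05 * L
  if (nrow(windows) == 0L) return(windows)
  centers <- ((windows$start + windows$end) %/% 2L) %% L
  d <- abs(centers - profile$argmin)
  if (circular) d <- pmin(d, L - d)
  out <- windows[d <= max_distance, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan for DnaA boxes
#'
#' Finds all windows within `max_mismatches` of the DnaA-box consensus on
#' either strand.  The default consensus TTATCCACA is the high-affinity
#' Escherichia coli box (R1/R4).  Windows containing `N` never match.
#'
#' @param sequence A [genome_record()] or sequence string.
#' @param consensus Box consensus over `{A,C,G,T}`.
#' @param max_mismatches Maximum Hamming distance (default 1).
#' @param both_strands Also scan for the reverse complement (default `TRUE`).
#' @return `data.frame(position, strand, n_mismatches)` sorted by position;
#'   positions 0-based on the forward sequence.
#' @export
dnaa_box_scan <- function(sequence, consensus = "TTATCCACA",
                          max_mismatches = 1L, both_strands = TRUE) {
  consensus <- toupper(consensus)
  if (grepl("[^ACGT]", consensus)) stop("consensus must be over {A,C,G,T}")
  s <- seq_of(sequence)
  fwd <- cpp_mismatch_scan(s, consensus, max_mismatches)
  out <- if (nrow(fwd) > 0L)
    data.frame(position = fwd$position, strand = "+",
               n_mismatches = fwd$mismatches, stringsAsFactors = FALSE)
  else
    data.frame(position = integer(0), strand = character(0),
               n_mismatches = integer(0), stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- reverse_complement(consensus)
    if (rc != consensus) {
      rev <- cpp_mismatch_scan(s, rc, max_mismatches)
      if (nrow(rev) > 0L)
        out <- rbind(out, data.frame(position = rev$position, strand = "-",
                                     n_mismatches = rev$mismatches,
                                     stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a seed-matched negative for a positive fragment
#'
#' Negative training examples share (I) the length and (II) the central seed
#' of their positive counterpart, taken from the same chromosome: a window of
#' identical length is centered on a uniformly chosen *other* occurrence of
#' the positive's seed, never overlapping the positive interval.
#'
#' @param positive_fragment One-row candidate data frame (with `start`,
#'   `end`, `seed` on `source_record`).
#' @param source_record The [genome_record()] the positive came from.
#' @param rng_seed Integer seed; the choice among alternative occurrences is
#'   deterministic given the seed.
#' @param search_reverse_strand Consider seed occurrences on both strands.
#' @return A one-row candidate data frame for the negative fragment.
#' @export
make_seed_matched_negatives <- function(positive_fragment, source_record,
                                        rng_seed = 1L,
                                        search_reverse_strand = TRUE) {
  stopifnot(nrow(positive_fragment) == 1L)
  seed <- positive_fragment$seed
  flen <- positive_fragment$end - positive_fragment$start
  idx <- seed_index(seed, nchar(seed))
  cand <- extract_candidates(source_record, idx, fragment_length = flen,
                             search_reverse_strand = search_reverse_strand)
  if (nrow(cand) > 0L) {
    overlaps <- cand$start < positive_fragment$end &
      cand$end > positive_fragment$start
    cand <- cand[!overlaps, , drop = FALSE]
  }
  if (nrow(cand) == 0L)
    stop("no alternative occurrence of seed '", seed,
         "' outside the positive interval on record '", source_record$id, "'")
  pick <- withr::with_seed(rng_seed, sample.int(nrow(cand), 1L))
  out <- cand[pick, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene intervals from BED or GFF3
#'
#' BED is 0-based half-open and passes through unchanged; GFF3 (1-based,
#' closed) is converted to the package's 0-based half-open convention, and
#' only `gene` features are kept unless `feature_type = NULL`.
#'
#' @param path Annotation file (`.bed`, `.gff`, `.gff3`).
#' @param feature_type GFF3 feature type filter (default `"gene"`).
#' @return `data.frame(source_id, start, end)`, 0-based half-open.
#' @export
read_gene_intervals <- function(path, feature_type = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading BED/GFF requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  if (!is.null(feature_type) && "type" %in% names(S4Vectors::mcols(gr))) {
    gr <- gr[S4Vectors::mcols(gr)$type == feature_type]
  }
  data.frame(source_id = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             stringsAsFactors = FALSE)
}
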