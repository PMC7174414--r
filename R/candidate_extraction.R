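#' Seed index construction
#'
#' The seed index is the set of central 9-mers of a collection of known oriC
#' sequences.  Candidate extraction anchors fixed-length windows on
#' occurrences of these seeds, which reduces a chromosome to a manageable
#' number of candidate fragments.
#'
#' For a record of length `L`, the extracted seed is
#' `sequence[(L - seed_length) %/% 2 + (1:seed_length)]` (0-based start
#' `(L - seed_length) %/% 2`), i.e. the same centering rule used when the
#' classifier's training fragments were cut.  Seeds containing `N` are dropped
#' with a warning; duplicates collapse.
#'
#' @param oric_records List of [genome_record()] objects (or plain sequence
#'   strings), each at least `seed_length` long.
#' @param seed_length Seed width in bases (default 9).
#' @return An object of class `seed_index`: list with `seeds` (sorted unique
#'   character vector) and `seed_length`.
#' @export
build_seed_index <- function(oric_records, seed_length = 9L) {
  if (inherits(oric_records, "genome_record")) oric_records <- list(oric_records)
  stopifnot(length(oric_records) >= 1L, seed_length >= 1L)
  seeds <- character(length(oric_records))
  for (i in seq_along(oric_records)) {
    r <- oric_records[[i]]
    s <- seq_of(r)
    id <- if (inherits(r, "genome_record")) r$id else paste0("record ", i)
    if (nchar(s) < seed_length)
      stop(sprintf("%s is shorter (%d bp) than the seed length %d",
                   id, nchar(s), seed_length))
    start0 <- (nchar(s) - seed_length) %/% 2L
    seeds[i] <- substr(s, start0 + 1L, start0 + seed_length)
  }
  seed_index(seeds, seed_length)
}

#' @rdname build_seed_index
#' @param seeds Character vector of seed sequences (all `seed_length` long,
#'   `{A,C,G,T}` only; seeds containing `N` are dropped with a warning).
#' @export
seed_index <- function(seeds, seed_length = 9L) {
  seeds <- toupper(seeds)
  if (any(nchar(seeds) != seed_length))
    stop("all seeds must have length ", seed_length)
  keep <- !grepl("[^ACGT]", seeds)
  if (!all(keep)) {
    warning(sum(!keep), " seed(s) containing ambiguous letters dropped")
    seeds <- seeds[keep]
  }
  seeds <- sort(unique(seeds))
  if (length(seeds) == 0L) stop("seed index is empty")
  structure(list(seeds = seeds, seed_length = as.integer(seed_length)),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("<seed_index> %d seed(s) of length %d\n", length(x$seeds),
              x$seed_length))
  invisible(x)
}

#' Read / write a plain-text seed list
#'
#' One seed per line; `#` starts a comment; blank lines ignored.
#'
#' @param path File path.
#' @param seed_length Expected seed width.
#' @return [seed_index()] object (`read_seed_list`) or `path` invisibly.
#' @export
read_seed_list <- function(path, seed_length = 9L) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no seeds in '", path, "'")
  seed_index(lines, seed_length)
}

#' @rdname read_seed_list
#' @param index A [seed_index()].
#' @export
write_seed_list <- function(index, path) {
  stopifnot(inherits(index, "seed_index"))
  writeLines(index$seeds, path)
  invisible(path)
}

#' Locate seed occurrences on a sequence
#'
#' Reports every position `p` (0-based, on the forward sequence) where the
#' forward `seed_length`-mer is in the index (strand `+`) and, when
#' `search_reverse_strand`, every position whose reverse complement is in the
#' index (strand `-`).  Overlapping occurrences are all reported; output is
#' sorted by position.  On circular records occurrences spanning the origin
#' of coordinates are found as well.
#'
#' @param record A [genome_record()] (or sequence string).
#' @param index A [seed_index()].
#' @param search_reverse_strand Also scan the reverse strand (default `TRUE`):
#'   training origins are co-oriented but arbitrary user input is not.
#' @param circular Treat the sequence as circular; defaults to the record's
#'   topology.
#' @return `data.frame(position, seed, strand)`; `seed` is the index member
#'   (for `-` hits, the seed whose reverse complement matched).
#' @export
find_seed_occurrences <- function(record, index, search_reverse_strand = TRUE,
                                  circular = NULL) {
  stopifnot(inherits(index, "seed_index"))
  s <- seq_of(record)
  if (is.null(circular)) {
    circular <- inherits(record, "genome_record") && record$topology == "circular"
  }
  sl <- index$seed_length
  L <- nchar(s)
  subject <- if (circular && L > sl) paste0(s, substr(s, 1L, sl - 1L)) else s
  subj <- Biostrings::DNAString(subject)

  scan_one <- function(patterns, strand) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(patterns))
    hits <- Biostrings::matchPDict(pd, subj)
    res <- lapply(seq_along(patterns), function(i) {
      st <- BiocGenerics::start(hits[[i]])
      if (length(st) == 0L) return(NULL)
      data.frame(position = st - 1L, seed = patterns[i], strand = strand,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  }

  occ <- scan_one(index$seeds, "+")
  if (search_reverse_strand) {
    rc <- reverse_complement(index$seeds)
    hits_rc <- scan_one(rc, "-")
    if (!is.null(hits_rc)) {
      hits_rc$seed <- index$seeds[match(hits_rc$seed, rc)]
      occ <- rbind(occ, hits_rc)
    }
  }
  if (is.null(occ)) {
    return(data.frame(position = integer(0), seed = character(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  occ <- occ[occ$position < L, , drop = FALSE]  # circular scan duplicates p >= L
  occ <- unique(occ)
  occ <- occ[order(occ$position, occ$strand, occ$seed), , drop = FALSE]
  rownames(occ) <- NULL
  occ
}

# Extract [start, end) from seq with wraparound; requires end - start <= 2L.
substr_wrap <- function(s, start0, end0) {
  L <- nchar(s)
  width <- end0 - start0
  start0 <- ((start0 %% L) + L) %% L
  end0 <- start0 + width
  if (end0 <= L) substr(s, start0 + 1L, end0)
  else substr(paste0(s, s), start0 + 1L, end0)
}

#' Extract fixed-length candidate fragments centered on seed occurrences
#'
#' For a plus-strand occurrence at position `p` the window is
#' `[p - (F - s) %/% 2, p - (F - s) %/% 2 + F)` with `F` the fragment length
#' and `s` the seed length, placing the seed at fragment offset
#' `(F - s) %/% 2` -- the same offset [build_seed_index()] extracts from.
#' Minus-strand occurrences use the mirrored start `p - (F - s + 1) %/% 2` and
#' the window is reverse complemented, so the returned fragment always reads
#' the seed forward at the central offset.  On linear records windows
#' extending past either end are discarded (the classifier requires exactly
#' `F` bases; padding would inject artificial composition); on circular
#' records they wrap.
#'
#' @inheritParams find_seed_occurrences
#' @param fragment_length Window length `F` in bases (default 1250, the
#'   fragment size the classifier is trained with).
#' @return `data.frame(source_id, start, end, strand, seed, wrap, sequence)`;
#'   coordinates 0-based half-open on the forward source (for wrapped windows
#'   `end` exceeds the source length by the wrapped amount).  Attribute
#'   `n_discarded_boundary` counts occurrences dropped at linear boundaries.
#' @export
extract_candidates <- function(record, index, fragment_length = 1250L,
                               search_reverse_strand = TRUE, circular = NULL) {
  stopifnot(inherits(index, "seed_index"))
  sl <- index$seed_length
  if (fragment_length < sl) stop("fragment_length must be >= seed length")
  s <- seq_of(record)
  id <- if (inherits(record, "genome_record")) record$id else "seq"
  if (is.null(circular)) {
    circular <- inherits(record, "genome_record") && record$topology == "circular"
  }
  L <- nchar(s)
  empty <- data.frame(source_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      seed = character(0), wrap = logical(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  attr(empty, "n_discarded_boundary") <- 0L
  if (fragment_length > L) {
    warning(sprintf("record '%s' (%d bp) is shorter than fragment_length %d; no candidates",
                    id, L, fragment_length))
    return(empty)
  }
  occ <- find_seed_occurrences(s, index, search_reverse_strand, circular)
  if (nrow(occ) == 0L) return(empty)

  left_plus <- (fragment_length - sl) %/% 2L
  left_minus <- (fragment_length - sl + 1L) %/% 2L
  start <- ifelse(occ$strand == "+", occ$position - left_plus,
                  occ$position - left_minus)
  end <- start + fragment_length
  inb <- start >= 0L & end <= L
  keep <- if (circular) rep(TRUE, nrow(occ)) else inb
  n_disc <- sum(!keep)
  if (n_disc > 0L)
    message(sprintf("record '%s': %d boundary occurrence(s) discarded", id, n_disc))
  occ <- occ[keep, , drop = FALSE]
  start <- start[keep]; end <- end[keep]; inb <- inb[keep]
  if (nrow(occ) == 0L) {
    attr(empty, "n_discarded_boundary") <- n_disc
    return(empty)
  }
  frag <- character(nrow(occ))
  for (i in seq_len(nrow(occ))) {
    w <- substr_wrap(s, start[i], end[i])
    frag[i] <- if (occ$strand[i] == "-") reverse_complement(w) else w
  }
  out <- data.frame(source_id = id,
                    start = ((start %% L) + L) %% L,
                    stringsAsFactors = FALSE)
  out$end <- out$start + fragment_length
  out$strand <- occ$strand
  out$seed <- occ$seed
  out$wrap <- !inb
  out$sequence <- frag
  attr(out, "n_discarded_boundary") <- n_disc
  out
}
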