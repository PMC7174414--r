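#' Construct a genome record
#'
#' A genome record holds one DNA sequence with its identifier, free-text
#' description and topology.  On construction the sequence is uppercased and
#' any IUPAC ambiguity letter outside `A`, `C`, `G`, `T`, `N` is mapped to `N`
#' with a warning; this mirrors how RefSeq fragments carrying ambiguity codes
#' are normally handled.
#'
#' @param id Sequence identifier (first whitespace-delimited FASTA header
#'   token).
#' @param sequence DNA sequence string; non-empty.
#' @param description Remainder of the FASTA header, may be empty.
#' @param topology `"linear"` or `"circular"`.  Bacterial chromosomes are
#'   circular; database fragments are linear.
#' @return An object of class `genome_record`: a list with elements `id`,
#'   `description`, `sequence` and `topology`.
#' @examples
#' rec <- genome_record("chr1", "acgtn")
#' rec$sequence  # "ACGTN"
#' @export
genome_record <- function(id, sequence, description = "",
                          topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("sequence of record '", id, "' is empty")
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad)) {
    warning(sprintf("record '%s': %d non-ACGTN letter(s) mapped to N", id, nchar(bad)))
    sequence <- gsub("[^ACGTN]", "N", sequence)
  }
  structure(list(id = id, description = description, sequence = sequence,
                 topology = topology),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s, %d bp)\n", x$id, x$topology,
              nchar(x$sequence)))
  invisible(x)
}

# Accept a genome_record or a plain string wherever a sequence is needed.
seq_of <- function(x) {
  if (inherits(x, "genome_record")) x$sequence
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else stop("expected a genome_record or a single sequence string")
}

#' Read a FASTA file into genome records
#'
#' Records are returned in file order.  Ids are the first whitespace-delimited
#' header token; duplicated ids are suffixed deterministically (`_2`, `_3`,
#' ...) with a message.  Sequences are normalized as in [genome_record()].
#'
#' @param path Path to a FASTA file.
#' @param topology Topology assigned to every record (FASTA does not encode
#'   it).
#' @return A list of [genome_record()] objects.
#' @export
read_fasta <- function(path, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  headers <- names(set)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[`, "", 1L)
  desc <- sub("^[^ \t]+[ \t]*", "", headers)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    message("duplicate FASTA ids suffixed: ", paste(dup, collapse = ", "))
    for (d in dup) {
      at <- which(ids == d)
      ids[at[-1]] <- paste0(d, "_", seq_along(at)[-1] + 0L)
    }
  }
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- genome_record(ids[i], as.character(set[[i]]), desc[i], topology)
  }
  out
}

#' Write genome records (or identified fragments) to FASTA
#'
#' Output round-trips losslessly through [read_fasta()] (id, description,
#' sequence).  Lines are wrapped at 70 columns.
#'
#' @param records A list of [genome_record()] objects (an empty list writes an
#'   empty file).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "genome_record")) records <- list(records)
  stopifnot(is.list(records))
  if (length(records) == 0L) {
    ok <- file.create(path)
    if (!ok) stop("cannot write to: ", path)
    return(invisible(path))
  }
  seqs <- vapply(records, function(r) r$sequence, "")
  ids <- vapply(records, function(r) r$id, "")
  desc <- vapply(records, function(r) r$description %||% "", "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ifelse(nzchar(desc), paste(ids, desc), ids)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement
#'
#' Watson-Crick complement, reversed; `N` maps to `N`.  Vectorized over its
#' input.
#'
#' @param seq Character vector of sequences over `{A,C,G,T,N}`.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("TAATAATAA")  # "TTATTATTA"
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  if (any(grepl("[^ACGTN]", seq))) stop("reverse_complement: alphabet is {A,C,G,T,N}")
  vapply(seq, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, "", USE.NAMES = FALSE)
}
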