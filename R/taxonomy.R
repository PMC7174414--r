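#' Eligible taxa at a taxonomic level
#'
#' A taxon is eligible for one-vs-rest classification when it has at least
#' `min_count` labelled sequences at the level ("more than 4 examples", i.e.
#' >= 5, by default).  Unknown labels (`NA` or empty) never count.
#'
#' @param label_table `data.frame(sequence_id, order, family, genus)`;
#'   `sequence_id` unique; empty or `NA` cells mean unknown.
#' @param level `"order"`, `"family"` or `"genus"`.
#' @param min_count Minimum examples per eligible taxon (default 5).
#' @return `data.frame(taxon, n)` sorted by taxon.
#' @export
filter_taxa <- function(label_table, level = c("order", "family", "genus"),
                        min_count = 5L) {
  level <- match.arg(level)
  stopifnot(nrow(label_table) > 0L,
            !anyDuplicated(label_table$sequence_id))
  lab <- trimws(as.character(label_table[[level]]))
  lab[is.na(lab) | !nzchar(lab)] <- NA
  if (all(is.na(lab))) {
    warning("no known labels at level '", level, "'")
    return(data.frame(taxon = character(0), n = integer(0)))
  }
  tab <- table(lab)
  keep <- tab >= min_count
  data.frame(taxon = names(tab)[keep], n = as.integer(tab[keep]),
             stringsAsFactors = FALSE)
}

#' One-hot encoding of a fixed-length sequence
#'
#' Per position a 4-slot indicator in base order A, C, G, T; `N` leaves all
#' four slots zero, so the vector sum equals the number of non-N bases.
#'
#' @param seq Sequence string of length `expected_length`.
#' @param expected_length Required length (defaults to `nchar(seq)`).
#' @return Numeric vector of length `4 * expected_length`.
#' @export
one_hot_encode <- function(seq, expected_length = nchar(seq)) {
  s <- seq_of(seq)
  if (nchar(s) != expected_length)
    stop("sequence length ", nchar(s), " != expected_length ", expected_length)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- match(ch, c("A", "C", "G", "T"))
  v <- numeric(4L * expected_length)
  ok <- !is.na(idx)
  v[4L * (which(ok) - 1L) + idx[ok]] <- 1
  v
}

#' k-mer count encoding
#'
#' Concatenated dense overlapping k-mer counts for each `k` in
#' `[k_min, k_max]`, lexicographic k-mer order within each block; windows
#' containing `N` are skipped.  For the default `1 <= k <= 6` the vector has
#' `4 + 16 + 64 + 256 + 1024 + 4096 = 5460` entries.
#'
#' @param seq Sequence string with `nchar(seq) >= k_max`.
#' @param k_min,k_max Word-length range.
#' @return Named numeric count vector of length `sum(4^(k_min:k_max))`.
#' @export
kmer_count_encode <- function(seq, k_min = 1L, k_max = 6L) {
  s <- seq_of(seq)
  stopifnot(k_min >= 1L, k_max >= k_min)
  if (nchar(s) < k_max) stop("sequence shorter than k_max")
  x <- Biostrings::DNAString(gsub("[^ACGT]", "N", s))
  blocks <- lapply(k_min:k_max, function(k) {
    cnt <- Biostrings::oligonucleotideFrequency(x, width = k)
    stats::setNames(as.numeric(cnt), names(cnt))
  })
  do.call(c, blocks)
}

#' Pseudo-sentences of consecutive 10-mers
#'
#' Splits a sequence into all frames of consecutive non-overlapping
#' `token_length`-mers: one sentence per frame offset `0..token_length - 1`,
#' trailing remainders dropped.  This tokenization feeds word-embedding style
#' encoders, which treat each k-mer as a word.
#'
#' @param seq Sequence string.
#' @param token_length Token width (default 10).
#' @return List of `token_length` character vectors (empty list when the
#'   sequence is shorter than `token_length`).
#' @export
pseudo_sentences <- function(seq, token_length = 10L) {
  s <- seq_of(seq)
  L <- nchar(s)
  if (L < token_length) return(list())
  lapply(0:(token_length - 1L), function(f) {
    n <- (L - f) %/% token_length
    if (n == 0L) return(character(0))
    starts <- f + (0:(n - 1L)) * token_length
    substring(s, starts + 1L, starts + token_length)
  })
}

#' Train one-vs-rest taxonomic classifiers
#'
#' For each eligible taxon at the chosen level, a binary classifier is
#' trained with the taxon's sequences as positives and all other eligible
#' sequences at that level as negatives.  The `"gkm"` backend uses the same
#' string-kernel SVM as origin identification (one shared Gram matrix, one
#' SVM per taxon); the `"forest"` backend trains random forests on one-hot
#' or k-mer count encodings.
#'
#' @param fragments Named character vector of sequences (names =
#'   `sequence_id`), or a data frame with `id`/`sequence_id` and `sequence`
#'   columns.
#' @param label_table See [filter_taxa()].
#' @param level Taxonomic level.
#' @param backend `"gkm"` or `"forest"`.
#' @param encoder Encoder for the forest backend: `"onehot"` or `"kmer"`.
#' @param params [gkm_params()] for the gkm backend (its `fragment_length`
#'   must match the sequences).
#' @param min_count Eligibility threshold (default 5).
#' @param C Soft-margin cost for the gkm backend.
#' @param rng_seed Integer seed; results are deterministic given the seed.
#' @param n_trees Trees per forest (forest backend).
#' @return An object of class `taxon_model_set` with per-taxon models.
#' @export
train_taxon_models <- function(fragments, label_table,
                               level = c("order", "family", "genus"),
                               backend = c("gkm", "forest"),
                               encoder = c("onehot", "kmer"),
                               params = gkm_params(), min_count = 5L,
                               C = 1.0, rng_seed = 1L, n_trees = 200L) {
  level <- match.arg(level); backend <- match.arg(backend)
  encoder <- match.arg(encoder)
  fr <- as_fragment_vector(fragments)
  eligible <- filter_taxa(label_table, level, min_count)
  if (nrow(eligible) < 2L)
    stop("need at least 2 eligible taxa at level '", level, "'")
  lab <- trimws(as.character(label_table[[level]]))
  names(lab) <- label_table$sequence_id
  keep_ids <- names(fr)[names(fr) %in% names(lab)[lab %in% eligible$taxon]]
  keep_ids <- sort(keep_ids)  # determinism independent of input order
  fr <- fr[keep_ids]
  lab <- lab[keep_ids]
  if (length(fr) == 0L) stop("no fragments carry an eligible label")

  models <- list()
  if (backend == "gkm") {
    if (any(nchar(fr) != params$fragment_length))
      stop("all fragments must have length params$fragment_length = ",
           params$fragment_length)
    for (tx in eligible$taxon) {
      pos <- fr[lab == tx]; neg <- fr[lab != tx]
      models[[tx]] <- train_svm(unname(pos), unname(neg), params,
                                kernel_type = "gkm", C = C,
                                rng_seed = rng_seed)
    }
  } else {
    if (!requireNamespace("randomForest", quietly = TRUE))
      stop("the forest backend requires the randomForest package")
    X <- encode_matrix(fr, encoder)
    for (tx in eligible$taxon) {
      y <- factor(ifelse(lab == tx, "pos", "neg"), levels = c("neg", "pos"))
      models[[tx]] <- withr::with_seed(rng_seed, {
        randomForest::randomForest(X, y, ntree = n_trees)
      })
    }
  }
  structure(list(level = level, backend = backend, encoder = encoder,
                 params = params, models = models,
                 eligible_taxa = eligible, rng_seed = as.integer(rng_seed)),
            class = "taxon_model_set")
}

as_fragment_vector <- function(fragments) {
  if (is.data.frame(fragments)) {
    idcol <- intersect(c("id", "sequence_id", "source_id"), names(fragments))[1]
    if (is.na(idcol)) stop("fragment data frame needs an id column")
    stats::setNames(toupper(fragments$sequence), fragments[[idcol]])
  } else if (is.character(fragments) && !is.null(names(fragments))) {
    stats::setNames(toupper(fragments), names(fragments))
  } else stop("fragments must be a named character vector or a data frame")
}

encode_matrix <- function(fr, encoder) {
  if (encoder == "onehot") {
    len <- unique(nchar(fr))
    if (length(len) != 1L) stop("one-hot encoding needs equal-length sequences")
    X <- t(vapply(fr, one_hot_encode, numeric(4L * len),
                  expected_length = len))
  } else {
    X <- t(vapply(fr, kmer_count_encode, numeric(5460)))
  }
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  X
}

#' @export
print.taxon_model_set <- function(x, ...) {
  cat(sprintf("<taxon_model_set> level=%s backend=%s, %d taxa\n",
              x$level, x$backend, length(x$models)))
  invisible(x)
}

#' Per-taxon decision scores
#'
#' @param model_set A [train_taxon_models()] model set.
#' @param fragments Sequences to score (named vector or data frame).
#' @return Numeric matrix, rows = sequences, columns = taxa; larger score =
#'   more taxon-like (SVM decision value, or forest positive-class vote
#'   fraction).
#' @export
taxon_scores <- function(model_set, fragments) {
  stopifnot(inherits(model_set, "taxon_model_set"))
  fr <- as_fragment_vector(fragments)
  taxa <- names(model_set$models)
  if (model_set$backend == "gkm") {
    S <- vapply(taxa, function(tx)
      decision_values(model_set$models[[tx]], unname(fr)),
      numeric(length(fr)))
  } else {
    X <- encode_matrix(fr, model_set$encoder)
    S <- vapply(taxa, function(tx)
      as.numeric(stats::predict(model_set$models[[tx]], X,
                                type = "prob")[, "pos"]),
      numeric(length(fr)))
  }
  S <- matrix(S, nrow = length(fr), dimnames = list(names(fr), taxa))
  S
}

#' Area under the precision-recall curve
#'
#' Average-precision step summation: scores are swept in descending order,
#' tied scores grouped at one threshold, and each threshold that introduces
#' positives contributes `delta_recall * precision`.  No interpolation is
#' applied, so the value is reproducible bit for bit.
#'
#' @param scores Numeric scores (larger = more positive).
#' @param binary_labels Logical or 0/1 labels; both classes must be present.
#' @return AUPR in `[0, 1]`.
#' @examples
#' aupr(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))  # 5/6
#' @export
aupr <- function(scores, binary_labels) {
  y <- as.logical(binary_labels)
  stopifnot(length(scores) == length(y), !anyNA(scores), !anyNA(y))
  if (!any(y) || all(y)) stop("aupr needs at least one positive and one negative")
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(y)
  area <- 0; prev_recall <- 0; tp <- 0; n_pred <- 0
  for (t in thr) {
    at <- scores == t
    tp <- tp + sum(y[at])
    n_pred <- n_pred + sum(at)
    recall <- tp / n_pos
    if (recall > prev_recall) {
      area <- area + (recall - prev_recall) * (tp / n_pred)
      prev_recall <- recall
    }
  }
  area
}

#' Macro-averaged AUPR evaluation of a taxon model set
#'
#' Computes one-vs-rest AUPR per taxon on a test set and their unweighted
#' mean (macroAUPR) with standard deviation.  Taxa without both a positive
#' and a negative test example are excluded with a warning.
#'
#' @param model_set A [train_taxon_models()] model set.
#' @param test_fragments Test sequences (named vector or data frame).
#' @param label_table Labels covering the test ids.
#' @return List with `per_taxon` (`data.frame(taxon, n_pos, aupr)`),
#'   `macro_aupr` and `aupr_sd`.
#' @export
evaluate_taxa <- function(model_set, test_fragments, label_table) {
  fr <- as_fragment_vector(test_fragments)
  lab <- trimws(as.character(label_table[[model_set$level]]))
  names(lab) <- label_table$sequence_id
  lab <- lab[names(fr)]
  S <- taxon_scores(model_set, fr)
  rows <- list()
  for (tx in colnames(S)) {
    y <- !is.na(lab) & lab == tx
    if (!any(y) || all(y)) {
      warning("taxon '", tx, "' lacks a positive or negative test example; excluded")
      next
    }
    rows[[tx]] <- data.frame(taxon = tx, n_pos = sum(y),
                             aupr = aupr(S[, tx], y), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no evaluable taxon in the test set")
  per <- do.call(rbind, rows); rownames(per) <- NULL
  list(per_taxon = per, macro_aupr = mean(per$aupr),
       aupr_sd = if (nrow(per) > 1L) stats::sd(per$aupr) else 0)
}
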