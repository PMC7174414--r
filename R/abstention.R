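#' Two-cutoff abstention configuration
#'
#' After per-sequence min-max normalization of decision values, candidates
#' with a normalized value strictly above `upper_cutoff` are labelled
#' `positive`, strictly below `lower_cutoff` `negative`, and everything in
#' between is left to the user (`abstain`).  The defaults (0.41, 0.99) are
#' the Pareto-optimal pair trading F1 against the number of true origins in
#' the abstained space.
#'
#' @param lower_cutoff,upper_cutoff Reals with
#'   `0 <= lower_cutoff < upper_cutoff <= 1`.
#' @return An object of class `abstain_config`.
#' @export
abstain_config <- function(lower_cutoff = 0.41, upper_cutoff = 0.99) {
  if (!(lower_cutoff >= 0 && lower_cutoff < upper_cutoff && upper_cutoff <= 1))
    stop("need 0 <= lower_cutoff < upper_cutoff <= 1")
  structure(list(lower_cutoff = lower_cutoff, upper_cutoff = upper_cutoff),
            class = "abstain_config")
}

#' Min-max normalization of decision values within one source sequence
#'
#' `(v - min) / (max - min)` elementwise.  When all values are equal
#' (including the single-candidate case) every value maps to 1.0: the method
#' presumes each chromosome carries one origin, so its best (only) candidate
#' is kept rather than discarded.
#'
#' @param raw_values Non-empty numeric vector of decision values from the
#'   candidates of one input sequence.
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' normalize_scores(c(2, 1, 0))  # 1.0 0.5 0.0
#' @export
normalize_scores <- function(raw_values) {
  if (length(raw_values) == 0L) stop("no decision values to normalize")
  rng <- range(raw_values)
  if (rng[1] == rng[2]) return(rep(1.0, length(raw_values)))
  (raw_values - rng[1]) / (rng[2] - rng[1])
}

#' Three-way abstaining label rule
#'
#' @param normalized_values Numeric vector in `[0, 1]` (output of
#'   [normalize_scores()]).
#' @param config An [abstain_config()].
#' @return Character vector over `{"positive", "abstain", "negative"}`.
#'   Comparisons are strict, so values exactly at a cutoff abstain.
#' @examples
#' classify_with_abstention(c(1, 0.5, 0), abstain_config())
#' @export
classify_with_abstention <- function(normalized_values, config = abstain_config()) {
  stopifnot(inherits(config, "abstain_config"))
  if (any(normalized_values < 0 | normalized_values > 1))
    stop("normalized values must lie in [0, 1]")
  ifelse(normalized_values > config$upper_cutoff, "positive",
         ifelse(normalized_values < config$lower_cutoff, "negative", "abstain"))
}

#' Identify oriC fragments in input sequences
#'
#' End-to-end identification: per input record, seed-anchored candidates are
#' extracted, scored by the SVM, min-max normalized within the record and
#' labelled by the abstaining rule.  Negatives are discarded; positives and
#' abstained candidates are returned with provenance, ready for FASTA export
#' via [fragments_to_records()].
#'
#' @param records List of [genome_record()] objects (or one record).
#' @param index A [seed_index()].
#' @param model A [train_svm()] model.
#' @param config An [abstain_config()].
#' @param fragment_length Candidate window length; defaults to the model's
#'   training fragment length.
#' @param search_reverse_strand Scan both strands for seeds (default `TRUE`).
#' @param circular Override record topology (`NULL` = use each record's).
#' @return A list with `positives` and `abstained` (candidate data frames
#'   with `raw_value`, `normalized_value`, `label` columns) and `report`
#'   (per-record counts: `source_id`, `n_candidates`, `n_positive`,
#'   `n_abstained`, `n_negative`, `n_discarded_boundary`).
#' @export
identify_origins <- function(records, index, model, config = abstain_config(),
                             fragment_length = NULL,
                             search_reverse_strand = TRUE, circular = NULL) {
  if (inherits(records, "genome_record")) records <- list(records)
  stopifnot(inherits(model, "gkm_model"))
  if (is.null(fragment_length)) fragment_length <- model$params$fragment_length
  if (model$kernel_type == "gkm" && fragment_length != model$params$fragment_length)
    stop("fragment_length (", fragment_length, ") must equal the model's ",
         "training fragment length (", model$params$fragment_length, ")")
  pos_list <- list(); abs_list <- list(); rep_list <- list()
  for (rec in records) {
    cand <- extract_candidates(rec, index, fragment_length,
                               search_reverse_strand, circular)
    n_disc <- attr(cand, "n_discarded_boundary") %||% 0L
    if (nrow(cand) == 0L) {
      message("record '", rec$id, "': no candidates")
      rep_list[[length(rep_list) + 1L]] <-
        data.frame(source_id = rec$id, n_candidates = 0L, n_positive = 0L,
                   n_abstained = 0L, n_negative = 0L,
                   n_discarded_boundary = n_disc, stringsAsFactors = FALSE)
      next
    }
    cand$raw_value <- decision_values(model, cand$sequence)
    cand$normalized_value <- normalize_scores(cand$raw_value)
    cand$label <- classify_with_abstention(cand$normalized_value, config)
    rep_list[[length(rep_list) + 1L]] <-
      data.frame(source_id = rec$id, n_candidates = nrow(cand),
                 n_positive = sum(cand$label == "positive"),
                 n_abstained = sum(cand$label == "abstain"),
                 n_negative = sum(cand$label == "negative"),
                 n_discarded_boundary = n_disc, stringsAsFactors = FALSE)
    pos_list[[length(pos_list) + 1L]] <- cand[cand$label == "positive", , drop = FALSE]
    abs_list[[length(abs_list) + 1L]] <- cand[cand$label == "abstain", , drop = FALSE]
  }
  bind <- function(lst) {
    if (length(lst) == 0L) return(empty_scored_candidates())
    out <- do.call(rbind, lst)
    rownames(out) <- NULL
    out
  }
  list(positives = bind(pos_list), abstained = bind(abs_list),
       report = { r <- do.call(rbind, rep_list); rownames(r) <- NULL; r })
}

empty_scored_candidates <- function() {
  data.frame(source_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), seed = character(0), wrap = logical(0),
             sequence = character(0), raw_value = numeric(0),
             normalized_value = numeric(0), label = character(0),
             stringsAsFactors = FALSE)
}

#' Convert scored candidate fragments to FASTA-writable records
#'
#' Headers carry provenance in a machine-parseable form:
#' id `source|start-end|strand`, description `norm_score=... seed=...`;
#' [parse_fragment_header()] inverts the id.
#'
#' @param fragments Candidate data frame from [identify_origins()].
#' @return List of [genome_record()] objects.
#' @export
fragments_to_records <- function(fragments) {
  lapply(seq_len(nrow(fragments)), function(i) {
    f <- fragments[i, ]
    desc <- if (!is.null(f$normalized_value))
      sprintf("norm_score=%.6f seed=%s", f$normalized_value, f$seed)
    else sprintf("seed=%s", f$seed)
    genome_record(sprintf("%s|%d-%d|%s", f$source_id, f$start, f$end, f$strand),
                  f$sequence, desc)
  })
}

#' @rdname fragments_to_records
#' @param id A header id produced by [fragments_to_records()].
#' @return `parse_fragment_header`: `data.frame(source_id, start, end, strand)`.
#' @export
parse_fragment_header <- function(id) {
  parts <- strsplit(id, "|", fixed = TRUE)
  out <- lapply(parts, function(p) {
    if (length(p) != 3L) stop("not a fragment header id: ", paste(p, collapse = "|"))
    coords <- as.integer(strsplit(p[2], "-", fixed = TRUE)[[1]])
    data.frame(source_id = p[1], start = coords[1], end = coords[2],
               strand = p[3], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Grid scan for abstention cutoffs
#'
#' Scans (lower, upper) pairs on a labelled candidate set, maximizing the F1
#' of the `positive` label against the truth while minimizing the number of
#' true origins in the abstained space; ties break toward fewer abstentions,
#' then a higher upper cutoff.
#'
#' @param normalized_values Numeric vector in `[0, 1]`.
#' @param is_origin Logical truth per candidate.
#' @param step Grid step (default 0.01).
#' @return List with `best` (an [abstain_config()]), `best_row` and the full
#'   `grid` data frame (`lower`, `upper`, `f1`, `abstained_true`,
#'   `n_abstained`).
#' @export
cutoff_scan <- function(normalized_values, is_origin, step = 0.01) {
  stopifnot(length(normalized_values) == length(is_origin))
  cuts <- seq(0, 1, by = step)
  grid <- expand.grid(lower = cuts, upper = cuts)
  grid <- grid[grid$lower < grid$upper, , drop = FALSE]
  eval_one <- function(lo, up) {
    lab <- ifelse(normalized_values > up, "positive",
                  ifelse(normalized_values < lo, "negative", "abstain"))
    tp <- sum(lab == "positive" & is_origin)
    fp <- sum(lab == "positive" & !is_origin)
    fn <- sum(lab != "positive" & is_origin)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    c(f1 = f1, abstained_true = sum(lab == "abstain" & is_origin),
      n_abstained = sum(lab == "abstain"))
  }
  m <- t(mapply(eval_one, grid$lower, grid$upper))
  grid <- cbind(grid, as.data.frame(m))
  ord <- order(-grid$f1, grid$abstained_true, grid$n_abstained, -grid$upper,
               grid$lower)
  grid <- grid[ord, , drop = FALSE]
  rownames(grid) <- NULL
  best <- grid[1L, ]
  list(best = abstain_config(best$lower, best$upper), best_row = best,
       grid = grid)
}
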