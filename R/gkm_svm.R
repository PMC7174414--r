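#' Gapped k-mer kernel hyperparameters
#'
#' The gapped k-mer kernel compares two sequences through all pairs of
#' length-`l` words; a pair at Hamming distance `m` contributes
#' `choose(l - m, k)` -- the number of `k`-column subsets avoiding every
#' mismatch -- truncated to zero beyond `d` mismatches.  The defaults
#' (`l = 10`, `k = 6`, `d = 4`, 1250 bp fragments) are the configuration that
#' discriminates gammaproteobacterial oriC from non-oriC fragments best;
#' note that with `k = 6` the combinatorial weight already vanishes for
#' `m >= 5`, so the truncation is inactive and the kernel is exactly the
#' inner product of explicit gapped k-mer feature vectors.
#'
#' @param word_length Word length `l` (2..15).
#' @param informative_columns Number of informative (ungapped) columns `k`,
#'   `1 <= k <= l`.
#' @param max_mismatches Mismatch truncation `d`, `0 <= d <= l`.
#' @param fragment_length Fragment length the SVM is trained/applied on.
#' @return An object of class `gkm_params`.
#' @export
gkm_params <- function(word_length = 10L, informative_columns = 6L,
                       max_mismatches = 4L, fragment_length = 1250L) {
  l <- as.integer(word_length); k <- as.integer(informative_columns)
  d <- as.integer(max_mismatches); f <- as.integer(fragment_length)
  if (l < 2L || l > 15L) stop("word_length must be in 2..15")
  if (k < 1L || k > l) stop("informative_columns must satisfy 1 <= k <= l")
  if (d < 0L || d > l) stop("max_mismatches must satisfy 0 <= d <= l")
  if (f < l) stop("fragment_length must be >= word_length")
  structure(list(word_length = l, informative_columns = k,
                 max_mismatches = d, fragment_length = f),
            class = "gkm_params")
}

#' @export
print.gkm_params <- function(x, ...) {
  cat(sprintf("<gkm_params> l=%d k=%d d=%d fragment_length=%d\n",
              x$word_length, x$informative_columns, x$max_mismatches,
              x$fragment_length))
  invisible(x)
}

# Mismatch weight table w(m), m = 0..l, zero beyond the truncation point.
gkm_weights <- function(params) {
  l <- params$word_length; k <- params$informative_columns
  d <- params$max_mismatches
  m <- 0:l
  w <- ifelse(m <= d, choose(l - m, k), 0)
  w
}

#' Gapped k-mer string kernel
#'
#' `gkm_kernel` returns the raw (unnormalized) kernel
#' `K(a, b) = sum over word pairs of w(hamming(u, v))` with
#' `w(m) = choose(l - m, k)` for `m <= d` and 0 otherwise.  Words containing
#' `N` contribute zero.  `normalized_kernel` is the cosine normalization
#' `K(a,b) / sqrt(K(a,a) K(b,b))`, which makes decision values comparable
#' across fragments.
#'
#' @param seq_a,seq_b Sequences (strings or [genome_record()]), each at least
#'   `l` long.
#' @param params A [gkm_params()].
#' @return A single numeric kernel value.
#' @examples
#' p <- gkm_params(fragment_length = 10)
#' gkm_kernel("ACGTACGTAC", "ACGTACGTAC", p)  # 210 = choose(10, 6)
#' @export
gkm_kernel <- function(seq_a, seq_b, params = gkm_params()) {
  a <- seq_of(seq_a); b <- seq_of(seq_b)
  l <- params$word_length
  if (nchar(a) < l || nchar(b) < l)
    stop("sequences must be at least word_length (", l, ") long")
  cpp_gkm_kernel(a, b, gkm_weights(params), l)
}

#' @rdname gkm_kernel
#' @export
normalized_kernel <- function(seq_a, seq_b, params = gkm_params()) {
  a <- seq_of(seq_a); b <- seq_of(seq_b)
  w <- gkm_weights(params); l <- params$word_length
  if (nchar(a) < l || nchar(b) < l)
    stop("sequences must be at least word_length (", l, ") long")
  saa <- cpp_gkm_kernel(a, a, w, l)
  sbb <- cpp_gkm_kernel(b, b, w, l)
  if (saa <= 0 || sbb <= 0)
    stop("zero self-kernel (sequence has no valid ACGT word of length ", l, ")")
  cpp_gkm_kernel(a, b, w, l) / sqrt(saa * sbb)
}

#' Gram matrix of the gapped k-mer kernel
#'
#' @param seqs Character vector of sequences.
#' @param params A [gkm_params()].
#' @param normalize Cosine-normalize (default `TRUE`).
#' @return A symmetric numeric matrix.
#' @export
gkm_gram <- function(seqs, params = gkm_params(), normalize = TRUE) {
  seqs <- toupper(seqs)
  K <- cpp_gkm_gram(seqs, gkm_weights(params), params$word_length)
  if (normalize) {
    dg <- diag(K)
    if (any(dg <= 0)) stop("zero self-kernel in Gram matrix")
    K <- K / sqrt(outer(dg, dg))
  }
  K
}

#' Spectrum string kernel
#'
#' Inner product of dense overlapping k-mer count vectors; windows containing
#' `N` are skipped.
#'
#' @param seq_a,seq_b Sequences, each at least `spectrum_k` long.
#' @param spectrum_k Word length (>= 1).
#' @return A single non-negative numeric.
#' @examples
#' spectrum_kernel("ACGT", "ACGT", 3)  # 2
#' @export
spectrum_kernel <- function(seq_a, seq_b, spectrum_k = 6L) {
  if (spectrum_k < 1L) stop("spectrum_k must be >= 1")
  a <- seq_of(seq_a); b <- seq_of(seq_b)
  if (nchar(a) < spectrum_k || nchar(b) < spectrum_k)
    stop("sequences must be at least spectrum_k long")
  ca <- kmer_counts(a, spectrum_k)
  cb <- kmer_counts(b, spectrum_k)
  sum(ca * cb)
}

# Dense k-mer counts (lexicographic order); windows with N contribute nothing.
kmer_counts <- function(seq, k) {
  x <- Biostrings::DNAString(gsub("[^ACGT]", "N", toupper(seq)))
  as.numeric(Biostrings::oligonucleotideFrequency(x, width = k))
}

spectrum_gram <- function(seqs, spectrum_k, normalize = TRUE) {
  M <- t(vapply(seqs, kmer_counts, numeric(4^spectrum_k), k = spectrum_k))
  K <- M %*% t(M)
  if (normalize) {
    dg <- diag(K)
    if (any(dg <= 0)) stop("zero self-kernel in spectrum Gram matrix")
    K <- K / sqrt(outer(dg, dg))
  }
  K
}

#' Train a string-kernel SVM on oriC-positive and negative fragments
#'
#' Solves a soft-margin SVM on the cosine-normalized precomputed kernel
#' matrix (gapped k-mer or spectrum kernel).  Inputs are sorted before
#' solving so the result is a pure function of the sequence sets, `C` and
#' `rng_seed`.  The positive class is oriC: decision values of positives are
#' positive at the margin.
#'
#' @param pos_fragments,neg_fragments Character vectors of fragment
#'   sequences; for the gkm kernel all must have length
#'   `params$fragment_length`; at least 2 per class.
#' @param params A [gkm_params()].
#' @param kernel_type `"gkm"` or `"spectrum"`.
#' @param spectrum_k Word length for the spectrum kernel.
#' @param C Soft-margin cost (default 1).
#' @param rng_seed Integer seed recorded in the model and used for any
#'   stochastic step of the solver.
#' @return An object of class `gkm_model`: support sequences, signed dual
#'   coefficients, intercept, kernel parameters and training metadata.
#' @export
train_svm <- function(pos_fragments, neg_fragments, params = gkm_params(),
                      kernel_type = c("gkm", "spectrum"), spectrum_k = 6L,
                      C = 1.0, rng_seed = 1L) {
  kernel_type <- match.arg(kernel_type)
  pos <- toupper(pos_fragments); neg <- toupper(neg_fragments)
  if (length(pos) < 2L || length(neg) < 2L)
    stop("need at least 2 examples per class")
  if (kernel_type == "gkm") {
    if (any(nchar(c(pos, neg)) != params$fragment_length))
      stop("all fragments must have length params$fragment_length = ",
           params$fragment_length, " for the gkm kernel")
  } else {
    if (any(nchar(c(pos, neg)) < spectrum_k))
      stop("all fragments must be at least spectrum_k long")
  }
  pos <- sort(pos); neg <- sort(neg)
  seqs <- c(pos, neg)
  y <- c(rep(1, length(pos)), rep(-1, length(neg)))
  K <- if (kernel_type == "gkm") gkm_gram(seqs, params)
       else spectrum_gram(seqs, spectrum_k)

  fit <- withr::with_seed(rng_seed, {
    tryCatch(
      kernlab::ksvm(kernlab::as.kernelMatrix(K), y = factor(y, levels = c(-1, 1)),
                    type = "C-svc", C = C, scaled = FALSE),
      error = function(e) stop("SVM solver failed (degenerate or non-separable ",
                               "input?): ", conditionMessage(e))
    )
  })
  sv_idx <- unlist(kernlab::alphaindex(fit))
  duals <- unlist(kernlab::coef(fit))
  intercept <- -unlist(kernlab::b(fit))
  model <- structure(list(
    params = params, kernel_type = kernel_type,
    spectrum_k = as.integer(spectrum_k),
    support_sequences = seqs[sv_idx],
    dual_coefficients = as.numeric(duals),
    intercept = as.numeric(intercept),
    support_self_kernels = diag_self_kernels(seqs[sv_idx], params,
                                             kernel_type, spectrum_k),
    C = C,
    metadata = list(n_pos = length(pos), n_neg = length(neg),
                    rng_seed = as.integer(rng_seed),
                    created_at = format(Sys.time(), tz = "UTC"))),
    class = "gkm_model")
  # kernlab's decision sign depends on its internal class ordering; anchor
  # the oriC class to positive decision values.
  dec <- decision_values(model, seqs)
  if (mean(dec[y > 0]) < mean(dec[y < 0])) {
    model$dual_coefficients <- -model$dual_coefficients
    model$intercept <- -model$intercept
  }
  model
}

diag_self_kernels <- function(seqs, params, kernel_type, spectrum_k) {
  if (kernel_type == "gkm") {
    as.numeric(cpp_gkm_self(seqs, gkm_weights(params), params$word_length))
  } else {
    vapply(seqs, function(s) sum(kmer_counts(s, spectrum_k)^2), 0,
           USE.NAMES = FALSE)
  }
}

#' @export
print.gkm_model <- function(x, ...) {
  cat(sprintf("<gkm_model> kernel=%s, %d support sequences, n_pos=%d n_neg=%d\n",
              x$kernel_type, length(x$support_sequences), x$metadata$n_pos,
              x$metadata$n_neg))
  invisible(x)
}

#' SVM decision values
#'
#' `decision_value(model, seq)` returns
#' `sum_i dual_i K'(seq, support_i) + intercept` with `K'` the normalized
#' kernel of the model; positive values indicate the oriC class.
#' `decision_values` is the vectorized form.
#'
#' @param model A [train_svm()] model.
#' @param seq,seqs Sequence(s) to score.
#' @return Numeric decision value(s).
#' @export
decision_value <- function(model, seq) {
  decision_values(model, seq_of(seq))
}

#' @rdname decision_value
#' @export
decision_values <- function(model, seqs) {
  stopifnot(inherits(model, "gkm_model"))
  seqs <- toupper(seqs)
  sv <- model$support_sequences
  if (model$kernel_type == "gkm") {
    p <- model$params; w <- gkm_weights(p); l <- p$word_length
    if (any(nchar(seqs) < l))
      stop("sequence shorter than word_length ", l)
    Kx <- cpp_gkm_cross(seqs, sv, w, l)
    self <- as.numeric(cpp_gkm_self(seqs, w, l))
  } else {
    k <- model$spectrum_k
    if (any(nchar(seqs) < k)) stop("sequence shorter than spectrum_k ", k)
    Mq <- t(vapply(seqs, kmer_counts, numeric(4^k), k = k))
    Ms <- t(vapply(sv, kmer_counts, numeric(4^k), k = k))
    Kx <- Mq %*% t(Ms)
    self <- rowSums(Mq^2)
  }
  if (any(self <= 0)) stop("zero self-kernel for a query sequence")
  Kn <- Kx / sqrt(outer(self, model$support_self_kernels))
  as.numeric(Kn %*% model$dual_coefficients + model$intercept)
}

#' Score l-mers by their bare decision value
#'
#' Assigns each length-`l` word the decision value it would obtain as a bare
#' input to the model -- the per-motif importance used for motif extraction.
#' By default only l-mers actually occurring in the support sequences are
#' scored; full `4^l` enumeration is available but costly.
#'
#' @param model A gkm-kernel [train_svm()] model.
#' @param restrict_to_observed Score only l-mers occurring in the support
#'   sequences (default `TRUE`).
#' @return `data.frame(kmer, score)` sorted by decreasing score (ties broken
#'   lexicographically).
#' @export
score_all_lmers <- function(model, restrict_to_observed = TRUE) {
  stopifnot(inherits(model, "gkm_model"))
  if (model$kernel_type != "gkm")
    stop("l-mer importance scoring is defined for the gkm kernel")
  p <- model$params; l <- p$word_length; w <- gkm_weights(p)
  sv <- model$support_sequences
  # Aggregate all support-vector windows into one weighted bag:
  # K'(u, sv_i) = K(u, sv_i) / sqrt(K(u,u) K_ii) and K(u,u) = choose(l, k)
  # for a bare l-mer, so the decision value is a single weighted mismatch sum.
  codes <- lapply(sv, cpp_encode_codes, l = l)
  wts <- rep(model$dual_coefficients / sqrt(model$support_self_kernels),
             lengths(codes))
  all_codes <- unlist(codes)
  agg <- rowsum(wts, all_codes)
  win_codes <- as.integer(rownames(agg))
  win_wts <- as.numeric(agg)
  query <- if (restrict_to_observed) {
    sort(unique(all_codes))
  } else {
    if (l > 10L) stop("full enumeration not supported for l > 10")
    0:(4^l - 1)
  }
  raw <- cpp_score_lmers(as.integer(query), win_codes, win_wts, w)
  score <- raw / sqrt(choose(l, p$informative_columns)) + model$intercept
  kmer <- cpp_decode_codes(as.integer(query), l)
  out <- data.frame(kmer = kmer, score = score, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize / restore a trained model as JSON
#'
#' The JSON document holds kernel parameters, support sequences, dual
#' coefficients, intercept and training metadata at full precision, so a
#' restored model reproduces decision values exactly.
#'
#' @param model A [train_svm()] model.
#' @param path File path.
#' @return `path` invisibly (`write_model`) or a `gkm_model` (`read_model`).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "gkm_model"))
  x <- unclass(model)
  x$params <- unclass(x$params)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$params <- do.call(gkm_params, as.list(x$params))
  x$support_sequences <- as.character(x$support_sequences)
  x$dual_coefficients <- as.numeric(x$dual_coefficients)
  x$support_self_kernels <- as.numeric(x$support_self_kernels)
  x$metadata <- as.list(x$metadata)
  structure(x, class = "gkm_model")
}
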