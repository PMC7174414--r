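# Independent brute-force oracles used across the kernel tests.  These stay
# deliberately naive (explicit enumeration) so they share no code path with
# the package implementation.

random_dna <- function(n, len, gc = 0.5, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                                 prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                          (1 - gc) / 2)), collapse = "")
  if (is.null(seed)) vapply(seq_len(n), function(i) gen(), "")
  else withr::with_seed(seed, vapply(seq_len(n), function(i) gen(), ""))
}

mutate_at <- function(s, positions) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  for (p in positions) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

# Subset-enumeration oracle for the per-word-pair weight: the number of
# k-column subsets of 1..l avoiding every mismatch position, zeroed beyond d.
oracle_pair_weight <- function(u, v, l, k, d) {
  cu <- strsplit(u, "")[[1]]; cv <- strsplit(v, "")[[1]]
  mm <- which(cu != cv)
  if (length(mm) > d) return(0)
  subsets <- utils::combn(l, k)
  sum(apply(subsets, 2, function(cols) !any(cols %in% mm)))
}

# Explicit gapped k-mer feature map: one feature per (column-subset id,
# k-letter word), counted over all l-windows.  Returns a named count vector.
oracle_gkm_features <- function(seq, l, k) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  subsets <- utils::combn(l, k)
  per_window <- lapply(0:(n - l), function(w) {
    win <- ch[(w + 1):(w + l)]
    if (any(!win %in% c("A", "C", "G", "T"))) return(character(0))
    vapply(seq_len(ncol(subsets)), function(sid)
      paste0(sid, ":", paste(win[subsets[, sid]], collapse = "")), "")
  })
  table(unlist(per_window))
}

oracle_gkm_inner_product <- function(a, b, l, k) {
  fa <- oracle_gkm_features(a, l, k)
  fb <- oracle_gkm_features(b, l, k)
  common <- intersect(names(fa), names(fb))
  sum(as.numeric(fa[common]) * as.numeric(fb[common]))
}

# Naive spectrum kernel: enumerate every window pair.
oracle_spectrum <- function(a, b, k) {
  wins <- function(s) {
    out <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
    out[!grepl("[^ACGT]", out)]
  }
  wa <- wins(a); wb <- wins(b)
  sum(outer(wa, wb, "=="))
}

# Exhaustive threshold-sweep AUPR oracle: precision/recall at every distinct
# score cutoff, rectangle summation over recall increments.
oracle_aupr <- function(scores, labels) {
  y <- as.logical(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0; area <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & y)
    r <- tp / sum(y)
    p <- tp / sum(pred)
    if (r > prev_r) {
      area <- area + (r - prev_r) * p
      prev_r <- r
    }
  }
  area
}
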