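IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T",
                 AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
                 ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", M = "K", R = "Y",
                      W = "W", S = "S", Y = "R", K = "M", V = "B", H = "D",
                      D = "H", B = "V", N = "N")

#' Keep non-negatively scored motif importances
#'
#' A motif is deemed important when its decision score is `>= 0` (boundary
#' inclusive); order is preserved and the filter is idempotent.
#'
#' @param importances `data.frame(kmer, score)` as from [score_all_lmers()].
#' @return The retained subset.
#' @export
positive_importance_filter <- function(importances) {
  out <- importances[importances$score >= 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-scoring motifs
#'
#' The `n` highest-scoring entries, descending; ties broken lexicographically
#' by k-mer so selection is deterministic.
#'
#' @param importances `data.frame(kmer, score)`.
#' @param n Number of motifs (default 20).
#' @return Data frame of at most `n` rows.
#' @export
top_motifs <- function(importances, n = 20L) {
  out <- importances[order(-importances$score, importances$kmer), , drop = FALSE]
  out <- head(out, n)
  rownames(out) <- NULL
  out
}

# Longest exact suffix(a)/prefix(b) overlap in [min_o, max_o]; 0 if none.
best_overlap <- function(a, b, min_o, max_o = min(nchar(a), nchar(b)) - 1L) {
  if (max_o < min_o) return(0L)
  for (o in max_o:min_o) {
    if (substr(a, nchar(a) - o + 1L, nchar(a)) == substr(b, 1L, o)) return(o)
  }
  0L
}

new_motif <- function(kmer, score) {
  list(consensus = kmer,
       members = data.frame(kmer = kmer, score = score, offset = 0L,
                            stringsAsFactors = FALSE),
       score_sum = score)
}

merge_motifs <- function(a, b, overlap) {
  # b's consensus is appended after a's with `overlap` shared columns
  shift <- nchar(a$consensus) - overlap
  mb <- b$members
  mb$offset <- mb$offset + shift
  list(consensus = paste0(a$consensus, substr(b$consensus, overlap + 1L,
                                              nchar(b$consensus))),
       members = rbind(a$members, mb),
       score_sum = a$score_sum + b$score_sum)
}

#' Assemble scored k-mers by exact suffix-prefix overlap
#'
#' Greedy assembly: the pair of motifs with the longest exact suffix-prefix
#' overlap of at least `min_overlap` bases is merged repeatedly (ties broken
#' toward the higher combined score, then lexicographically), until no
#' admissible overlap remains.  Unmerged k-mers become singleton motifs.
#' The default `min_overlap = 5` (half the default word length) excludes
#' chance joins while admitting the long 8-base overlaps that characterize
#' genuine shared motifs.
#'
#' @param importances `data.frame(kmer, score)`; all k-mers the same length.
#' @param min_overlap Minimum exact overlap in bases (`< nchar(kmer)`).
#' @return List of `assembled_motif` objects (consensus, members with
#'   offsets, `score_sum`), sorted by decreasing `score_sum` then consensus.
#' @examples
#' imp <- data.frame(kmer = c("AAAGATCTT", "AAGATCTTT"), score = c(1, 1))
#' assemble_by_overlap(imp, 5)[[1]]$consensus  # "AAAGATCTTT"
#' @export
assemble_by_overlap <- function(importances, min_overlap = 5L) {
  kmers <- importances$kmer
  scores <- importances$score
  if (length(kmers) == 0L) return(list())
  l <- unique(nchar(kmers))
  if (length(l) != 1L) stop("all k-mers must have the same length")
  if (min_overlap >= l) stop("min_overlap must be smaller than the k-mer length")
  # deterministic initial order regardless of input order
  ord <- order(kmers, -scores)
  kmers <- kmers[ord]; scores <- scores[ord]
  dup <- duplicated(kmers)
  kmers <- kmers[!dup]; scores <- scores[!dup]
  motifs <- mapply(new_motif, kmers, scores, SIMPLIFY = FALSE, USE.NAMES = FALSE)

  n <- length(motifs)
  cons <- vapply(motifs, `[[`, "", "consensus")
  ssum <- vapply(motifs, `[[`, 0, "score_sum")
  # ov[i, j] = best overlap of suffix(i) with prefix(j)
  ov <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) ov[i, j] <- best_overlap(cons[i], cons[j], min_overlap)
  }
  alive <- rep(TRUE, n)
  repeat {
    ov_alive <- ov
    ov_alive[!alive, ] <- 0L
    ov_alive[, !alive] <- 0L
    o <- max(ov_alive)
    if (o < min_overlap) break
    idx <- which(ov_alive == o, arr.ind = TRUE)
    if (nrow(idx) > 1L) {
      comb <- ssum[idx[, 1]] + ssum[idx[, 2]]
      key <- paste(cons[idx[, 1]], cons[idx[, 2]])
      idx <- idx[order(-comb, key), , drop = FALSE]
    }
    i <- idx[1, 1]; j <- idx[1, 2]
    merged <- merge_motifs(motifs[[i]], motifs[[j]], o)
    motifs[[i]] <- merged
    cons[i] <- merged$consensus
    ssum[i] <- merged$score_sum
    alive[j] <- FALSE
    ov[j, ] <- 0L; ov[, j] <- 0L
    for (m in which(alive)) {
      if (m == i) next
      ov[i, m] <- best_overlap(cons[i], cons[m], min_overlap)
      ov[m, i] <- best_overlap(cons[m], cons[i], min_overlap)
    }
    ov[i, i] <- 0L
  }
  out <- motifs[alive]
  out <- lapply(out, function(m) structure(m, class = "assembled_motif"))
  ord <- order(-vapply(out, `[[`, 0, "score_sum"),
               vapply(out, `[[`, "", "consensus"))
  out[ord]
}

#' @export
print.assembled_motif <- function(x, ...) {
  cat(sprintf("<assembled_motif> %s (%d member(s), score_sum=%.4g)\n",
              x$consensus, nrow(x$members), x$score_sum))
  invisible(x)
}

#' IUPAC consensus of aligned motif members
#'
#' Per column, the IUPAC ambiguity code for the set of observed bases
#' (`{A,T}` -> `W`, `{A,C,T}` -> `H`, all four -> `N`, ...).  Members are
#' laid out by their `offset`; every column must be covered by at least one
#' member.
#'
#' @param aligned_members `data.frame(kmer, offset)` (offsets 0-based).
#' @return IUPAC consensus string.
#' @examples
#' consensus_with_iupac(data.frame(kmer = c("TAA", "AAT"), offset = c(0, 0)))
#' @export
consensus_with_iupac <- function(aligned_members) {
  stopifnot(nrow(aligned_members) >= 1L)
  km <- aligned_members$kmer
  off <- as.integer(aligned_members$offset)
  width <- max(off + nchar(km))
  cols <- vector("list", width)
  for (i in seq_along(km)) {
    ch <- strsplit(km[i], "", fixed = TRUE)[[1]]
    for (p in seq_along(ch)) {
      cols[[off[i] + p]] <- union(cols[[off[i] + p]], ch[p])
    }
  }
  code <- vapply(cols, function(set) {
    if (is.null(set)) stop("uncovered column in member alignment")
    set <- sort(unique(unlist(strsplit(IUPAC_EXPAND[set], ""))))
    IUPAC_CODES[[paste(set, collapse = "")]]
  }, "")
  paste(code, collapse = "")
}

# Expansion of IUPAC letters to their base sets (so consensus over members
# that already contain ambiguity codes stays well defined).
IUPAC_EXPAND <- c(A = "A", C = "C", G = "G", T = "T", M = "AC", R = "AG",
                  W = "AT", S = "CG", Y = "CT", K = "GT", V = "ACG",
                  H = "ACT", D = "AGT", B = "CGT", N = "ACGT")

iupac_revcomp <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  paste(rev(unname(IUPAC_COMPLEMENT[ch])), collapse = "")
}

#' Pair motifs with their reverse complements
#'
#' Greedy maximal pairing of motifs whose consensi are exact IUPAC-aware
#' reverse complements of each other (`W` pairs with `W`, `H` with `D`, ...).
#' A palindromic consensus cannot pair with itself.
#'
#' @param motifs List of `assembled_motif` objects (or character consensi).
#' @return List with `pairs` (`data.frame(first, second)` of consensus
#'   indices) and `unpaired` (integer indices).
#' @export
revcomp_pairing <- function(motifs) {
  cons <- vapply(motifs, function(m)
    if (is.character(m)) m else m$consensus, "")
  rc <- vapply(cons, iupac_revcomp, "", USE.NAMES = FALSE)
  n <- length(cons)
  paired <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (!is.na(paired[i])) next
    js <- which(is.na(paired) & seq_len(n) > i & cons == rc[i])
    if (length(js) > 0L) {
      j <- js[1L]
      paired[i] <- j; paired[j] <- i
    }
  }
  firsts <- which(!is.na(paired) & paired > seq_len(n))
  list(pairs = data.frame(first = firsts, second = paired[firsts]),
       unpaired = which(is.na(paired)))
}

#' Count exact submotif occurrences in motif consensi
#'
#' Overlapping exact occurrences of `pattern` in each consensus; IUPAC
#' ambiguity letters never match, so only unambiguous stretches count.  The
#' default pattern GATC is the Dam methylation site.
#'
#' @param motifs List of `assembled_motif` objects or character consensi.
#' @param pattern Pattern over `{A,C,G,T}`.
#' @return List with `per_motif` (integer vector named by consensus) and
#'   `total`.
#' @examples
#' count_submotif(list("GATCGATC"))$total  # 2
#' @export
count_submotif <- function(motifs, pattern = "GATC") {
  if (grepl("[^ACGT]", pattern)) stop("pattern must be over {A,C,G,T}")
  cons <- vapply(motifs, function(m)
    if (is.character(m)) m else m$consensus, "")
  per <- vapply(cons, function(s) {
    hits <- gregexpr(paste0("(?=", pattern, ")"), s, perl = TRUE)[[1]]
    if (hits[1] == -1L) 0L else length(hits)
  }, 0L)
  list(per_motif = per, total = sum(per))
}

#' Motif extraction pipeline and report
#'
#' Runs the full motif workflow on a trained model: score observed l-mers,
#' keep non-negative importances, cap to the `n_top` strongest (assembly is
#' meant for curated-scale motif sets), assemble by exact overlap, pair
#' reverse complements and count GATC sites.
#'
#' @param model A gkm [train_svm()] model.
#' @param n_top Maximum number of motifs entering assembly (default 200).
#' @param min_overlap Assembly overlap threshold (default 5).
#' @param submotif Pattern counted per consensus (default `"GATC"`).
#' @return List with `importances`, `motifs`, `pairing` and `report`
#'   (`data.frame(motif_id, consensus, n_members, score_sum, paired_with,
#'   gatc_count, member_kmers)`).
#' @export
extract_motifs <- function(model, n_top = 200L, min_overlap = 5L,
                           submotif = "GATC") {
  imp <- score_all_lmers(model, restrict_to_observed = TRUE)
  kept <- positive_importance_filter(imp)
  kept <- top_motifs(kept, n_top)
  motifs <- assemble_by_overlap(kept, min_overlap)
  pairing <- revcomp_pairing(motifs)
  counts <- count_submotif(motifs, submotif)
  paired_with <- rep(NA_integer_, length(motifs))
  if (nrow(pairing$pairs) > 0L) {
    paired_with[pairing$pairs$first] <- pairing$pairs$second
    paired_with[pairing$pairs$second] <- pairing$pairs$first
  }
  report <- data.frame(
    motif_id = seq_along(motifs),
    consensus = vapply(motifs, `[[`, "", "consensus"),
    n_members = vapply(motifs, function(m) nrow(m$members), 0L),
    score_sum = vapply(motifs, `[[`, 0, "score_sum"),
    paired_with = paired_with,
    gatc_count = unname(counts$per_motif),
    member_kmers = vapply(motifs, function(m)
      paste(m$members$kmer, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  list(importances = imp, motifs = motifs, pairing = pairing, report = report)
}
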