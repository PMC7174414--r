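imp_df <- function(kmers, scores) data.frame(kmer = kmers, score = scores,
                                             stringsAsFactors = FALSE)

test_that("importance filter keeps scores >= 0, preserves order, idempotent", {
  x <- imp_df(c("AAAAATTTTT", "CCCCCGGGGG", "ACGTACGTAC"), c(1.2, 0.0, -0.3))
  f <- positive_importance_filter(x)
  expect_equal(f$kmer, x$kmer[1:2])
  expect_equal(positive_importance_filter(f), f)
  allneg <- positive_importance_filter(imp_df("AAAAATTTTT", -1))
  expect_equal(nrow(allneg), 0L)
})

test_that("top-n selection is a deterministic prefix of the sorted list", {
  x <- imp_df(c("TTTT", "AAAA", "CCCC", "GGGG"), c(1, 2, 2, 0.5))
  t2 <- top_motifs(x, 2)
  expect_equal(t2$kmer, c("AAAA", "CCCC"))  # tie at 2 broken lexicographically
  expect_equal(top_motifs(x, 20)$kmer, c("AAAA", "CCCC", "TTTT", "GGGG"))
  full <- top_motifs(x, 4)
  expect_equal(top_motifs(x, 2), head(full, 2))
})

test_that("greedy overlap assembly reproduces the canonical merge", {
  m <- assemble_by_overlap(imp_df(c("AAAGATCTT", "AAGATCTTT"), c(1, 1)), 5)
  expect_length(m, 1L)
  expect_equal(m[[1]]$consensus, "AAAGATCTTT")
  expect_equal(nrow(m[[1]]$members), 2L)
  # members are substrings of the consensus at their offsets
  for (i in seq_len(nrow(m[[1]]$members))) {
    mem <- m[[1]]$members[i, ]
    expect_equal(substr(m[[1]]$consensus, mem$offset + 1,
                        mem$offset + nchar(mem$kmer)), mem$kmer)
  }
  # non-overlapping k-mers stay singletons
  m2 <- assemble_by_overlap(imp_df(c("AAAAAAAAAA", "CCCCCCCCCC"), c(1, 1)), 5)
  expect_length(m2, 2L)
  expect_equal(sort(vapply(m2, `[[`, "", "consensus")),
               c("AAAAAAAAAA", "CCCCCCCCCC"))
})

test_that("assembly is order-invariant and chains multi-way overlaps", {
  kmers <- c("TTATCCACAG", "ATTATCCACA", "TATCCACAGC")
  scores <- c(3, 2, 1)
  m1 <- assemble_by_overlap(imp_df(kmers, scores), 5)
  perm <- c(3, 1, 2)
  m2 <- assemble_by_overlap(imp_df(kmers[perm], scores[perm]), 5)
  expect_equal(lapply(m1, `[[`, "consensus"), lapply(m2, `[[`, "consensus"))
  expect_length(m1, 1L)
  expect_equal(m1[[1]]$consensus, "ATTATCCACAGC")
  expect_equal(m1[[1]]$score_sum, 6)
  for (i in seq_len(nrow(m1[[1]]$members))) {
    mem <- m1[[1]]$members[i, ]
    expect_equal(substr(m1[[1]]$consensus, mem$offset + 1,
                        mem$offset + nchar(mem$kmer)), mem$kmer)
  }
})

test_that("IUPAC consensus covers the full ambiguity table", {
  expect_equal(consensus_with_iupac(data.frame(kmer = c("A", "T"), offset = 0)),
               "W")
  expect_equal(consensus_with_iupac(data.frame(kmer = c("A", "C", "T"),
                                               offset = 0)), "H")
  expect_equal(consensus_with_iupac(data.frame(kmer = c("A", "C", "G", "T"),
                                               offset = 0)), "N")
  expect_equal(consensus_with_iupac(data.frame(kmer = "GATC", offset = 0)),
               "GATC")
  # staggered members produce per-column codes
  expect_equal(consensus_with_iupac(data.frame(kmer = c("TAA", "AAT"),
                                               offset = c(0, 0))), "WAW")
  # uncovered column errors
  expect_error(consensus_with_iupac(data.frame(kmer = c("AA", "AA"),
                                               offset = c(0, 3))), "uncovered")
})

test_that("reverse-complement pairing is IUPAC-aware and excludes palindromes", {
  p <- revcomp_pairing(list("TAATAATAA", "TTATTATTA"))
  expect_equal(nrow(p$pairs), 1L)
  expect_length(p$unpaired, 0L)
  # W is self-complementary as a letter; ATAWWHATA pairs with TATDWWTAT
  p2 <- revcomp_pairing(list("ATAWWHATA", "TATDWWTAT"))
  expect_equal(nrow(p2$pairs), 1L)
  # palindromic consensus cannot pair with itself
  p3 <- revcomp_pairing(list("GATC"))
  expect_equal(nrow(p3$pairs), 0L)
  expect_equal(p3$unpaired, 1L)
  p4 <- revcomp_pairing(list("AAAA"))
  expect_equal(p4$unpaired, 1L)
  # symmetric under reverse complementing the whole set
  set <- list("TAATAATAA", "TTATTATTA", "CCCCAAAAA")
  fwd <- revcomp_pairing(set)
  rev <- revcomp_pairing(lapply(set, function(s)
    as.character(reverse_complement(s))))
  expect_equal(nrow(fwd$pairs), nrow(rev$pairs))
})

test_that("GATC counting is overlapping, exact, and blind to ambiguity codes", {
  expect_equal(count_submotif(list("AAAGATCTTT"))$total, 1L)
  expect_equal(count_submotif(list("GATCGATC"))$total, 2L)
  expect_equal(count_submotif(list("GAGATATC"))$total, 0L)
  expect_equal(count_submotif(list("GATGATC", "GATCATC"))$per_motif,
               c(GATGATC = 1L, GATCATC = 1L))
  expect_equal(count_submotif(list("GRTC"))$total, 0L)
  expect_equal(count_submotif(list("AAAA"), "AA")$total, 3L)
  expect_error(count_submotif(list("GATC"), "GATN"), "\\{A,C,G,T\\}")
})

test_that("motif pipeline recovers a strongly planted motif end to end", {
  # positives carry GGATCCGGAT twice on clean background: the full pipeline
  # (score -> filter/top -> assemble) must surface it
  withr::with_seed(31, {
    motif <- "GGATCCGGAT"
    len <- 80
    pos <- vapply(1:18, function(i) {
      s <- random_dna(1, len)
      s <- paste0(substr(s, 1, 10), motif, substr(s, 21, 50), motif,
                  substr(s, 61, len))
      s
    }, "")
    neg <- random_dna(18, len)
  })
  m <- train_svm(pos, neg, gkm_params(fragment_length = 80), rng_seed = 1)
  mx <- extract_motifs(m, n_top = 20)
  expect_true(any(grepl(motif, mx$report$consensus) |
                    grepl(as.character(reverse_complement(motif)),
                          mx$report$consensus)) ||
                motif %in% head(mx$importances$kmer, 20))
  expect_equal(nrow(mx$report), length(mx$motifs))
})
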