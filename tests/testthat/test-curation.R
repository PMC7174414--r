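test_that("cumulative GC-skew matches direct summation", {
  p <- cumulative_gc_skew("CCCCGGGG")
  expect_equal(p$values, c(-1, -2, -3, -4, -3, -2, -1, 0))
  expect_equal(p$argmin, 3L)
  p2 <- cumulative_gc_skew("ATAT")
  expect_true(all(p2$values == 0))
  expect_equal(p2$argmin, 0L)
  expect_equal(cumulative_gc_skew("GCNNG")$total, 1)
})

test_that("skew is additive under concatenation and antisymmetric under revcomp", {
  withr::with_seed(12, {
    for (i in 1:5) {
      s1 <- random_dna(1, 200); s2 <- random_dna(1, 150)
      expect_equal(cumulative_gc_skew(paste0(s1, s2))$total,
                   cumulative_gc_skew(s1)$total + cumulative_gc_skew(s2)$total)
      # revcomp negates and reverses the per-base steps
      v <- cumulative_gc_skew(s1)$values
      vr <- cumulative_gc_skew(reverse_complement(s1))$values
      steps <- diff(c(0, v)); steps_r <- diff(c(0, vr))
      expect_equal(steps_r, -rev(steps))  # complement flips sign, reversal flips order
    }
  })
})

test_that("intergenic windows are midpoint-centered", {
  rec <- genome_record("g", strrep("ACGT", 100))  # 400 bp
  genes <- data.frame(start = c(0, 200), end = c(100, 300))
  w <- intergenic_windows(rec, genes, window_length = 50)
  centers <- (w$start + w$end) %/% 2
  expect_true(150 %in% centers)  # midpoint of [100, 200)
  expect_true(350 %in% centers)  # midpoint of [300, 400)
  expect_equal(unique(w$end - w$start), 50L)
  # no genes: whole record intergenic, window at L %/% 2
  w2 <- intergenic_windows(rec, genes[0, ], window_length = 50)
  expect_equal((w2$start + w2$end) %/% 2, 200)
  # abutting genes leave no junction window
  genes3 <- data.frame(start = c(0, 100), end = c(100, 400))
  expect_warning(w3 <- intergenic_windows(rec, genes3, window_length = 50),
                 "no intergenic")
  expect_equal(nrow(w3), 0L)
})

test_that("near-minimum filter uses (circular) center distance", {
  s <- paste0(strrep("C", 500), strrep("G", 500))  # argmin at 499
  prof <- cumulative_gc_skew(s)
  expect_equal(prof$argmin, 499L)
  wins <- data.frame(source_id = "x", start = c(474, 300, 0),
                     end = c(524, 350, 50), strand = "+", seed = NA,
                     wrap = FALSE, sequence = NA)
  # centers are 499, 325 and 25: distances 0, 174 and 474 from the argmin
  kept <- near_minimum_filter(wins, prof, max_distance = 100, circular = FALSE)
  expect_equal(kept$start, 474)
  kept2 <- near_minimum_filter(wins, prof, max_distance = 174, circular = FALSE)
  expect_equal(kept2$start, c(474, 300))
  # boundary: distance exactly max_distance is kept, one less drops it
  kept3 <- near_minimum_filter(wins[2, ], prof, max_distance = 173,
                               circular = FALSE)
  expect_equal(nrow(kept3), 0L)
  # circular distance rescues windows across the coordinate origin
  s2 <- paste0(strrep("G", 500), strrep("C", 500))  # argmin at 999
  prof2 <- cumulative_gc_skew(s2)
  expect_equal(prof2$argmin, 999L)
  wins4 <- data.frame(source_id = "x", start = 5, end = 55, strand = "+",
                      seed = NA, wrap = FALSE, sequence = NA)  # center 30
  expect_equal(nrow(near_minimum_filter(wins4, prof2, 100, circular = FALSE)), 0L)
  expect_equal(nrow(near_minimum_filter(wins4, prof2, 100, circular = TRUE)), 1L)
})

test_that("synthetic chromosomes place the skew minimum at the planted origin", {
  cfg <- synthetic_config(fragment_length = 300,
                          due_window = list(offset = 30, length = 100,
                                            at_fraction = 0.9))
  hits <- 0L
  for (sd in 1:10) {
    sim <- generate_skewed_chromosome(30000, 18000, 0.1, cfg, rng_seed = sd)
    am <- cumulative_gc_skew(sim$record)$argmin
    if (abs(am - 18000) <= 1000) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("DnaA-box scan agrees with naive substring comparison", {
  s <- paste0("GG", "TTATCCACA", "AA", "TGTGGATAA", "C")
  hits <- dnaa_box_scan(s, max_mismatches = 0)
  expect_equal(hits$position[hits$strand == "+"], 2L)
  expect_equal(hits$position[hits$strand == "-"], 13L)
  # exhaustive oracle on random sequence, forward strand, 0 mismatches
  withr::with_seed(19, {
    r <- random_dna(1, 1000, gc = 0.4)
    naive <- which(substring(r, 1:(1000 - 8), 9:1000) == "TTATCCACA") - 1L
    got <- dnaa_box_scan(r, max_mismatches = 0, both_strands = FALSE)
    expect_equal(got$position, naive)
    # 1-mismatch counts match a hamming oracle
    ham <- vapply(1:(1000 - 8), function(i)
      sum(strsplit(substr(r, i, i + 8), "")[[1]] !=
            strsplit("TTATCCACA", "")[[1]]), 0L)
    got1 <- dnaa_box_scan(r, max_mismatches = 1, both_strands = FALSE)
    expect_equal(got1$position, which(ham <= 1) - 1L)
    expect_equal(got1$n_mismatches, ham[ham <= 1])
  })
  # N never matches
  expect_equal(nrow(dnaa_box_scan("TTATCCACN", max_mismatches = 0)), 0L)
})

test_that("seed-matched negatives share size and seed, never overlap, deterministic", {
  withr::with_seed(23, {
    s <- paste0(random_dna(1, 3000), "TTATCCACA", random_dna(1, 4000),
                "TTATCCACA", random_dna(1, 3000))
  })
  rec <- genome_record("chr", s)
  idx <- seed_index("TTATCCACA")
  cand <- extract_candidates(rec, idx, fragment_length = 501,
                             search_reverse_strand = FALSE)
  expect_equal(nrow(cand), 2L)
  pos <- cand[1, ]
  neg <- make_seed_matched_negatives(pos, rec, rng_seed = 1,
                                     search_reverse_strand = FALSE)
  expect_equal(neg$end - neg$start, pos$end - pos$start)
  off <- (501 - 9) %/% 2
  expect_equal(substr(neg$sequence, off + 1, off + 9), pos$seed)
  expect_true(neg$start >= pos$end || neg$end <= pos$start)
  neg2 <- make_seed_matched_negatives(pos, rec, rng_seed = 1,
                                      search_reverse_strand = FALSE)
  expect_equal(neg, neg2)
  # no alternative occurrence -> error
  s1 <- paste0(strrep("G", 1000), "TTATCCACA", strrep("G", 1000))
  rec1 <- genome_record("single", s1)
  cand1 <- extract_candidates(rec1, idx, fragment_length = 101,
                              search_reverse_strand = FALSE)
  expect_error(make_seed_matched_negatives(cand1[1, ], rec1),
               "no alternative occurrence")
})
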