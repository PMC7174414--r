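test_that("background generator hits its composition and is reproducible", {
  expect_error(generate_background(100, gc = 1.0), "open interval")
  expect_error(synthetic_config(background_gc = 0), "open interval")
  s1 <- generate_background(10000, 0.5, rng_seed = 1)
  s2 <- generate_background(10000, 0.5, rng_seed = 1)
  expect_identical(s1, s2)
  gcf <- mean(strsplit(s1, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gcf - 0.5), 0.02)
  s3 <- generate_background(10000, 0.3, rng_seed = 2)
  gcf3 <- mean(strsplit(s3, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gcf3 - 0.3), 0.02)
})

test_that("positives carry seed, boxes and an AT-rich DUE; negatives only the seed", {
  cfg <- synthetic_config(fragment_length = 500)
  pos <- generate_positive(cfg, rng_seed = 1)
  neg <- generate_negative(cfg, rng_seed = 1)
  c0 <- (500 - 9) %/% 2
  expect_equal(substr(pos, c0 + 1, c0 + 9), "TTATCCACA")
  expect_equal(substr(neg, c0 + 1, c0 + 9), "TTATCCACA")
  expect_equal(nchar(pos), 500L)
  expect_equal(nchar(neg), 500L)
  # >= 3 planted boxes on the forward strand beyond the central copy
  hits <- dnaa_box_scan(pos, max_mismatches = 0, both_strands = FALSE)
  expect_gte(nrow(hits), 4L)
  expect_identical(generate_positive(cfg, rng_seed = 9),
                   generate_positive(cfg, rng_seed = 9))
})

test_that("the DUE window is AT-enriched relative to the rest, per record", {
  cfg <- synthetic_config(fragment_length = 500)
  at_frac <- function(s) mean(strsplit(s, "")[[1]] %in% c("A", "T"))
  due <- cfg$due_window
  ok <- vapply(1:100, function(sd) {
    p <- generate_positive(cfg, rng_seed = sd)
    inside <- substr(p, due$offset + 1, due$offset + due$length)
    outside <- paste0(substr(p, 1, due$offset),
                      substr(p, due$offset + due$length + 1, nchar(p)))
    at_frac(inside) > at_frac(outside)
  }, TRUE)
  expect_true(all(ok))
})

test_that("planted elements collide with fixed placements predictably", {
  expect_error(synthetic_config(fragment_length = 500, planted_elements = list(
    list(motif = "TTATCCACA", copies = 1, placement = 150))), "DUE")
  cfg <- synthetic_config(fragment_length = 500, planted_elements = list(
    list(motif = "TTATCCACA", copies = 1, placement = 10),
    list(motif = "TAATAATAA", copies = 1, placement = 12)))
  expect_error(generate_positive(cfg, rng_seed = 1), "collides")
})

test_that("fragment sets are balanced, labelled and seed-reproducible", {
  cfg <- synthetic_config(n_pos = 5, n_neg = 7, fragment_length = 300,
                          due_window = list(offset = 30, length = 100,
                                            at_fraction = 0.9), rng_seed = 11)
  fs <- generate_fragment_set(cfg)
  expect_equal(table(fs$class), table(c(rep("pos", 5), rep("neg", 7))))
  expect_equal(fs, generate_fragment_set(cfg))
  expect_false(anyDuplicated(fs$id) > 0)
})

test_that("skewed chromosomes have extrema at origin and antipode", {
  cfg <- synthetic_config(fragment_length = 300,
                          due_window = list(offset = 30, length = 100,
                                            at_fraction = 0.9))
  sim <- generate_skewed_chromosome(50000, 20000, 0.1, cfg, rng_seed = 1)
  expect_equal(sim$record$topology, "circular")
  expect_equal(nchar(sim$record$sequence), 50000L)
  prof <- cumulative_gc_skew(sim$record)
  expect_lte(abs(prof$argmin - 20000), 1000)
  expect_lte(abs(prof$argmax - 45000), 2000)
  # the planted interval carries the seed at its center
  frag <- substr(sim$record$sequence, sim$truth$planted_start + 1,
                 sim$truth$planted_end)
  c0 <- (300 - 9) %/% 2
  expect_equal(substr(frag, c0 + 1, c0 + 9), cfg$seed)
  expect_error(generate_skewed_chromosome(10000, 12000, 0.1, cfg), "origin_position")
  expect_error(generate_skewed_chromosome(10000, 100, 0.5, cfg), "skew_strength")
})

test_that("taxon datasets plant private motifs with valid labels", {
  cfg <- synthetic_config(fragment_length = 200,
                          due_window = list(offset = 10, length = 60,
                                            at_fraction = 0.9))
  td <- generate_taxon_dataset(n_taxa = 3, per_taxon_n = 4, config = cfg,
                               rng_seed = 1)
  expect_equal(nrow(td$fragments), 12L)
  expect_equal(nrow(td$label_table), 12L)
  expect_equal(sort(unique(td$label_table$order)),
               c("taxon_1", "taxon_2", "taxon_3"))
  motifs <- c("AGGCTTGACC", "CTTGAGGCAT", "GCCAATCGTG")
  for (t in 1:3) {
    seqs <- td$fragments$sequence[td$label_table$order == sprintf("taxon_%d", t)]
    n_hits <- vapply(seqs, function(s)
      length(gregexpr(paste0("(?=", motifs[t], ")"), s, perl = TRUE)[[1]]), 0L)
    expect_true(all(n_hits >= 2))
  }
  expect_equal(td, generate_taxon_dataset(n_taxa = 3, per_taxon_n = 4,
                                          config = cfg, rng_seed = 1))
  expect_error(generate_taxon_dataset(2, 4, c("AAAAAAAAAA", "AAAAAAAAAT"),
                                      cfg), "Hamming")
})
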