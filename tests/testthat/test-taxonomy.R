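make_label_table <- function(counts, level = "order") {
  ids <- character(0); tax <- character(0)
  for (i in seq_along(counts)) {
    ids <- c(ids, sprintf("t%d_s%d", i, seq_len(counts[i])))
    tax <- c(tax, rep(names(counts)[i], counts[i]))
  }
  lt <- data.frame(sequence_id = ids, order = NA_character_,
                   family = NA_character_, genus = NA_character_,
                   stringsAsFactors = FALSE)
  lt[[level]] <- tax
  lt
}

test_that("taxon eligibility is count >= 5, unknowns excluded", {
  lt <- make_label_table(c(A = 4, B = 5, C = 7))
  lt$order[lt$order == "C"][1] <- NA  # C drops to 6
  el <- filter_taxa(lt, "order")
  expect_equal(el$taxon, c("B", "C"))
  expect_equal(el$n, c(5L, 6L))
  lt2 <- make_label_table(c(A = 6))
  lt2$order <- NA_character_
  expect_warning(el2 <- filter_taxa(lt2, "order"), "no known labels")
  expect_equal(nrow(el2), 0L)
})

test_that("encoders obey their conservation laws", {
  v <- one_hot_encode("ACGT")
  expect_equal(which(v == 1), c(1L, 6L, 11L, 16L))
  expect_equal(one_hot_encode("N"), c(0, 0, 0, 0))
  withr::with_seed(3, {
    s <- random_dna(1, 40)
    expect_equal(sum(one_hot_encode(s)), 40)
    k <- kmer_count_encode(s)
    expect_length(k, 5460L)
    for (kk in 1:6) {
      block <- kmer_count_encode(s, kk, kk)
      expect_equal(sum(block), 40 - kk + 1)
    }
  })
  expect_equal(unname(kmer_count_encode("AAAA", 2, 2)["AA"]), 3)
  expect_error(one_hot_encode("ACG", 4), "length")
})

test_that("pseudo-sentences tile every frame with trailing remainder dropped", {
  s <- withr::with_seed(4, random_dna(1, 30))
  ps <- pseudo_sentences(s)
  expect_length(ps, 10L)
  expect_equal(lengths(ps), c(3L, rep(2L, 9)))
  expect_equal(paste(ps[[1]], collapse = ""), s)
  L <- 47
  s2 <- withr::with_seed(5, random_dna(1, L))
  ps2 <- pseudo_sentences(s2)
  expect_equal(sum(lengths(ps2)), sum((L - 0:9) %/% 10))
  expect_equal(pseudo_sentences("ACGT"), list())
})

test_that("AUPR matches the exhaustive oracle on all tiny instances", {
  expect_equal(aupr(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 5 / 6)
  expect_equal(aupr(c(3, 2, 1), c(1, 1, 0)), 1.0)
  # enumerate every labelling of up to 8 items on fixed score vectors,
  # including tied scores
  withr::with_seed(6, {
    for (n in 2:8) {
      scores <- round(runif(n), 1)  # coarse grid forces ties
      for (mask in 1:(2^n - 2)) {
        labels <- as.integer(intToBits(mask))[1:n] == 1L
        expect_equal(aupr(scores, labels), oracle_aupr(scores, labels))
      }
    }
  })
  # anti-ranking is bounded near prevalence
  expect_lte(aupr(1:10, c(rep(1, 3), rep(0, 7))), 0.3 + 0.05)
  expect_error(aupr(c(1, 2), c(1, 1)), "positive and one negative")
})

test_that("one-vs-rest training recovers private taxon motifs", {
  cfg <- synthetic_config(fragment_length = 260,
                          due_window = list(offset = 10, length = 60,
                                            at_fraction = 0.9))
  td <- generate_taxon_dataset(n_taxa = 3, per_taxon_n = 9, config = cfg,
                               rng_seed = 2)
  fr <- stats::setNames(td$fragments$sequence, td$fragments$id)
  train_ids <- unlist(lapply(1:3, function(t)
    sprintf("taxon%d_frag%d", t, 1:6)))
  test_ids <- setdiff(names(fr), train_ids)
  ms <- train_taxon_models(fr[train_ids], td$label_table,
                           level = "order",
                           params = gkm_params(fragment_length = 260),
                           min_count = 5, rng_seed = 1)
  expect_s3_class(ms, "taxon_model_set")
  expect_length(ms$models, 3L)
  ev <- evaluate_taxa(ms, fr[test_ids], td$label_table)
  expect_equal(ev$macro_aupr, mean(ev$per_taxon$aupr))
  expect_gt(ev$macro_aupr, 0.6)
  # each model ranks its own taxon's held-out sequences on top
  S <- taxon_scores(ms, fr[test_ids])
  truth <- sub("_frag.*", "", test_ids)
  pred <- sub("taxon_", "taxon", colnames(S)[max.col(S)])
  expect_gt(mean(pred == truth), 0.6)
})

test_that("model-set training is deterministic and validates its inputs", {
  cfg <- synthetic_config(fragment_length = 220,
                          due_window = list(offset = 5, length = 40,
                                            at_fraction = 0.9))
  td <- generate_taxon_dataset(n_taxa = 2, per_taxon_n = 6, config = cfg,
                               rng_seed = 3)
  fr <- stats::setNames(td$fragments$sequence, td$fragments$id)
  p <- gkm_params(fragment_length = 220)
  m1 <- train_taxon_models(fr, td$label_table, "order", params = p, rng_seed = 5)
  m2 <- train_taxon_models(fr, td$label_table, "order", params = p, rng_seed = 5)
  strip <- function(ms) lapply(ms$models, function(m) {
    m$metadata$created_at <- NULL; unclass(m) })
  expect_equal(strip(m1), strip(m2))
  # a taxon below min_count is absent; a single eligible taxon errors
  lt <- td$label_table
  lt$order[lt$order == "taxon_2"][1:2] <- NA  # taxon_2 drops to 4
  expect_error(train_taxon_models(fr, lt, "order", params = p), "2 eligible")
})

test_that("macro summary averages per-taxon AUPRs and excludes absent taxa", {
  cfg <- synthetic_config(fragment_length = 220,
                          due_window = list(offset = 5, length = 40,
                                            at_fraction = 0.9))
  td <- generate_taxon_dataset(n_taxa = 2, per_taxon_n = 6, config = cfg,
                               rng_seed = 7)
  fr <- stats::setNames(td$fragments$sequence, td$fragments$id)
  ms <- train_taxon_models(fr, td$label_table, "order",
                           params = gkm_params(fragment_length = 220),
                           rng_seed = 1)
  # test set lacking taxon_2 positives: taxon_2 excluded with a warning,
  # sd = 0 over the single remaining taxon (the unlabeled decoy sequence
  # provides taxon_1's negative)
  sub <- c(fr[grepl("taxon1", names(fr))],
           decoy = generate_negative(cfg, rng_seed = 99))
  expect_warning(ev <- evaluate_taxa(ms, sub, td$label_table), "excluded")
  expect_equal(nrow(ev$per_taxon), 1L)
  expect_equal(ev$aupr_sd, 0)
})
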