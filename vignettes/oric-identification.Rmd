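---
title: "Identifying bacterial replication origins with gapped k-mer SVMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying bacterial replication origins with gapped k-mer SVMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bacterial chromosomes replicate from a single origin, *oriC*: a mostly
intergenic locus of roughly a kilobase that carries binding sites for the
initiator protein DnaA (9 bp "DnaA boxes", high-affinity exemplar
`TTATCCACA`), short AT-rich DnaA-trio repeats (`TAATAATAA`-like), and an
AT-rich DNA unwinding element (DUE) where the duplex first opens.  On
complete chromosomes the cumulative GC skew — the running sum of +1 per G
and −1 per C — typically traces a V whose minimum marks the origin, but that
chromosome-scale signal is useless on the sequence fragments that dominate
public databases.  `oricsvm` implements a sequence-only, fragment-capable
identification pipeline for this setting, together with the surrounding
machinery: ground-truth curation primitives, taxonomic classification of
origin sequences, motif extraction from trained models, and a synthetic data
generator that makes the whole package testable without downloads.

## The pipeline

Identification runs in three stages per input sequence:

1. **Seed-anchored candidate extraction.** The central 9 bp of each known
   origin in the training set form a *seed index*.  Every occurrence of a
   seed in the input (both strands by default) anchors one candidate window
   of fixed length *F* (default 1250 bp), placed so the seed sits at offset
   `(F − 9) %/% 2` — the same offset the seeds were extracted from.  This
   reduces a chromosome to a manageable candidate set instead of a sliding
   scan.

2. **Gapped k-mer SVM scoring.** Candidates are scored by a support vector
   machine over the gapped k-mer string kernel
   \[ K(a, b) = \sum_{u \in a,\, v \in b} w\big(d_H(u, v)\big), \qquad
      w(m) = \binom{l - m}{k}\ \text{for } m \le d,\ 0\ \text{otherwise}, \]
   where the sum runs over all length-*l* words of the two sequences,
   $d_H$ is Hamming distance, and $\binom{l-m}{k}$ counts the
   informative-column subsets that avoid every mismatch.  The defaults are
   $l = 10$, $k = 6$, $d = 4$: note $\binom{l-m}{k} = 0$ for $m \ge 5$
   anyway, so at these parameters the kernel is *exactly* the inner product
   of explicit gapped k-mer feature vectors, which is how the test suite
   oracle-checks it.  The kernel is cosine-normalized
   ($K' = K/\sqrt{K_{aa}K_{bb}}$) before the SVM is solved so decision
   values are comparable across fragments; whether the original LS-GKM-style
   tooling normalizes is tool-internal, and this package states its choice
   explicitly.  A spectrum-kernel backend (plain k-mer count inner product)
   is available for comparison.

3. **Abstaining two-cutoff decision.** Because one chromosome yields many
   candidates but carries one origin, decision values are min–max normalized
   *within each input sequence* to [0, 1] and labelled with two cutoffs
   (defaults 0.41 and 0.99): strictly above the upper cutoff → `positive`,
   strictly below the lower → `negative` (discarded), in between the
   classifier abstains and returns the fragment to the user.  Abstention
   trades a few extra manual decisions for fewer irreversible false
   negatives.  `cutoff_scan()` reproduces the cutoff-selection procedure as
   a grid scan maximizing F1 while minimizing abstained true origins, ties
   broken toward fewer abstentions and then a higher upper cutoff.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `word_length` (l) | 10 | kernel word size, bases |
| `informative_columns` (k) | 6 | ungapped columns per word |
| `max_mismatches` (d) | 4 | mismatch truncation of the weight |
| `fragment_length` (F) | 1250 | candidate window, bases |
| seed length | 9 | central anchor extracted from known origins |
| cutoffs | 0.41 / 0.99 | abstention band on normalized scores |
| soft-margin C | 1.0 | solver default, exposed as an argument |

## Design choices in corner cases

* **Even-length centering.** "Central" is ambiguous for even `F`; the
  package fixes seed offset `(F − 9) %/% 2` everywhere, so index building
  and candidate extraction are mutually consistent.  On the minus strand the
  window start uses the mirrored offset `(F − 9 + 1) %/% 2` so that the
  reverse-complemented fragment carries the seed at the same central offset
  — with an odd `F − 9` the naive formula would shift the seed by one and
  break the round trip.
* **Reverse-strand search defaults on.** Training origins are co-oriented,
  arbitrary user input is not.  A flag restores forward-only scanning.
* **Boundary windows are discarded, not padded** (the SVM contract requires
  exactly `F` bases; padding would inject artificial composition); on
  records declared circular, windows wrap instead.
* **Degenerate normalization maps to 1.0.**  A record with a single
  candidate (or all-equal scores) labels its best candidate positive, which
  matches the premise that every chromosome carries one origin.
* **Cutoff comparisons are strict**, so a normalized value exactly at a
  cutoff abstains.
* **N handling.** Words containing `N` contribute zero to every kernel;
  non-ACGTN IUPAC letters are mapped to `N` on input with a warning rather
  than rejected, since public-database fragments contain ambiguity codes.
* **Determinism.** Training sorts its inputs before solving the dual
  problem, every stochastic step flows from one integer seed, and models
  serialize to JSON at full precision, so a retrain or a reload reproduces
  decision values exactly (the `created_at` timestamp is the one field
  excluded from such comparisons).

## Curation primitives

The semi-automated procedure that produced origin ground truth rests on four
assumptions — origins are intergenic, near the cumulative GC-skew minimum,
contain a DUE, and carry DnaA boxes.  The package provides the mechanical
parts: `cumulative_gc_skew()` (with first-attaining argmin), 2.5 kb
`intergenic_windows()` centered on intergenic midpoints,
`near_minimum_filter()` (the literature never quantifies "close to the
minimum"; the default of 5% of chromosome length is this package's declared
choice), `dnaa_box_scan()` with a mismatch budget, and
`make_seed_matched_negatives()`, which builds the negative training set:
same length, same central seed, different locus of the same chromosome.
Strand-separation (SIDD) thermodynamics is deliberately out of scope; the
pipeline accepts user-supplied destabilization scores instead, and the final
accept/reject decision of the curation procedure remains manual.

## Taxonomic classification

`train_taxon_models()` fits one-vs-rest binary classifiers per taxon at the
order, family or genus level, for every taxon with at least five labelled
sequences ("more than 4").  Negatives for each taxon are all other
*eligible* sequences at the same level — the standard one-vs-rest reading.
The gkm backend shares the identification kernel; a random-forest backend
over one-hot or k-mer-count (1 ≤ k ≤ 6) encodings is included for
comparison.  Word-embedding encodings are supported only at the tokenization
level (`pseudo_sentences()` emits all ten frames of consecutive
non-overlapping 10-mers — the frame reading of an ambiguous construction;
the sliding-window reading would duplicate every token ten times):
embedding training itself is stochastic and library-specific, and it was the
weakest encoder in this setting, so it is left behind an external-trainer
contract rather than reimplemented.

Evaluation uses macro-averaged AUPR, the unweighted mean over per-taxon
areas under the precision–recall curve, computed by average-precision step
summation with tied scores grouped — no trapezoidal interpolation, so values
reproduce bit for bit and match an exhaustive threshold-sweep oracle on
small instances.

## Motif extraction

Each length-`l` word can be scored as a bare input to the trained SVM; the
resulting importance list drives motif discovery.  Words with score ≥ 0 are
"important" (boundary inclusive), the strongest are assembled greedily by
exact suffix–prefix overlap of at least 5 bases (half the word length —
long enough that chance joins among a few dozen random 10-mers are not
expected, short enough to admit the 8-base overlaps genuine shared motifs
produce), ties broken toward higher combined score and then
lexicographically.  Assembly is quadratic in the number of motifs and aimed
at curated-scale sets, so the `extract_motifs()` pipeline caps its input at
the 200 strongest non-negative importances.  `consensus_with_iupac()`
collapses aligned members to IUPAC ambiguity codes, `revcomp_pairing()`
matches motifs to their reverse complements (a palindrome cannot pair with
itself), and `count_submotif()` counts exact GATC (Dam methylation site)
occurrences; any statistical comparison of such counts between taxon groups
is delegated to standard rank-sum routines.

By default `score_all_lmers()` scores only words observed in the support
sequences: full $4^{10}$ enumeration is supported but costs minutes against
large models, and the observed set is what the downstream motif steps
consume.

## What the synthetic generator emulates — and what it does not

`synthetic_config()` describes positives as i.i.d. background (GC 0.5) with
a 300 bp DUE at offset 100 resampled at 90% A+T, three planted DnaA boxes,
two DnaA-trio copies, and the seed 9-mer written at the exact center;
negatives share length and central seed but no other grammar.  These
defaults mirror the four motif classes recoverable from real origin
models.  `generate_skewed_chromosome()` embeds one positive fragment in a
circular chromosome whose G/C probabilities shift by ±0.1 between the two
replichores, producing the V-shaped cumulative skew with its minimum at the
planted origin.  `generate_taxon_dataset()` adds two copies of a
taxon-private motif (pairwise Hamming ≥ 3) on top of the shared grammar.

Real gammaproteobacterial chromosomes are not i.i.d.: they have codon
structure, repeats, mobile elements, strand-specific composition beyond GC
skew, and origins whose grammar varies across taxa.  Passing the synthetic
tests therefore demonstrates that the machinery is correct and that the
kernel can learn planted grammar against seed-matched controls — it does not
certify field performance on RefSeq data, which depends on curated training
sets the package does not ship.

## Problem sizes used by the test suite and acceptance script

Training uses 200 positives / 200 negatives of 500 bp (a size at which the
kernel remains strongly informative while a full run of suite plus script
stays in the minutes range), evaluation 100/100 held out; identification
runs on ten 100 kb circular chromosomes with skew strength 0.1; taxonomy
uses three taxa of 40 fragments with a held-out third.  Unit tests shrink
these further (tens of fragments, 80–300 bp) since the properties they check
are size-independent.

## Known limitations

* Criterion-level caveat observed on the synthetic conditions above: with a
  500 bp fragment whose DUE covers 60% of the sequence and with the DnaA box
  doubling as the universal seed (so every negative carries one copy at its
  center), no bare 10-mer attains a non-negative decision score — the
  intercept dominates — and the best box-containing 10-mer ranks in the top
  1% but not the top 20 of observed words; DnaA-trio and DUE-derived AT-rich
  words outrank it.  Importance extraction behaves as designed (the score of
  a bare word is its decision value, bias included); the ranking simply
  reflects where the discriminative mass of this generative model lies.
* Greedy overlap assembly approximates the manual grouping of motifs by
  similarity; the optimal-superstring problem it sidesteps is NP-hard, and
  the mismatch-tolerant clustering used to form ambiguous consensi in the
  field is judgment-laden, so only exact-overlap assembly plus IUPAC
  collapse is automated.
* The hyperparameter sweep that selected the default kernel configuration
  is represented only by its winning configuration and a reduced
  fragment-length grid (150–1500 bp in 50 bp steps via `gkm_params()`
  arguments); rerunning a thousands-of-models sweep is out of scope.
* `aupr()` requires both classes present; taxa missing from a test set are
  excluded from the macro average with a warning rather than imputed.
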