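---
title: "Re-targeting classification label spaces to a human population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Re-targeting classification label spaces to a human population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crtkit)
```

## The problem

Image-classification datasets ship with a label space chosen by their
curators. The categories a given human population actually perceives and
names rarely coincide with it: people merge fine-grained categories they
cannot tell apart (several bird species become "bird"), split heterogeneous
ones (a "library" category separates into book close-ups and library
interiors), and prefer different names ("fox" for a wild dog they have never
heard of). A classifier evaluated against the curators' labels can therefore
look better or worse than it is *for those users*.

`crtkit` measures that gap and applies it. The central object is a
**cognitive relevance transform** (CRT): a set of new categories, each
realized as a merge of image sets (with separations of original categories
resolved image by image), annotated with where its images came from, named
by the population's own words, and accompanied by a prediction map that
re-targets any classifier output onto the new label space. The package
covers the full workflow:

1. **Design** (`subsample_design()`, `population_design()`,
   `solve_n_anova()`): how many categories, images, batches, observations
   and subjects a crowd study needs, from statistical power requirements.
2. **Consensus** (`consensus_labels()`): per-image population answers from
   per-subject forced-choice answers, via an exact binomial test.
3. **Derivation** (`derive_crt()`): k-modes clustering of grouping
   responses, elbow-based cluster-count suggestion, text cleaning of
   free-text labels, modal naming, same-name merging, thresholded
   merge/separation bookkeeping.
4. **Application** (`transform_cfm()`, `compute_metrics()`): transformed
   confusion matrices and macro Top-1/precision/recall/F1.
5. **Verification** (`random_crt()`, `null_metric_distribution()`,
   `wilcoxon_signed_rank()`, `preference_test()`, `contingency_chisq()`):
   is the derived transform better than chance, and do people prefer it?
6. **Simulation** (`simulate_study()`): synthetic crowds with planted
   structure so the entire pipeline is testable with no crowd platform and
   no image data.

## Study design model

Two powered sizing steps precede any crowd work.

**Subset size.** With `|C|` original categories, a task showing `nu_c`
categories times `nu_i` images, and effect sizes `h_c` (Cohen's h) and `w`
(Cohen's w), the minimal real number of categories `n_c` solves the
normal-approximation power of the two-sample proportions test with unequal
sizes — closed form `n2 = K n1 / (n1 - K)`, `K = ((z_{1-a/2} + z_{pow}) /
h)^2` — and the minimal images per category solve the noncentral
chi-squared power of the independence test on the eventual human confusion
matrix, with `df = (n_c - 1)^2` and noncentrality `N w^2`, by root-finding.
Both are then rounded up to task-divisible integers (`to_integer()`), and
the batch count follows from the accounting identity
`|B| nu_c nu_i = |C'| |H'|`.

The chi-squared degrees of freedom use the *unrounded* `n_c` by default.
For both parameter sets exercised in the tests the rounded variant yields
the same final image count; the flag `round_df_nc` exposes it.

**Population size.** The expected (`p_est`) and minimum acceptable
(`p_min`) human success probabilities give Cohen's h
(`2 asin sqrt(p1) - 2 asin sqrt(p2)`); the arcsine normal approximation of
the binomial test gives the observations each image needs
(`n = ((z_{1-a} + z_{pow})/h)^2`, one-sided by default since the consensus
question is directional), and subjects are `batches x observations`. At
`(p_min, p_est) = (0.5, 0.75)` with power 0.8 this yields 23 observations
per image. A no-square-root variant of the effect size is kept behind
`literal_h` for audit only; it does not reproduce the standard sizing.
(For a 6-batch design the same parameters give 23 observations and 138
subjects; sizing tables in circulation sometimes print 24/144 for that
configuration, which this solver does not reproduce.)

Sidedness defaults are two-sided for the two-proportion and chi-squared
solvers and one-sided for the one-proportion solver; all are overridable
through `power_spec()`.

## Consensus model

Per image, the crowd's answers are reduced to a two-class problem: the
positive class is the most frequent answer, everything else is negative.
The original dataset label is replaced by the crowd's top answer only when
the top answer's support significantly exceeds `p_est` under a one-sided
exact binomial test at `alpha = 0.05` — the prior being that curated labels
are correct, if not optimal. Ties for most frequent go to the original
label, then lexicographic. Images with fewer than 5 votes are flagged and
kept at the original label, where the test is powerless. A `"literal"` mode
that counts agreement with the original label and tests the lower tail is
available for audit; it is not the default because only the
positive-class semantics yields the intended keep/replace behaviour (a
crowd at or below the expected success rate never triggers replacement, so
the truth-versus-consensus matrix stays diagonal).

## Deriving the transform

**Clustering.** Grouping responses form an images-by-subjects categorical
matrix; each entry is a subject-unique group id, `NA` where the subject did
not see the image. k-modes minimizes total Hamming mismatch to per-cluster
modes. The missing-value rule is strict: *a missing attribute never matches
anything, including another missing value*. Since each subject sees one
batch, images from different batches share no observed attributes and are
maximally dissimilar — clusters are effectively batch-local, and cross-batch
unification happens through same-name merging.

Two numerical consequences are worth knowing:

* The cost has a floor (every image mismatches all other-batch columns),
  and once every within-batch group is internally pure, moving whole
  batch-local groups between clusters is cost-free. Cluster counts at or
  above the number of batch-local groups are therefore cost-equivalent,
  and the elbow of a multi-batch cost curve can sit below that number.
  The elbow suggestion (`elbow_scan()`, maximal perpendicular distance
  from the chord of the normalized curve) is advisory and meant to be
  overridden; single-batch studies have a zero floor and a sharp elbow.
* Initialization must cover every batch-local group before seeding any
  group twice. The initializer is density-seeded farthest-point
  (Cao-style): densest point first, then maximin distance with density as
  tie-break. A density-times-distance product was evaluated and rejected:
  under the distance floor it double-seeds large local groups and breaks
  zero-noise recovery.

Restarts beyond the deterministic first one use seeded random row
sampling; empty clusters are repaired by reassigning the farthest point;
assignment ties go to the lowest cluster index; mode ties are
lexicographic. All randomness flows from one integer seed and never
disturbs the caller's random stream.

**Text cleaning.** Free-text labels pass through a fixed chain:
lowercasing, ASCII transliteration, removal of non-alphabetic characters,
abbreviation expansion (small default table, user-extensible), whitespace
stripping, dictionary word segmentation (dynamic programming, fewest
pieces), tokenization, retention of nouns/adjectives/prepositions, spell
correction (edit distance at most 2, reduced to 1 for words of four letters
or fewer, where distance 2 overcorrects), and lemmatization (lexicon lookup
plus regular-plural rules and irregular-plural entries). A token whose
lemma is not in the lexicon becomes the sentinel `"unknown"`. The shipped
lexicon is a compact word/part-of-speech/lemma table of ~290 common English
words; study-specific vocabulary is added via `extra_words`.

**Naming and merging.** Each cluster takes the most frequent cleaned label
over all of its images' responses (lexicographic tie-break, logged in the
provenance). Clusters sharing a name are merged — crowds routinely keep two
visually distinct groups apart yet call them the same word, which is
evidence the groups form one named category. Naming reuses the grouping
partition rather than clustering the label matrix separately: grouping and
labeling responses come from the same subjects on the same images and are
dependent, so the correspondence is exact by construction; independent
label clustering is available behind a flag for comparison, and no
cluster-matching heuristic is invented.

**Merge/separation bookkeeping.** With `n[j, i]` the fraction of category
`j`'s images in new category `i`, sources with `n > tau` are recorded; a
category above threshold in several new categories is thereby separated.
`tau` defaults to 0.1 — small enough to keep genuine splits, large enough
to drop single stray images at typical study sizes (1/16 of a category) —
and is configurable. Thresholding edits recorded provenance only; image
membership stays the full cluster, so the new categories always partition
the study's images (conservation is asserted). A cluster with no
above-threshold source is retained with its sub-threshold provenance and
flagged. The prediction map sends each original category to the new
category holding the largest share of its images; any label outside the
study subset maps to `"unknown"`.

## Applying the transform

Truth labels transform image-by-image (the only correct way once
separations exist: an aggregated confusion matrix no longer knows which
images went where, and `transform_cfm()` refuses to guess — it requires
records). Predicted labels transform through the prediction map, with
out-of-subset predictions going to `"unknown"`; human "don't know" answers
and machine off-subset predictions share that sentinel deliberately, as
both are "not one of the study's categories" from the population's side.

Metrics are macro-averaged over classes that occur as true classes: a class
never predicted has precision 0; F1 is 0 where precision + recall is 0; a
predicted-only column (typically `"unknown"`) contributes
misclassifications but is not itself averaged. Macro is the default since
micro-averaged precision/recall/F1 all collapse to accuracy in single-label
classification; micro is available by flag.

## Verification

The null model asks: would *any* transform to the same number of categories
have produced these metrics? `random_crt()` draws an exactly uniform
surjective assignment of images to `n_final` new categories — sampled via
the Stirling-number recurrence (uniform set partition into exactly
`n_final` blocks, then a random block-to-name permutation), since rejection
sampling collapses when `n_final` approaches the image count — and
`null_metric_distribution()` collects the metric distribution over seeded
replicates. The default replicate count is 10,000; the test suite uses 500,
which already pins the 95th percentile well for these smooth metric
distributions. A category-level randomization (whole categories assigned to
new categories) is available as a coarser null.

The observed metric is compared against the null by a one-sample Wilcoxon
signed-rank test: exact enumeration of the positive-rank-sum distribution
for up to 15 nonzero differences (dynamic programming over doubled
midranks, exact under ties), otherwise a normal approximation with
tie-corrected variance and continuity correction; two-sided by default,
since the direction of a real transform's effect is not known a priori.
Label preference uses an exact two-sided binomial test against
indifference per category, and the demography check is a Pearson
chi-squared test of independence (no continuity correction; a warning is
raised when any expected count falls below 1).

## What the simulator emulates — and what it does not

`simulate_study()` generates: a batch-partitioned manifest (seeded category
shuffle, round-robin chunking into `nu_c`-category by `nu_i`-image
batches); a planted image-level partition into perceptual clusters
(whole-category merges via `cluster_map`, image-level splits via `splits`);
grouping responses equal to the planted clusters restricted to each
subject's batch, perturbed by `grouping_noise` (uniform misassignment to
another of the subject's groups); label responses drawn from per-cluster
vocabularies (canonical word plus weighted synonyms) corrupted by typo,
plural and off-topic rates; forced-choice answers from a subject kernel
(correct / same-cluster confusion / "don't know"); and classifier
predictions from an analogous kernel whose remainder goes to out-of-subset
labels. Defaults follow the powered design for a large-scale image-dataset
study: 10 categories, 16 images each, 5x8 tasks, 23 subjects per batch (92
subjects over 4 batches), subject accuracy 0.75 (the expected success
probability used in the population sizing), classifier accuracy 0.7 with
0.1 out-of-subset mass.

The simulator is deliberately the simplest model consistent with the
methodology's assumptions. It does **not** emulate: per-subject reliability
differences (no spammers or experts), correlated errors across images,
image-difficulty heterogeneity, vocabulary drift within a subject,
non-uniform grouping noise, or any perceptual model of why clusters form.
Passing recovery tests therefore shows the pipeline is correct *given* the
assumed response structure; it does not show the assumptions hold for any
particular real crowd.

## Numerical choices

* Root-finding bracket for the chi-squared solver: `[1, 1e9]`, relative
  tolerance `1e-8`; non-bracketed roots raise an error reporting the
  bracket.
* ANOVA sizing walks integer per-group sizes (power is cheap to evaluate);
  all noncentral distributions are evaluated in double precision through
  the standard distribution functions.
* All solver outputs are minimal: power at the returned size meets the
  target and power at 99% of it does not (asserted in tests).
* Degenerate inputs: empty label strings clean to `"unknown"`; an image
  with all-missing grouping attributes still pays full mismatch cost;
  `to_integer()` rejects non-positive block sizes; consensus rejects
  zero-vote images; the signed-rank test rejects all-zero differences.
* Test-suite problem sizes are chosen to exercise each property at the
  smallest scale where it is non-trivial: exhaustive k-modes search on
  10-image instances, signed-rank enumeration at 15 differences,
  binomial enumeration at 23 trials, planted-recovery studies of 6
  categories x 4 images with 8-10 subjects, and 500-replicate nulls. The
  Monte-Carlo power checks run 20,000 replicates per solver at effect
  sizes (h = 0.1-0.2, w = 0.1, f = 0.25) whose solved sizes are large
  enough for the arcsine/noncentral approximations to hold to within the
  99% Monte-Carlo band.

## Known limitations

* The power solvers implement the standard normal/noncentral
  approximations, not exact tests. At small solved sizes (tens of
  observations) the approximations carry a bias of up to about one
  percentage point of power — visible if one simulates the underlying test
  at, say, n around 20-150 — which is a property of the approximations, not
  of the implementation. Exact binomial power is out of scope.
* Multi-batch cost curves are floor-degenerate (see above): the elbow
  suggestion is reliable for single-batch studies and advisory otherwise;
  cross-batch structure is recovered through names, so naming quality
  bounds cross-batch unification quality.
* The lexicon is small and English-only; real free-text crowds need
  study-specific `extra_words`. The cleaning chain has no part-of-speech
  disambiguation (a word's lexicon entry decides).
* Separation fractions are estimated from a single study; with 16 images
  per category the resolution of `n[j, i]` is 1/16, so `tau` below that is
  meaningless.
* The random-transform null randomizes image assignments uniformly;
  alternatives that preserve batch structure are not implemented.
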