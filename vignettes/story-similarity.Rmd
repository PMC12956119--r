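---
title: "Measuring story evolution across retellings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring story evolution across retellings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(storysim)
```

## The problem

In repeated-reproduction designs a participant reads (or hears) a story once
and then recalls it in writing on several consecutive days. The scientific
questions — does recall stabilize, does it drift in a consistent direction,
do independent participants converge on similar retellings — all reduce to
one measurement problem: *how structurally similar are two free-text
tellings of a story?* Hand-coding distortions does not scale and is hard to
replicate, so `storysim` implements an automated measure of story structure,
defined by which events a story contains and in what order, plus the
analysis layers built on top of it.

Throughout, sentences are used as the proxy for events. This is an
approximation: it is adequate for short stories in which each sentence
carries roughly one action, and it is the main assumption a user should
check against their materials.

## The story similarity measure

For two segmented stories $A = (a_1, \dots, a_m)$ and
$B = (b_1, \dots, b_n)$ and a sentence-pair similarity function
$s(\cdot,\cdot) \in [-1, 1]$:

**Content.** Each sentence $a_i$ first receives a within-story threshold
$$\theta_i = \max_{j \neq i} s(a_i, a_j),$$
the most similar $a_i$ can be to a sentence describing a *different*
occurrence of the same story. Sentence $a_i$ is classified *Remembered* in
$B$ if its best cross-story match $\max_j s(a_i, b_j)$ strictly exceeds
$\theta_i$, otherwise *Forgotten*. Directional content similarity is the
fraction of $A$'s events Remembered in $B$; the final content score averages
the $A{\to}B$ and $B{\to}A$ directions, so the measure is symmetric by
construction. It lies in $[0, 1]$.

**Sequence.** Each $a_i$ is mapped to its most similar sentence in $B$ —
with *no* threshold, so every event gets its best available match, and one
target sentence may serve several reference sentences. Directional sequence
similarity is the Spearman rank-order correlation between the reference
positions $1..m$ and the matched positions; the final score averages both
directions and lies in $[-1, 1]$.

**Combined.** The overall story similarity is the product
$\text{content} \times \text{sequence}$, computed from the two symmetrized
components. It ranges from $-1$ (all events retained, order exactly
reversed) through $0$ (no content overlap, or no order information) to $1$
(identical structure).

```{r toy}
A <- c("the cat sat.", "the dog ran.", "birds sing loudly.")
B <- c("the cat sat.", "birds sing loudly.")
story_similarity(A, B, lexical_backend())
```

The middle sentence of `A` is Forgotten in `B`: its best match scores 0.2,
which equals (and therefore does not strictly exceed) its within-story
threshold of 0.2.

### Numerical and edge-case choices

These corner cases are deliberate choices, fixed so that every score is
defined and reproducible:

* *Remembered* requires a **strict** inequality; a best match exactly at
  threshold is Forgotten.
* Best-match ties break to the **lowest target index** — deterministic and
  order-respecting.
* The threshold is **per-sentence** by default. A single global threshold
  (the maximum of the per-sentence ones) is available via
  `threshold_mode = "global"` for sensitivity analysis; the per-sentence
  rule is the default because the threshold's rationale is about what a
  *particular* sentence can share with a different occurrence.
* A single-sentence story has $\theta = 0$ and contributes sequence
  similarity 0 (one position carries no order information). Constant
  matched-position vectors likewise score 0 rather than `NA`.
* Spearman correlations use average ranks on ties; exact rank concordance
  and anti-concordance return exactly $\pm 1$ (guarding against 1-ulp
  floating-point residue, which matters because downstream identities are
  asserted exactly).

## Similarity backends

The matching algorithms only require a symmetric sentence-pair similarity
in $[-1, 1]$ with self-similarity 1. Two interchangeable backends are
provided:

* `lexical_backend()` — the Jaccard index of lowercased alphabetic token
  sets. Fully deterministic and dependency-free; this is the backend used
  by the package's validation suite, where exact expectations are needed.
* `vector_backend(table)` — each sentence is the mean of its in-vocabulary
  word vectors and the pair score is the cosine of the means, the standard
  bag-of-vectors sentence similarity. Vector tables load from the common
  text format (token followed by float components, optional `count dim`
  header) via `load_word_vectors()`.

Sentences with no usable tokens (or out-of-vocabulary sentences under the
vector backend) score 0 against everything — bounded and conservative, and
it keeps thresholds well defined. Because the exact embedding model behind
any published analysis is generally unknown, no numeric parity with
published scores is claimed; the backend contract is what is tested.

## Evolution metrics

For one participant's lineage (stimulus at day 0, retellings on days
1..T), three trajectories of the combined measure:

* **Stabilization** — similarity of each adjacent day pair, starting with
  (Initial, Day 1). Rising values mean the story is settling.
* **Consistency** — similarity of every earlier story to the final
  retelling. Rising values mean evolution in a consistent direction.
* **Modification** — similarity of the stimulus to each retelling. Lower
  values mean more modification of the original.

`cross_reference_series()` compares retellings against an arbitrary
reference story (for instance, the other condition's stimulus, to ask which
structure scrambled-story retellings gravitate toward); with the lineage's
own stimulus it reproduces the modification series exactly.

`group_curves()` aggregates per-participant series into per-condition
mean ± SE curves. For between-condition contrasts the package provides
`condition_permutation_test()`: participant condition labels are shuffled
and a two-sided add-one p-value
$(\#\{|\Delta_{perm}| \ge |\Delta_{obs}|\} + 1)/(n_{perm} + 1)$ is
reported. Inferential machinery beyond this (repeated-measures ANOVA,
corrected pairwise tests) is intentionally out of scope: the long-format
CSV exports feed any dedicated statistics package.

## Dispersion across participants

Convergence *across* minds is measured geometrically:

1. `all_pairs_matrix()` — combined similarity between all stories in the
   pool (per-story representations and thresholds are computed once);
2. `similarity_to_distance()` — $d = 1 - s$, mapping $[-1,1]$ scores to
   $[0,2]$ distances ($d = (1-s)/2$ is available where a $[0,1]$ range is
   preferred; results differ only by scale);
3. `embed_2d()` — multidimensional scaling into a shared 2-D story space.
   Classical (Torgerson) scaling is the default because it is exact for
   Euclidean inputs and fully deterministic; a Sammon-stress refinement is
   available behind `method = "stress"`;
4. `standard_distance_deviation()` — the root-mean-square distance of a
   condition's points from their centroid,
   $SDD = \sqrt{\sum_i \left[(x_i - \bar x)^2 + (y_i - \bar y)^2\right]/N}$.
   Lower SDD = tighter clustering = greater cross-participant convergence;
5. `dispersion_permutation_test()` — the condition difference in SDD
   tested by shuffling condition labels over the fixed embedding
   (two-sided, add-one p-value, default 10,000 permutations).

When several conditions or days are analysed, embed the *whole* story pool
once (stimuli included) and compute SDDs on subsets within that shared
space — this is what the bundled command-line `dispersion` tool does —
rather than re-embedding each subset separately.

## The synthetic corpus generator

Validating a similarity measure on real retellings requires hand ratings;
validating its *mechanics* does not. `generate_corpus()` produces corpora
with the study's structure — two conditions, a shared stimulus, five daily
retellings per participant, chained day-to-day — under a controllable
forward model of recall distortion applied in a fixed order:

1. **Forgetting**: each event dropped with probability `p_forget`
   (redrawn if everything would be dropped);
2. **Reordering**: `n_transpositions` adjacent swaps. With probability
   `convergence` a swap is *attractor-biased* — one bubble-sort step toward
   a condition-level attractor order (a shared schema) — otherwise random.
   Adjacent swaps keep reorder magnitude a single interpretable count;
3. **Paraphrase**: each token substituted with probability `p_paraphrase`
   into a disjoint synonym vocabulary;
4. **Intrusion**: with probability `p_intrude`, one sentence from a
   distractor vocabulary (never Remembered against the stimulus).

A `noise_schedule` multiplies `p_forget` and `n_transpositions` per day;
the default halves each day, which reproduces the canonical empirical
pattern (adjacent-day similarity lowest between the stimulus and Day 1,
then rising; consistency non-decreasing). Default rates
(`p_forget = 0.15`, `n_transpositions = 2`) are round placeholder values
for a moderate forgetter; no quantitative realism is claimed and none is
needed for the properties being tested.

Event vocabularies are synthetic, purely alphabetic, and pairwise disjoint
(a base-16 letter code with reserved prefixes for synonyms and intruders).
Under the lexical backend this makes closed forms exact: if $d$ of $N$
events are dropped and nothing else changes, directional contents are
$(N-d)/N$ and $1$, so averaged content is exactly $1 - d/2N$ — asserted for
every $d$ in the test suite.

What the generator does **not** emulate: real prose, semantic schema
content, paraphrase that a lexical measure would partially credit,
length-dependent segmentation noise, or participants' idiosyncratic styles.
Passing the suite therefore demonstrates the *measure's* correctness and
the pipeline's statistical calibration, not that any particular embedding
backend scores human paraphrase well — that requires human-rating data.

## Validation suite and problem sizes

The package's checks are property-based, at sizes chosen to run on a
single desktop core in a few minutes: exact identity/symmetry/reversal over
500 generated stories; agreement with naive double-loop reference
implementations on 200 random story pairs; exact pure-deletion closed
forms; exact SDD examples and isometry invariance; classical-MDS recovery
of planted 2-D configurations to 1e-6; null calibration of both permutation
tests over 400 simulated corpora (rejection rate at $\alpha = 0.05$ within
[0.03, 0.07], with 199 permutations so the nominal level is attainable
exactly); and Monte-Carlo reproduction of the qualitative stabilization and
convergence patterns (50-participant and 25 + 25-participant corpora).

## Limitations

* Sentence segmentation is rule-based (terminal punctuation with an
  abbreviation list). It is deterministic, which the test suite relies on,
  but will mis-split unusual prose; a model-based splitter can be applied
  upstream and pre-segmented sentences passed to `story()` directly.
* Meta-commentary cleaning removes configured phrases and drops sentences
  left with fewer than `min_content_tokens` (default 2) word tokens; it
  does not correct spelling, which published pipelines have sometimes done
  by hand — autocorrection would add nondeterminism.
* Combined similarity conflates content and order by design; report the
  components alongside it when the distinction matters.
* Scores are not standardized across stories of very different lengths;
  comparisons are meaningful within a design, not across materials.
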