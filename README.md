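# storysim

Automated measurement of how story *structure* — which events a story
contains and in what order — changes across retellings, for
repeated-reproduction (serial recall) and transmission-chain research.

When the same person recalls a story day after day, or many people recall
the same story independently, the interesting quantities are structural:
does recall stabilize, does it drift toward a consistent final form, and do
different minds converge on the same telling? `storysim` answers these with
a fully automated, replicable pipeline instead of hand-coded distortion
counts.

## The measure

Stories are segmented into sentences, which act as a proxy for events. For
stories *A* and *B* and a sentence similarity function *s*:

- **Content similarity** — each sentence *a<sub>i</sub>* of *A* gets a
  within-story threshold θ<sub>i</sub> = max<sub>j≠i</sub>
  *s*(a<sub>i</sub>, a<sub>j</sub>); it is classified **Remembered** in *B*
  when its best cross-story match strictly exceeds θ<sub>i</sub>, else
  **Forgotten**. Directional content = (# Remembered)/|A|, and the final
  score averages both directions. Range [0, 1].
- **Sequence similarity** — each sentence is mapped to its best match (no
  threshold) and the Spearman rank correlation between reference positions
  and matched positions is averaged over both directions. Range [−1, 1].
- **Story similarity** = content × sequence. Range [−1, 1].

On top of the pairwise measure:

- **Evolution metrics** per retelling lineage: *stabilization* (adjacent
  days), *consistency* (similarity to the final retelling), *modification*
  (similarity to the initial story), plus cross-reference comparisons and
  per-condition group curves with permutation contrasts.
- **Dispersion** across participants: all-pairs similarity → distance
  (d = 1 − s) → 2-D multidimensional scaling → Standard Distance Deviation
  SDD = sqrt(Σ[(x−x̄)² + (y−ȳ)²]/N) per condition → permutation test of the
  condition difference.
- **Similarity backends**: deterministic lexical token-overlap (Jaccard)
  and averaged word vectors + cosine (tables load from the standard text
  format); any symmetric sentence similarity in [−1, 1] plugs in.
- **Synthetic corpus generator**: stimulus + chained daily retellings with
  controllable forgetting, adjacent-transposition reordering (optionally
  biased toward a shared attractor order, modeling schema convergence),
  paraphrase, and intrusions — the self-contained test bed for the whole
  pipeline.

## Worked example

```r
library(storysim)
A <- c("the cat sat.", "the dog ran.", "birds sing loudly.")
B <- c("the cat sat.", "birds sing loudly.")
story_similarity(A, B, lexical_backend())
#> <story_similarity a vs b>
#>   content  0.8333  (a->b 0.6667, b->a 1.0000)
#>   sequence 0.9330  (a->b 0.8660, b->a 1.0000)
#>   combined 0.7775
```

Two of A's three sentences are Remembered in B (the middle one's best
match, 0.2, only *ties* its within-story threshold, so it is Forgotten):
content = (2/3 + 2/2)/2 = 5/6. The matched orders correlate at 0.866 and
1.0, so sequence = 0.933, and the combined structural similarity is
5/6 × 0.933 ≈ 0.78.

A full simulated study, end to end:

```r
cfg <- generator_config(n_events = 8, tokens_per_event = 3, p_forget = 0.05,
                        n_transpositions = 3, n_days = 5,
                        noise_schedule = rep(1, 5))
corp <- generate_corpus(cfg, 25,
  conditions = list(convergent = list(convergence = 1),
                    drifting   = list(convergence = 0)),
  seed = 2)

day5 <- lapply(corp, function(l) l$stories[[6]])
pts  <- embed_2d(similarity_to_distance(all_pairs_matrix(day5, lexical_backend())))
dispersion_permutation_test(pts, vapply(day5, `[[`, "", "condition"),
                            n_perm = 999, seed = 2)
#> <dispersion_result> SDD convergent = 0.2814, drifting = 0.4464;
#>   delta = -0.1650, p = 0.005 (999 permutations)
```

Retellings biased toward a shared attractor order end up far more tightly
clustered in story space (lower SDD) than freely drifting ones.

A thin command-line front end over the same functions ships at
`inst/cli/storysim.R` (subcommands `simulate`, `similarity`, `evolve`,
`dispersion`; see the file header for usage).

## Documentation

The methods vignette (`vignettes/story-similarity.Rmd`) documents the
measure's definition and assumptions, every edge-case and numerical
choice, the generator's forward model, and known limitations.
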