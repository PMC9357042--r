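# linger

Quantifying how recently read material **lingers** in spontaneous thought.

## What this package is for

A robust phenomenon in reading research: after finishing a coherent story,
its themes keep intruding into people's thoughts for minutes, while the same
words read as an incoherent scramble fade almost immediately. A clean way to
measure this is **free association**: a participant types whatever words come
to mind, one at a time, for several minutes — once *before* and once *after*
reading. Lingering then shows up as a pre-to-post shift in what the chains
contain.

`linger` implements the full analysis pipeline for such pre/post
free-association designs, for researchers in computational cognitive science
and psycholinguistics:

- **Document classification** — a document-term matrix over all chains of a
  condition (raw counts, then within-participant mean-centering and
  column-SD scaling) is fed to a linear SVM under leave-one-participant-out
  cross-validation with bootstrap repeats. Above-chance accuracy against a
  label-flip permutation null means reading measurably changed the content
  of spontaneous thought.
- **Theme similarity** — each associate with embedding vector *A* is scored
  by its maximal cosine similarity to the story's theme-word vectors
  *B&#8321;…B&#8321;&#8320;*:
  `max_i (A·B_i)/(||A|| ||B_i||)`, averaged per chain. Pre/post contrasts
  give the size of the drift, and 10-associate bins (≈49 s each at the
  typical 4888 ms per associate) give its **time-course** as paired Cohen's
  d with 95% CIs, summarized as a lingering duration in seconds.
- **Word-level bias** — per token, `bias = p(Post) − p(Pre)` over chain
  presence, with odds ratios `p(Post)/p(Pre)` and the standard display
  filter (≥16% prevalence or ≥10% |bias|).
- **Nonparametric effect sizes** — rank-biserial `r_rb = |1 − 2U/(n1·n2)|`
  for Mann-Whitney and ranked `ε² = H(n+1)/(n²−1)` for Kruskal-Wallis,
  plus Pearson r with t.
- **Predicting lingering** — cross-validated backward stepwise regression of
  the self-reported lingering rating (and of the theme-similarity delta) on
  z-scored transportation, comprehension, and condition dummies.
- **A synthetic cohort generator** — cohorts with a known, position-decaying
  theme-injection effect (`δ·exp(−λ(t−1))` at token position *t*),
  correlated self-reports, and clustered toy embeddings, so the whole
  pipeline is testable with exact ground truth and no external data.

## Worked example

Simulate a three-condition study (20 participants per condition here for
speed; the generator defaults to 80) and run every stage:

```r
library(linger)

syn <- synthetic_config(
  n_participants_per_condition = 20,
  conditions = list(intact   = list(delta = 0.40, lambda = 0.05),
                    sentence = list(delta = 0.20, lambda = 0.05),
                    word     = list(delta = 0.05, lambda = 0.05)),
  chain_length_mean = 60, vocab_size_base = 300, seed = 42)

cfg <- run_config(synthetic = syn, n_repeats = 20, n_perm = 100, seed = 42)
report <- run_pipeline(cfg, out_dir = "out")
print(report)
#> <linger_report> seed 42
#>   intact     accuracy 92.2% (p < 0.01); delta +0.1232; 4 sig bin(s)
#>   sentence   accuracy 88.0% (p < 0.01); delta +0.0680; 4 sig bin(s)
#>   word       accuracy 57.2% (p 0.230); delta +0.0072; 1 sig bin(s)
```

Reading the output: in the `intact` condition the classifier tells pre from
post chains 92.2% of the time (chance = 50%), and no permutation null value
reached that accuracy (`p < 0.01` at 100 permutations). Mean theme
similarity rises by +0.123 from pre to post, and the post-minus-pre effect
stays significant for 4 consecutive 10-associate bins (~196 s). The `word`
condition — injection rate 0.05 — is statistically indistinguishable from
chance (p = 0.23), with a near-zero theme delta: the graded-coherence
pattern the injection rates encode.

The condition contrast on self-reported lingering and the stepwise model
are in the same report:

```r
report$lingering_tests$kruskal_wallis[c("H", "epsilon_squared")]
#> $H
#> [1] 42.29...
#> $epsilon_squared
#> [1] 0.72...

print(report$stepwise$lingering)
#> <linger_stepwise> selected {condition_intact}; R^2 = 0.637
```

`run_pipeline(cfg, out_dir = ...)` also writes `report.json`,
`classification.json`, `bias.tsv`, `timecourse.tsv` and `themes.tsv`. The
same pipeline runs on on-disk data (chain TSV, questionnaire CSV, and an
embedding table in the standard text format) via
`run_config(chains_path = ..., questionnaires_path = ...,
embeddings_path = ...)`, and a thin command-line wrapper is installed at
`inst/scripts/run-pipeline.R`.

Individual stages are exported directly: `build_dtm()`, `scale_dtm()`,
`run_classification()`, `permutation_null()`, `select_theme_words()`,
`chain_theme_similarity()`, `timecourse()`, `bias_scores()`,
`mann_whitney()`, `kruskal_wallis()`, `backward_stepwise_cv()`, and the
generator family `synthetic_config()` / `generate_cohort()` /
`generate_word_list()`.

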