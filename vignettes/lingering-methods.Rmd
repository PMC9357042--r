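---
title: "Measuring how reading lingers in free association: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring how reading lingers in free association: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linger)
```

## The problem

After we finish reading, the material does not always leave us: themes and
details of a just-read story can keep resurfacing in spontaneous thought for
minutes. `linger` implements a quantitative pipeline for measuring this
*lingering* from free-association data. The unit of observation is a
**free-association chain**: a participant types whatever words come to mind,
one at a time, for several minutes, once *before* (pre) and once *after*
(post) reading. If the reading lingers, the post chain should drift toward
the story's semantic neighbourhood, and that drift should be detectable,
quantifiable, and time-resolved.

The package provides two complementary objective measures plus the
supporting statistics:

1. **Document classification.** Can a linear classifier tell pre from post
   chains using only which words occur? Above-chance accuracy means the
   reading measurably changed the content of spontaneous thought.
2. **Theme similarity.** How close is each associate, in word-embedding
   space, to the story's central themes? The pre-to-post change in this
   score measures *how much* and, binned over chain position, *for how
   long* the themes linger.

Because the pipeline is meant to be testable without access to any
particular study's data, it ships with a synthetic cohort generator whose
ground truth is known exactly; every stage is validated against it.

## The synthetic cohort model

The generator emulates a between-participant reading study: several
conditions (by default three, labelled `intact`, `sentence`, `word`,
mirroring decreasing narrative coherence of the read material), 80
participants per condition, two chains each of mean length 60, and a mean
production latency of 4888 ms per associate (so a 10-associate bin spans
about 49 s, and a 60-token chain about five minutes).

**Injection model.** Pre-phase chains are i.i.d. draws from a Zipfian base
distribution over a background vocabulary (500 tokens by default). In the
post phase, the token at 1-based position $t$ is drawn from the theme
cluster with probability

$$p_t = \delta\, e^{-\lambda (t-1)},$$

and from the base distribution otherwise. $\delta$ is the condition's
injection rate at the start of the chain and $\lambda$ the per-position
decay. Real time-courses show a decaying effect without committing to a
functional form; the exponential is the simplest monotone choice and gives
a closed-form expected injected-token count,
$\delta (1 - e^{-\lambda L}) / (1 - e^{-\lambda})$ for a length-$L$ chain
(`expected_injected()`), which the tests check against Monte-Carlo
simulation. The defaults $\delta = 0.40/0.20/0.05$ across the three
conditions with $\lambda = 0.05$ (e-folding over ~20 associates, about two
bins) produce the qualitative pattern a graded-coherence study shows:
strong, detectable lingering in the most coherent condition, intermediate
in the middle one, little in the last.

**Individual variability.** Each participant's realized rate $\delta_i$ is
the condition's $\delta$ plus uniform $\pm 0.05$ jitter. A condition with
$\delta = 0$ represents *no effect*, so it gets no jitter: clamping jitter
at zero would otherwise hand half the "null" participants a small positive
injection rate and quietly break every null-calibration property (we found
exactly this while testing — a null cohort classified at up to 59%).

**Self-reports.** The 1-7 lingering rating, the 13-item (1-7)
transportation questionnaire, and the 24-item binary comprehension test are
linear-then-clamped monotone functions of $\delta_i$ plus Gaussian noise.
Only ordinal summaries of such scales are typically analyzed, so any
monotone link suffices; linearity is the documented default. A generator
switch (`lingering_source = "transportation"`) makes the lingering rating
depend on the participant's transportation score alone, so that condition
carries no information beyond transportation — the configuration used to
test whether stepwise selection correctly attributes lingering to
transportation rather than condition.

**Embeddings.** Tokens get toy embeddings: each semantic cluster has a
random unit center, and a token's vector is its center plus isotropic noise
of expected norm $1/\text{concentration}$. Within-cluster cosines then
exceed between-cluster cosines by construction, which is all the
theme-similarity statistic needs. The theme cluster doubles as the pool of
participant-generated "theme words".

**What the generator does not emulate.** Tokens are symbolic (`w0042`,
`theme03`); there is no natural-language plausibility, no morphology, no
part-of-speech structure, no semantic drift within a chain beyond the
injection model, and no relationship between latency and content. Passing
tests therefore show that the *pipeline machinery* is correct and
calibrated — not that any particular real corpus will show an effect.

## Document classification

Chains from one condition are assembled into a document-term matrix: one
row per chain (two per participant), one column per unique token, raw
counts as values. Scaling follows a within-participant two-step: each
column is mean-centered within participant (turning each participant's
pre/post pair into $\pm(\text{post}-\text{pre})/2$), then divided by the
across-chain standard deviation of the centered column. We use the
population (n) convention for that SD; the choice between n and n−1 only
rescales each column by a positive constant, to which the
margin classifier's decision is insensitive. Zero-variance columns (words
with identical pre and post counts for every participant) carry no signal
and are set to zero rather than raising an error.

Classification is leave-one-participant-out: both of a participant's rows
are held out together; a linear soft-margin SVM (hinge loss, L2 penalty,
cost $C = 1$ by default) is trained on the rest and predicts the held-out
pair. The procedure is repeated (500 times at full scale) with the training
participants of every fold resampled with replacement — a participant-level
bootstrap — and the reported accuracy is the mean over repeats. The repeat
machinery is isolated behind `resample = FALSE`, which degenerates to a
single deterministic pass. A score of exactly zero classifies as "pre"; the
tie is arbitrary and documented. Note one deliberate simplification: the
matrix is scaled once, as a whole, not refit within each training fold, so
column scales carry a whiff of the held-out rows. Centering is purely
within-participant, so no label information leaks; the caveat is noted
here.

**Permutation null.** Held-out labels never enter training, so each fold's
predictions are fixed; a null accuracy is obtained by independently
swapping each held-out pair's labels with probability 1/2 and rescoring
(equivalent to, and much cheaper than, retraining per permutation). The
one-sided p-value is the proportion of null accuracies strictly greater
than the observed accuracy; with 500 permutations the smallest reportable
value is $p < 0.002$, flagged rather than reported as zero. Because the
strict-inequality rule is anticonservative when the observed value ties
the null lattice, the observed statistic should be the bootstrap mean (as
in the full procedure), not a single plain pass; the calibration test
demonstrates the difference.

## Theme similarity

Given a set of up to 10 theme words with embedding vectors $B_i$, the theme
similarity of an associate with vector $A$ is

$$\max_i \frac{A \cdot B_i}{\lVert A\rVert\, \lVert B_i\rVert},$$

i.e. the cosine similarity to the *closest* theme. Scores are computed for
every token occurrence (no deduplication) and averaged per chain; tokens
absent from the embedding table are dropped from numerator and denominator
alike, and a chain with no in-vocabulary tokens propagates a flagged
missing value. The statistic is scale-invariant in $A$ and unaffected by
duplicated theme vectors.

Theme words are the $k = 10$ most frequently generated words across
participants' theme-generation responses, after normalization, exclusion
of cue words and proper nouns (which lack the distributional properties of
common nouns), and removal of embedding-OOV tokens; frequency ties break
alphabetically. When scoring a given participant, their own generated
words can be excluded from the count (`leave_out`), so nobody is scored
against themes they personally nominated.

**Time-course.** Chains are cut into consecutive complete bins of 10
associates; partial trailing bins are discarded, and a participant
contributes to bin $k$ only if *both* phases have a complete bin $k$ —
the strictest eligibility rule, chosen so that every bin's contrast is a
genuine within-participant pair. Per bin, the post-minus-pre difference in
bin-mean theme similarity is expressed as a paired Cohen's d with a 95% CI
($d \pm 1.96\sqrt{1/n + d^2/2n}$), uncorrected for multiple bins. Two d
conventions are provided — $d_z$ (mean difference over SD of differences,
default) and $d_{av}$ (mean difference over the average phase SD) — because
printed values in the literature often cannot be traced to a unique
variant; neither is asserted as canonical. The *lingering duration* is the
number of significant bins (total, not necessarily consecutive) times the
bin duration, $10 \times 4888\,\text{ms} \approx 49$ s per bin.

## Bias scores and effect sizes

Word-level bias is presence-based: $p(\text{Post})$ and $p(\text{Pre})$ are
the proportions of post and pre chains *containing* a token (counted once
per chain), bias is their difference, and the odds ratio is their quotient.
Ratios with $p(\text{Pre}) = 0$ are flagged with a lower bound
("$> p(\text{Post}) \cdot N$") rather than smoothed. The display filter
keeps tokens that are prevalent ($\ge 16\%$ of chains) or strongly biased
($|{\rm bias}| \ge 10\%$).

Rank statistics delegate to the standard R tests and add the effect sizes:
rank-biserial $r_{rb} = |1 - 2U/(n_1 n_2)|$ for Mann-Whitney and ranked
$\varepsilon^2 = H(n+1)/(n^2-1)$ for Kruskal-Wallis. Both are invariant
under strictly monotone transforms of the ratings, and both are magnitudes;
the direction is reported alongside.

## Predicting lingering

Transportation and comprehension proportions (each scored as sum over
maximum achievable) are z-scored; condition enters as dummies against the
least-coherent level (a factor cannot be z-scored). Backward stepwise
selection removes, at each size, the predictor whose removal least
increases the residual sum of squares, then 10-fold cross-validation
(seeded participant-level fold assignment) compares the sizes. The selected
size follows the **one-standard-error rule**: the smallest size whose mean
CV RMSE is within one SE of the minimum. Plain min-RMSE selection is
available (`selection = "min"`) but keeps pure-noise predictors a
substantial fraction of the time — with it, noise-exclusion recovery drops
well below the levels the parsimony rule attains, so one-SE is the default.
The selected set is refit on all data by OLS, with coefficients, t
statistics and $R^2$.

## Numerical and procedural choices

- **Normalization**: lowercase, strip surrounding punctuation, collapse
  internal whitespace to a hyphen (multiword entries like "small town"
  become single tokens), drop entries that normalize to empty. No stemming
  or spell correction: the classifier intentionally works on exact matches,
  while theme similarity generalizes across near-synonyms via embeddings.
- **Determinism**: every stochastic stage takes a seed; the pipeline
  derives per-stage seeds by hashing (global seed, stage name)
  (`stage_seed()`), so any stage can be re-run in isolation bit-identically.
- **Degenerate inputs**: zero embedding vectors are rejected at load;
  zero-variance DTM columns become zeros; a paired contrast with identical
  pre and post values reports $d = 0$ with a CI spanning zero rather than
  0/0; an all-tied Kruskal-Wallis reports $H = 0$.
- **Simulation sizes.** The validation suite runs its Monte-Carlo checks at
  deliberately modest sizes chosen once: the null-calibration study uses
  one full-scale cohort (80 participants, 60-token chains, 500-token
  vocabulary) plus 200 reduced replicates (30 participants, 30-token
  chains, 150-token vocabulary, 99 permutations each); the injection-rate
  recovery grid uses 20 seeds of 40-participant cohorts; stepwise recovery
  uses 20 seeds of 90-participant cohorts. These are the package's own
  choices of problem size for its validation experiments.

## Known limitations

- The bootstrap interpretation of the classification "repeats" is one of
  several defensible readings of such a procedure; it is isolated so a
  plain re-run strategy is a one-argument change.
- Whole-matrix scaling (rather than per-fold refitting) is a mild
  train/test contamination of column scales, kept because a single shared
  document-term matrix is the natural formulation; labels never leak.
- The permutation null randomizes only the held-out pair's labels, the
  literal reading of the procedure it mirrors; shuffling all training
  labels would give a different (typically wider) null.
- Synthetic self-reports have a simple monotone-plus-noise structure;
  they cannot validate ordinal-scale pathologies (floor/ceiling clumping,
  response styles) that real questionnaire data may show.
- Real embeddings (e.g. 300-dimensional pretrained tables in the standard
  text format) are supported by the loader but not shipped; all shipped
  fixtures are synthetic and labelled as such.
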