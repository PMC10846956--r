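---
title: "Scoring and validating associative-dissociative retrieval: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and validating associative-dissociative retrieval: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The task and its measures

The associative-dissociative retrieval task (ADT) probes two modes of
semantic memory retrieval with the same verbal stimuli. On a
free-associative (FA) trial the participant types the first related word
that comes to mind; on a dissociative (DA) trial they must produce an
*unrelated* word, which requires suppressing the prepotent associates the
cue activates. Because both conditions share their peripheral stages
(reading, lexical access, response preparation and typing), the latency
difference

$$\mathrm{IC} = \overline{RT}_{DA} - \overline{RT}_{FA}$$

isolates, by the subtraction method, the processing time attributable to
inhibitory control. The package scores these three measures per
participant and parallel form, quantifies their reliability as a function
of test length, characterizes the stimuli through free-association norms
and co-occurrence networks, and computes the construct-validity
statistics relating the measures to auxiliary tasks.

# Preprocessing decisions

Trial screening and filtering follow a fixed, documented order:

1. **Labelling.** Rater-style labels (`rule`, `repetition`, `strategy`)
   take precedence. `auto_screen()` adds the two machine-derivable
   labels: repetitions of a normalized response string within a
   participant x form x block, and runs of three or more successive DA
   responses sharing an initial letter. Normalization is case-folding
   and whitespace trimming only -- diacritics are meaningful in the
   Slovak-like inputs the task was designed around, and no stemming is
   attempted. Semantic-category strategy runs and rule violations are
   semantic judgements that require human raters; only the
   initial-letter heuristic is automated.
2. **Removal order.** `filter_trials()` removes repetitions first, then
   errors (rule + strategy), and only then screens latencies, so the
   moments used by the latency screen are not contaminated by labelled
   errors. The screen removes trials above mean + 3 SD computed per
   participant x form x condition on the surviving trials, one-sided
   (slow tail only): anticipatory fast responses are caught by the error
   labels, not by a symmetric cut. Whether such a screen should be
   global or conditional is genuinely open; the per-participant x
   condition choice respects the large, stable individual differences
   in retrieval speed.
3. **Winsorization.** `winsorize()` uses the order-statistic definition:
   the lowest and highest `k = floor(trim * n)` values are replaced by
   the nearest retained order statistics (default `trim = 0.10` per
   tail). No percentile interpolation is involved, which makes the
   operation exact, idempotent and positional. Note one consequence of
   `floor()`: with fewer than 10 values and `trim = 0.10`, nothing is
   replaced.
4. **Aggregation.** Scores are winsorized means per participant x form x
   condition; `ic = da_mean - fa_mean` holds exactly. The exclusion rule
   (error rate above 30%) uses all of a participant's ADT trials across
   forms as the denominator, with a per-form rate also reported. A
   condition with no surviving trials yields a missing score, never
   zero.

# Reliability

Internal consistency uses McDonald's omega from a single-factor model
fitted by minimum residual to the item covariance matrix (latencies
share a unit, so covariances rather than correlations are the default;
`standardize = TRUE` is available). Uniquenesses that go negative
(Heywood cases) are clamped at a small positive fraction of the item
variance with a warning. Covariances are computed over pairwise-complete
observations so that the scattered missingness produced by trial
filtering does not annihilate the sample.

`sampling_curve()` reproduces the trial-sampling projection of
reliability against test length: for each set size *n* and each of
`reps` repetitions (200 by default, matching the reference procedure), a
random subset of exactly *n* items is drawn per form -- the *same*
subset for every participant within a form and repetition, independent
subsets across forms. This is item sampling, not a participant
bootstrap: it asks how reliable a shorter test *form* would be. Omega is
marked unavailable below three sampled items, where a one-factor model
is not estimable. For parallel items with person variance
$\sigma^2_p$ and residual variance $\sigma^2_e$, the expected retest
correlation of *n*-item form means is the Spearman-Brown form
$\sigma^2_p / (\sigma^2_p + \sigma^2_e/n)$; the test suite verifies the
curve tracks this oracle. Stimulus main effects shift all participants
in a form equally and therefore do not enter this variance ratio when
the same item subset is applied to everyone -- which is exactly the
design implemented.

The Cronbach-Mesbah curve (`cronbach_mesbah()`) runs backward stepwise
item removal, dropping at each step the item whose removal maximizes
alpha of the remainder (ties broken by the lowest column index) and
recording alpha from the full set down to two items. A curve that rises
monotonically toward the full set is the signature of unidimensionality;
an early hump indicates items that pull alpha down.

# Norms and networks

`clean_norms()` fixes the cleaning order: synonyms are mapped to
canonical terms *first*, counts are then recomputed, and responses with
a per-stimulus frequency below 2 are dropped -- so two variants of
frequency 1 that merge to one canonical term of frequency 2 survive.
Entries on an exclusion list (e.g. flagged non-nouns) are marked, not
dropped, because that judgement belongs to a human curator.

Hierarchy statistics per stimulus: proportional dominance
$f_1/\sum_i f_i$ over *all* associations; the frequency-decrease slope
from an OLS regression of the top-10 frequencies on ranks 1..10; and the
frequency intercept defined as the *mean* frequency of those top-10
responses.

Edge weights use LogDice,

$$14 + \log_2 \frac{2 f_{xy}}{f_x + f_y},$$

with $f_x$, $f_y$ the marginal response frequencies *within that
stimulus's norms* (the natural reference corpus for a per-stimulus
network) and $f_{xy}$ the number of respondents whose four-association
sequence contained both responses -- each unordered pair counted once
per respondent, with no ordering or chaining weight. LogDice is bounded
above by 14 and zero co-occurrence yields no edge.

Path-based metrics run on the positive-weight subgraph with edge
distance 1/weight after normalizing weights by the strongest edge, so a
hop along the strongest collocation has distance 1, the measures are
invariant to the weight scale, and global efficiency lands in [0, 1]. A
`max_minus` distance transform is available behind a flag. Average
shortest path length is computed over connected pairs with the
disconnected fraction reported separately (a convention choice --
alternatives silently mix scales); efficiency gives disconnected pairs
their natural contribution of 0. The weighted global clustering
coefficient is the Onnela construction (geometric mean of normalized
triangle weights), with a binary option. Louvain modularity is
stochastic, so the partition is the best of 10 seeded restarts at
resolution 1.0, ties broken by first encounter; with the seed fixed,
repeated calls are identical.

# Composites and validity statistics

Component retention uses parallel analysis: eigenvalues of the sample
correlation matrix against the 95th percentile of eigenvalues from 500
simulated standard-normal datasets of the same shape, retaining the
leading run of exceedances. Multi-component solutions are rotated
obliquely with the quartimin (oblimin) criterion via the standard
gradient-projection algorithm, and standardized composite scores are
produced from the pattern matrix by regression so each score captures
the unique variance of its component. PCA signs are arbitrary, so each
component is reflected to make its largest-magnitude loading positive.

Paired contrasts are two-sided paired t-tests with the repeated-measures
effect size $d = t/\sqrt{n} = t/\sqrt{df+1}$; multiple contrasts are
Holm-adjusted (`stats::p.adjust`). For comparing two correlations that
share a variable in one sample (e.g. r(FA, fluency) versus
r(DA, fluency)), the dependent-overlapping (Steiger-type) Fisher-Z test
is recommended and is the default in `compare_correlations()`; it needs
the correlation between the two non-shared variables. The
independent-samples Fisher test is provided for between-sample use. The
confidence interval for the difference uses the Zou back-transformed
construction in both cases, which respects the asymmetry of the
correlation scale near its bounds. Full mixed-effects estimation of
stimulus effects is deliberately out of scope: `stimulus_level_table()`
produces the stimulus-aggregated correlations and emits a long-format
design table that any general mixed-model routine can consume.

# The synthetic-data generator

Every stage is exercised on data from a seeded generator whose defaults
are the study conditions the package targets: 3 parallel forms x 40
stimuli x 2 blocks (20 FA + 20 DA per block, conditions swapped across
blocks and counterbalanced over stimuli), around 100 participants, and
90 norm respondents contributing 4 distinct associations per stimulus
(about 360 tokens, the scale of the reference norms).

Latencies are lognormal -- positive by construction with the right skew
latency data show; the reference descriptives report means and SDs only,
so the distributional family and the variance decomposition are the
generator's own choices. On the log-seconds scale:

$$\log RT = \mu_{FA} + a_p + b_s + \beta_{typFA}\,T_s\,[FA] +
(\gamma_{DA} + d_p + \beta_{typIC}\,T_s)\,[DA] + \varepsilon$$

with independent zero-mean normal person speed ($\sigma_p = 0.20$),
person inhibition ($\sigma_d = 0.15$), stimulus ($\sigma_s = 0.10$) and
residual ($\sigma_\varepsilon = 0.35$) effects. The intercepts
($\mu_{FA} = 1.123$, $\gamma_{DA} = 0.555$) are calibrated once so the
grand means land near 3.35 s (FA) and 5.90 s (DA), the published scale
for young adults; the typicality slopes default to $-0.18$ (FA) and
$+0.15$ (DA-specific), echoing the reported directions: typical cues
speed associative retrieval and raise the inhibition cost. Error labels
are drawn per trial at the reported marginal rates (rule violations
2.05% FA / 4.45% DA, repetitions 3%, strategy 1.83% DA-only), mutually
exclusive in the priority order rule > repetition > strategy -- the
reference reports only marginal rates, so the joint structure is a
documented invention.

Association norms draw from a per-stimulus vocabulary of 50 opaque
tokens with Zipf-decaying pick probabilities (exponent 1.1) partitioned
into 2 clusters; after the first pick, each subsequent association stays
in the cluster of the previous one with probability 0.7. This yields
the two features the analysis consumes -- a dominance hierarchy and
clustered co-occurrence -- without any linguistic realism: tokens are
IDs, and none of the semantic judgement steps (synonym discovery,
non-noun detection) can be exercised beyond their mechanical interfaces.
Passing tests therefore show that the *pipeline arithmetic* is right
under a plausible generative model, not that the model captures real
response behaviour; with real data, rater labels, synonym maps and
curated exclusions replace the simulated ones.

All randomness flows from one integer seed through a fixed splitting
scheme (large-prime stepping into the 32-bit seed space), so every
artifact is bit-reproducible; the pipeline driver refuses to overwrite a
non-empty output directory.

# Problem sizes and numerical choices

The test suite and the bundled acceptance script run the study-scale
configuration (100 participants, 3 forms, 90 respondents) with the
trial-sampling curves at 50 repetitions -- an accuracy/runtime balance
chosen once for routine verification; the 200-repetition default
remains for analyses, and per-set-size means at 50 repetitions already
agree across seeds to about 0.01. Parallel analysis keeps its 500
simulated datasets everywhere. The minimum-residual omega fit uses an
analytic-gradient BFGS with a tight relative tolerance (1e-10);
degenerate inputs (zero variance, fewer than 3 items, constant
variables, singular correlation matrices) are rejected with explicit
errors rather than propagated as NaN.

# Known limitations

- Rule-violation and semantic-category strategy errors cannot be derived
  from text alone; the auto-screen covers only repetitions and
  initial-letter runs.
- Omega assumes a single factor per form; no hierarchical or
  multi-factor omega is provided.
- The LogDice marginals are per-stimulus by design; whole-norms
  marginals are a documented alternative flag, and the choice matters
  for responses shared across stimuli.
- The dependent-correlation test needs the inter-predictor correlation;
  when only published correlations are available without it, the
  independent-samples form is the fallback, with its known conservatism
  for overlapping designs.
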