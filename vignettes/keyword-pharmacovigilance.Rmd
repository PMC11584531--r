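---
title: "Differential word-frequency analysis for social-media pharmacovigilance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential word-frequency analysis for social-media pharmacovigilance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmakeyword)
```

## The problem

Clinical trials under-detect adverse events that only surface in broader,
more heterogeneous real-world populations. Patients, however, discuss their
medication experiences at length on anonymous forums. `pharmakeyword`
implements a corpus-comparison approach to mining such discussions: posts
mentioning a drug (by brand or generic name) form that drug's *corpus*;
each post is a *text*; and words whose frequency is significantly elevated
in one corpus relative to a comparison corpus are flagged as candidate
keywords — some of which turn out to name adverse events ("appetite",
"constipation", "dizziness"), to be adjudicated downstream by humans or an
explicit highlight dictionary. The package never labels a word as an
adverse event by itself.

## The statistical procedure

For a word $q$, corpora $S$ and $T$, the test compares mean frequencies
$\bar{x}_1, \bar{x}_2$ of $q$ with a one-tailed Welch $t$ statistic

$$ t = \frac{\bar{x}_1 - \bar{x}_2}
            {\sqrt{v_1 / n_1 + v_2 / n_2}}. $$

Two sampling-unit conventions are provided (`test_config(mode = )`):

* **token mode** (default): every token position is a Bernoulli trial for
  $q$, so $n_i$ is the corpus token total, $\bar{x}_i = c_i / n_i$ for
  word count $c_i$, and $v_i = \bar{x}_i (1 - \bar{x}_i)$ is the exact
  population variance of the 0/1 indicator vector. This matches the
  notation in which the method was originally stated.
* **text mode**: posts are the sampling units; $\bar x_i$ and the unbiased
  sample variance are taken over per-text relative frequencies and $n_i$
  is the number of texts. This is the convention recommended in the
  corpus-comparison literature to guard against *burstiness* — a word
  occurring many times inside a few texts can inflate token-mode
  significance while text mode correctly discounts it.

The p-value is the upper-tail probability at $t$ under the
Welch–Satterthwaite degrees of freedom. It is used for ranking and for
Benjamini–Hochberg retention only; the *significance* decision is the
literal rule $t > 1.73$ (`t_threshold`), kept as a configurable constant
because the procedure being replicated printed that threshold (for large
degrees of freedom the one-tailed 5% critical value would be 1.645; 1.73
corresponds to roughly 19 degrees of freedom). Degenerate cases are fixed
by convention: if both variance estimates are zero, $t = 0$ when the means
agree and $\pm\infty$ otherwise; $t = 0$ reports $p = 0.5$.

### Multiple testing

Significant words are ranked by ascending p-value (ties broken by
descending $t$, then alphabetically, for deterministic output) and the
Benjamini–Hochberg step-up rule retains ranks $1..k$ where
$k = \max\{i : p_{(i)} \le i\,q/m\}$. Two scopes exist
(`test_config(bh_scope = )`):

* `"significant_only"` (default) replicates the two-stage procedure this
  package reimplements: BH runs over the pre-selected significant words,
  with $m$ equal to their number. Note a structural property of this
  rule: the largest significant p-value is at most
  $P(t > 1.73) \approx 0.042 < q = 0.05 = m\,q/m$, so the last rank
  essentially always passes and the step-up rule retains the whole
  significant list. The default therefore reproduces the replicated
  behaviour faithfully but provides almost no additional filtering.
* `"all_words"` is the statistically standard alternative: BH runs over
  the full tested vocabulary, and retention then has its usual
  false-discovery interpretation. The package's null-calibration tests
  use this scope, since under the two-stage default an empty retained
  list is structurally impossible whenever any word crosses the
  threshold.

## Text processing

Posts are normalized by joining title and body with a single space and
lowercasing (joining first prevents boundary artifacts that fuse the last
title word to the first body word). The tokenizer splits on maximal runs
of non-letter characters — digits, punctuation, apostrophes and other
symbols all *separate* tokens rather than being stripped — and keeps
tokens of at least 3 letters (`min_chars`). There is no stemming,
stop-word removal or spelling correction: the analysis operates on raw
surface forms, which is why e.g. "taste" and "tastes" can both be
reported.

Drug-mention matching is whole-token, with one deliberate asymmetry: the
match boundary is a maximal *alphanumeric* run, stricter than the
tokenizer's letter runs, so a name fused to a dose ("topamax50") does not
register as a mention. At corpus scale the loss is negligible and the
alternative (counting "topamax50" as a mention while the tokenizer sees
the post's token as "topamax") was judged more surprising.

## Corpus assembly and controls

`build_corpora()` assigns every post mentioning a drug's synonyms to that
drug's corpus (a post mentioning two study drugs is in both; pairwise
comparisons later drop shared posts via `remove_shared()`). The control
pool contains posts mentioning no study drug *and* no CGRP-class
therapeutic from the lexicon — the shipped default lexicon flags all four
CGRP monoclonal antibodies (erenumab, fremanezumab, galcanezumab,
eptinezumab), the latter two existing only for this exclusion; the set is
user-overridable since reasonable designs could exclude more or fewer.
`partition_controls()` mimics assigning each control post an independent
uniform digit in $1..k$ ($k=4$ by default), so group sizes are
multinomial, not balanced. The partition seed is recorded in the study
output; one partition is drawn per study so validation and application
comparisons share control assignments.

## The synthetic-data generator

Because the original forum extract is not redistributable, the package
ships a seeded generator (`generate_posts()`) that emulates the features
the analysis actually consumes:

* a Zipf background vocabulary (`vocab_size = 5000`,
  `zipf_exponent = 1.05` — a typical fitted exponent for forum-scale
  English, with a vocabulary large enough to exercise the rare-word tail
  without dominating runtime);
* negative-binomial post lengths (`post_length_mean = 50`,
  `post_length_dispersion = 1.2`, floored at 3 tokens — short,
  strongly overdispersed posts, matching the token counts a 3-letter
  filter leaves of typical forum submissions);
* independent per-post drug mentions at configured prevalences, with one
  randomly chosen synonym inserted at a random token position per
  mentioned drug;
* planted signals: inside posts mentioning a given drug, a chosen word's
  per-token rate is multiplied by `rate_ratio`. Novel planted words enter
  the vocabulary at the Zipf probability of `base_rank = 300` — a
  moderately common word, about where genuine symptom vocabulary sits in
  forum text;
* timestamps uniform over 2010–2020, matching the decade the pipeline's
  date filter targets.

The preset `synth_config_paper_like()` fixes `n_posts = 22467` and
prevalences 0.0179/0.0633/0.0208/0.0032 for
propranolol/topiramate/erenumab/fremanezumab, reproducing the corpus-size
structure of the study design — including the small (~73-post)
fremanezumab corpus whose low power the test suite demonstrates.

What the generator does **not** emulate: topical structure, semantics, or
correlated vocabulary (every non-planted word is exchangeable); user
identity and posting dynamics; time trends (e.g. a drug approved
mid-decade); comment threads; misspellings beyond those baked into the
lexicon. By default it also has no burstiness — each token is an
independent draw — which is exactly the regime where token-mode variance
is correct. A Dirichlet-multinomial option (`burstiness = ` finite
concentration) lets users stress the token-vs-text mode difference, but
passing tests on the default generator say nothing about robustness to
real bursty text; analysts of real data should compare both modes.

## Calibration and power, as verified by the test suite

The test suite runs the whole pipeline at study scale (22,467 posts per
run) and checks, among others:

* **oracle equivalence** — token-mode $t$ equals a brute-force
  computation that materializes the 0/1 indicator vectors, to $10^{-12}$;
* **null calibration** — comparing two control groups of the same
  generated collection (i.i.d. draws from one distribution), the
  `all_words` retained list is empty in at least 95% of 200 seeded runs,
  and the pre-BH fraction of words with $t > 1.73$ stays below 0.07
  (the one-tailed nominal rate is ~0.042; rare-word discreteness keeps
  the average below the bound). A drug-vs-control comparison is *not* a
  null even at rate ratio 1: the drug's own synonyms appear only in the
  drug corpus and are correctly retained;
* **power** — a rate-ratio-8 signal planted in the 6.33%-prevalence drug
  corpus is recovered with recall at least 0.9 over 100 seeds; recall is
  non-decreasing in rate ratio over 1, 2, 4, 8 (50 seeds each); and at a
  fixed rate ratio, recall in the ~73-post corpus is strictly below the
  ~468-post corpus, reproducing the qualitative small-corpus null result
  the design is known for;
* **determinism** — two runs with identical inputs and seed produce
  byte-identical TSV outputs (fixed `%.10g` numeric formatting; no
  wall-clock metadata in outputs).

These problem sizes (200/100/50 seeds at full study scale) were chosen so
the Monte-Carlo estimates are tight enough for the stated bounds while the
suite stays comfortably runnable on a laptop.

## Known limitations

* The default two-stage BH scope retains nearly every significant word by
  construction (see above); treat the default keyword lists as "ranked
  significant words", and use `bh_scope = "all_words"` when actual FDR
  control is wanted.
* Token mode is anti-conservative for bursty words; text mode is the
  robust choice for real data.
* One symptom spread over many near-synonyms ("dizzy", "dizziness",
  "lightheaded") dilutes power; an optional pooling map
  (`study_plan(pooling_map = )`) can merge surface forms but is off by
  default.
* No negation handling: "never took topamax" counts as a mention.
* Welch's test on sparse counts is approximate; words with total count
  below ~4 cannot reach the significance threshold in token mode, which
  acts as an implicit frequency floor.
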