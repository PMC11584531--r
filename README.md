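# pharmakeyword

Keyword-level pharmacovigilance for social-media post collections.

Clinical trials under-detect adverse events that only appear in broader
real-world populations, while patients discuss their medication
experiences freely on anonymous forums. `pharmakeyword` implements the
corpus-comparison approach to mining those discussions: all posts
mentioning a drug (by brand or generic name) form the drug's *corpus*,
and per-word one-tailed Welch t-tests against a comparison corpus flag
words that are significantly more frequent — candidate adverse-event
keywords for human review. It is aimed at pharmacoepidemiologists and
computational-linguistics researchers who want a reproducible, seeded,
tested version of this pipeline.

## The statistic

For word *q* in corpora *S* and *T*,

    t = (x̄₁ − x̄₂) / sqrt(v₁/n₁ + v₂/n₂)

where, in the default **token mode**, n·i· is the corpus token total,
x̄ᵢ = cᵢ/nᵢ is the word's mean frequency and vᵢ = x̄ᵢ(1 − x̄ᵢ) the
Bernoulli indicator variance (a **text mode** using per-post relative
frequencies, robust to burstiness, is also provided). Words with
t > 1.73 (one-tailed) are significant; significant words are ranked by
p-value and the Benjamini–Hochberg step-up rule decides retention.
Pairwise drug comparisons first drop posts shared by both corpora;
control corpora are random partitions of the posts mentioning no study
drug and no CGRP therapeutic. See the methods vignette
(`vignettes/keyword-pharmacovigilance.Rmd`) for the full model,
parameter defaults and design discussion — including why the replicated
two-stage BH scope retains nearly every significant word and when to
prefer `bh_scope = "all_words"`.

## Worked example

The package ships a seeded synthetic-corpus generator emulating a decade
of migraine-forum posts (Zipf background vocabulary, negative-binomial
post lengths, configured drug-mention prevalences, planted signal
words), so the full pipeline can be exercised without the original forum
data:

```r
library(pharmakeyword)

cfg <- synth_config_paper_like(
  seed = 42,
  planted_signals = list(
    list(drug = "topiramate", word = "appetite",     rate_ratio = 8),
    list(drug = "erenumab",   word = "constipation", rate_ratio = 8)))
posts <- generate_posts(cfg)

study <- run_study(posts, plan = study_plan(seed = 42))
study
#> <keyword_study> 22467 posts, 6 comparison(s)
#> corpus summary:
#>          drug count percent
#>    topiramate  1445    6.43
#>   propranolol   418    1.86
#>      erenumab   467    2.08
#>  fremanezumab    68    0.30
#>   topiramate_vs_propranolol    4713 tested, 829 significant, 829 retained
#>   propranolol_vs_group1        5005 tested, 30 significant, 30 retained
#>   topiramate_vs_group2         5005 tested, 94 significant, 94 retained
#>   erenumab_vs_group3           5005 tested, 23 significant, 23 retained
#>   fremanezumab_vs_group4       5002 tested, 5 significant, 5 retained
#>   erenumab_vs_fremanezumab     3314 tested, 550 significant, 550 retained
```

The per-drug counts land at the configured prevalences (e.g. 467 ≈ 2.08%
erenumab posts of 22,467). Inside one comparison, the top-ranked words
are the drug's own synonyms — which only occur in the drug corpus —
followed by the planted adverse-event word:

```r
res <- study$results$erenumab_vs_group3
head(res$table[, c("word", "count1", "count2", "t", "p", "retained")], 3)
#>           word count1 count2         t            p retained
#> 1     erenumab    235      0 15.404001 1.370462e-53     TRUE
#> 2      aimovig    232      0 15.304413 6.271389e-53     TRUE
#> 3 constipation     65     87  6.978895 1.524620e-12     TRUE

score_recovery(res, "constipation")
#> <recovery_metrics> recall 1.000, precision 0.043, false-flag rate 0.004396 (1 planted, 23 retained)
```

`recall 1.000` means the planted signal was retained; the low precision
is expected, since retained lists also contain drug synonyms and generic
treatment vocabulary — the same reason the method's real outputs require
human adjudication (supply `study_plan(highlight_terms = )` to flag a
curated term list in reports).

Real data enter through `load_posts()` (Pushshift-style JSON-lines or
CSV), `filter_by_date()`, and a user lexicon (`read_lexicon()`); a thin
CLI wraps the same functions:

```sh
inst/scripts/pharmakeyword simulate --seed 7 --out posts.jsonl
inst/scripts/pharmakeyword run --posts posts.jsonl --seed 17 --outdir out/
```

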