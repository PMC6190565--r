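---
title: "Quantifying what a short food questionnaire misses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying what a short food questionnaire misses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietmap)
```

## The problem

A multi-day weighed food diary records every eating occasion of a subject —
food code, name, description, cooking method, and the weighed amount in
grams — against a catalogue of ~1,600 food codes organised in ~77 food
groups. A short food questionnaire (SFQ), as used in large cohort surveys,
records only whether a small set of food groups (here 15, split into
"healthy" and "unhealthy") was consumed in the previous 24 hours, with no
portion sizes. Validating the screener against the diary requires a *food
code → SFQ group* mapping: only then can one ask which fraction of real,
habitual consumption the questionnaire has no question for.

`dietmap` implements that mapping, the construction of the augmented
consumption database, the coverage statistics, and the inferential
machinery, together with a synthetic-data generator that stands in for the
access-restricted survey microdata.

## The mapping protocol

Each catalogue entry is assigned a verdict — `covered`, `partial` (with a
coverage fraction in (0,1)), or `non_covered` — by four steps applied
strictly in order; the first match wins and later steps are never consulted:

1. **Exact name match.** The normalized food name equals a group label or an
   include-keyword phrase. Normalization lowercases, replaces all
   punctuation by spaces, tokenizes, and removes caller-supplied stopwords
   (none by default: dropping words silently is a decision the analyst
   should make explicitly).
2. **Exact description match.** Same comparison for the food description.
3. **Fuzzy match.** Normalized Levenshtein similarity
   $\mathrm{sim}(a,b) = 1 - \mathrm{lev}(a', b') / \max(|a'|, |b'|)$ on the
   normalized strings, against every label and include phrase. The best
   candidate is accepted when $\mathrm{sim} \ge$ `fuzzy_threshold`; ties go
   to the higher similarity, then to the group listed first in the SFQ
   definition (reproducibility requires a total order).
4. **Token search.** Each token of the name, then of the description (with
   cooking-method text appended), is looked up in the groups'
   include-keyword tokens, scanning groups in definition order; a group is
   blocked whenever *any* input token sits in its exclude keywords. The
   exclude mechanism is what keeps "fruit juices" out of the fresh-fruit
   group while plain "fruit" maps there.

Matches produced by the fuzzy or token step carry `needs_review = TRUE`: the
original protocol had each automated step verified by a human annotator, and
the flag is the scriptable stand-in for that verification. A separate
manual-override channel (`match_step = "manual"`) models the final
nutritionist check; `compare_mappings()` reports code-level discordance
between two independently produced tables, the repeatability statistic of
the protocol.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `fuzzy_threshold` | 0.85 | minimum similarity for a fuzzy match; one typo in a ≥7-character label still passes (`1 − 1/7 ≈ 0.857`), unrelated labels do not |
| `review_band` | [0.85, 0.95] | fuzzy similarities additionally flagged for review |
| `use_fuzzy` | `TRUE` | ablation switch for the fuzzy step |
| `stopwords` | none | tokens dropped during normalization |

The threshold and band are design choices of this package: the source
protocol relied on human judgment at the fuzzy step and published no
numeric threshold. Two conventions are worth stating: the similarity of two
empty strings is defined as 1 (they are indistinguishable), and empty
against non-empty as 0.

### Partial coverage

Some catalogue groups map only at sub-code granularity ("other fruit" was
the canonical example: part of the group has a questionnaire home, part has
none). `assign_partial_fraction()` reports the group's non-covered share in
both plausible readings — count-based over member codes, and
consumption-weighted over diary occasions — because the source analysis did
not state which denominator produced its ~63% figure; both are exposed and
labelled. Codes explicitly declared "mixed" can be stamped with the uniform
group fraction, becoming `partial` verdicts.

## Coverage statistics

Augmentation joins each diary row with its code's verdict; each eating
occasion then carries a covered weight $f$ (its code's coverage fraction)
and a non-covered weight $1-f$, which sum to 1 exactly. For subject $i$ on
day $d$:

$$\text{freq ratio}_{id} = \frac{\sum_j (1-f_j)}{n_{id}}, \qquad
  \text{amount ratio}_{id} = \frac{\sum_j a_j (1-f_j)}{\sum_j a_j},$$

with $a_j$ the grams of occasion $j$. Days are treated as independent,
matching the source analysis. A zero-intake day leaves the amount ratio
undefined; the record is kept, flagged, excluded from amount-ratio
aggregation, and tallied. Note that averaging the per-subject-day ratios is
*not* the same statistic as pooling all occasions before dividing; the
per-day average is the primary definition here and the pooled variant is
exported separately (`pooled_noncovered_fractions()`).

Mean daily intake of a group is the subject's 4-day total divided by the
number of survey days (absent days count 0), averaged across subjects.
The per-group report pairs eating-occasion counts with mean daily amounts
among *consumers* of the group — chosen because a count/amount table is
most naturally read per consumer — with the all-subjects denominator
available as an option.

## Densities and day-of-week tests

Ratios live on $[0,1]$, so a plain Gaussian KDE would leak mass past both
boundaries. `ratio_density()` uses boundary reflection: kernels are mirrored
at 0 and 1, giving a non-negative estimate whose trapezoid integral over the
unit interval is 1 within $10^{-3}$ for any bandwidth small relative to the
support (Silverman's rule by default).

`day_of_week_tests()` interprets the day-of-week comparison as
leave-one-day-out: each weekday's subject-day ratios against all other
weekdays pooled, with a two-sided Wilcoxon rank-sum test. The phrasing of
the source analysis ("omitted 1 day from each test while retaining all the
others") is ambiguous between this reading and all pairwise comparisons; the
day-vs-rest reading is the default and a pairwise variant sits behind the
`pairwise` flag. Raw p-values at $\alpha = 0.01$ are the primary output, to
mirror the source analysis, with Holm-adjusted values emitted alongside.

The rank-sum test itself uses mid-ranks for ties and the rank sum $W$ of the
first sample, with two-sidedness measured by $|W - n(N{+}1)/2|$:

* **exact** mode enumerates all $\binom{n+m}{n}$ assignments (capped at
  $10^5$ by default), giving a rational p-value;
* **permutation** mode draws `n_perm` (default 9,999) label shuffles and
  uses the add-one estimator $p = (1 + \#\,\text{extreme})/(1 + n_{perm})$,
  which is never exactly zero; seeds are mandatory in the pipeline
  configuration and per-weekday seeds derive from the single run seed;
* **normal** mode applies the tie-corrected normal approximation with a 0.5
  continuity correction, useful for large simulation studies.

## The synthetic-data generator

The source microdata (a national preschool nutrition survey and a national
infant-cohort questionnaire) are access-restricted, so the generator
reproduces their published *structure* and plants a known truth:

* 1,652 food codes in 77 catalogue groups; 15 questionnaire groups with the
  published labels and polarity split (8 healthy, 7 unhealthy);
* 126 subjects × 4 diary days; with the weekend guarantee on (the source
  survey required a weekend day), each subject's consecutive 4-day window
  contains Saturday or Sunday, and all seven weekdays occur sample-wide;
* eating-occasion counts per subject-day are negative binomial (mean 12,
  size 8) — overdispersed counts are typical of diary data, and ~12 diary
  entries a day is realistic for a weighed preschool record that counts
  every item of a meal separately;
* a truly non-covered food is drawn with design probability
  `target_noncov_freq` (default 0.44); non-covered groups are weighted by
  the published eating-occasion counts of the most commonly consumed
  non-covered items, whose per-group amount means/SDs also parameterise the
  amount model;
* amounts are lognormal, moment-matched to the configured per-occasion
  (mean, SD) — only means and SDs are published, and lognormality enforces
  positivity; mappable groups use typical preschool portion sizes (e.g.
  ~150 g for milk, ~20 g for sweets) chosen once as a design decision;
* mappable code names are built from the target group's include phrases,
  half as the bare phrase (exactly matchable) and half with a neutral
  qualifier word (token-matchable); `typo_rate` applies one
  substitution/deletion per affected name, the minimal perturbation that
  exercises the fuzzy step. Non-covered names come from a disjoint
  vocabulary.

The bundled questionnaire fixture's keyword sets are curated so the
token-scan resolves unambiguously (e.g. the hamburger/hot-dog group excludes
"chips" and "fries"; the diet and non-diet drinks groups have disjoint
tokens). Real instruments are messier; with real data the review flags and
the override channel are expected to carry more weight.

**What passing tests show — and what they do not.** On generator output with
`typo_rate = 0`, mapping accuracy against the planted truth is exactly 100%
and the pipeline's coverage ratios equal the ground-truth ratios
identically; with typos, accuracy degrades and the fuzzy step recovers part
of it. This validates the *machinery* — conservation, determinism, recovery
of designed quantities at study scale. It does not certify performance on
real survey text, whose misspellings, brand names and compound descriptions
are richer than the single-typo family simulated here; the human-review
flags exist precisely because of that gap.

## Numerical and degenerate-input conventions

* Quartiles use linear interpolation (R quantile type 7); SDs use the n−1
  denominator; `sem = sd/√n`; a single observation yields `NA` for both.
* Coverage weights satisfy `covered + non-covered = 1` exactly in floating
  point (fractions of 0 and 1 dominate; Sterbenz's lemma covers fractions
  above one half).
* Readers never drop rows silently: rows in = rows out + rows reported, and
  a diary code missing from the mapping table aborts the merge by default
  (`force = TRUE` downgrades it to a warning plus an explicit `non_covered`
  classification).
* All randomness in a pipeline run derives from one configuration seed;
  stage seeds are fixed offsets of it, and rerunning a resolved
  configuration reproduces every CSV byte for byte.

## Problem sizes used in validation

The shipped validation suite exercises the full study scale where the claim
depends on it — catalogue recovery on all 1,652 codes, coverage recovery on
126 × 4 subject-days at design probabilities 0.2, 0.44 and 0.7, test
calibration on 500 simulated null datasets of 504 subject-days and power on
100 seeds with a one-SD Friday shift — and smaller generated studies
(~120 codes, 15 subjects) for the structural and round-trip properties,
where scale adds nothing to the assertion.

## Known limitations

* The mapping operates on one language and one catalogue convention; no
  multilingual or nutrient-composition matching is attempted.
* Partial-coverage fractions at sub-code granularity depend on overrides
  (or the group-level stamping operation); the algorithm itself only emits
  fully covered or non-covered verdicts.
* Within-subject correlation across days is deliberately ignored (days are
  treated as independent, as in the source analysis); no usual-intake /
  measurement-error deattenuation is provided.
* The generator does not simulate under-reporting, social-desirability bias
  or nutrient composition.
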