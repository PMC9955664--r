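---
title: "Determining and validating mode of HIV acquisition with mohatree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining and validating mode of HIV acquisition with mohatree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mohatree)
```

## The problem

Adolescents living with HIV acquired the virus either **vertically**
(parent-to-child, in utero, perinatally, or through breastfeeding) or
**sexually**. The two groups reach care through different doors, at different
ages, with different treatment histories and support needs — but in settings
with fragmented, paper-based medical records, acquisition mode is almost
never documented. The pragmatic proxy is an age cutoff on ART initiation:
initiation before age 10 (sometimes 15) is read as vertical, later as
sexual. That proxy had not been validated against anything stronger.

`mohatree` implements a two-part remedy:

1. a **logic tree** that builds a reference-standard MOHA label from
   self-reported sexual, family, and treatment history collected over
   longitudinal survey waves, and
2. **diagnostic validation** of the age-cutoff classifiers (ages 10–15)
   against that reference: sensitivity, specificity, predictive values, and
   the ROC AUC of a single-threshold test.

## Data model and harmonization

Input is long format: one row per participant-wave of raw self-reports
(`read_cohort()`; see `moha_columns()` for the dictionary), plus an optional
medical-record table with abstracted ART-initiation ages. Missing cells stay
missing — a factor never observed is **unobserved**, not false-as-evidence;
the tree treats it as non-confirming and the per-factor `avail_*` mask
records the distinction for audit.

`harmonize_cohort()` collapses waves to one profile per participant:

* every boolean factor is the OR over available waves ("reported at any
  wave");
* sexual debut age and (within self-reports) ART-initiation age take the
  youngest report across waves; the abstracted **medical-record initiation
  age takes strict precedence** over any self-report, because clinic files
  are the less error-prone source — "youngest across waves" resolves
  disagreement among self-reports only;
* ART initiation **year** is `birth_year + initiation age` (integer years:
  every rule in the pipeline is an integer-year threshold, so no fractional
  ages are carried);
* **discordant disclosure**: the wave-1 interview is face to face, later
  waves use ACASI (audio computer-assisted self-interview), which elicits
  more honest reporting of stigmatized behaviour. A participant who
  (1) reported no debut at wave 1 but a debut at a later wave, or
  (2) reported a wave-1 debut at least 3 years older than a later report, is
  flagged. We read rule (1) as "any later wave", not wave 2 only: the
  concealment mechanism is the interview mode, which waves 2 and 3 share,
  and a participant absent at wave 2 can disclose for the first time at
  wave 3;
* **parental history**: a parent reported dead of HIV/AIDS at any wave sets
  the HIV-orphan flag; a parent on ART or HIV-symptomatic sets the
  parent-on-ART flag; death with an evasive or vague cause ("I don't know",
  illness, poison) when the participant was **10 or younger** sets the
  presumed-HIV-orphan flag. The age-10 bound follows from the ~10.2-year
  median from adult seroconversion to AIDS death without treatment: a parent
  dying that early in the child's life was plausibly infected around the
  child's conception. Cause "other" (e.g. accident) never triggers the
  presumption. Contradictory vital status (dead, then alive later) resolves
  toward death with a warning — deaths are not retractable; the most likely
  cause is a roster error at the "alive" wave.

Participants of a **single-wave sample** (young mothers recruited at wave 3
only) cannot exhibit discordance across waves and lack the wave-1-only
age-at-parental-death item, so `discordant_disclosure` and both presumed
orphan-at-≤10 flags are forced false with availability `unobserved`.

## The classifiers

**Cutoff rule** (`allocate_by_cutoff()`): vertical iff initiation age is
*strictly below* the cutoff; **at the cutoff or older is sexual**. This
boundary convention is taken literally from the method's definition and is
worth stating twice: moving the boundary by one year changes every
downstream metric.

**Logic tree** (`allocate_moha()`): a gateway routes participants who ever
reported sexual activity or penetrative sexual abuse into the *sexual* arm,
everyone else into the *vertical* arm. Each arm is an ordered list of pure
predicates (`moha_branches()`), strongest evidence first; the first true
predicate is the **exit branch** and fixes the label. Participants who enter
the sexual arm but clear all six branches **switch** to the vertical arm,
where only branches V1, V2, V3, V6, V7 (parental-history evidence) are
offered — the developmental and era-based branches V4, V5, V8, V9 are not
reliable for someone with a sexual history that simply failed to confirm.
Vertical-arm fall-throughs are *unclassified*; there is no vertical-to-sexual
switch, because sexual evidence is already exhausted by the gateway
(someone with no reported activity or abuse has no sexual-arm evidence by
construction). Opposite-arm predicates that are also true are surfaced as
`conflict_flags` for audit but never overturn a label: the method defines no
reversal rule, so we log rather than invent one.

Two ordering details are easy to get wrong:

* **V9 versus the slow-progressor branch.** Both fire on a first HIV test
  before age 10. V9 is restricted to ART-initiated participants; the SLOW
  branch requires ART naivety. Without that split, V9 would always shadow
  SLOW and no slow progressor could ever be identified.
* **Affirmatory counts** (`count_affirmatory_factors()`) are the plain sum
  of the final arm's enabled predicates, ignoring the switcher restriction.
  Some vertical factors are mutually exclusive in real data (a mother cannot
  be both dead of HIV and currently on ART) but the count stays a pure sum —
  it measures corroboration, not coherence. The SLOW predicate is included
  in the vertical count as an ordinary branch.

For the young-mothers variant, `tree_config(mothers_variant = TRUE)` forces
the sexual gateway (every member of that sample is a mother, hence sexually
active) and disables S3, V3, V7 — a configuration, not a code fork.

## Validation metrics

Positive = sexual. Participants unclassified by the tree or missing an
initiation age are excluded from the confusion matrix — reported `n` makes
that denominator explicit. PPV/NPV are `NA` (not 0) when nobody tests
positive/negative. The ROC of a single-threshold test has one operating
point; its trapezoidal AUC through `(0,0)`, `(1−spec, sens)`, `(1,1)` equals
`(sens + spec)/2`, and the test suite cross-checks it against a brute-force
Mann–Whitney pairwise enumeration. Reported tables round half-up to three
decimals; internal arithmetic is unrounded. Optimal-cutoff flags mark the
three published criteria separately: maximum sensitivity, minimum
|sens − spec|, maximum AUC.

## The synthetic world

Real cohort data are not deposited, so `generate_cohort()` simulates the
structure the pipeline assumes, with known true labels. Defaults state the
development cohort: n = 1107, 57% female, P(vertical) = 0.70, follow-up
retention 93.6%/91.5% (wave 1 complete — the design reached essentially all
eligible adolescents at baseline), medical-record coverage 88.1%, vertical
ART-initiation ages peaked at 5 years (Poisson-weighted integers 0–12),
sexual debut peaked at 15 (mothers sample: 16, initiating 0–4 years after
debut), birth years 1995–2004 (ages 10–19 at a 2014 baseline; mothers
1997–2001).

Choices the source does not fix, made once and kept:

* `wave1_underreport_prob = 0.25`: a quarter of truly sexually infected
  participants conceal (half) or inflate by 3+ years (half) their debut at
  the face-to-face wave-1 interview, disclosing under ACASI later. This is
  the *mechanism* behind discordant disclosure, not random noise; it is
  applied only to truly sexually infected participants, because a
  concealment by a vertically infected participant would manufacture a
  mislabel, which belongs to `noise_rate`.
* `noise_rate = 0.05`: probability that a factor confirming the *opposite*
  arm is expressed. This is the single mislabeling channel; at 0 the tree
  can abstain but never err, which is what makes the zero-noise recovery
  test sharp.
* Factor informativeness defaults are set to the published per-factor
  affirmative rates among classified participants (e.g. abuse 0.39,
  consistent unprotected sex 0.76, awareness 0.91; maternal states 0.38 /
  0.20 / 0.25; cognitive delay 0.51); parent states are one categorical
  draw per parent because a coherent record cannot have a mother
  simultaneously dead of HIV and alive on ART — within-parent exclusivity
  is the only departure from conditional independence given the label.
* `p_sexually_active_vertical = 0.25` gives the switch path realistic
  traffic (the real cohort contained many sexually active, vertically
  infected adolescents, including mothers); their debuts are drawn at 13+,
  after any childhood diagnosis, so activity alone never fakes S1.
* `art_naive_rate = 0.005`, `selfreport_art_prob = 0.8`,
  `factor_obs_prob = 0.95` (absent factors are recorded as explicit 0s most
  of the time, else left missing).

What the generator does **not** emulate: correlations among factors beyond
the parent-state exclusivity (no orphanhood × poverty × risky-behaviour
structure), reporting drift over waves, age-dependent retention, or the real
cohort's exact exit-branch frequencies. A green recovery test therefore
establishes that the pipeline's logic is faithful — rules fire exactly when
their inputs say so — not that the synthetic world is demographically
realistic.

## Numerical and degenerate-input conventions

Ages are integers in [0, 25]; anything else is a row-level validation error
naming the participant and column. Duplicate participant-wave keys are hard
errors. Booleans serialize as 0/1 with missing as the empty cell, and
read-back preserves per-column missingness exactly (round-trip identity is
tested). An empty medical table is valid (self-report fallback). A
participant with no informative factor is unclassified, never defaulted.
Rounding of reported proportions is half-up (`round_half_up()`), not
banker's rounding, to match published tables.

## Known limitations

* The tree's branch order and switcher set are fixed to the published exit
  order; the package deliberately offers no re-weighting or probabilistic
  scoring of branches.
* Countering information is logged, not adjudicated.
* Exact published cohort frequencies (exit-branch counts, per-factor
  percentages) are not reproducible without the original data; the test
  suite checks the identities and properties those tables must satisfy
  instead of their cell values.
* The two-point AUC applies to single-threshold classifiers only; it is not
  a pooled multi-threshold ROC.
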