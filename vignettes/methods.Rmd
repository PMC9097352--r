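---
title: "Methods: concept extraction and risk prediction for MCI from clinical notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concept extraction and risk prediction for MCI from clinical notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcitext)
```

## The problem and the modeling stance

Mild cognitive impairment is usually first visible not in structured EHR
data but in prose: a daughter calls about her father's memory, a clinician
notes "patient got lost driving home". `mcitext` operationalizes a simple
stance: treat those narrative signals as features, treat a standardized
cognitive instrument administered later (MMSE or MoCA, positive at a score
of 26 or below) as the label, and ask how well a sparse linear model
predicts the instrument from the notes alone. The pipeline is
deliberately interpretable — a dictionary, binary indicators, a lasso —
because the target users are health systems that must audit and embed the
model, not maximize leaderboard accuracy.

Two cohort designs are supported: a general population indexed at the
first structured MCI diagnosis (controls matched 1:1 inherit their case's
index date), and a research-cohort design indexed at the first positive
CASI screen (score ≤ 85 on the 0–100 scale). In both, features come only
from notes in the 730 days *preceding* the index date — the half-open
window `[index − 730d, index)` — from Family Practice and Behavioral
Health departments. Neurology and Speech/Language Pathology notes are
always excluded: patients seen there already have recognized deficits,
and the point is to find the ones who do not.

## Dictionary and matching

The dictionary maps 42 concept identifiers (CUIs) to term/phrase
patterns. The bundled file is a **reconstruction** from published concept
descriptions (2–8 plausible patterns per CUI, versioned
`concept-reconstruction-1.0`); it is configurable YAML, and any production
use should substitute a locally validated term list. Roles separate
predictor concepts from guard concepts: stroke (`S_EXCL`) and trauma
(`W_EXCL`) references mark *patients* for exclusion rather than becoming
features, while lexical negation is handled by dedicated concepts
(`DENIAL`, `NEGATE`, `EXM_EXCL`) rather than a syntactic negation
detector — an intentional simplification that keeps matching auditable.

Matching decisions worth knowing:

* **Variant expansion happens once, at load time.** Each pattern word is
  expanded to its regular inflectional family (`-s/-es/-ies`, `-ed`
  with e-drop, `-ing`) and matching is pure set lookup — no runtime
  stemming, so behavior is reproducible and inspectable. Where English
  doubling is stress-dependent (`plan → planned` but `wander → wandered`)
  both orthographies are generated; over-generation costs nothing but
  inert lookup entries. Irregular forms must be listed explicitly
  (the bundled FORGET concept lists `forgot` as its own pattern).
* **Phrase matching allows up to `max_gap = 2` intervening words**
  between consecutive pattern words, within a single sentence only —
  cross-sentence matches would inflate gap-rule hits with spurious
  pairings. Punctuation is tokenized away, so only word tokens count
  toward the gap.
* **Tie-breaking is leftmost-start, then shortest-end, non-overlapping**
  per pattern, with scanning resuming after each match — standard
  dictionary-tagger behavior. The implementation searches the (small) gap
  windows exhaustively, so this selection rule is exact, not a greedy
  approximation; the test suite checks equality against a brute-force
  subsequence enumerator on hundreds of random corpora. Overlapping
  matches of *different* CUIs are all kept: downstream features are
  per-CUI presence indicators, so ambiguity is harmless and resolving it
  would discard information.
* Offsets are 1-based and inclusive throughout
  (`substr(text, start, end) == matched_text`), the natural R convention.
* The sentence splitter is intentionally small: terminal `.!?` followed
  by whitespace and a capital/digit, a short abbreviation list (Dr, Mr,
  Mrs, Ms, St, vs, Jr, Sr, Prof, e.g, i.e), and blank lines as hard
  breaks, because EHR notes are fragmentary.

## Boilerplate

EHR template text (medication reminders such as "remember to take...",
counseling scripts) is injected into many patients' notes and says nothing
about any of them. A mention is flagged as boilerplate when its preceding
*or* following 180 raw characters are exactly shared (after trimming
surrounding whitespace) with a mention from at least one **other**
patient. Three consequences of the exact definition: contexts shorter
than 180 characters at note boundaries participate as-is; duplication
within one patient's chart (self copy-paste) is never flagged; and the
sharing threshold (`min_other_patients`) is configurable for sensitivity
analyses, with 1 as the default. Whether contexts should be compared
corpus-wide or within department strata is an open question; the package
compares corpus-wide, the more aggressive choice.

## Features, label, model

Each of the 42 CUIs contributes a 0/1 indicator (any non-boilerplate
in-window mention). Three fixed aggregates follow clinical judgment:
Symptom Sum (9 components), Behavior Sum (7 components: family concern and
communication), Forgetful Sum (3 components). The components are *presence*
indicators, which is the only reading under which the documented ranges
0–9 / 0–7 / 0–3 hold; a raw occurrence-count mode exists behind
`mode = "occurrences"` for exploration. The Forgetful Sum's second
component is the FORGETFL ("forgetful") concept; a FORGETFUL spelling that
sometimes appears in prose descriptions of the formula has no concept of
its own and is mapped there. Demographics enter as age in years at index,
a male indicator, race indicators with White as reference, Hispanic and
unknown-ethnicity indicators, and neighborhood income (< $25,000) and
education (< 25% college) as binary strata with missing-value indicator
columns — missingness is data, not something to impute silently. Census
covariates are offered to the penalty like everything else; the lasso is
free to drop them.

The model minimizes mean binomial deviance plus λ·Σ|βj| with an
unpenalized intercept. Numerical choices: predictors are standardized
internally and coefficients reported on the original scale (so the age
coefficient is per year of age); the λ grid is 100 log-spaced values from
λ_max (the smallest penalty that zeroes every slope, computed from the
data) down to λ_max·10⁻⁴; fold assignment is stratified by outcome to
stabilize cross-validation at moderate prevalence; λ minimizes mean
held-out deviance by default, with the one-standard-error rule available
(`rule = "1se"`). Fitting is delegated to coordinate descent in `glmnet`
(convergence threshold 10⁻¹⁰, 10⁻¹² for fixed-λ fits); the surrounding
contract — fold construction, λ selection, original-scale reporting,
single-λ exact extraction — is the package's. Degenerate inputs are
handled explicitly: constant columns get a warning and a forced zero
coefficient; a single-predictor matrix is padded internally with an inert
zero column because the backend requires two. An unpenalized fit
(`lambda_grid = 0`) agrees with an independent iteratively-reweighted
least-squares implementation to 10⁻⁶ in the test suite.

## Evaluation

Classification at cutoff c is `probability ≥ c` (the boundary counts as
positive; the convention is stated because it is not universal). Undefined
ratios (0/0) are reported as `NA`, never silently zero. F1 is derived from
PPV and sensitivity. AUC is the midrank Mann–Whitney statistic, which
equals the trapezoidal ROC area; its confidence interval is a stratified
bootstrap (2000 replicates, seeded) by default because no analytic method
is canonical for this design, with a DeLong-style interval as an
alternative. `ppv_npv_at_prevalence()` exposes the Bayes-rule dependence
of predictive values on prevalence — essential reading for screening: the
same sensitivity and specificity yield a higher PPV wherever prevalence is
higher.

## What the synthetic corpus does and does not emulate

The generator exists so that every stage has testable ground truth. It
emulates: the demographic strata of a 65-and-over screening population
(~59% female, five age bands, ~90% White); a latent MCI state from a
logistic model on age and sex whose prevalence rises from under 20% in the
youngest band to over 44% at 85+, about 31% overall (intercept −0.73,
0.062 per year centred at 77, −0.185 for male sex); roughly 10 notes per
patient of ~260 words inside the 730-day window; concept phrases planted
at per-note rates conditional on the latent state (with occasional filler
words inserted inside phrases to exercise the gap rule); fixed boilerplate
paragraphs shared across patients with at least 180 deterministic
characters on each side of their planted phrase, so context-sharing
detection actually fires; and an index-date MMSE that disagrees with the
latent state with probability 0.1, reflecting imperfect instruments.

Deliberate simplifications: filler text is drawn from a vocabulary
verified disjoint from every dictionary form, so the matcher's recall on
planted mentions is exactly measurable — real notes contain near-miss
language, typos and OCR noise that this corpus cannot represent; note
content is independent across notes given the latent state (no
within-patient progression); planted carrier sentences avoid the final
two sentences of a note so planted mentions always carry random context
on both sides (otherwise truncated boundary contexts could collide across
patients and be flagged as boilerplate by the exact-match rule — real
short notes *can* produce such collisions, and the package follows the
definition faithfully there). Consequently, passing the planted-recall
and flagging-exactness tests certifies the machinery, not performance on
real clinical language, and the default synthetic cohort separates far
more cleanly than real notes would.

Three configurations are fixed in code: the default (the study
conditions above), a zero-signal configuration (status-independent
planting rates *and* a flat demographic gradient, so no feature carries
information and discrimination must sit at chance — flattening the
gradient matters because age is a model feature), and a strong-signal
configuration (planting-rate contrasts scaled up 2.5×/0.5× with label
noise 0.02). All randomness descends from one root seed through three
substreams (patients, notes, scores).

The exclusion funnel has its own generator
(`generate_screening_population()`): mutually exclusive planted groups —
enrollment gaps, ADRD, psychosis, prior MCI, bipolar disorder, medication
use, research-cohort overlap, no in-window notes — scaled from a
15,396-candidate screen down to 2391 analyzable patients, so the tally of
`apply_exclusions()` is checkable step by step. Exclusion code lists are
configuration (`exclusion-codes.yaml`), not hard-coded: the method names
conditions, sites name codes.

## Other design choices

* Age matching granularity in 1:1 control matching defaults to 5-year
  bands (the granularity of standard demographic tables), configurable to
  exact year; the "visit in the same 3-month period" requirement is read
  as the case's calendar quarter. Matching is greedy in randomized case
  order under a seed — optimal bipartite matching buys little at
  screening-cohort sizes and costs reproducibility transparency.
* The train/validation split is always at the patient level (never the
  note level, which would leak), 60/40 by default, seeded; research-cohort
  patients are always training data.
* The pipeline fits one model on pooled training data and scores every
  subset, rather than refitting per cohort.
* Problem sizes in the test suite and acceptance script (250-patient toy
  corpora for recall, n = 2000 for the discrimination and
  coefficient-recovery checks, 20 simulation seeds, 200 oracle corpora)
  were chosen as the smallest sizes at which the checked properties are
  stable, keeping the full suite fast enough to run routinely.

## Limitations

The dictionary is a reconstruction and cannot be verified term-for-term
against any clinical system's list; treat it as a starting point. The
mention-level extractor has no annotated reference corpus, so its
precision/recall on real notes is unmeasured — only its agreement with
its own specification is certified. Negation handling is lexical, not
syntactic. The synthetic corpus cannot stand in for real clinical
language, and any performance numbers obtained on it say nothing about
deployment performance. CASI-to-MMSE crosswalking, income/education
imputation from census tracts, and EHR-system integration are out of
scope: the corresponding covariates are plain inputs.
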