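---
title: "Identifying military service in free-text clinical notes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying military service in free-text clinical notes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msitr)
```

## The problem

UK electronic health records carry no universal marker of prior military
service, so veteran status must be inferred from what clinicians happen to
write in free-text notes. `msitr` implements a Military Service
Identification Tool (MSIT)-style two-stage pipeline for that task: a
keyword rule stage over curated lexicons, and a machine-learned stage
(TF-IDF features plus a linear classifier) whose positive calls are gated
by the same keyword rule. Document decisions are aggregated to patient
level and evaluated against self-reported status with screening
statistics.

The package runs entirely on synthetic corpora plus a packaged external
validation contingency table; it connects to no record system.

## The two-stage model

**Stage 1 (rule).** A document is positive iff, after punctuation
stripping and removal of other people's service mentions, it contains a
military-lexicon phrase whose match span is not contained inside a
confounder phrase. The two suppression mechanisms target the documented
false-positive modes in this problem domain:

* *Containment suppression.* "army" inside "salvation army" is not
  evidence; span-inside-span containment on the normalized text handles
  every such superstring confounder. We chose containment over
  sentence-level exclusion because the canonical failure case is a strict
  superstring of a military term, and sentence scope would also discard
  genuine evidence elsewhere in the sentence.
* *Other-person attribution.* A military phrase with a relation word
  ("father", "husband", ...) within a symmetric window of `relation_window`
  tokens (default 5) is deleted together with the relation tokens. The
  original tool's mechanism for this step is not publicly specified at
  phrase/sentence/document granularity; a token window is the simplest
  rule that reproduces the family-member failure mode, and both the window
  and the lexicon are configuration, not code.

**Stage 2 (ML).** Documents are preprocessed in four ordered steps —
(1) strip punctuation, (2) remove other-person service mentions,
(3) remove stop words and tokens whose document frequency exceeds
`frequent_term_threshold` (tokens occurring in any military-lexicon entry
are always exempt), (4) delete confounder token subsequences as a unit —
then vectorized as TF-IDF and scored by a ridge-penalized logistic
regression. Positive ML calls are postprocessed by the stage-1 evidence
check; a positive without surviving military evidence is flipped to
negative, and negatives are never touched, so postprocessing is monotone
by construction.

**Aggregation.** A patient is labelled a veteran iff any of their
documents is positive. This matches how the tool is deployed (one
disclosure anywhere in the record suffices) and makes aggregation
order-invariant and idempotent.

## TF-IDF and classifier choices

The representation is fixed and documented because the source material
names TF-IDF but no dialect: smoothed inverse document frequency
`idf(t) = ln((1 + N) / (1 + df(t))) + 1`, term counts times idf,
L2-normalized rows, unigrams plus bigrams by default. The classifier is a
ridge-penalized (`alpha = 0`) logistic regression fitted with `glmnet`
along a short decreasing lambda path and evaluated at `lambda = 1e-3`,
with a 0.5 probability threshold. A regularized linear model on TF-IDF
matches the toolkit era of the original framework, is deterministic, and
is adequate at desk scale; the family, n-gram range and threshold are
config-overridable stand-ins, not claims about the original tool. Empty
documents predict 0 directly — a conservative, evidence-free document
should never create a veteran flag. All randomness sits behind a single
seed (default 42); the ridge fit itself uses no RNG, and the seed is
recorded in the model bundle.

## Evaluation layer and the class convention

`validation_report()` computes percent agreement `(a+d)/n`, PPV and NPV
for the veteran class, sensitivity/specificity, and the Youden index
`J = sensitivity + specificity − 1`. Two orientation conventions are
computed and labelled explicitly:

* `paper`: sensitivity is the detection rate of **non-veterans**
  (`a/(a+c)`) and specificity the recovery of veterans (`d/(b+d)`). This
  non-standard orientation is the one under which the published validation
  figures (0.83 / 0.92) reconcile with the printed 2×2 table, given the
  heavy non-veteran majority.
* `veteran_positive`: the conventional epidemiological orientation.

Swapping the convention swaps sensitivity and specificity exactly and
leaves `J` unchanged. Agreement and the Youden index are reported as
distinct named fields and never conflated: on the packaged validation
counts (a=111, b=1, c=23, d=11) agreement is 122/146 = 0.8356 while
`J` = 0.745, and conflating them is a known source of confusion for this
table. Note also that 122/146 is 83.6%, not the 84.2% sometimes quoted
alongside the same counts; the package always reports the value computed
from the counts. Statistics with zero denominators are returned as `NA`
("undefined"), never as 0, so a degenerate corpus cannot masquerade as a
perfect one. Values are stored unrounded; 2-decimal rounding happens only
in the print method. Wilson confidence intervals were considered and left
out: the evaluation design is a single external survey comparison and the
package reports exactly what that design supports.

## Eligibility screening

`filter_eligible()` applies seven criteria in a fixed order (alive, age ≥
18, consent for contact, no dementia/psychosis indicator, has email or
phone, English without an interpreter, coordinator approval for active
patients) and emits one cohort-flow stage per criterion with chained
counts. A missing attribute fails its criterion: the screening this
mirrors resolved uncertain cases by manual exclusion, and a conservative
filter is the safe default when contacting patients. "Active" is consumed
as an explicit boolean flag rather than inferred, because no operational
definition of activity is available to infer from.

## The synthetic corpus generator

`generate()` assembles notes from plain-text sentence templates
(`inst/extdata/templates/note_templates.txt`) with slots for self-service
phrases, other-person service (relation word + short service phrase),
Salvation Army mentions and military metaphors, over psychiatric-care
filler sentences. Templates are data, not code, so the clinical wording
stays auditable and extensible. Defaults define the study conditions:

* 400 patients, 3–7 notes each (about 2,000 documents) — the scale of the
  package's end-to-end checks;
* veteran prevalence 0.233, the veteran proportion the tool assigned in
  the external validation sample;
* per-note disclosure probability 0.8 for veterans — clinicians do not
  record service history in every note, but most veterans disclose
  somewhere in a 3–7 note record;
* confounder rates 0.15 (family member's service), 0.10 (Salvation Army),
  0.10 (military metaphor) per non-veteran note — chosen for test power
  over the documented false-positive modes, since their true prevalence in
  clinical notes is unknown; confounders are injected into non-veteran
  records only by default (they are the false-positive mechanism),
  overridable via `confounders_in_veterans`.

Determinism: each patient draws from a substream seeded by a stable hash
of `(seed, patient_id)`, so corpora are byte-identical across runs and
locally stable — growing `n_patients` does not alter existing patients'
notes.

Templates and lexicons are co-designed and tested together: every
self-service phrase contains a military-lexicon entry, other-person
phrases keep the military term within the relation window, filler avoids
both military vocabulary and relation words (so window-based removal
cannot clip genuine evidence across sentence boundaries), and metaphors
either avoid lexicon tokens morphologically ("soldiering on") or are
themselves confounder entries ("military precision").

What the generator does **not** emulate: realistic clinical language
variety, spelling noise, negated disclosures ("denies ever serving" — the
pipeline has no negation handling, by design), OCR artefacts, or
class-dependent note length. Passing the end-to-end checks therefore
demonstrates the pipeline's mechanics — suppression, gating, aggregation,
determinism — not expected performance on real records, where the
published external validation is the relevant evidence.

## Numerical and degenerate-input choices

* Matching operates on normalized text (lowercase, punctuation to spaces,
  collapsed whitespace); offsets are 0-based half-open on the normalized
  string, and token boundaries are the transitions created by
  normalization. Original-text offsets are out of scope.
* At a shared match start, the longest lexicon entry wins; matches at
  different starts may overlap.
* `frequent_term_threshold` defaults to 0.85 document-frequency: high
  enough that only boilerplate crosses it in realistic corpora, but it is
  a parameter, not a claim about the original tool, which published no
  number.
* Empty documents flow through every stage without error and always end
  labelled 0.
* Document and patient identifiers are opaque strings; duplicate ids are
  hard errors at I/O boundaries rather than silent de-duplication.

## Problem sizes used by the checks

The shipped tests and the acceptance script run the full pipeline on the
default 400-patient corpus (~2,000 documents), brute-force oracle
comparisons on 500+ notes, and exhaustive enumeration of all 2×2 tables
with `n ≤ 20` for the metric identities — sizes chosen so the whole suite
exercises every contract at desk scale.

## Known limitations

* The original tool's full gold-standard vocabulary is unpublished; the
  packaged military lexicon is a best-effort, versioned stand-in seeded
  with branch names, ranks and service phrases.
* No negation, no fuzzy matching, no lemmatization beyond lowercasing, no
  multilingual support.
* The original development-corpus performance figures cannot be reproduced
  without the source record system; the package substitutes property-based
  guarantees (oracle agreement, postprocessing monotonicity, end-to-end
  recovery on synthetic data, metric identities, directional reproduction
  of the family-confounder failure mode).
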