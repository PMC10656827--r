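---
title: "Methods: rule-based CAN screening of clinical notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based CAN screening of clinical notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canscreen)
```

## The problem

Child abuse and neglect (CAN) is chronically under-recognized in pediatric
care, and the evidence that a child has experienced or is at risk for CAN is
scattered through free-text clinical notes rather than structured fields.
`canscreen` implements a precision-oriented screening pipeline for such
notes: a curated dictionary of CAN-related terms is matched against
sentences, matches are filtered by negation and false-positive rules, and
any note with at least one surviving mention is flagged for clinician
review. The package also provides the surrounding workflow: consensus-based
lexicon curation from expert surveys, descriptive summaries, a
machine-learning sentence classifier, an adjudicated precision evaluation,
and a synthetic corpus generator so the entire pipeline is testable without
protected health data.

## Lexicon curation

Candidate terms are rated by domain experts on a 3-point importance scale
(1 = not important, 2 = somewhat important, 3 = critical for inclusion).
The retention rule is: keep a term when **at least 80%** of its raters
scored it 2 or higher. Ties at exactly 80% are retained, following the
wording of the rule. Free-text suggestions from one round become candidates
for the next when endorsed by at least 10% of the round's respondents;
suggestions are merged by exact string equality after normalization
(lowercasing, hyphen-to-space, punctuation stripping) and deliberately not
stemmed, so distinct clinical concepts are never conflated silently.

Every lexicon entry carries one of five subtypes — `ABUSE`, `SEXUAL_ABUSE`,
`PHYSICAL_INDICATION`, `EMOTIONAL_INDICATION`, `SERVICE` — and a
specificity class. `standard` terms are positive evidence on their own;
`low` terms (e.g. "police", "case manager", "incarcerated") name agencies
and circumstances that surround CAN but also appear in unrelated contexts,
so they only count when corroborated (below). The bundled starter lexicon
contains the ~40 published example surfaces; the TSV format is the
extension point for site-specific dictionaries, since no full validated
term list is publicly available.

## The annotation pipeline

Stages run per note, in order; all offsets are 0-based, half-open,
in note coordinates (BRAT-compatible).

**Sentence detection** is rule-based: boundaries after `.`, `!`, `?` when
followed by whitespace, at blank-line runs, and before list-item markers. A
small abbreviation list (Dr., Mr., vs., e.g., mg., yo., ...) suppresses
false boundaries. Colons never split, because clinical notes are full of
agrammatical header constructions ("sexual abuse health since last visit:
No illnesses...") that must stay in one sentence for the exclusion rules to
see them whole.

**Tokenization** produces alphanumeric runs plus standalone punctuation;
hyphens and slashes split. Dictionary matching operates over word tokens
only, so "foster-care" matches "foster care".

**Dictionary NER** is leftmost-longest, non-overlapping matching of every
lexicon surface and variant. On equal-length matches the more clinically
specific subtype wins (SEXUAL_ABUSE > PHYSICAL_INDICATION >
EMOTIONAL_INDICATION > ABUSE > SERVICE); the underlying study does not
state a tie rule, so this is the package's own choice, made once. Matching
is case-insensitive except for all-uppercase variants of up to 4 characters
("SA", "CPS"): these are clinical abbreviations whose lowercase homographs
("sa") would otherwise flood the output, so they match case-sensitively.
Mentions never cross sentence boundaries. The matcher is validated against
a brute-force enumerate-all-then-select oracle on fuzzed lexicon/text
pairs.

**Negation** follows the NegEx convention: a mention is negated when a
trigger ("no", "not", "denies", "without", "no evidence of", ...) occurs
within **6 word tokens** before it (the published community default scope)
with no terminator ("but", "however", "although", "except") in between.
Post-triggers are supported in the rule format but the default set is
pre-only, matching the published examples. Rules are data (YAML), not code.

**Exclusion rules** approximate the five false-positive categories observed
when the approach was applied to real pediatric notes:

| id | kind | suppresses |
|----|------|------------|
| r1 | non_patient_subject | kin token within 6 tokens before the mention plus a history marker (event concerns a relative) |
| r2 | template_pattern | abbreviation legends ("AV = alleged victim") |
| r3 | template_pattern | first-aid / instruction templates ("First Aid:", "Call 911") |
| r4 | section_header | mention inside a verb-less fragment ending in ":" |
| r5 | template_pattern | parenthetical abbreviation expansions ("STD (sexually transmitted disease") |

These formalize behaviors that were described only by example, so they are
shipped as an editable YAML file: the refinement loop that produced them on
real data is expected to continue at every site. Exclusions are monotone —
they only ever turn mentions off — which gives the testable property that
adding rules never increases the number of positive sentences.

**Low-specificity corroboration**: a `low` mention is excluded unless a
standard, non-negated, non-excluded mention occurs within
`window_sentences` sentences (default 3) in the same note. The window
default is the package's reading of "clear supportive information nearby
within the note"; it is a visible parameter, and window 0 restricts
corroboration to the same sentence.

**Classification** is deliberately simple and sensitive: a sentence is
positive iff it retains at least one qualifying mention, and a note is
positive iff any sentence is. There is no scoring or thresholding — the
design goal is a reviewable highlight, not an autonomous decision.

## The SVM sentence classifier

The machine-learning comparator classifies whether a sentence is *about*
CAN, using unigram, bigram and trigram features over lowercased word
tokens and a linear-kernel SVM (libsvm, via e1071). Features are binary
presence indicators: with sentences this short, counts add almost no
information, and binary features keep the model bundle portable; the
weighting is configurable. `C = 1` is the libsvm default and is exposed as
a parameter, since no hyperparameters were published. The vocabulary is
built from training sentences only. Models serialize to a JSON bundle
(vocabulary, weights, bias) whose predictions round-trip exactly.

The published per-class figures for this classifier (92% for CAN, 100% for
non-CAN) equal the per-class predictive values of the printed confusion
counts (22/24, 6/6), although the surrounding text says "sensitivity and
specificity"; `per_class_report()` therefore emits all four metrics so
either reading can be checked against the counts.

## Evaluation

Precision — confirmed positives over NLP-identified positives — is the
primary metric because recall is unmeasurable on real data without
exhaustive chart review. Review follows a two-expert protocol with a third
as tiebreaker; "unsure" counts as disagreement (the conservative reading;
the protocol does not say). Percentages are formatted half-up to 1 decimal
(2 decimals in the note-type table), matching the conventions of the
published tables; `precision()`-style ratios with zero denominator are
reported as not-available, never as zero. On synthetic corpora, where gold
labels exist, `evaluate_against_gold()` adds recall and F1.

## The synthetic corpus generator

The generator emulates the statistical structure the pipeline assumes:

* **note types** drawn from a 22-type pediatric outpatient profile with
  realistic relative frequencies;
* **positive-note rate** 0.03 by default (matching the ~2.9% of notes
  flagged in a real pediatric corpus);
* **subtype mixture** defaulting to .67/.22/.06/.05/.00 over
  SERVICE/ABUSE/SEXUAL_ABUSE/PHYSICAL_INDICATION/EMOTIONAL_INDICATION, the
  distribution observed in confirmed sentences, with "child protective
  services" up-weighted within SERVICE to mirror its real-world dominance;
* **negated plants** wrapping the planted surface in a negation trigger;
* **trap sentences** instantiating the five false-positive categories as
  parameterized variants of the published examples — the only ground-truth
  hard negatives available;
* optional verbatim **duplicates**, for exercising corpus cleaning.

Everything is deterministic given the spec seed, and every plant is
recorded as a gold annotation whose span slices exactly to the planted
surface. Filler sentences are synthetic well-child boilerplate written for
this package and verified to contain no lexicon surface, which yields the
central contract: with negation and traps disabled, the annotator's
sentence labels equal gold exactly.

What the generator does **not** emulate: real clinical language variety
(misspellings, ad-hoc abbreviations, copy-forward noise), discourse-level
phenomena (coreference, family history sections spanning paragraphs), and
mentions that only context makes ambiguous. Passing the synthetic suites
therefore demonstrates that the mechanics — matching, scoping, exclusion,
bookkeeping — are correct, not that real-data precision will match the
published figures; those depend on site-specific lexicon refinement.

Default problem sizes in the test and acceptance suites — 200 patients
(~800 notes, ~5,000 sentences) for end-to-end properties, 500 fuzzed
matcher cases, 20 seeds × 300 sentences for the SVM recovery suite — were
chosen as the smallest scales at which the distributional checks (subtype
mixture within ±2%, binomial duplicate counts) are stable.

## Numerical and degenerate-input choices

* Rounding is half-up everywhere percentages are formatted, because that is
  how the reference tables round; base R's banker's rounding would disagree
  on exact halves.
* Duplicate-note detection keys on exact (`patient_id`, `note_type`,
  `text`) and keeps the earliest date, tie-broken by `note_id`:
  reproducible and conservative (fuzzy matching would risk deleting
  legitimate notes). "Orphan" records are read as notes lacking patient
  linkage; they are rejected with line numbers but never abort a run.
* Empty notes annotate to zero sentences and a negative document label;
  zero qualifying mentions give a flagged empty subtype distribution, not
  a division error.
* Every random operation (splits, samples, generation) takes an explicit
  integer seed; there is no hidden global RNG state.

## Known limitations

The sentence splitter and tokenizer are rule-based approximations tuned to
outpatient note conventions; the negation rule set is the published trigger
list plus NegEx defaults, with no uncertainty or experiencer classes
beyond rules r1–r5; and the starter lexicon is a fraction of a fully
validated dictionary. The pipeline is a screening aid: its output is a
highlighted note for a clinician, and its error profile (precision-first,
recall unknown on real data) should be kept in mind when interpreting
counts.
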