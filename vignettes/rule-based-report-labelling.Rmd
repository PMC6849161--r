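---
title: "Rule-based annotation and phenotype labelling of brain-scan radiology reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based annotation and phenotype labelling of brain-scan radiology reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radlabel)
```

## The problem

Radiologists' free-text reports of CT and MRI brain scans encode, in a few
short sentences, whether a stroke or other finding was observed, where it
sits (deep versus cortical/lobar tissue), and how old it is. Turning those
narratives into structured phenotypes — "Ischaemic stroke, deep, old",
"Small vessel disease" — makes large report archives usable for
epidemiology and audit. `radlabel` implements a fully rule-based pipeline
for this task: every decision is traceable to a lexicon entry, a chunk
boundary or a declarative rule row, which is what clinical users typically
require before trusting extracted phenotypes.

Two principles drive the annotation scheme:

* **Only linguistically explicit evidence counts.** The labeller models
  what the radiologist wrote, not what a clinician could infer.
* **Only clearly positive findings support labels.** Negated mentions
  ("no acute haemorrhage") and hedged non-exclusions ("a small focus of
  acute infarct cannot be completely excluded") are both recorded as
  *negative* entities: present in the mark-up, barred from labelling.

## Data model

A `rad_document` carries the raw text plus tibble layers: sections,
sentences, tokens, chunks, entities, relations, and the full 24-label
inventory with selected flags and evidence pointers. All character offsets
are 0-based half-open intervals over the raw text — the BRAT standoff
convention — so exported `.ann` files need no offset translation.

Entities come from two closed vocabularies: 13 observation types
(ischaemic/haemorrhagic/unknown stroke, four tumour categories, subdural
haematoma, small vessel disease, atrophy, microbleed, subarachnoid
haemorrhage, haemorrhagic transformation) and 4 modifier types (`loc_deep`,
`loc_cortical`, `time_old`, `time_recent`). A surface form such as "POCI"
(posterior circulation infarct) carries both observation and location
meaning; it becomes two co-extensive *nested* entities linked by
`nested_with`, and the implied relation is deliberately not materialised —
the labeller consults the nesting directly.

## Pipeline stages

Stages run in a fixed order, each consuming the previous layers:

1. **Zoning.** Line-initial headers (case-insensitive, optional colon) map
   to `clinical_details`, `report_body` or `conclusion`; the table is
   configurable because hospital header dialects vary. Unheadered text is a
   single `report_body`; a preamble before the first header is treated as
   clinical details. Section spans partition the text exactly.
2. **Tokenisation.** Punctuation splits off as tokens; hyphenated medical
   compounds ("extra-axial") stay whole. Newlines end sentences — dictated
   reports use short newline-terminated lines — and a small abbreviation
   list stops "e.g." from splitting one.
3. **POS tagging with reconciliation.** Two taggers implement one
   contract (surfaces in, equal-length Penn-style tags out): a general
   closed-class/suffix tagger and a clinical tagger that retags lexicon
   words (modifiers as adjectives, observation heads as nouns). Where they
   disagree, the default rule prefers the clinical tagger on tokens found
   in the lexicons and the general tagger elsewhere. The architecture —
   two models plus a correction stage — matters more than the particular
   models; any tagger pair satisfying the contract can be plugged in, and
   reconciling a tagger with itself is the identity.
4. **Lemmatisation.** Plural nouns and inflected verbs reduce to lowercase
   stems by suffix rules plus an irregular table, so "infarcts" matches a
   lexicon entry "infarct". Lemmas drive all downstream matching.
5. **Entity lookup.** Two lexicon passes — observations, then modifiers —
   with maximal matching: longest match wins, ties go leftmost, matches
   never overlap within a pass. A modifier match exactly co-extensive with
   an observation nests; a partial overlap is suppressed in favour of the
   observation, because observations drive labelling. Entries match on
   lemma by default, or literally for abbreviations (`POCI`, `SAH`).
   Internal sorting makes the result independent of lexicon file order.
6. **Chunking and negation.** A shallow chunker builds maximal noun groups
   (determiner, premodifiers, coordinated heads joined by commas/"and"/
   "or") and verb groups (modals, auxiliaries, internal adverbs). A
   negative cue ("no", "without", "absence of", ...) marks its own noun
   group negative and every entity inside it — so all three observations in
   "No acute haemorrhage, masses or extra-axial collections" come out
   negative, while "but" starts a fresh, unaffected group. Hedge patterns
   ("cannot be excluded" and variants) negate the chain of noun groups on
   either side of the hedge verb group, bounded by neighbouring verb
   groups.
7. **Relations and verbal negation.** Each location modifier attaches to at
   most one stroke or microbleed observation, each time modifier to at most
   one stroke (microbleeds take no time): nearest type-compatible
   observation in the same noun group first, then nearest in the sentence,
   ties resolved leftward. Attachment across chunks is blocked when the
   endpoints disagree in polarity; inside a chunk it is unconditional.
   A verb group containing "not" negates its neighbouring noun-group
   chains — an attribute on the entities, never a relation. When one
   observation would collect conflicting values ("old" and "recent"), the
   nearest wins and a warning is logged.
8. **Labelling.** A declarative TSV rule table (`label_rules.tsv`) maps
   each non-negated observation in the report body or conclusion, together
   with its resolved location value (deep/cortical/none, from relations or
   nesting), time value (old/recent/none) and cue context, to one of the
   24 labels, recording entity and relation ids as evidence. Labels are
   not mutually exclusive. Clinical-details evidence never fires a rule.

## Label-rule decisions that were genuinely open

* *Assumed-old default.* A deep ischaemic stroke with no explicit time
  modifier is labelled "deep, old" — encoded as an ordinary rule row, so
  the default is visible and auditable in the data file.
* *Cortical without time.* The published default covers only the deep
  case, so a cortical ischaemic stroke lacking a time modifier maps to
  "Ischaemic stroke, underspecified"; sites that prefer a cortical default
  can edit one TSV row.
* *Haemorrhagic strokes* get no assumed-old default at all, for the same
  reason; location without time maps to "Haemorrhagic stroke,
  underspecified". Cortical location surfaces label as "lobar", the
  conventional term for haemorrhage.
* *Unknown-type strokes* always map to "Stroke, underspecified" whatever
  their modifiers.
* *Aneurysmal subarachnoid haemorrhage* is distinguished by a lemma
  starting "aneurysm" in the same sentence; absent a published criterion
  this one-cue rule is deliberately minimal.

## Scoring

`score_entities()`, `score_negation()`, `score_relations()` and
`score_labels()` count exact matches: an entity matches on exact span and
type (no partial credit — the strictest defensible convention); negation
scoring restricts both sides to negated entities; a relation matches on
type plus matched endpoints, and in inter-annotator (`iaa_mode`) use a
relation only enters the counts when both endpoint entities are agreed
between the two sides; labels count selected (report, label) pairs.
Precision, recall and F1 are computed on the 0–100 scale per type, and
micro totals always come from summed TP/FP/FN counts, never from averaging
per-type scores. Zero denominators yield `NaN` rather than a conventional
0 or 100, keeping genuinely undefined cells visible. Swapping the two
sides swaps precision and recall and preserves F1, which is why agreement
between two annotators can be quoted as a single F1.

Reported values are rounded to two decimals with base R `round()`; F1 is
always computed from unrounded precision and recall. `round()`'s
nearest-even behaviour at exact halves (90.625 prints as 90.62) is what
reproduces published two-decimal benchmark rows exactly, and the test
suite pins all 70 frozen reference rows
(`tests/testthat/prf-reference-rows.csv`) at full precision.

## The synthetic-report generator

The original stroke-study corpus is access-restricted, so the package
ships a seedable generator (`generate_reports()`) whose output stands in
for it in every test. Reports mimic the corpus shape: a clinical-details
preamble, a findings body of 4–7 short sentences, and (80% of the time) a
conclusion — around 60–90 words per report. Sentences are drawn from
templates instantiated only with shipped lexicon surface forms:
positive modified strokes, negated coordinated noun groups (1–3 heads),
hedged non-exclusions, verbal "not" constructions, nested classification
acronyms, microbleeds with and without location, aneurysmal and plain
subarachnoid haemorrhage, and simple-presence findings. Gold entities,
negation flags, relations and labels are recorded during assembly, and
every gold document passes the full validator.

Default rates are fixed once at values typical of such corpora: a third of
findings sentences negated (annotated report sets show roughly one
negative entity for every two positive), 8% hedges, 5% verbal negation,
70%/60% location/time modifier attachment, and observation-type weights
dominated by ischaemic stroke, small vessel disease and atrophy. The
defaults are study conditions, not tuning knobs.

Because templates only use constructions the rules cover, the pipeline
must reproduce generator gold *exactly* — the closure property, asserted
at F1 = 100 in all four categories on a 60-report corpus in the test suite
and a 100-report corpus in `scripts/acceptance.R` (sizes chosen to keep
the suite fast while exercising every template repeatedly). This is a
consistency proof of the implementation, not an accuracy claim: real
reports contain constructions outside the template inventory — long-range
negation, unseen synonyms, typos — on which rule coverage, not rule
correctness, becomes the limiting factor. `corrupt_document()` closes the
other gap: it perturbs gold documents in counted single units so scorer
counts can be checked against predictable deltas and a brute-force
recount.

## Numerical and degenerate-input conventions

* Empty report text is rejected with an explicit "empty report" error;
  a batch (`annotate_reports()`) logs the error and continues.
* A report with no recognised headers becomes one `report_body` section;
  zoning is idempotent.
* Matching and relation tie-breaks are total (length desc / start asc /
  type asc; nearest / leftward), so annotation is a pure function of
  (text, config) — byte-identical on repeated runs.
* Scoring documents with no units in a category (e.g. no negated entities
  anywhere) gives `NaN` scores rather than silently perfect ones.

## Known limitations

* **Negation scope is local.** A negative determiner scopes over its own
  noun group only; genuinely long-distance negation ("there is no
  evidence on this study of ...") is out of scope and documented rather
  than guessed at.
* **No double-negation resolution** ("no evidence against ...").
* **Lexicon coverage is approximate.** The shipped lexicons contain the
  documented surface forms of the scheme plus marked common synonyms; real
  deployments should substitute site lexicons (plain TSV).
* **One modifier, one observation.** A modifier never links to two
  coordinated observations sharing it ("old cortical and deep infarcts"
  resolves to the nearest only).
* Combined brain+neck/chest reports and non-brain findings are not
  filtered; callers should exclude them upstream.
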