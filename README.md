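# radlabel

Rule-based text mining for free-text CT and MRI brain-scan radiology
reports: named entities, negation, relations, and 24 report-level stroke
and tumour phenotype labels, with a full precision/recall/F1 evaluation
harness.

## Who this is for

Clinical NLP and epidemiology groups who need structured stroke phenotypes
from report archives and who need every extracted label to be auditable:
each selected label traces back to specific entity spans, relation links
and a row of a human-readable rule table. Everything the rules consume —
lexicons, negation cues, section headers, label rules — is plain TSV and
can be replaced with site-specific versions.

## The method

A report is processed in fixed stages: **zoning** into clinical-details /
findings / conclusion sections; **tokenisation** and sentence splitting;
**POS tagging** by two taggers (general + clinical) with a reconciliation
rule; **lemmatisation**; **lexicon lookup** of observation entities (13
types: ischaemic/haemorrhagic/unknown stroke, tumour subtypes, small
vessel disease, atrophy, microbleed, subarachnoid haemorrhage, ...) and
modifier entities (`loc:deep`, `loc:cortical`, `time:old`, `time:recent`),
including nested observation+modifier acronyms such as "POCI";
**chunking** into noun/verb groups, through which negative determiners
propagate ("No acute haemorrhage, masses or extra-axial collections"
negates all three findings) and hedged non-exclusions ("... cannot be
completely excluded") are marked negative; **relation extraction** linking
strokes to location and time modifiers, and microbleeds to location only,
by nearest type-compatible attachment; and **labelling**, in which a
declarative rule table maps each non-negated observation plus its resolved
location/time values to one of 24 labels, e.g.

* non-negated `small_vessel_disease` in body or conclusion →
  *Small vessel disease*;
* `ischaemic_stroke` + mod:loc(`loc_deep`) + mod:time(`time_old`) →
  *Ischaemic stroke, deep, old* — and a deep ischaemic stroke with **no**
  time modifier is assumed old by an explicit rule row.

Scoring uses the standard definitions on the 0–100 scale,

P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R),

with exact span+type entity matching, micro totals from summed counts
(never averaged per-type scores), NaN on zero denominators, and an
inter-annotator mode for relations that only counts relations whose
endpoint entities both sides agree on.

## Worked example

```r
library(radlabel)
library(tibble)

reports <- tribble(
  ~report_id, ~text,
  "r001", paste0("Clinical details:\nSudden onset weakness.\n\n",
                 "Report:\nOld thalamic infarcts. No acute haemorrhage, ",
                 "masses or extra-axial collections.\n\n",
                 "Conclusion:\nEstablished small vessel disease."),
  "r002", paste0("Report:\nDeep infarct seen. A small focus of acute ",
                 "infarct cannot be completely excluded.")
)

ann <- annotate_reports(reports)
entities(ann)
#> # A tibble: 13 × 5
#>    report_id entity_id etype                text                    negated
#>  1 r001      T1        time_old             Old                     FALSE
#>  2 r001      T2        loc_deep             thalamic                FALSE
#>  3 r001      T3        ischaemic_stroke     infarcts                FALSE
#>  4 r001      T4        time_recent          acute                   TRUE
#>  5 r001      T5        haemorrhagic_stroke  haemorrhage             TRUE
#>  6 r001      T6        tumour               masses                  TRUE
#>  7 r001      T7        subdural_haematoma   extra-axial collections TRUE
#>  8 r001      T8        time_old             Established             FALSE
#>  9 r001      T9        small_vessel_disease small vessel disease    FALSE
#> 10 r002      T1        loc_deep             Deep                    FALSE
#> 11 r002      T2        ischaemic_stroke     infarct                 FALSE
#> 12 r002      T3        time_recent          acute                   TRUE
#> 13 r002      T4        ischaemic_stroke     infarct                 TRUE
```

The coordinated negation in r001 marks all three findings after "No"
negative; in r002 the hedge marks the second infarct mention negative, so
only the first (deep, no time ⇒ assumed old) contributes a label:

```r
subset(report_labels(ann), selected)[, c("report_id", "label")]
#> 1 r001      Ischaemic stroke, deep, old
#> 2 r001      Small vessel disease
#> 3 r002      Ischaemic stroke, deep, old

explain(ann$doc[[1]], "Small vessel disease")
#> [r001] Small vessel disease: SELECTED
#>   entity T9 small_vessel_disease [155,175) "small vessel disease"
```

Every stage's output is a tibble layer on the document (`doc$entities`,
`doc$relations`, `doc$chunks`, ...); `write_brat()`, `document_to_json()`
and `document_to_xml()` export BRAT standoff pairs, a lossless JSON dump,
and inline XML. `score_documents(gold, pred)` returns a tidy
`rad_scores` table with `tidy()`/`glance()`/`autoplot()` methods.

Because the real stroke-study corpus is access-restricted, the package
ships a seedable synthetic-report generator with complete gold
annotations. The pipeline reproduces generator gold exactly:

```r
corp <- generate_reports(generator_spec(n_reports = 50), seed = 7)
sc <- score_documents(corp$gold, annotate_reports(corp)$doc)
sc[sc$type == "TOTAL", ]
#>   category  type     tp    fp    fn precision recall    f1
#> 1 entities  TOTAL   538     0     0       100    100   100
#> 2 negation  TOTAL   298     0     0       100    100   100
#> 3 relations TOTAL   151     0     0       100    100   100
#> 4 labels    TOTAL   131     0     0       100    100   100
```

A thin command-line wrapper ships in `inst/cli/radlabel.R`
(`annotate`, `score`, `synth` verbs) for shell use.

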