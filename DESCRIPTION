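Package: radlabel
Title: Rule-Based Entity, Negation, Relation and Phenotype Labelling for
    Brain Imaging Radiology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A rule-based text-mining pipeline for free-text CT and MRI
    brain-scan radiology reports. Reports are zoned into clinical-details,
    findings and conclusion sections, tokenised, part-of-speech tagged with a
    two-tagger reconciliation stage, and lemmatised; lexicon-driven named
    entity recognition finds radiological observations (ischaemic and
    haemorrhagic stroke, tumour subtypes, small vessel disease, atrophy,
    microbleeds and others) and location/time modifiers, including nested
    observation+modifier entities; shallow chunking propagates negation
    through coordinated noun groups and hedged non-exclusions; relation
    extraction links strokes and microbleeds to their modifiers; and a
    declarative rule table derives 24 report-level phenotype labels from the
    non-negated evidence. Includes BRAT standoff, JSON and inline-XML
    serialisation, a per-type and micro-averaged precision/recall/F1 scorer
    for entities, negation, relations and labels (also usable for
    inter-annotator agreement), and a seedable synthetic-report generator
    with complete gold annotations for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    stats,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
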