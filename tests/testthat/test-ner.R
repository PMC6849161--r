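annotate_upto_ner <- function(text) {
  read_report(text) |>
    zone() |>
    tokenize() |>
    pos_tag() |>
    lemmatise() |>
    match_entities()
}

test_that("lexicon loading validates types, modes and surfaces", {
  lex <- load_lexicons()
  expect_true(all(lex$observations$etype %in% observation_types()))
  expect_true(all(lex$modifiers$etype %in% modifier_types()))
  # documented multi-token entries are present
  expect_true("inter-cerebral volume loss" %in% lex$observations$surface)
  four <- lex$observations[
    lex$observations$surface == "inter-cerebral volume loss",
  ]
  expect_length(four$tokens[[1]], 3) # hyphenated compound is one token
  expect_true("established" %in% lex$modifiers$surface)
  expect_equal(
    lex$modifiers$etype[lex$modifiers$surface == "established"], "time_old"
  )
  expect_true("lacunar event" %in% lex$observations$surface)

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("something\tnot_a_type", path)
  expect_error(
    load_lexicons(path, radlabel_resource("modifiers.tsv")),
    "line 1.*unknown entity type"
  )
  writeLines("surface only no tab", path)
  expect_error(
    load_lexicons(path, radlabel_resource("modifiers.tsv")),
    "line 1"
  )
})

test_that("lemma matching finds inflected mentions; nesting marks acronyms", {
  doc <- annotate_upto_ner("Report:\nOld thalamic infarcts.")
  expect_setequal(
    doc$entities$etype, c("time_old", "loc_deep", "ischaemic_stroke")
  )
  expect_equal(
    doc$entities$text[doc$entities$etype == "ischaemic_stroke"], "infarcts"
  )
  # nested acronym: co-extensive observation + modifier, symmetric link
  doc2 <- annotate_upto_ner("Report:\nAppearances suggest a POCI.")
  en <- doc2$entities
  expect_equal(nrow(en), 2)
  expect_setequal(en$etype, c("ischaemic_stroke", "loc_cortical"))
  expect_equal(en$start[1], en$start[2])
  expect_equal(en$end[1], en$end[2])
  expect_equal(en$nested_with[1], en$entity_id[2])
  expect_equal(en$nested_with[2], en$entity_id[1])
})

test_that("longest match wins and observations beat partial modifier overlap", {
  doc <- annotate_upto_ner("Report:\nSubarachnoid haemorrhage seen.")
  expect_equal(doc$entities$etype, "subarachnoid_haemorrhage")
  # "lacunar event" (observation) suppresses the partial "lacunar" modifier
  doc2 <- annotate_upto_ner("Report:\nPrevious lacunar event.")
  expect_setequal(doc2$entities$etype, c("time_old", "ischaemic_stroke"))
  expect_equal(
    doc2$entities$text[doc2$entities$etype == "ischaemic_stroke"],
    "lacunar event"
  )
})

test_that("matching is insensitive to lexicon file ordering", {
  lex <- load_lexicons()
  shuffled <- lex
  set.seed(4)
  shuffled$observations <- shuffled$observations[
    sample(nrow(shuffled$observations)),
  ]
  shuffled$observations <- shuffled$observations[
    order(
      -lengths(shuffled$observations$tokens),
      shuffled$observations$surface, shuffled$observations$etype
    ),
  ]
  doc <- read_report("Report:\nOld thalamic infarcts and masses.") |>
    zone() |>
    tokenize() |>
    pos_tag() |>
    lemmatise()
  a <- match_entities(doc, lex)$entities
  b <- match_entities(doc, shuffled)$entities
  expect_equal(a, b)
})

test_that("matcher equals the brute-force longest-match oracle on 1000 random sentences", {
  lex <- load_lexicons()
  set.seed(2024)
  n_checked <- 0L
  for (i in seq_len(1000)) {
    doc <- random_synthetic_doc(lex, n_words = sample(3:10, 1))
    got <- match_entities(doc, lex)$entities
    got_keys <- sort(paste(got$start, got$end, got$etype, sep = ":"))
    want_keys <- oracle_entity_keys(doc, lex)
    expect_identical(got_keys, want_keys)
    n_checked <- n_checked + length(want_keys)
  }
  expect_gt(n_checked, 1000) # the sentences actually contained entities
})

test_that("entity overlap discipline holds on generated corpora", {
  corp <- generate_reports(generator_spec(n_reports = 10), seed = 31)
  ann <- annotate_reports(corp)
  for (d in ann$doc) {
    en <- d$entities
    for (cat in c("observation", "modifier")) {
      e <- en[en$category == cat, ]
      e <- e[order(e$start), ]
      if (nrow(e) > 1) {
        expect_true(all(utils::head(e$end, -1) <= utils::tail(e$start, -1)))
      }
    }
  }
})
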