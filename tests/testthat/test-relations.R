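annotate_full <- function(text) annotate_report(text, "rel")

test_that("the worked two-stroke sentence yields the documented relations", {
  doc <- annotate_full("Report:\nOld thalamic infarcts. No acute infarction.")
  en <- doc$entities
  rl <- doc$relations
  first <- en$entity_id[en$text == "infarcts"]
  second <- en$entity_id[en$text == "infarction"]
  expect_setequal(rl$rtype[rl$observation == first], c("mod_time", "mod_loc"))
  expect_equal(
    en$etype[en$entity_id == rl$modifier[rl$rtype == "mod_loc"]], "loc_deep"
  )
  expect_equal(rl$rtype[rl$observation == second], "mod_time")
  expect_equal(
    en$text[en$entity_id == rl$modifier[rl$observation == second]], "acute"
  )
})

test_that("a modifier with no compatible observation links to nothing", {
  doc <- annotate_full("Report:\nOld appearances.")
  expect_equal(nrow(doc$relations), 0)
  # time modifier with only an atrophy observation: atrophy takes no time
  doc2 <- annotate_full("Report:\nEstablished atrophy.")
  expect_equal(nrow(doc2$relations), 0)
})

test_that("microbleeds take location but never time relations", {
  doc <- annotate_full("Report:\nRecent deep microbleeds.")
  rl <- doc$relations
  expect_equal(rl$rtype, "mod_loc")
  en <- doc$entities
  expect_equal(
    en$etype[en$entity_id == rl$observation], "microbleed"
  )
})

test_that("relation endpoints sit in one sentence and satisfy type constraints", {
  corp <- generate_reports(generator_spec(n_reports = 12), seed = 5)
  ann <- annotate_reports(corp)
  for (d in ann$doc) {
    expect_true(validate_document(d)) # includes endpoint/type checks
    if (nrow(d$relations)) {
      en <- d$entities
      so <- en$sentence_id[match(d$relations$observation, en$entity_id)]
      sm <- en$sentence_id[match(d$relations$modifier, en$entity_id)]
      expect_equal(so, sm)
    }
  }
})

test_that("relation extraction is deterministic", {
  txt <- "Report:\nOld thalamic infarcts and cortical haemorrhage."
  a <- annotate_full(txt)$relations
  b <- annotate_full(txt)$relations
  expect_identical(a, b)
})

test_that("nearest type-compatible attachment; nested pairs never linked", {
  doc <- annotate_full(
    "Report:\nOld infarct and recent haemorrhage."
  )
  en <- doc$entities
  rl <- doc$relations
  inf <- en$entity_id[en$text == "infarct"]
  hae <- en$entity_id[en$text == "haemorrhage"]
  expect_equal(rl$observation[rl$modifier ==
    en$entity_id[en$text == "Old"]], inf)
  expect_equal(rl$observation[rl$modifier ==
    en$entity_id[en$text == "recent"]], hae)

  doc2 <- annotate_full("Report:\nAppearances suggest a POCI.")
  expect_equal(nrow(doc2$relations), 0) # nesting implies, never explicit
})

test_that("verbal 'not' negates without creating a relation", {
  doc <- annotate_full("Report:\nVery acute infarction may not be visible on CT.")
  en <- doc$entities
  expect_true(en$negated[en$etype == "time_recent"])
  expect_true(en$negated[en$etype == "ischaemic_stroke"])
  # the mod_time relation still links the negated pair, and nothing links
  # the negation itself
  expect_equal(doc$relations$rtype, "mod_time")
  expect_false(any(doc$labels$selected))

  doc2 <- annotate_full("Report:\nThis is not a mass.")
  expect_true(doc2$entities$negated[doc2$entities$etype == "tumour"])

  doc3 <- annotate_full("Report:\nFindings may not be significant.")
  expect_equal(nrow(doc3$entities), 0) # no entities in scope: no change
})

test_that("conflicting time values on one observation keep the nearest", {
  expect_warning(
    doc <- annotate_full("Report:\nOld recent infarct."),
    "conflicting"
  )
  rl <- doc$relations
  expect_equal(nrow(rl[rl$rtype == "mod_time", ]), 1)
  en <- doc$entities
  expect_equal(
    en$text[en$entity_id == rl$modifier[rl$rtype == "mod_time"]], "recent"
  )
})
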