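annotate_upto_chunks <- function(text) {
  read_report(text) |>
    zone() |>
    tokenize() |>
    pos_tag() |>
    lemmatise() |>
    match_entities() |>
    chunk()
}

chunk_covering <- function(doc, word) {
  tok <- doc$tokens[doc$tokens$surface == word, ]
  doc$chunks[doc$chunks$sentence_id == tok$sentence_id &
    doc$chunks$token_start <= tok$token_id &
    doc$chunks$token_end >= tok$token_id, ]
}

test_that("coordinated negative noun groups chunk as one group", {
  doc <- annotate_upto_chunks(
    "No acute haemorrhage, masses or extra-axial collections"
  )
  ng <- doc$chunks[doc$chunks$kind == "noun_group", ]
  expect_equal(nrow(ng), 1)
  expect_equal(ng$token_end - ng$token_start + 1L, 8L)
})

test_that("modal verb groups and single-noun groups chunk correctly", {
  doc <- annotate_upto_chunks("Very acute infarction may not be visible on CT.")
  vg <- doc$chunks[doc$chunks$kind == "verb_group", ]
  expect_equal(nrow(vg), 1)
  toks <- doc$tokens$surface[doc$tokens$token_id >= vg$token_start &
    doc$tokens$token_id <= vg$token_end]
  expect_equal(toks, c("may", "not", "be"))
  doc2 <- annotate_upto_chunks("atrophy")
  expect_equal(doc2$chunks$kind, "noun_group")
  expect_equal(doc2$chunks$token_start, doc2$chunks$token_end)
  doc3 <- annotate_upto_chunks("Lesion cannot be completely excluded.")
  vg3 <- doc3$chunks[doc3$chunks$kind == "verb_group", ]
  expect_equal(nrow(vg3), 1)
  expect_equal(vg3$token_end - vg3$token_start + 1L, 4L)
})

test_that("chunks are ordered and non-overlapping within sentences", {
  corp <- generate_reports(generator_spec(n_reports = 8), seed = 17)
  for (i in seq_len(nrow(corp))) {
    doc <- annotate_upto_chunks(corp$text[i])
    for (s in split(doc$chunks, doc$chunks$sentence_id)) {
      expect_true(all(diff(s$token_start) > 0))
      expect_true(all(
        utils::head(s$token_end, -1) < utils::tail(s$token_start, -1)
      ))
    }
  }
})

test_that("negation propagates through the whole coordinated noun group", {
  doc <- annotate_upto_chunks(
    "Report:\nNo acute haemorrhage, masses or extra-axial collections seen."
  ) |> apply_noun_group_negation()
  obs <- doc$entities[doc$entities$category == "observation", ]
  expect_equal(nrow(obs), 3)
  expect_true(all(obs$negated))
  expect_setequal(
    obs$text, c("haemorrhage", "masses", "extra-axial collections")
  )
})

test_that("negation stops at the noun-group boundary", {
  doc <- annotate_upto_chunks(
    "Report:\nNo old infarct but acute haemorrhage seen."
  ) |> apply_noun_group_negation()
  en <- doc$entities
  expect_true(en$negated[en$text == "infarct"])
  expect_false(en$negated[en$text == "haemorrhage"])
  expect_false(en$negated[en$text == "acute"])
})

test_that("entities outside negated groups stay positive by default", {
  doc <- annotate_upto_chunks("Report:\nOld deep infarct and atrophy.") |>
    apply_noun_group_negation() |>
    apply_hedge_negation()
  expect_false(any(doc$entities$negated))
})

test_that("prepositional cues negate the following noun group", {
  doc <- annotate_upto_chunks("Report:\nBrain without acute infarct.") |>
    apply_noun_group_negation()
  en <- doc$entities
  expect_true(all(en$negated[en$text %in% c("acute", "infarct")]))
})

test_that("hedged non-exclusions are negative; bare 'excluded' is not a cue", {
  doc <- annotate_upto_chunks(
    "Report:\nA small focus of acute infarct cannot be completely excluded."
  ) |> apply_hedge_negation()
  en <- doc$entities
  expect_true(en$negated[en$etype == "ischaemic_stroke"])
  expect_true(en$negated[en$etype == "time_recent"])

  doc2 <- annotate_upto_chunks("Report:\nCannot exclude meningioma.") |>
    apply_hedge_negation()
  expect_true(doc2$entities$negated[1])

  doc3 <- annotate_upto_chunks("Report:\nThe scan excluded haemorrhage.") |>
    apply_hedge_negation()
  expect_false(any(doc3$entities$negated))
})

test_that("negation is monotone and nested pairs share flags", {
  base <- annotate_upto_chunks("Report:\nOld POCI and atrophy seen.")
  pos <- apply_noun_group_negation(base)
  neg <- annotate_upto_chunks("Report:\nNo old POCI and atrophy seen.") |>
    apply_noun_group_negation()
  # adding a cue never un-negates: everything negated in pos stays negated
  pos_keys <- paste(pos$entities$text, pos$entities$etype)[pos$entities$negated]
  neg_keys <- paste(neg$entities$text, neg$entities$etype)[neg$entities$negated]
  expect_true(all(pos_keys %in% neg_keys))
  # nested POCI pair agrees on the flag
  nested <- neg$entities[!is.na(neg$entities$nested_with), ]
  expect_equal(nrow(nested), 2)
  expect_equal(nested$negated[1], nested$negated[2])
  expect_true(all(nested$negated))
})
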