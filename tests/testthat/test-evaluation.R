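test_that("compute_prf matches hand-checked counts and the NaN convention", {
  expect_equal(
    as.list(compute_prf(453, 9, 2)),
    list(precision = 98.05, recall = 99.56, f1 = 98.80)
  )
  r <- compute_prf(0, 0, 1)
  expect_true(is.nan(r$precision))
  expect_equal(r$recall, 0)
  expect_true(is.nan(r$f1))
  expect_equal(
    as.list(compute_prf(10, 0, 0)),
    list(precision = 100, recall = 100, f1 = 100)
  )
  # all-zero row is fully undefined
  z <- compute_prf(0, 0, 0)
  expect_true(all(is.nan(unlist(z))))
})

test_that("compute_prf reproduces every frozen reference row exactly", {
  ref <- reference_rows()
  got <- compute_prf(ref$tp, ref$fp, ref$fn, digits = 2)
  for (i in seq_len(nrow(ref))) {
    expect_prf_row(got[i, ], ref[i, ])
  }
})

test_that("micro totals are computed from summed counts, not averaged F1s", {
  ref <- reference_rows()
  for (src in unique(ref$source)) {
    block <- ref[ref$source == src, ]
    per <- block[block$type != "TOTAL", ]
    tot <- block[block$type == "TOTAL", ]
    expect_equal(sum(per$tp), tot$tp)
    expect_equal(sum(per$fp), tot$fp)
    expect_equal(sum(per$fn), tot$fn)
    expect_prf_row(compute_prf(tot$tp, tot$fp, tot$fn), tot)
    # and averaging per-type F1s would NOT give the printed total
    mean_f1 <- mean(per$f1, na.rm = TRUE)
    expect_gt(abs(mean_f1 - tot$f1), 0.5)
  }
})

test_that("identical annotation sets score perfect across categories", {
  corp <- generate_reports(generator_spec(n_reports = 6), seed = 19)
  sc <- score_documents(corp$gold, corp$gold, iaa_mode = TRUE)
  tot <- sc[sc$type == "TOTAL", ]
  expect_equal(tot$fp, rep(0L, 4))
  expect_equal(tot$fn, rep(0L, 4))
  expect_true(all(tot$f1 == 100))
})

test_that("a one-character span shift costs exact-match credit", {
  corp <- generate_reports(generator_spec(n_reports = 1), seed = 23)
  gold <- corp$gold
  pred <- list(corrupt_document(gold[[1]], list(shift_span = 1), seed = 1))
  sc <- score_entities(gold, pred)
  tot <- sc[sc$type == "TOTAL", ]
  expect_equal(tot$fp, 1L)
  expect_equal(tot$fn, 1L)
  expect_equal(tot$tp, nrow(gold[[1]]$entities) - 1L)
})

test_that("negation scoring is restricted to negated entities", {
  doc <- annotate_report(
    "Report:\nNo acute haemorrhage, masses or extra-axial collections seen."
  )
  sc <- score_negation(list(doc), list(doc))
  tot <- sc[sc$type == "TOTAL", ]
  expect_equal(tot$tp, 4L) # 3 observations + 1 time modifier
  expect_equal(tot$f1, 100)
  obs <- sc[sc$category == "negation" & sc$type != "TOTAL", ]
  expect_setequal(
    obs$type[obs$tp > 0],
    c("haemorrhagic_stroke", "tumour", "subdural_haematoma", "time_recent")
  )
  # a pred that marks one matching entity positive loses it as FN
  pred <- doc
  i <- which(pred$entities$etype == "tumour")
  pred$entities$negated[i] <- FALSE
  sc2 <- score_negation(list(doc), list(pred))
  tot2 <- sc2[sc2$type == "TOTAL", ]
  expect_equal(tot2$fn, 1L)
  expect_equal(tot2$fp, 0L)
  # no negated entities anywhere: undefined (NaN) scores
  pos <- annotate_report("Report:\nOld deep infarct.")
  sc3 <- score_negation(list(pos), list(pos))
  expect_true(is.nan(sc3$f1[sc3$type == "TOTAL"]))
})

test_that("IAA mode drops relations whose endpoints are not agreed", {
  gold <- annotate_report("Report:\nOld thalamic infarcts.", "r1")
  pred <- gold
  # retype the location modifier: endpoint no longer an entity-match
  i <- which(pred$entities$etype == "loc_deep")
  pred$entities$etype[i] <- "loc_cortical"
  strict <- score_relations(list(gold), list(pred), iaa_mode = FALSE)
  iaa <- score_relations(list(gold), list(pred), iaa_mode = TRUE)
  # strict counting: the mod_loc relation is FP+FN
  stot <- strict[strict$type == "TOTAL", ]
  expect_equal(stot$fp, 1L)
  expect_equal(stot$fn, 1L)
  # IAA counting: excluded from the denominator entirely
  itot <- iaa[iaa$type == "TOTAL", ]
  expect_equal(itot$fp, 0L)
  expect_equal(itot$fn, 0L)
  expect_equal(itot$tp, 1L) # the mod_time relation still counts
})

test_that("label scoring counts selected (report, label) pairs", {
  g <- annotate_report("Report:\nDeep infarct and atrophy.", "a")
  p <- annotate_report("Report:\nDeep infarct seen.", "a")
  sc <- score_labels(list(g), list(p))
  tot <- sc[sc$type == "TOTAL", ]
  expect_equal(tot$tp, 1L) # Ischaemic stroke, deep, old
  expect_equal(tot$fn, 1L) # Atrophy missed
  expect_equal(tot$fp, 0L)
  expect_equal(sc$fn[sc$type == "Atrophy"], 1L)
})

test_that("swapping gold and pred swaps P and R and preserves F1", {
  corp <- generate_reports(generator_spec(n_reports = 6), seed = 29)
  gold <- corp$gold
  pred <- lapply(gold, function(d) {
    corrupt_document(
      d,
      list(drop_entity = 1, flip_negation = 1, toggle_label = 1),
      seed = nchar(d$text)
    )
  })
  a <- score_documents(gold, pred)
  b <- score_documents(pred, gold)
  at <- a[a$type == "TOTAL", ]
  bt <- b[b$type == "TOTAL", ]
  expect_equal(at$precision, bt$recall)
  expect_equal(at$recall, bt$precision)
  expect_equal(at$f1, bt$f1)
})

test_that("scorer counts equal the brute-force oracle under random corruption", {
  corp <- generate_reports(generator_spec(n_reports = 8), seed = 37)
  gold <- corp$gold
  set.seed(99)
  pred <- lapply(gold, function(d) {
    corrupt_document(
      d,
      list(
        drop_entity = min(2, nrow(d$entities)),
        shift_span = min(1, nrow(d$entities)),
        flip_negation = min(2, nrow(d$entities)),
        retype = min(1, nrow(d$entities)),
        drop_relation = min(1, nrow(d$relations)),
        toggle_label = 3
      ),
      seed = sample.int(10000, 1)
    )
  })
  sc <- score_documents(gold, pred)
  for (cat in c("entities", "negation", "relations", "labels")) {
    want <- oracle_counts(gold, pred, cat)
    tot <- sc[sc$category == cat & sc$type == "TOTAL", ]
    expect_equal(tot$tp, unname(want["tp"]), label = paste(cat, "tp"))
    expect_equal(tot$fp, unname(want["fp"]), label = paste(cat, "fp"))
    expect_equal(tot$fn, unname(want["fn"]), label = paste(cat, "fn"))
  }
})

test_that("unpaired report ids are an explicit error", {
  corp <- generate_reports(generator_spec(n_reports = 2), seed = 41)
  expect_error(
    score_entities(corp$gold, corp$gold[1]),
    "unpaired report ids.*synth-002"
  )
})

test_that("tidy, glance and autoplot work on score reports", {
  corp <- generate_reports(generator_spec(n_reports = 3), seed = 43)
  sc <- score_documents(corp$gold, corp$gold)
  td <- tidy(sc)
  expect_s3_class(td, "tbl_df")
  gl <- glance(sc)
  expect_equal(gl$entities_f1, 100)
  expect_equal(gl$labels_f1, 100)
  p <- autoplot(sc)
  expect_s3_class(p, "ggplot")
})
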