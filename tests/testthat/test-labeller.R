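test_that("simple-presence labels fire from body or conclusion only", {
  doc <- annotate_report(
    "Report:\nUnremarkable.\n\nConclusion:\nEstablished small vessel disease."
  )
  expect_true(doc$labels$selected[doc$labels$label == "Small vessel disease"])
  # the same entity in clinical details must not fire
  doc2 <- annotate_report(
    "Clinical details:\nKnown small vessel disease.\n\nReport:\nNormal scan."
  )
  expect_false(any(doc2$labels$selected))
  expect_true("small_vessel_disease" %in% doc2$entities$etype)
})

test_that("deep ischaemic stroke without a time modifier defaults to old", {
  doc <- annotate_report("Report:\nDeep infarct seen.")
  expect_equal(
    doc$labels$label[doc$labels$selected], "Ischaemic stroke, deep, old"
  )
  # but an explicit recent wins over the default
  doc2 <- annotate_report("Report:\nAcute deep infarct seen.")
  expect_equal(
    doc2$labels$label[doc2$labels$selected], "Ischaemic stroke, deep, recent"
  )
  # cortical with no time is underspecified, not defaulted
  doc3 <- annotate_report("Report:\nCortical infarct seen.")
  expect_equal(
    doc3$labels$label[doc3$labels$selected], "Ischaemic stroke, underspecified"
  )
})

test_that("location and time resolve through relations and nesting alike", {
  doc <- annotate_report("Report:\nOld cortical infarct.")
  expect_equal(
    doc$labels$label[doc$labels$selected], "Ischaemic stroke, cortical, old"
  )
  nested <- annotate_report("Report:\nAppearances suggest an old POCI.")
  expect_equal(
    nested$labels$label[nested$labels$selected],
    "Ischaemic stroke, cortical, old"
  )
  laci <- annotate_report("Report:\nAppearances suggest a LACI.")
  expect_equal(
    laci$labels$label[laci$labels$selected], "Ischaemic stroke, deep, old"
  )
})

test_that("haemorrhagic stroke uses lobar naming and no assumed-old default", {
  doc <- annotate_report("Report:\nAcute lobar haemorrhage.")
  expect_equal(
    doc$labels$label[doc$labels$selected],
    "Haemorrhagic stroke, lobar, recent"
  )
  doc2 <- annotate_report("Report:\nDeep haemorrhage.")
  expect_equal(
    doc2$labels$label[doc2$labels$selected],
    "Haemorrhagic stroke, underspecified"
  )
})

test_that("stroke of unknown type and microbleed labels resolve correctly", {
  doc <- annotate_report("Report:\nOld stroke noted.")
  expect_equal(
    doc$labels$label[doc$labels$selected], "Stroke, underspecified"
  )
  mb <- annotate_report("Report:\nLobar microbleeds.")
  expect_equal(mb$labels$label[mb$labels$selected], "Microbleed, lobar")
  mb2 <- annotate_report("Report:\nMicrobleeds noted.")
  expect_equal(
    mb2$labels$label[mb2$labels$selected], "Microbleed, underspecified"
  )
})

test_that("subarachnoid haemorrhage splits on the aneurysm cue", {
  doc <- annotate_report(
    "Report:\nSubarachnoid haemorrhage from a ruptured aneurysm."
  )
  expect_equal(
    doc$labels$label[doc$labels$selected],
    "Subarachnoid haemorrhage, aneurysmal"
  )
  doc2 <- annotate_report("Report:\nSubarachnoid haemorrhage noted.")
  expect_equal(
    doc2$labels$label[doc2$labels$selected],
    "Subarachnoid haemorrhage, other"
  )
})

test_that("a fully negated document selects no labels", {
  doc <- annotate_report(
    "Report:\nNo acute infarct, haemorrhage or masses. Atrophy cannot be excluded."
  )
  expect_true(all(doc$entities$negated))
  expect_false(any(doc$labels$selected))
})

test_that("labels are not mutually exclusive and evidence is referential", {
  doc <- annotate_report(
    "Report:\nEstablished small vessel disease and atrophy."
  )
  expect_setequal(
    doc$labels$label[doc$labels$selected],
    c("Small vessel disease", "Atrophy")
  )
  for (i in which(doc$labels$selected)) {
    ev <- doc$labels$evidence[[i]]
    expect_gt(length(ev), 0)
    ent_ev <- grep("^T", ev, value = TRUE)
    expect_true(all(ent_ev %in% doc$entities$entity_id))
    expect_false(any(doc$entities$negated[
      match(ent_ev, doc$entities$entity_id)
    ]))
  }
})

test_that("adding an independent positive entity never deselects a label", {
  base <- annotate_report("Report:\nDeep infarct seen.")
  more <- annotate_report("Report:\nDeep infarct seen. Atrophy noted.")
  expect_true(all(
    base$labels$label[base$labels$selected] %in%
      more$labels$label[more$labels$selected]
  ))
})

test_that("explain produces traces and rejects unknown labels", {
  doc <- annotate_report("Report:\nDeep infarct seen.")
  tr <- explain(doc, "Ischaemic stroke, deep, old")
  expect_gt(length(tr), 1)
  expect_match(tr[1], "SELECTED")
  tr2 <- explain(doc, "Atrophy")
  expect_match(tr2, "no evidence")
  expect_error(explain(doc, "Not A Label"), "unknown label")
  # evidence ids in traces exist in random documents
  corp <- generate_reports(generator_spec(n_reports = 5), seed = 8)
  ann <- annotate_reports(corp)
  for (d in ann$doc) {
    for (lab in d$labels$label[d$labels$selected]) {
      expect_silent(capture.output(explain(d, lab)))
    }
  }
})
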