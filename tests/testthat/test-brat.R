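test_that("a minimal document writes one T line and nothing else", {
  doc <- read_report(paste0(strrep("x", 10), "small vessel disease ..."), "m1")
  # place one non-negated entity at [10, 33) by hand
  doc$entities <- tibble::add_row(doc$entities,
    entity_id = "T1", etype = "small_vessel_disease",
    category = "observation", start = 10L, end = 33L,
    text = substr(doc$text, 11, 33), negated = FALSE,
    nested_with = NA_character_, sentence_id = NA_integer_,
    section_kind = NA_character_
  )
  out <- write_brat(doc)
  lines <- strsplit(out$ann, "\n")[[1]]
  expect_length(grep("^T", lines), 1)
  expect_length(grep("^A", lines), 0)
  expect_length(grep("^R", lines), 0)
  expect_match(lines[1], "^T1\tsmall_vessel_disease 10 33\t")
})

test_that("the worked two-stroke report emits the expected standoff lines", {
  # first stroke holds a time and a location relation (2), the second a
  # time relation (1); the second stroke and its modifier are negated
  txt <- "Report:\nOld thalamic infarcts. No acute infarction."
  doc <- annotate_report(txt, "fig")
  out <- write_brat(doc)
  lines <- strsplit(out$ann, "\n")[[1]]
  expect_length(grep("^T", lines), 5)
  expect_length(grep("^A", lines), 2)
  expect_length(grep("^R", lines), 3)
  # the first ischaemic stroke is in two relations, the second in one
  rel <- doc$relations
  first_obs <- doc$entities$entity_id[doc$entities$text == "infarcts"]
  second_obs <- doc$entities$entity_id[doc$entities$text == "infarction"]
  expect_setequal(
    rel$rtype[rel$observation == first_obs], c("mod_time", "mod_loc")
  )
  expect_equal(rel$rtype[rel$observation == second_obs], "mod_time")
  expect_true(all(doc$entities$negated[doc$entities$entity_id %in%
    c(second_obs, rel$modifier[rel$observation == second_obs])]))
})

test_that("write then parse preserves entities, negation, relations, labels", {
  corp <- generate_reports(generator_spec(n_reports = 5), seed = 3)
  ann <- annotate_reports(corp)
  for (d in ann$doc) {
    out <- write_brat(d)
    back <- parse_brat(out$ann, out$txt, d$report_id)
    key <- function(x) {
      sort(paste(
        x$entities$start, x$entities$end, x$entities$etype,
        x$entities$negated
      ))
    }
    expect_equal(key(back), key(d))
    rkey <- function(x) {
      en <- x$entities
      io <- match(x$relations$observation, en$entity_id)
      im <- match(x$relations$modifier, en$entity_id)
      sort(paste(
        x$relations$rtype, en$start[io], en$end[io], en$start[im],
        en$end[im]
      ))
    }
    expect_equal(rkey(back), rkey(d))
    expect_equal(back$labels$selected, d$labels$selected)
    expect_true(validate_document(back, require_evidence = FALSE))
  }
})

test_that("parser reports structural errors with the offending line", {
  txt <- "No acute infarct."
  expect_error(
    parse_brat("T1\tischaemic_stroke 9 3\tacute", txt),
    "line 1.*end <= start"
  )
  expect_error(
    parse_brat("T1\tischaemic_stroke 9 300\tinfarct", txt),
    "line 1.*outside text"
  )
  expect_error(
    parse_brat("A1\tNegated T9", txt),
    "line 1.*missing entity T9"
  )
  expect_error(
    parse_brat("T1\tklingon_stroke 9 16\tinfarct", txt),
    "unknown type tag"
  )
  expect_error(
    parse_brat("garbage line", txt),
    "unrecognised line"
  )
})

test_that("parser accepts the legacy microhaemorrhage type alias", {
  txt <- "Deep microbleeds."
  doc <- parse_brat("T1\tmicrohaemorrhage 5 16\tmicrobleeds", txt)
  expect_equal(doc$entities$etype, "microbleed")
})

test_that("dangling relation endpoints are a structural integrity error", {
  doc <- annotate_report("Report:\nOld deep infarct.")
  doc$relations$observation[1] <- "T99"
  expect_error(write_brat(doc), "structural integrity")
})

test_that("brat corpus files round-trip through disk", {
  dir <- withr::local_tempdir()
  corp <- generate_reports(generator_spec(n_reports = 3), seed = 9)
  ann <- annotate_reports(corp)
  write_corpus(ann, dir, format = "brat")
  back <- read_brat_corpus(dir)
  expect_equal(back$report_id, ann$report_id)
  sc <- score_documents(ann$doc, back$doc)
  expect_true(all(sc$f1[sc$type == "TOTAL"] == 100))
})
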