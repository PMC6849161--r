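# End-to-end orchestration: the fixed stage order is zoning, tokenisation,
# POS tagging, lemmatisation, entity lookup, chunking + noun-group and
# hedge negation, verbal negation + relation extraction, labelling.

#' Pipeline configuration
#'
#' Bundles the declarative resources every stage needs. All defaults are
#' shipped with the package and user-replaceable.
#'
#' @param obs_lexicon,mod_lexicon Paths to observation / modifier lexicon
#'   TSVs.
#' @param cue_file Path to the negation/hedge cue TSV.
#' @param header_file Optional path to a section-header TSV; `NULL` uses
#'   the built-in table.
#' @param label_rule_file Path to the label rule TSV.
#' @param tagger_general,tagger_biomedical,reconcile POS tagging setup, see
#'   [pos_tag()].
#' @return A `rad_config` list with the loaded resources.
#' @export
rad_config <- function(obs_lexicon = radlabel_resource("observations.tsv"),
                       mod_lexicon = radlabel_resource("modifiers.tsv"),
                       cue_file = radlabel_resource("negation_cues.tsv"),
                       header_file = NULL,
                       label_rule_file = radlabel_resource("label_rules.tsv"),
                       tagger_general = tag_general,
                       tagger_biomedical = tag_clinical,
                       reconcile = reconcile_default) {
  structure(
    list(
      lexicons = load_lexicons(obs_lexicon, mod_lexicon),
      cues = load_cues(cue_file),
      headers = if (is.null(header_file)) {
        default_header_table()
      } else {
        read_header_table(header_file)
      },
      label_rules = load_label_rules(label_rule_file),
      tagger_general = tagger_general,
      tagger_biomedical = tagger_biomedical,
      reconcile = reconcile
    ),
    class = "rad_config"
  )
}

#' Annotate a single report
#'
#' Runs the full pipeline over one report text. A pure function of
#' (text, config): repeated runs give identical output.
#'
#' @param text Raw report text.
#' @param report_id Report identifier.
#' @param config A [rad_config()].
#' @return An annotated, validated `rad_document`.
#' @examples
#' doc <- annotate_report("Report:\nOld deep infarct.", "ex1")
#' doc$labels$label[doc$labels$selected]
#' @export
annotate_report <- function(text, report_id = "report",
                            config = rad_config()) {
  doc <- read_report(text, report_id)
  doc <- zone(doc, config$headers)
  doc <- tokenize(doc)
  doc <- pos_tag(doc, config$tagger_general, config$tagger_biomedical,
    config$reconcile
  )
  doc <- lemmatise(doc)
  doc <- match_entities(doc, config$lexicons)
  doc <- chunk(doc)
  doc <- apply_noun_group_negation(doc, config$cues)
  doc <- apply_hedge_negation(doc, config$cues)
  doc <- apply_verbal_negation(doc)
  doc <- extract_relations(doc)
  doc <- assign_labels(doc, config$label_rules)
  validate_document(doc)
  doc
}

#' Annotate a corpus of reports
#'
#' Tidy batch interface: takes a tibble with `report_id` and `text`
#' columns, annotates each report, and returns the input with a `doc`
#' list-column plus summary counts. A report whose annotation fails is kept
#' in the output with `doc = NULL` and the error message in `error`; the
#' batch continues. Order is preserved.
#'
#' @param reports A data frame with columns `report_id` and `text`.
#' @param config A [rad_config()].
#' @return A corpus tibble: `report_id`, `text`, `doc`, `n_entities`,
#'   `n_negated`, `n_relations`, `n_labels`, `error`.
#' @examples
#' library(tibble)
#' tibble(report_id = "r1", text = "Report:\nOld deep infarct.") |>
#'   annotate_reports()
#' @export
annotate_reports <- function(reports, config = rad_config()) {
  stopifnot(
    is.data.frame(reports),
    all(c("report_id", "text") %in% names(reports))
  )
  docs <- vector("list", nrow(reports))
  errs <- rep(NA_character_, nrow(reports))
  for (i in seq_len(nrow(reports))) {
    docs[[i]] <- tryCatch(
      annotate_report(reports$text[i], reports$report_id[i], config),
      error = function(e) {
        errs[i] <<- conditionMessage(e)
        message(
          "report ", reports$report_id[i], " failed: ",
          conditionMessage(e)
        )
        NULL
      }
    )
  }
  ok <- !vapply(docs, is.null, logical(1))
  tibble(
    report_id = reports$report_id,
    text = reports$text,
    doc = docs,
    n_entities = ifelse(ok, vapply(docs, function(d) {
      if (is.null(d)) NA_integer_ else nrow(d$entities)
    }, integer(1)), NA_integer_),
    n_negated = ifelse(ok, vapply(docs, function(d) {
      if (is.null(d)) NA_integer_ else sum(d$entities$negated)
    }, integer(1)), NA_integer_),
    n_relations = ifelse(ok, vapply(docs, function(d) {
      if (is.null(d)) NA_integer_ else nrow(d$relations)
    }, integer(1)), NA_integer_),
    n_labels = ifelse(ok, vapply(docs, function(d) {
      if (is.null(d)) NA_integer_ else sum(d$labels$selected)
    }, integer(1)), NA_integer_),
    error = errs
  )
}

#' Write an annotated corpus to disk
#'
#' @param corpus A corpus tibble from [annotate_reports()] (or with a
#'   `gold` column renamed to `doc`).
#' @param dir Output directory.
#' @param format One or more of `"brat"` (.txt/.ann pairs), `"json"`,
#'   `"xml"`.
#' @return Invisibly, the output directory.
#' @export
write_corpus <- function(corpus, dir, format = "brat") {
  format <- match.arg(format, c("brat", "json", "xml"), several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (d in corpus_docs(corpus)) {
    if (is.null(d)) next
    if ("brat" %in% format) write_brat(d, dir)
    if ("json" %in% format) {
      document_to_json(d, file.path(dir, paste0(d$report_id, ".json")))
    }
    if ("xml" %in% format) {
      document_to_xml(d, file.path(dir, paste0(d$report_id, ".xml")))
    }
  }
  invisible(dir)
}

#' Read a directory of BRAT standoff pairs
#'
#' @param dir Directory containing `<id>.txt` / `<id>.ann` pairs.
#' @return A corpus tibble with `report_id`, `text`, `doc`.
#' @export
read_brat_corpus <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  rows <- purrr::map(txts, function(tf) {
    af <- sub("\\.txt$", ".ann", tf)
    if (!file.exists(af)) {
      stop("no .ann file for ", basename(tf), call. = FALSE)
    }
    id <- sub("\\.txt$", "", basename(tf))
    txt <- paste(readLines(tf, warn = FALSE), collapse = "\n")
    doc <- parse_brat(readLines(af, warn = FALSE), txt, id)
    tibble(report_id = id, text = txt, doc = list(doc))
  })
  dplyr::bind_rows(rows)
}
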