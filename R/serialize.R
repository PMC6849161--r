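# JSON dump/restore (lossless) and a one-way inline-XML writer.

#' Serialise a document to JSON and back
#'
#' The JSON dump is lossless: all annotation layers, label evidence
#' included, round-trip exactly. This is the package's archival format;
#' BRAT standoff is the interchange format for annotation tools.
#'
#' @param doc A `rad_document`.
#' @param json A JSON string produced by `document_to_json()`.
#' @param path Optional file path to write to / read from.
#' @return `document_to_json()`: a JSON string (invisibly when `path` is
#'   given); `document_from_json()`: a `rad_document`.
#' @name json_io
NULL

#' @rdname json_io
#' @export
document_to_json <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "rad_document"))
  payload <- list(
    format = "radlabel-document",
    version = 1L,
    report_id = doc$report_id,
    text = doc$text,
    sections = doc$sections,
    sentences = doc$sentences,
    tokens = doc$tokens,
    chunks = doc$chunks,
    entities = doc$entities,
    relations = doc$relations,
    labels = list(
      label = doc$labels$label,
      selected = doc$labels$selected,
      evidence = doc$labels$evidence
    )
  )
  js <- jsonlite::toJSON(payload,
    dataframe = "columns", auto_unbox = TRUE, na = "null", null = "null",
    digits = NA
  )
  if (!is.null(path)) {
    writeLines(as.character(js), path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

as_typed_tibble <- function(x, template) {
  out <- template
  if (is.null(x) || length(x) == 0L) {
    return(out)
  }
  cols <- lapply(names(template), function(nm) {
    v <- x[[nm]]
    if (is.null(v)) {
      return(template[[nm]])
    }
    v <- unlist(lapply(v, function(e) if (is.null(e)) NA else e))
    mode_target <- class(template[[nm]])[1]
    switch(mode_target,
      integer = as.integer(v),
      character = as.character(v),
      logical = as.logical(v),
      v
    )
  })
  names(cols) <- names(template)
  tibble::as_tibble(cols)
}

#' @rdname json_io
#' @export
document_from_json <- function(json, path = NULL) {
  if (!is.null(path)) json <- paste(readLines(path, warn = FALSE), collapse = "\n")
  x <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  if (!identical(x$format, "radlabel-document")) {
    stop("not a radlabel document JSON dump", call. = FALSE)
  }
  doc <- read_report(x$text, x$report_id)
  doc$sections <- as_typed_tibble(x$sections, empty_sections())
  doc$sentences <- as_typed_tibble(x$sentences, empty_sentences())
  doc$tokens <- as_typed_tibble(x$tokens, empty_tokens())
  doc$chunks <- as_typed_tibble(x$chunks, empty_chunks())
  doc$entities <- as_typed_tibble(x$entities, empty_entities())
  doc$relations <- as_typed_tibble(x$relations, empty_relations())
  labs <- fresh_labels()
  got <- unlist(x$labels$label)
  idx <- match(labs$label, got)
  labs$selected <- unlist(x$labels$selected)[idx]
  labs$selected[is.na(labs$selected)] <- FALSE
  labs$evidence <- lapply(
    x$labels$evidence[idx],
    function(e) as.character(unlist(e))
  )
  doc$labels <- labs
  doc
}

#' Write a document as inline XML
#'
#' Versioned XML dialect (`radlabel-xml` v1): the report element carries
#' the 24-label metadata block (one `label` element each, with a
#' `selected` attribute), the zoned sections as elements wrapping their
#' text, and a standoff block with entity and relation elements referencing
#' character offsets. Writer only; JSON is the lossless archival format.
#'
#' @param doc A `rad_document`.
#' @param path Optional file path.
#' @return An `xml2` document (invisibly when `path` is given).
#' @export
document_to_xml <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "rad_document"))
  root <- xml2::xml_new_root("report",
    id = doc$report_id, format = "radlabel-xml", version = "1"
  )
  labs <- xml2::xml_add_child(root, "labels")
  for (i in seq_len(nrow(doc$labels))) {
    xml2::xml_add_child(labs, "label",
      name = doc$labels$label[i],
      selected = tolower(as.character(doc$labels$selected[i]))
    )
  }
  body <- xml2::xml_add_child(root, "text")
  for (i in seq_len(nrow(doc$sections))) {
    sec <- xml2::xml_add_child(body, "section",
      kind = doc$sections$kind[i],
      start = as.character(doc$sections$start[i]),
      end = as.character(doc$sections$end[i])
    )
    xml2::xml_text(sec) <- span_text(
      doc$text, doc$sections$start[i], doc$sections$end[i]
    )
  }
  so <- xml2::xml_add_child(root, "standoff")
  ents <- xml2::xml_add_child(so, "entities")
  for (i in seq_len(nrow(doc$entities))) {
    e <- doc$entities[i, ]
    node <- xml2::xml_add_child(ents, "entity",
      id = e$entity_id, type = e$etype,
      start = as.character(e$start), end = as.character(e$end),
      negated = tolower(as.character(e$negated))
    )
    if (!is.na(e$nested_with)) {
      xml2::xml_set_attr(node, "nested-with", e$nested_with)
    }
    xml2::xml_text(node) <- e$text
  }
  rels <- xml2::xml_add_child(so, "relations")
  for (i in seq_len(nrow(doc$relations))) {
    r <- doc$relations[i, ]
    xml2::xml_add_child(rels, "relation",
      id = r$relation_id, type = sub("_", "-", r$rtype),
      observation = r$observation, modifier = r$modifier
    )
  }
  if (!is.null(path)) {
    xml2::write_xml(root, path)
    return(invisible(root))
  }
  root
}
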