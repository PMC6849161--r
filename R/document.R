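#' @importFrom rlang .data
#' @importFrom tibble tibble
NULL

# ---- empty component tibbles -------------------------------------------

empty_sections <- function() {
  tibble(
    section_id = integer(), kind = character(),
    start = integer(), end = integer()
  )
}

empty_sentences <- function() {
  tibble(
    sentence_id = integer(), section_id = integer(),
    start = integer(), end = integer()
  )
}

empty_tokens <- function() {
  tibble(
    token_id = integer(), sentence_id = integer(),
    start = integer(), end = integer(),
    surface = character(), pos = character(), lemma = character(),
    lookup = character()
  )
}

empty_chunks <- function() {
  tibble(
    chunk_id = integer(), sentence_id = integer(), kind = character(),
    token_start = integer(), token_end = integer(),
    polarity = character()
  )
}

empty_entities <- function() {
  tibble(
    entity_id = character(), etype = character(), category = character(),
    start = integer(), end = integer(), text = character(),
    negated = logical(), nested_with = character(),
    sentence_id = integer(), section_kind = character()
  )
}

empty_relations <- function() {
  tibble(
    relation_id = character(), rtype = character(),
    observation = character(), modifier = character()
  )
}

fresh_labels <- function() {
  tibble(
    label = label_inventory(),
    selected = FALSE,
    evidence = vector("list", length(label_inventory()))
  )
}

# extract the substring for a 0-based half-open [start, end) span
span_text <- function(text, start, end) {
  substr(rep_len(text, length(start)), start + 1L, end)
}

#' Create a report document from raw text
#'
#' The document is the unit all pipeline stages operate on. Character offsets
#' throughout the package are 0-based, half-open intervals over the raw
#' report text (the BRAT standoff convention). A fresh document carries the
#' full 24-label inventory, all unselected; sections, tokens, entities,
#' relations are filled in by the pipeline stages.
#'
#' @param text Raw report text. Must be non-empty after whitespace stripping.
#' @param report_id Identifier for the report.
#' @return A `rad_document` object: a list with elements `report_id`, `text`,
#'   and tibbles `sections`, `sentences`, `tokens`, `chunks`, `entities`,
#'   `relations`, `labels`.
#' @examples
#' doc <- read_report("CT head. No acute infarct.", "r1")
#' nchar(doc$text)
#' sum(doc$labels$selected)
#' @export
read_report <- function(text, report_id = "report") {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    stop("empty report: text must be a non-empty string", call. = FALSE)
  }
  structure(
    list(
      report_id = as.character(report_id),
      text = text,
      sections = empty_sections(),
      sentences = empty_sentences(),
      tokens = empty_tokens(),
      chunks = empty_chunks(),
      entities = empty_entities(),
      relations = empty_relations(),
      labels = fresh_labels()
    ),
    class = "rad_document"
  )
}

#' @export
print.rad_document <- function(x, ...) {
  cat("<rad_document> ", x$report_id, "\n", sep = "")
  cat("  text:      ", nchar(x$text), " chars\n", sep = "")
  cat("  sections:  ", nrow(x$sections), "\n", sep = "")
  cat("  sentences: ", nrow(x$sentences), ", tokens: ", nrow(x$tokens),
    "\n",
    sep = ""
  )
  neg <- sum(x$entities$negated)
  cat("  entities:  ", nrow(x$entities), " (", neg, " negated)\n", sep = "")
  cat("  relations: ", nrow(x$relations), "\n", sep = "")
  sel <- x$labels$label[x$labels$selected]
  cat("  labels:    ", if (length(sel)) paste(sel, collapse = "; ") else
    "(none selected)", "\n", sep = "")
  invisible(x)
}

#' Validate a report document against the data-model invariants
#'
#' Checks span containment, section ordering and partition, token ordering,
#' entity overlap discipline (same-category entities never overlap; cross
#' category overlap only as exact co-extension with symmetric nesting),
#' relation endpoint type constraints and same-sentence requirement, the
#' 24-label inventory, and that selected labels carry non-negated evidence.
#'
#' @param doc A `rad_document`.
#' @param require_evidence Enforce that selected labels cite non-negated
#'   evidence entities. Pipeline and generator output always satisfies
#'   this; set to `FALSE` for documents ingested from BRAT standoff, where
#'   evidence pointers are not representable.
#' @return Invisibly `TRUE`; otherwise an error describing the first
#'   violated invariant.
#' @export
validate_document <- function(doc, require_evidence = TRUE) {
  stopifnot(inherits(doc, "rad_document"))
  n <- nchar(doc$text)
  fail <- function(...) stop("invalid document: ", ..., call. = FALSE)

  check_spans <- function(tb, what) {
    if (nrow(tb) == 0L) return(invisible())
    if (any(tb$start < 0L | tb$end > n | tb$start >= tb$end)) {
      fail(what, " span outside [0, ", n, ") or empty")
    }
  }
  check_spans(doc$sections, "section")
  check_spans(doc$sentences, "sentence")
  check_spans(doc$tokens, "token")
  check_spans(doc$entities, "entity")

  sec <- doc$sections
  if (nrow(sec) > 0L) {
    if (is.unsorted(sec$start, strictly = TRUE)) {
      fail("sections not ordered by start offset")
    }
    if (any(utils::head(sec$end, -1) > utils::tail(sec$start, -1))) {
      fail("sections overlap")
    }
    if (!all(sec$kind %in% section_kinds())) fail("unknown section kind")
  }

  if (nrow(doc$tokens) > 0L) {
    tk <- dplyr::arrange(doc$tokens, .data$token_id)
    by_sent <- split(tk, tk$sentence_id)
    for (s in by_sent) {
      if (is.unsorted(s$start, strictly = TRUE)) {
        fail("tokens unordered within a sentence")
      }
      if (any(utils::head(s$end, -1) > utils::tail(s$start, -1))) {
        fail("tokens overlap")
      }
    }
    bad_lemma <- nzchar(tk$surface) & !is.na(tk$lemma) & !nzchar(tk$lemma)
    if (any(bad_lemma)) fail("empty lemma on non-empty surface")
  }

  en <- doc$entities
  if (nrow(en) > 0L) {
    if (!all(en$etype %in% c(observation_types(), modifier_types()))) {
      fail("unknown entity type")
    }
    if (anyDuplicated(en$entity_id)) fail("duplicate entity ids")
    for (cat in c("observation", "modifier")) {
      e <- dplyr::arrange(en[en$category == cat, ], .data$start)
      if (nrow(e) > 1L &&
        any(utils::head(e$end, -1) > utils::tail(e$start, -1))) {
        fail("overlapping ", cat, " entities")
      }
    }
    # cross-category overlap only as exact co-extension
    obs <- en[en$category == "observation", ]
    mod <- en[en$category == "modifier", ]
    if (nrow(obs) && nrow(mod)) {
      for (i in seq_len(nrow(mod))) {
        ov <- obs$start < mod$end[i] & obs$end > mod$start[i]
        co <- obs$start == mod$start[i] & obs$end == mod$end[i]
        if (any(ov & !co)) fail("partial observation/modifier overlap")
      }
    }
    nested <- en[!is.na(en$nested_with), ]
    for (i in seq_len(nrow(nested))) {
      p <- en[en$entity_id == nested$nested_with[i], ]
      if (nrow(p) != 1L) fail("nested_with refers to missing entity")
      if (!identical(p$nested_with, nested$entity_id[i])) {
        fail("nested_with is not symmetric")
      }
      if (p$start != nested$start[i] || p$end != nested$end[i]) {
        fail("nested entities not co-extensive")
      }
      if (p$category == nested$category[i]) {
        fail("nested entities must pair an observation with a modifier")
      }
    }
  }

  rl <- doc$relations
  if (nrow(rl) > 0L) {
    if (!all(rl$rtype %in% relation_types())) fail("unknown relation type")
    idx <- match(rl$observation, en$entity_id)
    jdx <- match(rl$modifier, en$entity_id)
    if (anyNA(idx) || anyNA(jdx)) fail("relation endpoint not in document")
    ot <- en$etype[idx]
    mt <- en$etype[jdx]
    ok_loc <- rl$rtype == "mod_loc" &
      ot %in% loc_compatible_observations() &
      mt %in% c("loc_deep", "loc_cortical")
    ok_time <- rl$rtype == "mod_time" &
      ot %in% time_compatible_observations() &
      mt %in% c("time_old", "time_recent")
    if (!all(ok_loc | ok_time)) fail("relation endpoint types incompatible")
    if (nrow(doc$tokens) > 0L || nrow(doc$sentences) > 0L) {
      so <- en$sentence_id[idx]
      sm <- en$sentence_id[jdx]
      if (any(!is.na(so) & !is.na(sm) & so != sm)) {
        fail("relation endpoints in different sentences")
      }
    }
  }

  lb <- doc$labels
  if (!identical(sort(lb$label), sort(label_inventory())) ||
    nrow(lb) != 24L) {
    fail("label list must contain exactly the 24-label inventory")
  }
  for (i in if (require_evidence) which(lb$selected) else integer()) {
    ev <- lb$evidence[[i]]
    if (length(ev) == 0L) fail("selected label without evidence")
    ev_ent <- intersect(ev, en$entity_id)
    if (length(ev_ent) == 0L) fail("selected label evidence has no entities")
    if (any(en$negated[match(ev_ent, en$entity_id)])) {
      fail("selected label cites negated evidence")
    }
  }
  invisible(TRUE)
}

#' Tidy accessors for annotated documents and corpora
#'
#' Return the annotation layers of a `rad_document`, or of a corpus tibble
#' holding documents in a `doc` list-column, as flat tibbles keyed by
#' `report_id`.
#'
#' @param x A `rad_document` or a corpus tibble with a `doc` column.
#' @return A tibble with one row per entity / relation / label / section.
#' @name accessors
NULL

corpus_docs <- function(x) {
  if (inherits(x, "rad_document")) {
    return(list(x))
  }
  if (is.data.frame(x)) {
    if ("doc" %in% names(x)) {
      return(x$doc)
    }
    if ("gold" %in% names(x)) {
      return(x$gold)
    }
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "rad_document"))) {
    return(x)
  }
  stop(
    "expected a rad_document, a list of them, or a corpus tibble with a ",
    "'doc' (or 'gold') column",
    call. = FALSE
  )
}

gather_layer <- function(x, component) {
  docs <- corpus_docs(x)
  purrr::map_dfr(docs, function(d) {
    tb <- d[[component]]
    dplyr::bind_cols(tibble(report_id = rep(d$report_id, nrow(tb))), tb)
  })
}

#' @rdname accessors
#' @export
entities <- function(x) gather_layer(x, "entities")

#' @rdname accessors
#' @export
relations <- function(x) gather_layer(x, "relations")

#' @rdname accessors
#' @export
report_labels <- function(x) {
  out <- gather_layer(x, "labels")
  out$evidence <- purrr::map(out$evidence, ~ if (is.null(.x)) character() else .x)
  out
}

#' @rdname accessors
#' @export
sections <- function(x) gather_layer(x, "sections")

#' @export
tidy.rad_document <- function(x, ...) {
  entities(x)
}

#' @export
glance.rad_document <- function(x, ...) {
  tibble(
    report_id = x$report_id,
    n_sections = nrow(x$sections),
    n_sentences = nrow(x$sentences),
    n_tokens = nrow(x$tokens),
    n_entities = nrow(x$entities),
    n_negated = sum(x$entities$negated),
    n_relations = nrow(x$relations),
    n_labels_selected = sum(x$labels$selected)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
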