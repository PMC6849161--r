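# BRAT standoff (.ann/.txt) writer and parser. Offsets are 0-based
# half-open over the emitted text, i.e. BRAT's native convention and the
# same convention the package uses internally, so no translation is
# involved.

brat_type_out <- function(etype) etype

brat_type_in <- function(x, line_no) {
  t <- canonical_type(x)
  if (!t %in% c(observation_types(), modifier_types())) {
    stop("brat parse error at line ", line_no, ": unknown type tag '", x,
      "'",
      call. = FALSE
    )
  }
  t
}

#' Write a document as a BRAT standoff pair
#'
#' Emits the raw text and an `.ann` annotation block: `T` lines for
#' entities (type, start, end, surface), `A` lines (`Negated`) for the
#' negation attribute, `R` lines for mod-loc / mod-time relations, and
#' `# label:` comment lines for the selected report-level labels (BRAT has
#' no native document-level labels; the parser reads these back, though
#' evidence pointers do not survive the round trip). Nested entity pairs
#' are implied by their co-extensive spans.
#'
#' @param doc An annotated `rad_document`.
#' @param dir Optional directory; when given, writes
#'   `<report_id>.txt` / `<report_id>.ann` there.
#' @return A list with elements `txt` and `ann` (single strings),
#'   invisibly when `dir` is given.
#' @export
write_brat <- function(doc, dir = NULL) {
  stopifnot(inherits(doc, "rad_document"))
  en <- doc$entities
  rl <- doc$relations
  dangling <- setdiff(c(rl$observation, rl$modifier), en$entity_id)
  if (length(dangling)) {
    stop("structural integrity error: relation endpoint(s) ",
      paste(dangling, collapse = ", "), " not present as entities",
      call. = FALSE
    )
  }
  lines <- character()
  id_map <- stats::setNames(paste0("T", seq_len(nrow(en))), en$entity_id)
  for (i in seq_len(nrow(en))) {
    lines <- c(lines, sprintf(
      "%s\t%s %d %d\t%s",
      id_map[en$entity_id[i]], brat_type_out(en$etype[i]),
      en$start[i], en$end[i],
      span_text(doc$text, en$start[i], en$end[i])
    ))
  }
  neg <- which(en$negated)
  lines <- c(lines, sprintf(
    "A%d\tNegated %s", seq_along(neg), id_map[en$entity_id[neg]]
  ))
  if (nrow(rl)) {
    lines <- c(lines, sprintf(
      "R%d\t%s Arg1:%s Arg2:%s",
      seq_len(nrow(rl)), sub("_", "-", rl$rtype),
      id_map[rl$observation], id_map[rl$modifier]
    ))
  }
  sel <- doc$labels$label[doc$labels$selected]
  lines <- c(lines, sprintf("# label: %s", sel))
  out <- list(
    txt = doc$text,
    ann = paste0(paste(lines, collapse = "\n"), if (length(lines)) "\n")
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeLines(out$txt, file.path(dir, paste0(doc$report_id, ".txt")),
      sep = ""
    )
    writeLines(out$ann, file.path(dir, paste0(doc$report_id, ".ann")),
      sep = ""
    )
    return(invisible(out))
  }
  out
}

#' Parse a BRAT standoff pair into a document
#'
#' Inverse of [write_brat()] on its image: reads `T`/`A`/`R` lines and
#' `# label:` comments. Span, reference and type errors are reported with
#' the offending line number. Parsed documents carry no token or section
#' layer, and selected labels carry no evidence pointers, so validate them
#' with `require_evidence = FALSE`; they are intended as gold-annotation
#' containers for the scorer.
#'
#' @param ann_text The `.ann` content (single string or lines).
#' @param txt_text The report text.
#' @param report_id Identifier for the resulting document.
#' @return A `rad_document`.
#' @export
parse_brat <- function(ann_text, txt_text, report_id = "report") {
  if (length(txt_text) > 1L) txt_text <- paste(txt_text, collapse = "\n")
  doc <- read_report(txt_text, report_id)
  lines <- if (length(ann_text) == 1L) {
    strsplit(ann_text, "\n", fixed = TRUE)[[1]]
  } else {
    ann_text
  }
  n <- nchar(txt_text)
  ent <- list()
  neg_ids <- character()
  rel <- list()
  sel_labels <- character()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, "#")) {
      m <- stringr::str_match(line, "^#\\s*label:\\s*(.+?)\\s*$")
      if (!is.na(m[1, 2])) {
        if (!m[1, 2] %in% label_inventory()) {
          stop("brat parse error at line ", ln, ": unknown label '",
            m[1, 2], "'",
            call. = FALSE
          )
        }
        sel_labels <- c(sel_labels, m[1, 2])
      }
      next
    }
    if (startsWith(line, "T")) {
      m <- stringr::str_match(
        line, "^(T[0-9]+)\t(\\S+) ([0-9]+) ([0-9]+)(\t(.*))?$"
      )
      if (is.na(m[1, 1])) {
        stop("brat parse error at line ", ln, ": malformed T line",
          call. = FALSE
        )
      }
      s <- as.integer(m[1, 4])
      e <- as.integer(m[1, 5])
      if (e <= s) {
        stop("brat parse error at line ", ln, ": end <= start",
          call. = FALSE
        )
      }
      if (s < 0L || e > n) {
        stop("brat parse error at line ", ln, ": offset outside text",
          call. = FALSE
        )
      }
      ent[[m[1, 2]]] <- tibble(
        entity_id = m[1, 2], etype = brat_type_in(m[1, 3], ln),
        start = s, end = e
      )
    } else if (startsWith(line, "A")) {
      m <- stringr::str_match(line, "^A[0-9]+\t(\\S+) (T[0-9]+)\\s*$")
      if (is.na(m[1, 1])) {
        stop("brat parse error at line ", ln, ": malformed A line",
          call. = FALSE
        )
      }
      if (is.null(ent[[m[1, 3]]])) {
        stop("brat parse error at line ", ln, ": attribute references ",
          "missing entity ", m[1, 3],
          call. = FALSE
        )
      }
      neg_ids <- c(neg_ids, m[1, 3])
    } else if (startsWith(line, "R")) {
      m <- stringr::str_match(
        line, "^R[0-9]+\t(\\S+) Arg1:(T[0-9]+) Arg2:(T[0-9]+)\\s*$"
      )
      if (is.na(m[1, 1])) {
        stop("brat parse error at line ", ln, ": malformed R line",
          call. = FALSE
        )
      }
      rt <- gsub("-", "_", m[1, 2])
      if (!rt %in% relation_types()) {
        stop("brat parse error at line ", ln, ": unknown relation type '",
          m[1, 2], "'",
          call. = FALSE
        )
      }
      if (is.null(ent[[m[1, 3]]]) || is.null(ent[[m[1, 4]]])) {
        stop("brat parse error at line ", ln, ": relation references ",
          "missing entity",
          call. = FALSE
        )
      }
      rel[[length(rel) + 1L]] <- tibble(
        rtype = rt, observation = m[1, 3], modifier = m[1, 4]
      )
    } else {
      stop("brat parse error at line ", ln, ": unrecognised line type",
        call. = FALSE
      )
    }
  }
  if (length(ent)) {
    en <- dplyr::bind_rows(ent)
    en$category <- entity_category(en$etype)
    en$text <- span_text(txt_text, en$start, en$end)
    en$negated <- en$entity_id %in% neg_ids
    en$nested_with <- NA_character_
    for (i in seq_len(nrow(en))) {
      if (en$category[i] != "modifier") next
      j <- which(en$category == "observation" &
        en$start == en$start[i] & en$end == en$end[i])
      if (length(j) == 1L) {
        en$nested_with[i] <- en$entity_id[j]
        en$nested_with[j] <- en$entity_id[i]
      }
    }
    en$sentence_id <- NA_integer_
    en$section_kind <- NA_character_
    doc$entities <- en[
      order(en$start, en$end, en$category),
      names(empty_entities())
    ]
  }
  if (length(rel)) {
    rl <- dplyr::bind_rows(rel)
    rl$relation_id <- paste0("R", seq_len(nrow(rl)))
    doc$relations <- rl[, names(empty_relations())]
  }
  doc$labels$selected <- doc$labels$label %in% sel_labels
  doc
}
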