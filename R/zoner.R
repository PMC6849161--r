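#' Default section-header table
#'
#' Maps line-initial headers (matched case-insensitively, optional trailing
#' colon) to section kinds. Hospital dialects vary, so the table is plain
#' data and can be replaced or extended; patterns are tried in order and
#' longer patterns win where one is a prefix of another.
#'
#' @return A tibble with columns `pattern` and `kind`.
#' @export
default_header_table <- function() {
  tibble::tribble(
    ~pattern, ~kind,
    "clinical details", "clinical_details",
    "clinical history", "clinical_details",
    "clinical indication", "clinical_details",
    "history", "clinical_details",
    "indication", "clinical_details",
    "report", "report_body",
    "findings", "report_body",
    "conclusions", "conclusion",
    "conclusion", "conclusion",
    "impression", "conclusion",
    "comment", "conclusion",
    "opinion", "conclusion",
    "summary", "conclusion"
  )
}

#' Read a header table from a TSV file
#'
#' Two tab-separated columns (`pattern`, `kind`); `#` lines are comments.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `pattern` and `kind`.
#' @export
read_header_table <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- stringr::str_split_fixed(lines, "\t", 2)
  tb <- tibble(
    pattern = trimws(parts[, 1]),
    kind = trimws(parts[, 2])
  )
  bad <- which(!tb$kind %in% section_kinds())
  if (length(bad)) {
    stop("header table line ", bad[1], ": unknown section kind '",
      tb$kind[bad[1]], "'",
      call. = FALSE
    )
  }
  tb
}

#' Zone a report into sections
#'
#' Splits the raw text into clinical-details, report-body and conclusion
#' sections by scanning for line-initial headers from `header_table`
#' (case-insensitive, optional colon). Every character ends up in exactly one
#' section; each header belongs to the section it opens. Text before the
#' first recognised header becomes `clinical_details` when no body header
#' precedes it, and a report with no recognisable headers becomes a single
#' `report_body` section. Zoning an already-zoned document is a no-op.
#'
#' @param doc A `rad_document` from [read_report()].
#' @param header_table Header-pattern table, see [default_header_table()].
#' @return The document with its `sections` tibble populated.
#' @examples
#' doc <- read_report("Report: Old infarct.\nConclusion: Established infarct.")
#' zone(doc)$sections
#' @export
zone <- function(doc, header_table = default_header_table()) {
  stopifnot(inherits(doc, "rad_document"))
  if (nrow(doc$sections) > 0L) {
    return(doc)
  }
  text <- doc$text
  n <- nchar(text)

  # find line-start offsets (0-based)
  nl <- stringr::str_locate_all(text, "\n")[[1]][, 1]
  line_starts <- c(0L, as.integer(nl)) # char after each newline
  hits <- list()
  pats <- header_table[order(-nchar(header_table$pattern)), ]
  for (ls in line_starts) {
    rest <- substr(text, ls + 1L, n)
    # skip leading spaces on the line
    ws <- stringr::str_match(rest, "^[ \t]*")[1, 1]
    at <- ls + nchar(ws)
    line <- substr(text, at + 1L, n)
    for (i in seq_len(nrow(pats))) {
      p <- pats$pattern[i]
      if (stringr::str_starts(
        line,
        stringr::regex(
          paste0(stringr::str_escape(p), "\\s*:"),
          ignore_case = TRUE
        )
      ) ||
        stringr::str_detect(
          line,
          stringr::regex(paste0("^", stringr::str_escape(p), "\\s*$"),
            ignore_case = TRUE
          )
        )) {
        hits[[length(hits) + 1L]] <- list(start = at, kind = pats$kind[i])
        break
      }
    }
  }

  if (length(hits) == 0L) {
    doc$sections <- tibble(
      section_id = 1L, kind = "report_body", start = 0L, end = n
    )
    return(doc)
  }

  starts <- vapply(hits, `[[`, integer(1), "start")
  kinds <- vapply(hits, `[[`, character(1), "kind")
  o <- order(starts)
  starts <- starts[o]
  kinds <- kinds[o]

  sec_starts <- starts
  sec_kinds <- kinds
  if (starts[1] > 0L && nzchar(trimws(substr(text, 1, starts[1])))) {
    # preamble before the first header: clinical details unless a body
    # header never follows it first
    pre_kind <- if (kinds[1] == "clinical_details") "other" else
      "clinical_details"
    sec_starts <- c(0L, sec_starts)
    sec_kinds <- c(pre_kind, sec_kinds)
  } else if (starts[1] > 0L) {
    sec_starts[1] <- 0L # absorb leading whitespace
  }
  ends <- c(utils::tail(sec_starts, -1), n)
  doc$sections <- tibble(
    section_id = seq_along(sec_starts),
    kind = sec_kinds,
    start = as.integer(sec_starts),
    end = as.integer(ends)
  )
  doc
}
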