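# Lexicon-driven entity recognition. Two passes (observations first, then
# modifiers); within a pass matches are maximal: longest match wins, ties
# broken leftmost. The modifier pass may lay a co-extensive modifier over an
# observation span (nested entities, e.g. "POCI" = ischaemic stroke +
# loc_cortical); partial overlaps with an observation are suppressed in
# favour of the observation.

# does lexicon entry token `p` match document token row `tok`?
entry_token_matches <- function(p, mode, lemma, surface_lower) {
  if (mode == "literal") {
    return(tolower(p) == surface_lower)
  }
  p == lemma | p == surface_lower
}

# all candidate matches of `entries` against one sentence's tokens
# returns tibble(first, last, etype, len) in token indices (within sentence)
candidate_matches <- function(entries, lemmas, surfaces_lower) {
  n <- length(lemmas)
  out <- list()
  for (i in seq_len(nrow(entries))) {
    toks <- entries$tokens[[i]]
    k <- length(toks)
    if (k == 0L || k > n) next
    mode <- entries$mode[i]
    for (s in seq_len(n - k + 1L)) {
      ok <- TRUE
      for (j in seq_len(k)) {
        if (!entry_token_matches(
          toks[j], mode, lemmas[s + j - 1L], surfaces_lower[s + j - 1L]
        )) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        out[[length(out) + 1L]] <- c(s, s + k - 1L, i)
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(
      first = integer(), last = integer(),
      etype = character(), len = integer()
    ))
  }
  m <- do.call(rbind, out)
  tibble(
    first = m[, 1], last = m[, 2],
    etype = entries$etype[m[, 3]],
    len = m[, 2] - m[, 1] + 1L
  )
}

# greedy longest-match selection; `blocked` is an optional tibble of spans
# that candidates may not partially overlap (exact co-extension allowed)
select_matches <- function(cand, blocked = NULL) {
  if (nrow(cand) == 0L) {
    return(cand)
  }
  cand <- cand[order(-cand$len, cand$first, cand$etype), ]
  chosen <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    c1 <- cand$first[i]
    c2 <- cand$last[i]
    if (nrow(chosen) > 0L &&
      any(chosen$first <= c2 & chosen$last >= c1)) {
      next
    }
    if (!is.null(blocked) && nrow(blocked) > 0L) {
      ov <- blocked$first <= c2 & blocked$last >= c1
      co <- blocked$first == c1 & blocked$last == c2
      if (any(ov & !co)) next
    }
    chosen <- dplyr::bind_rows(chosen, cand[i, ])
  }
  dplyr::arrange(chosen, .data$first)
}

#' Recognise observation and modifier entities
#'
#' Runs lexical lookup over the lemmatised tokens: first the observations
#' lexicon, then the modifiers. Within each pass matches are maximal and
#' non-overlapping (longest wins, ties leftmost); a modifier match exactly
#' co-extensive with an observation creates a nested entity pair, while a
#' partially overlapping modifier match is suppressed in favour of the
#' observation. Matching is deterministic and independent of lexicon file
#' order. Entity ids are assigned in reading order (`T1`, `T2`, ...).
#'
#' @param doc A lemmatised `rad_document`.
#' @param lexicons As returned by [load_lexicons()].
#' @return The document with its `entities` tibble populated (negation
#'   flags all `FALSE` at this stage).
#' @examples
#' doc <- read_report("Old thalamic infarcts.") |>
#'   zone() |> tokenize() |> pos_tag() |> lemmatise() |>
#'   match_entities()
#' doc$entities[, c("entity_id", "etype", "text")]
#' @export
match_entities <- function(doc, lexicons = load_lexicons()) {
  stopifnot(inherits(doc, "rad_document"))
  if (nrow(doc$tokens) == 0L) {
    return(doc)
  }
  sec_kind <- doc$sections$kind[match(
    doc$sentences$section_id, doc$sections$section_id
  )]
  rows <- list()
  for (k in seq_len(nrow(doc$sentences))) {
    sid <- doc$sentences$sentence_id[k]
    tk <- doc$tokens[doc$tokens$sentence_id == sid, ]
    if (nrow(tk) == 0L) next
    lem <- tk$lemma
    low <- tolower(tk$surface)

    obs <- select_matches(candidate_matches(lexicons$observations, lem, low))
    mod <- select_matches(
      candidate_matches(lexicons$modifiers, lem, low),
      blocked = obs
    )
    if (nrow(obs) == 0L && nrow(mod) == 0L) next
    mk <- function(m, category) {
      if (nrow(m) == 0L) {
        return(NULL)
      }
      tibble(
        etype = m$etype, category = category,
        start = tk$start[m$first], end = tk$end[m$last],
        sentence_id = sid, section_kind = sec_kind[k]
      )
    }
    rows[[length(rows) + 1L]] <- dplyr::bind_rows(
      mk(obs, "observation"), mk(mod, "modifier")
    )
  }
  if (length(rows) == 0L) {
    doc$entities <- empty_entities()
    return(doc)
  }
  en <- dplyr::bind_rows(rows)
  # reading order: by start, observations before a co-extensive modifier
  en <- en[order(en$start, en$end, en$category), ]
  en$entity_id <- paste0("T", seq_len(nrow(en)))
  en$text <- span_text(doc$text, en$start, en$end)
  en$negated <- FALSE
  en$nested_with <- NA_character_
  # co-extensive observation+modifier pairs are nested
  for (i in seq_len(nrow(en))) {
    if (en$category[i] != "modifier") next
    j <- which(en$category == "observation" &
      en$start == en$start[i] & en$end == en$end[i])
    if (length(j) == 1L) {
      en$nested_with[i] <- en$entity_id[j]
      en$nested_with[j] <- en$entity_id[i]
    }
  }
  doc$entities <- en[, names(empty_entities())]
  # record lookup flags on tokens covered by entities
  doc$tokens$lookup <- NA_character_
  for (i in seq_len(nrow(en))) {
    hit <- doc$tokens$start < en$end[i] & doc$tokens$end > en$start[i]
    doc$tokens$lookup[hit] <- ifelse(
      is.na(doc$tokens$lookup[hit]), en$etype[i],
      paste(doc$tokens$lookup[hit], en$etype[i], sep = ";")
    )
  }
  doc
}
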