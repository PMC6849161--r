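# Shallow chunking into noun groups and verb groups, and the negation
# rules that operate over them: a negative determiner propagates through
# its (possibly coordinated) noun group; hedged non-exclusions ("cannot be
# excluded") mark the findings in their scope as negative.

noun_tags <- c("NN", "NNS", "NNP", "NNPS")
adj_tags <- c("JJ", "JJR", "JJS", "CD")
verb_tags <- c("MD", "VB", "VBZ", "VBP", "VBD", "VBN", "VBG")

#' Chunk a tagged report into noun and verb groups
#'
#' Maximal noun groups cover an optional determiner, premodifying
#' adjectives, and one or more head nouns, and extend through coordination
#' (commas, "and", "or") to further noun heads, so that "No acute
#' haemorrhage, masses or extra-axial collections" is a single noun group.
#' Verb groups cover auxiliaries, modals, internal adverbs and verb forms
#' ("may not be", "cannot be completely excluded"). Everything else becomes
#' an `other` chunk. Chunks are non-overlapping and ordered within each
#' sentence.
#'
#' @param doc A POS-tagged (and usually lemmatised) `rad_document`.
#' @return The document with its `chunks` tibble populated.
#' @export
chunk <- function(doc) {
  stopifnot(inherits(doc, "rad_document"))
  if (nrow(doc$tokens) == 0L) {
    return(doc)
  }
  rows <- list()
  cid <- 0L
  for (sid in unique(doc$tokens$sentence_id)) {
    tk <- doc$tokens[doc$tokens$sentence_id == sid, ]
    tags <- tk$pos
    low <- tolower(tk$surface)
    n <- nrow(tk)
    i <- 1L
    add <- function(kind, from, to) {
      cid <<- cid + 1L
      rows[[cid]] <<- tibble(
        chunk_id = cid, sentence_id = sid, kind = kind,
        token_start = tk$token_id[from], token_end = tk$token_id[to],
        polarity = "positive"
      )
    }
    # a nominal run starting at j: DT? (JJ|NN)* ; returns end index and
    # whether it contains a noun head, or NULL
    nominal_run <- function(j, allow_dt = TRUE) {
      k <- j
      if (allow_dt && k <= n && tags[k] == "DT") k <- k + 1L
      has_noun <- FALSE
      while (k <= n && (tags[k] %in% adj_tags || tags[k] %in% noun_tags)) {
        if (tags[k] %in% noun_tags) has_noun <- TRUE
        k <- k + 1L
      }
      if (k == j) {
        return(NULL)
      }
      list(to = k - 1L, has_noun = has_noun)
    }
    while (i <= n) {
      t <- tags[i]
      if (t == "DT" || t %in% adj_tags || t %in% noun_tags) {
        run <- nominal_run(i)
        j <- run$to
        if (run$has_noun) {
          # coordination: (, | and | or | , and | , or) + nominal run
          repeat {
            k <- j + 1L
            if (k <= n && low[k] == ",") k <- k + 1L
            if (k <= n && tags[k] == "CC" && low[k] %in% c("and", "or")) {
              k <- k + 1L
            }
            if (k == j + 1L) break # no separator consumed
            nxt <- nominal_run(k)
            if (is.null(nxt) || !nxt$has_noun) break
            j <- nxt$to
          }
          add("noun_group", i, j)
        } else {
          add("other", i, j)
        }
        i <- j + 1L
      } else if (t %in% verb_tags ||
        (t == "RB" && i < n && tags[i + 1L] %in% verb_tags)) {
        j <- i
        has_verb <- FALSE
        while (j <= n && (tags[j] %in% verb_tags || tags[j] == "RB" ||
          tags[j] == "TO")) {
          if (tags[j] %in% verb_tags) has_verb <- TRUE
          j <- j + 1L
        }
        add(if (has_verb) "verb_group" else "other", i, j - 1L)
        i <- j
      } else {
        add("other", i, i)
        i <- i + 1L
      }
    }
  }
  doc$chunks <- if (length(rows)) dplyr::bind_rows(rows) else empty_chunks()
  doc
}

# ---- helpers shared by the negation rules ------------------------------

# token index range (token_ids) covered by each entity
entity_token_range <- function(doc) {
  en <- doc$entities
  tk <- doc$tokens
  first <- integer(nrow(en))
  last <- integer(nrow(en))
  for (i in seq_len(nrow(en))) {
    hit <- tk$token_id[tk$start < en$end[i] & tk$end > en$start[i]]
    first[i] <- if (length(hit)) min(hit) else NA_integer_
    last[i] <- if (length(hit)) max(hit) else NA_integer_
  }
  tibble(first = first, last = last)
}

# chunk row index containing each entity's first token
entity_chunk <- function(doc, ranges = entity_token_range(doc)) {
  ch <- doc$chunks
  vapply(seq_len(nrow(doc$entities)), function(i) {
    j <- which(ch$token_start <= ranges$first[i] &
      ch$token_end >= ranges$first[i] &
      ch$sentence_id == doc$entities$sentence_id[i])
    if (length(j)) j[1] else NA_integer_
  }, integer(1))
}

# negate entities lying inside the given chunk rows; nested pairs stay in
# step (negation is monotone: flags are only ever set, never cleared here)
negate_in_chunks <- function(doc, chunk_rows) {
  if (length(chunk_rows) == 0L || nrow(doc$entities) == 0L) {
    return(doc)
  }
  rng <- entity_token_range(doc)
  for (j in chunk_rows) {
    ch <- doc$chunks[j, ]
    inside <- !is.na(rng$first) &
      doc$entities$sentence_id == ch$sentence_id &
      rng$first >= ch$token_start & rng$last <= ch$token_end
    doc$entities$negated[inside] <- TRUE
  }
  sync_nested_negation(doc)
}

sync_nested_negation <- function(doc) {
  en <- doc$entities
  for (i in which(!is.na(en$nested_with) & en$negated)) {
    en$negated[en$entity_id == en$nested_with[i]] <- TRUE
  }
  doc$entities <- en
  doc
}

# find occurrences of multi-token cue patterns in a sentence; a pattern
# token matches a document token's lemma or lowercase surface
find_cue_matches <- function(patterns, lemmas, lows) {
  n <- length(lemmas)
  out <- list()
  for (i in seq_len(nrow(patterns))) {
    toks <- patterns$tokens[[i]]
    k <- length(toks)
    if (k == 0L || k > n) next
    for (s in seq_len(n - k + 1L)) {
      ok <- all(vapply(seq_len(k), function(j) {
        toks[j] == lemmas[s + j - 1L] || toks[j] == lows[s + j - 1L]
      }, logical(1)))
      if (ok) out[[length(out) + 1L]] <- c(s, s + k - 1L, i)
    }
  }
  if (length(out) == 0L) {
    return(NULL)
  }
  m <- do.call(rbind, out)
  # drop matches contained in a longer match (e.g. "cannot be excluded"
  # inside "cannot be completely excluded")
  keep <- rep(TRUE, nrow(m))
  for (a in seq_len(nrow(m))) {
    for (b in seq_len(nrow(m))) {
      if (a != b && keep[b] &&
        m[b, 1] <= m[a, 1] && m[b, 2] >= m[a, 2] &&
        (m[b, 2] - m[b, 1]) > (m[a, 2] - m[a, 1])) {
        keep[a] <- FALSE
      }
    }
  }
  m[keep, , drop = FALSE]
}

# noun-group chunk rows forming the contiguous chain to the left/right of
# sentence-local token position `pos`, stopping at a verb group
ng_chain <- function(doc, sid, from_tok, to_tok) {
  ch_idx <- which(doc$chunks$sentence_id == sid)
  ch <- doc$chunks[ch_idx, ]
  left <- integer()
  for (j in rev(which(ch$token_end < from_tok))) {
    if (ch$kind[j] == "verb_group") break
    if (ch$kind[j] == "noun_group") left <- c(left, ch_idx[j])
  }
  right <- integer()
  for (j in which(ch$token_start > to_tok)) {
    if (ch$kind[j] == "verb_group") break
    if (ch$kind[j] == "noun_group") right <- c(right, ch_idx[j])
  }
  c(left, right)
}

#' Propagate negative determiners through noun groups
#'
#' Every entity whose span lies inside a noun group opened by a negative
#' cue ("no", "not", "without", "absence of", ...) is marked negated,
#' including entities after coordinating commas and conjunctions within the
#' same group: in "No acute haemorrhage, masses or extra-axial collections"
#' all three observations come out negative. A cue immediately preceding a
#' noun group (prepositional cues like "without") negates that group. The
#' scope of a cue is its own noun group only; long-distance negation is a
#' documented limitation.
#'
#' @param doc A chunked `rad_document` with entities.
#' @param cues Cue table from [load_cues()]; only `negation` rows are used.
#' @return The document with entity `negated` flags updated, with the
#'   affected noun groups' `polarity` set to `"negative"`.
#' @export
apply_noun_group_negation <- function(doc, cues = load_cues()) {
  stopifnot(inherits(doc, "rad_document"))
  neg <- cues[cues$cue_type == "negation", ]
  if (nrow(doc$chunks) == 0L || nrow(doc$entities) == 0L) {
    return(doc)
  }
  hit_chunks <- integer()
  for (sid in unique(doc$tokens$sentence_id)) {
    tk <- doc$tokens[doc$tokens$sentence_id == sid, ]
    m <- find_cue_matches(neg, tk$lemma, tolower(tk$surface))
    if (is.null(m)) next
    ch_idx <- which(doc$chunks$sentence_id == sid)
    ch <- doc$chunks[ch_idx, ]
    for (r in seq_len(nrow(m))) {
      cue_first <- tk$token_id[m[r, 1]]
      cue_last <- tk$token_id[m[r, 2]]
      # noun group containing the cue
      j <- which(ch$kind == "noun_group" &
        ch$token_start <= cue_first & ch$token_end >= cue_last)
      if (length(j) == 0L) {
        # or the noun group starting right after the cue
        j <- which(ch$kind == "noun_group" & ch$token_start == cue_last + 1L)
      }
      if (length(j)) hit_chunks <- c(hit_chunks, ch_idx[j[1]])
    }
  }
  hit_chunks <- unique(hit_chunks)
  doc$chunks$polarity[hit_chunks] <- "negative"
  negate_in_chunks(doc, hit_chunks)
}

#' Mark hedged non-exclusions as negative
#'
#' Findings that are merely "not excluded" ("a small focus of acute infarct
#' cannot be completely excluded") are not clearly positive, so the scheme
#' records them as negative. Entities in the hedge's scope -- the chain of
#' noun groups on either side of the hedge, bounded by neighbouring verb
#' groups -- get `negated = TRUE`.
#'
#' @param doc A chunked `rad_document` with entities.
#' @param cues Cue table from [load_cues()]; only `hedge` rows are used.
#' @return The document with entity `negated` flags updated.
#' @export
apply_hedge_negation <- function(doc, cues = load_cues()) {
  stopifnot(inherits(doc, "rad_document"))
  hed <- cues[cues$cue_type == "hedge", ]
  if (nrow(doc$chunks) == 0L || nrow(doc$entities) == 0L) {
    return(doc)
  }
  scope <- integer()
  for (sid in unique(doc$tokens$sentence_id)) {
    tk <- doc$tokens[doc$tokens$sentence_id == sid, ]
    m <- find_cue_matches(hed, tk$lemma, tolower(tk$surface))
    if (is.null(m)) next
    for (r in seq_len(nrow(m))) {
      scope <- c(scope, ng_chain(
        doc, sid, tk$token_id[m[r, 1]], tk$token_id[m[r, 2]]
      ))
    }
  }
  negate_in_chunks(doc, unique(scope))
}
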