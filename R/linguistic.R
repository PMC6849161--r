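# Tokenisation, sentence splitting, POS tagging with two-tagger
# reconciliation, and lemmatisation. Tags are Penn-Treebank style; the
# downstream chunker keys on them.

abbreviations <- c(
  "e.g", "i.e", "etc", "vs", "cf", "dr", "mr", "mrs", "ms", "prof",
  "approx", "no", "fig"
)

token_pattern <- "[A-Za-z0-9]+(?:[-'][A-Za-z0-9]+)*|[^\\sA-Za-z0-9]"

# split one section's text (0-based section start `off`) into sentence spans
split_sentences <- function(text, off) {
  n <- nchar(text)
  if (!nzchar(trimws(text))) {
    return(integer(0))
  }
  # candidate boundary: sentence-final punctuation followed by whitespace,
  # or a newline (dictated reports use newline-terminated lines)
  ends <- integer()
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "\n") {
      ends <- c(ends, i)
    } else if (ch %in% c(".", "?", "!")) {
      nxt <- if (i < n) chars[i + 1L] else " "
      if (grepl("^\\s$", nxt) || i == n) {
        # look back for an abbreviation: word chars and dots up to whitespace
        j <- i - 1L
        while (j >= 1L && grepl("[A-Za-z0-9.]", chars[j])) j <- j - 1L
        prev <- tolower(substr(text, j + 1L, i - 1L))
        is_abbrev <- ch == "." &&
          (prev %in% abbreviations || grepl("^[a-z]$", prev) ||
            grepl("^[a-z]\\.[a-z]*$", prev))
        if (!is_abbrev) ends <- c(ends, i)
      }
    }
    i <- i + 1L
  }
  ends <- sort(unique(c(ends, n)))
  starts <- c(1L, utils::head(ends, -1) + 1L)
  spans <- list()
  for (k in seq_along(starts)) {
    s <- starts[k]
    e <- ends[k]
    seg <- substr(text, s, e)
    lead <- nchar(stringr::str_match(seg, "^\\s*")[1, 1])
    trail <- nchar(stringr::str_match(seg, "\\s*$")[1, 1])
    s2 <- s + lead
    e2 <- e - trail
    if (s2 <= e2) spans[[length(spans) + 1L]] <- c(s2, e2)
  }
  # convert to 0-based half-open document offsets
  vapply(spans, function(sp) c(off + sp[1] - 1L, off + sp[2]), integer(2))
}

#' Tokenise a zoned report
#'
#' Splits each section into sentences and word tokens. Punctuation
#' characters are emitted as standalone tokens; hyphenated compounds such as
#' "extra-axial" are kept as single tokens; a short abbreviation list
#' ("e.g.", "i.e.", single letters, ...) prevents spurious sentence breaks;
#' newlines always end a sentence, matching the short dictated lines common
#' in radiology reports. Sentences never cross section boundaries.
#'
#' @param doc A zoned `rad_document`.
#' @return The document with `sentences` and `tokens` populated.
#' @examples
#' doc <- tokenize(zone(read_report("No acute haemorrhage, masses seen.")))
#' doc$tokens$surface
#' @export
tokenize <- function(doc) {
  stopifnot(inherits(doc, "rad_document"))
  if (nrow(doc$sections) == 0L) {
    stop("tokenize: document must be zoned first", call. = FALSE)
  }
  sent_rows <- list()
  tok_rows <- list()
  sid <- 0L
  tid <- 0L
  for (i in seq_len(nrow(doc$sections))) {
    sec <- doc$sections[i, ]
    sec_text <- span_text(doc$text, sec$start, sec$end)
    spans <- split_sentences(sec_text, sec$start)
    if (length(spans) == 0L) next
    for (k in seq_len(ncol(spans))) {
      sid <- sid + 1L
      s0 <- spans[1, k]
      s1 <- spans[2, k]
      sent_rows[[sid]] <- tibble(
        sentence_id = sid, section_id = sec$section_id,
        start = s0, end = s1
      )
      stext <- span_text(doc$text, s0, s1)
      loc <- stringr::str_locate_all(stext, token_pattern)[[1]]
      if (nrow(loc) == 0L) next
      tok_rows[[length(tok_rows) + 1L]] <- tibble(
        token_id = tid + seq_len(nrow(loc)),
        sentence_id = sid,
        start = s0 + loc[, 1] - 1L,
        end = s0 + loc[, 2],
        surface = stringr::str_sub(stext, loc[, 1], loc[, 2]),
        pos = NA_character_,
        lemma = NA_character_,
        lookup = NA_character_
      )
      tid <- tid + nrow(loc)
    }
  }
  doc$sentences <- if (length(sent_rows)) dplyr::bind_rows(sent_rows) else
    empty_sentences()
  doc$tokens <- if (length(tok_rows)) dplyr::bind_rows(tok_rows) else
    empty_tokens()
  doc$tokens$start <- as.integer(doc$tokens$start)
  doc$tokens$end <- as.integer(doc$tokens$end)
  doc
}

# ---- POS taggers --------------------------------------------------------

closed_class_tags <- function() {
  c(
    "the" = "DT", "a" = "DT", "an" = "DT", "no" = "DT", "this" = "DT",
    "that" = "DT", "these" = "DT", "those" = "DT", "any" = "DT",
    "some" = "DT", "each" = "DT", "both" = "DT", "either" = "DT",
    "of" = "IN", "in" = "IN", "on" = "IN", "at" = "IN", "with" = "IN",
    "within" = "IN", "without" = "IN", "for" = "IN", "from" = "IN",
    "by" = "IN", "into" = "IN", "near" = "IN", "over" = "IN",
    "under" = "IN", "throughout" = "IN", "around" = "IN", "as" = "IN",
    "than" = "IN", "secondary" = "JJ", "to" = "TO",
    "and" = "CC", "or" = "CC", "but" = "CC", "nor" = "CC",
    "may" = "MD", "might" = "MD", "can" = "MD", "cannot" = "MD",
    "could" = "MD", "should" = "MD", "would" = "MD", "will" = "MD",
    "must" = "MD", "shall" = "MD",
    "not" = "RB", "n't" = "RB", "very" = "RB", "completely" = "RB",
    "entirely" = "RB", "probably" = "RB", "possibly" = "RB",
    "likely" = "RB", "previously" = "RB", "also" = "RB", "now" = "RB",
    "again" = "RB", "only" = "RB",
    "is" = "VBZ", "are" = "VBP", "was" = "VBD", "were" = "VBD",
    "be" = "VB", "been" = "VBN", "being" = "VBG", "am" = "VBP",
    "has" = "VBZ", "have" = "VBP", "had" = "VBD",
    "does" = "VBZ", "do" = "VBP", "did" = "VBD",
    "there" = "EX", "it" = "PRP", "which" = "WDT", "who" = "WP",
    "he" = "PRP", "she" = "PRP", "they" = "PRP",
    "exclude" = "VB", "suggest" = "VBP", "suggests" = "VBZ",
    "represent" = "VBP", "represents" = "VBZ", "indicate" = "VBP",
    "indicates" = "VBZ", "shows" = "VBZ", "show" = "VBP",
    "appear" = "VBP", "appears" = "VBZ", "remain" = "VBP",
    "remains" = "VBZ", "see" = "VB", "seen" = "VBN", "note" = "VB",
    "lie" = "VBP", "lies" = "VBZ"
  )
}

adjective_list <- function() {
  c(
    "acute", "old", "recent", "new", "chronic", "longstanding", "mature",
    "fresh", "early", "late", "deep", "cortical", "lobar", "subcortical",
    "subdural", "subarachnoid", "extradural", "small", "large", "tiny",
    "extensive", "mild", "moderate", "severe", "marked", "significant",
    "ischaemic", "haemorrhagic", "established", "previous", "lacunar",
    "thalamic", "pontine", "cerebellar", "periventricular", "extra-axial",
    "intracranial", "intracerebral", "focal", "diffuse", "generalised",
    "generalized", "bilateral", "unilateral", "left", "right", "visible",
    "several", "few", "multiple", "scattered", "prominent", "aneurysmal",
    "metastatic", "consistent", "sudden", "further", "low", "high",
    "patchy", "widespread", "ruptured", "stable", "normal"
  )
}

#' Built-in part-of-speech taggers
#'
#' Both taggers satisfy the tagger contract: a function from a character
#' vector of token surfaces to an equal-length vector of Penn-Treebank-style
#' tags. `tag_general()` is a closed-class plus suffix-rule tagger for
#' general English; `tag_clinical()` overrides it on tokens found in the
#' clinical lexicons (modifier surfaces are tagged JJ, observation heads NN),
#' standing in for a biomedical tagging model.
#'
#' @param surfaces Character vector of token surfaces.
#' @param lexicon_terms Optional character vector of single-token clinical
#'   lexicon surfaces used by the clinical tagger; defaults to the terms of
#'   the shipped lexicons.
#' @return A character vector of tags, same length as `surfaces`.
#' @examples
#' tag_general(c("No", "acute", "infarct", "."))
#' @name taggers
NULL

#' @rdname taggers
#' @export
tag_general <- function(surfaces) {
  cc <- closed_class_tags()
  adj <- adjective_list()
  vapply(surfaces, function(w) {
    lw <- tolower(w)
    if (!is.na(cc[lw])) {
      return(unname(cc[lw]))
    }
    if (grepl("^[^A-Za-z0-9]$", w)) {
      return(if (w %in% c(".", ",", ":", ";")) w else "SYM")
    }
    if (grepl("^[0-9]+([.,][0-9]+)?$", w)) {
      return("CD")
    }
    if (lw %in% adj) {
      return("JJ")
    }
    if (grepl("^[A-Z0-9][A-Z0-9-]+$", w)) {
      return("NNP") # acronyms: CT, MRI, POCI
    }
    if (grepl("ly$", lw)) {
      return("RB")
    }
    if (grepl("(ing)$", lw) && nchar(lw) > 4) {
      return("VBG")
    }
    if (grepl("(ed)$", lw) && nchar(lw) > 3) {
      return("VBN")
    }
    if (grepl("(ic|al|ous|ar|ive|able|ible)$", lw) && nchar(lw) > 4) {
      return("JJ")
    }
    if (grepl("s$", lw) && !grepl("(ss|us|is)$", lw) && nchar(lw) > 2) {
      return("NNS")
    }
    "NN"
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname taggers
#' @export
tag_clinical <- function(surfaces, lexicon_terms = NULL) {
  if (is.null(lexicon_terms)) lexicon_terms <- default_lexicon_terms()
  base <- tag_general(surfaces)
  lw <- tolower(surfaces)
  mods <- lexicon_terms$modifier
  obs <- lexicon_terms$observation
  out <- base
  out[lw %in% mods] <- "JJ"
  hit_obs <- lw %in% obs
  out[hit_obs] <- ifelse(grepl("s$", lw[hit_obs]) &
    !grepl("(ss|us|is)$", lw[hit_obs]), "NNS", "NN")
  # medical noun suffixes
  suffix_nn <- grepl("(oma|osis|itis|pathy|rrhage|rhage)$", lw)
  out[suffix_nn] <- "NN"
  out
}

# single-token surfaces and lemmas of the shipped lexicons, split by category
default_lexicon_terms <- function() {
  lex <- load_lexicons()
  all <- dplyr::bind_rows(
    dplyr::mutate(lex$observations, cat = "observation"),
    dplyr::mutate(lex$modifiers, cat = "modifier")
  )
  singles <- all[lengths(all$tokens) == 1L, ]
  list(
    observation = tolower(unlist(
      singles$tokens[singles$cat == "observation"]
    )),
    modifier = tolower(unlist(singles$tokens[singles$cat == "modifier"]))
  )
}

#' Default tagger-reconciliation rule
#'
#' Where the two taggers disagree, prefer the clinical (biomedical) tagger's
#' tag for tokens whose surface or lemma appears in the clinical lexicons,
#' otherwise keep the general tagger's tag. Returns a resolved tag for every
#' disagreement (the rule is total).
#'
#' @param surfaces,tags_a,tags_b Token surfaces and the two tag sequences.
#' @param lexicon_terms As in [tag_clinical()].
#' @return A character vector of resolved tags.
#' @export
reconcile_default <- function(surfaces, tags_a, tags_b,
                              lexicon_terms = NULL) {
  if (is.null(lexicon_terms)) lexicon_terms <- default_lexicon_terms()
  known <- tolower(surfaces) %in%
    c(lexicon_terms$observation, lexicon_terms$modifier) |
    lemmatise_words(tolower(surfaces), tags_b) %in%
      c(lexicon_terms$observation, lexicon_terms$modifier)
  ifelse(tags_a == tags_b, tags_a, ifelse(known, tags_b, tags_a))
}

#' Part-of-speech tag a tokenised report
#'
#' Runs a general and a biomedical tagger over each sentence and reconciles
#' disagreements with a preference rule (see [reconcile_default()]). With
#' `tagger_biomedical = NULL` the general tagger's tags pass through
#' unchanged.
#'
#' @param doc A tokenised `rad_document`.
#' @param tagger_general,tagger_biomedical Functions from surface vector to
#'   tag vector (the tagger contract). A tagger returning a vector of the
#'   wrong length is a contract violation and raises an error.
#' @param reconcile Reconciliation function
#'   `(surfaces, tags_a, tags_b) -> tags`.
#' @return The document with `tokens$pos` filled.
#' @export
pos_tag <- function(doc, tagger_general = tag_general,
                    tagger_biomedical = tag_clinical,
                    reconcile = reconcile_default) {
  stopifnot(inherits(doc, "rad_document"))
  if (nrow(doc$tokens) == 0L) {
    return(doc)
  }
  surf <- doc$tokens$surface
  ta <- tagger_general(surf)
  if (length(ta) != length(surf)) {
    stop("tagger contract violation: output length ", length(ta),
      " != input length ", length(surf),
      call. = FALSE
    )
  }
  if (is.null(tagger_biomedical)) {
    doc$tokens$pos <- ta
    return(doc)
  }
  tb <- tagger_biomedical(surf)
  if (length(tb) != length(surf)) {
    stop("tagger contract violation: output length ", length(tb),
      " != input length ", length(surf),
      call. = FALSE
    )
  }
  doc$tokens$pos <- reconcile(surf, ta, tb)
  doc
}

# ---- lemmatisation ------------------------------------------------------

irregular_lemmas <- c(
  "metastases" = "metastasis", "foci" = "focus", "thrombi" = "thrombus",
  "nuclei" = "nucleus", "gyri" = "gyrus", "sulci" = "sulcus",
  "ventricles" = "ventricle", "seen" = "see", "saw" = "see",
  "was" = "be", "were" = "be", "is" = "be", "are" = "be", "am" = "be",
  "been" = "be", "being" = "be", "has" = "have", "had" = "have",
  "did" = "do", "does" = "do", "shown" = "show", "showed" = "show",
  "found" = "find", "men" = "man", "women" = "woman", "feet" = "foot"
)

singularise <- function(w) {
  if (!is.na(irregular_lemmas[w])) {
    return(unname(irregular_lemmas[w]))
  }
  if (grepl("ies$", w) && nchar(w) > 4) {
    return(sub("ies$", "y", w))
  }
  if (grepl("(ch|sh|ss|x|z)es$", w)) {
    return(sub("es$", "", w))
  }
  if (grepl("ses$", w) && nchar(w) > 4) {
    return(sub("s$", "", w)) # masses -> masse? no: handled above by sses
  }
  if (grepl("s$", w) && !grepl("(ss|us|is)$", w) && nchar(w) > 2) {
    return(sub("s$", "", w))
  }
  w
}

verb_stem <- function(w) {
  if (!is.na(irregular_lemmas[w])) {
    return(unname(irregular_lemmas[w]))
  }
  if (grepl("ied$", w) && nchar(w) > 4) {
    return(sub("ied$", "y", w))
  }
  if (grepl("ed$", w) && nchar(w) > 3) {
    # prefer restoring a stem-final e (noted -> note, excluded -> exclude)
    stem_e <- sub("d$", "", w)
    stem <- sub("ed$", "", w)
    if (grepl("[^aeiou]e$", stem_e) || grepl("[aeiou][^aeiou]e$", stem_e)) {
      return(stem_e)
    }
    # doubled final consonant (scanned -> scan)
    if (grepl("([b-df-hj-np-tv-z])\\1$", stem)) {
      return(sub(".$", "", stem))
    }
    return(stem)
  }
  if (grepl("ing$", w) && nchar(w) > 5) {
    stem <- sub("ing$", "", w)
    if (grepl("([b-df-hj-np-tv-z])\\1$", stem)) {
      return(sub(".$", "", stem))
    }
    if (grepl("[^aeiou][bcdfgkstvz]$", stem) &&
      !grepl("[aeiou]{2}[^aeiou]$", stem)) {
      return(paste0(stem, "e")) # involving -> involve
    }
    return(stem)
  }
  if (grepl("(ch|sh|ss|x|z)es$", w)) {
    return(sub("es$", "", w))
  }
  if (grepl("s$", w) && !grepl("(ss|us|is)$", w) && nchar(w) > 2) {
    return(sub("s$", "", w))
  }
  w
}

# vectorised lemma computation given tags; always lowercase
lemmatise_words <- function(surfaces, tags) {
  lw <- tolower(surfaces)
  out <- lw
  for (i in seq_along(lw)) {
    t <- tags[i]
    if (is.na(t)) next
    if (t %in% c("NNS")) {
      out[i] <- singularise(lw[i])
    } else if (t %in% c("VBD", "VBN", "VBZ", "VBG", "VBP", "VB")) {
      out[i] <- verb_stem(lw[i])
    }
  }
  out
}

#' Lemmatise a tagged report
#'
#' Computes a lowercase morphological stem for every token: plural nouns are
#' singularised and inflected verbs reduced to their base form via suffix
#' rules plus a small irregular table; all other tokens are lowercased.
#' Lexicon lookup downstream matches on these lemmas, so "infarcts" matches
#' a lexicon entry "infarct".
#'
#' @param doc A POS-tagged `rad_document`.
#' @return The document with `tokens$lemma` filled.
#' @export
lemmatise <- function(doc) {
  stopifnot(inherits(doc, "rad_document"))
  if (nrow(doc$tokens) == 0L) {
    return(doc)
  }
  doc$tokens$lemma <- lemmatise_words(doc$tokens$surface, doc$tokens$pos)
  doc
}
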