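# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive results by exhaustive enumeration and stay
# independent of the package's internal matching/scoring code paths.

# Brute-force lexicon matcher: enumerate every lexicon entry against every
# token subsequence of a sentence, then greedily select non-overlapping
# matches by (length desc, start asc, type asc). `lemmas`/`lows` are the
# sentence's token lemmas and lowercased surfaces.
oracle_match_pass <- function(entries, lemmas, lows, blocked = NULL) {
  cand <- list()
  for (i in seq_len(nrow(entries))) {
    toks <- entries$tokens[[i]]
    k <- length(toks)
    if (k == 0 || k > length(lemmas)) next
    for (s in seq_len(length(lemmas) - k + 1)) {
      window_lem <- lemmas[s:(s + k - 1)]
      window_low <- lows[s:(s + k - 1)]
      hit <- if (entries$mode[i] == "literal") {
        all(tolower(toks) == window_low)
      } else {
        all(toks == window_lem | toks == window_low)
      }
      if (hit) {
        cand[[length(cand) + 1]] <- data.frame(
          first = s, last = s + k - 1, etype = entries$etype[i], len = k
        )
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(
      first = integer(), last = integer(), etype = character()
    ))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$len, cand$first, cand$etype), ]
  sel <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    overlaps_sel <- nrow(sel) > 0 &&
      any(sel$first <= cand$last[i] & sel$last >= cand$first[i])
    if (overlaps_sel) next
    if (!is.null(blocked) && nrow(blocked) > 0) {
      ov <- blocked$first <= cand$last[i] & blocked$last >= cand$first[i]
      co <- blocked$first == cand$first[i] & blocked$last == cand$last[i]
      if (any(ov & !co)) next
    }
    sel <- rbind(sel, cand[i, ])
  }
  sel[order(sel$first), c("first", "last", "etype")]
}

# keys "first:last:etype" of the oracle's two-pass matching for a document
oracle_entity_keys <- function(doc, lexicons) {
  out <- character()
  for (sid in unique(doc$tokens$sentence_id)) {
    tk <- doc$tokens[doc$tokens$sentence_id == sid, ]
    lem <- tk$lemma
    low <- tolower(tk$surface)
    obs <- oracle_match_pass(lexicons$observations, lem, low)
    mod <- oracle_match_pass(lexicons$modifiers, lem, low, blocked = obs)
    both <- rbind(obs, mod)
    if (nrow(both)) {
      out <- c(out, paste(
        tk$start[both$first], tk$end[both$last], both$etype,
        sep = ":"
      ))
    }
  }
  sort(out)
}

# Brute-force set-intersection scorer over paired documents: returns
# total tp/fp/fn for one category.
oracle_counts <- function(gold_docs, pred_docs, category) {
  keyfun <- switch(category,
    entities = function(d) {
      en <- d$entities
      if (!nrow(en)) return(character())
      paste(d$report_id, en$start, en$end, en$etype)
    },
    negation = function(d) {
      en <- d$entities[d$entities$negated, ]
      if (!nrow(en)) return(character())
      paste(d$report_id, en$start, en$end, en$etype)
    },
    labels = function(d) {
      sel <- d$labels$label[d$labels$selected]
      if (!length(sel)) return(character())
      paste(d$report_id, sel)
    },
    relations = function(d) {
      rl <- d$relations
      if (!nrow(rl)) return(character())
      en <- d$entities
      io <- match(rl$observation, en$entity_id)
      im <- match(rl$modifier, en$entity_id)
      paste(
        d$report_id, rl$rtype,
        en$start[io], en$end[io], en$etype[io],
        en$start[im], en$end[im], en$etype[im]
      )
    }
  )
  ids <- vapply(gold_docs, function(d) d$report_id, character(1))
  names(gold_docs) <- ids
  pids <- vapply(pred_docs, function(d) d$report_id, character(1))
  names(pred_docs) <- pids
  tp <- fp <- fn <- 0L
  for (id in ids) {
    g <- keyfun(gold_docs[[id]])
    p <- keyfun(pred_docs[[id]])
    tp <- tp + length(intersect(g, p))
    fn <- fn + length(setdiff(g, p))
    fp <- fp + length(setdiff(p, g))
  }
  c(tp = tp, fp = fp, fn = fn)
}

# random sentence of lexicon surfaces and filler words, tokenised and
# lemmatised through the pipeline's linguistic stages
random_synthetic_doc <- function(lexicons, n_words = 8) {
  pool <- c(
    lexicons$observations$surface, lexicons$modifiers$surface,
    "the", "with", "and", "or", "of", "scan", "head", "left", "right",
    "no", "area", "region", "appearance"
  )
  words <- sample(pool, n_words, replace = TRUE)
  text <- paste0("Report:\n", paste(words, collapse = " "), ".")
  doc <- read_report(text, "rnd")
  doc <- zone(doc)
  doc <- tokenize(doc)
  doc <- pos_tag(doc)
  lemmatise(doc)
}

reference_rows <- function() {
  read.csv(testthat::test_path("prf-reference-rows.csv"),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}

expect_prf_row <- function(got, want) {
  for (col in c("precision", "recall", "f1")) {
    if (is.na(want[[col]])) {
      testthat::expect_true(is.nan(got[[col]]))
    } else {
      testthat::expect_equal(got[[col]], want[[col]], tolerance = 1e-9)
    }
  }
}
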