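# Seedable generator of radiology-style reports with complete gold
# annotations. Reports mimic the structure of hospital brain-scan reports:
# a clinical-details preamble, a findings body of a handful of short
# sentences, and a conclusion, at roughly 90 words per report. Sentences
# are built from templates instantiated only with shipped lexicon surface
# forms, so the rule pipeline covers every construction the generator
# emits; gold entity spans, negation flags, relations and labels are
# recorded during assembly.

#' Specification for the synthetic report generator
#'
#' @param n_reports Number of reports to generate.
#' @param obs_weights Named non-negative sampling weights over the 13
#'   observation types (not all zero).
#' @param p_negation Probability that a findings sentence is a negated
#'   (possibly coordinated) noun group.
#' @param coord_width_probs Probabilities of 1, 2 or 3 coordinated heads
#'   in a negated group.
#' @param p_hedge Probability of a hedged non-exclusion sentence.
#' @param p_verbal_not Probability of a verbal "not" sentence.
#' @param p_loc,p_time Probabilities that a positive stroke sentence
#'   carries a location / time modifier.
#' @param p_nested Probability that a positive ischaemic-stroke sentence
#'   uses a nested stroke-classification acronym (POCI etc.).
#' @param p_conclusion Probability that a report has a conclusion section.
#' @param p_details_entity Probability that the clinical-details preamble
#'   mentions a previous stroke (entities that must never yield labels).
#' @param body_sentences Integer range (min, max) of findings sentences.
#' @return A `rad_generator_spec` list.
#' @export
generator_spec <- function(n_reports = 20,
                           obs_weights = c(
                             ischaemic_stroke = 5, haemorrhagic_stroke = 2,
                             stroke_unknown = 1, tumour_meningioma = 0.5,
                             tumour_metastasis = 0.5, tumour_glioma = 0.3,
                             tumour = 1.5, subdural_haematoma = 1,
                             small_vessel_disease = 4, atrophy = 3,
                             microbleed = 0.5,
                             subarachnoid_haemorrhage = 0.5,
                             haemorrhagic_transformation = 0.3
                           ),
                           p_negation = 0.33,
                           coord_width_probs = c(0.5, 0.25, 0.25),
                           p_hedge = 0.08,
                           p_verbal_not = 0.05,
                           p_loc = 0.7,
                           p_time = 0.6,
                           p_nested = 0.12,
                           p_conclusion = 0.8,
                           p_details_entity = 0.2,
                           body_sentences = c(4L, 7L)) {
  probs <- c(
    p_negation, p_hedge, p_verbal_not, p_loc, p_time, p_nested,
    p_conclusion, p_details_entity, coord_width_probs
  )
  if (any(probs < 0 | probs > 1)) {
    stop("generator probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p_negation + p_hedge + p_verbal_not > 1) {
    stop("sentence-type probabilities sum to more than 1", call. = FALSE)
  }
  if (!setequal(names(obs_weights), observation_types()) ||
    any(obs_weights < 0) || sum(obs_weights) == 0) {
    stop("obs_weights must be named non-negative weights over the 13 ",
      "observation types, not all zero",
      call. = FALSE
    )
  }
  if (n_reports < 0) stop("n_reports must be >= 0", call. = FALSE)
  structure(
    list(
      n_reports = as.integer(n_reports), obs_weights = obs_weights,
      p_negation = p_negation, coord_width_probs = coord_width_probs,
      p_hedge = p_hedge, p_verbal_not = p_verbal_not, p_loc = p_loc,
      p_time = p_time, p_nested = p_nested, p_conclusion = p_conclusion,
      p_details_entity = p_details_entity,
      body_sentences = as.integer(body_sentences)
    ),
    class = "rad_generator_spec"
  )
}

# surface pools (must stay in step with the shipped lexicons)
.surf <- list(
  time_old = c("old", "established", "chronic"),
  time_recent = c("acute", "recent", "new"),
  loc_deep = c("deep", "thalamic", "lacunar"),
  loc_cortical = c("cortical", "lobar"),
  ischaemic_stroke = c("infarct", "infarction"),
  haemorrhagic_stroke = "haemorrhage"
)

.simple_obs <- tibble::tribble(
  ~surface, ~etype, ~label, ~countable,
  "small vessel disease", "small_vessel_disease", "Small vessel disease",
  FALSE,
  "atrophy", "atrophy", "Atrophy", FALSE,
  "mass", "tumour", "Tumour, other", TRUE,
  "extra-axial collection", "subdural_haematoma", "Subdural haematoma",
  TRUE,
  "subdural haematoma", "subdural_haematoma", "Subdural haematoma", TRUE,
  "meningioma", "tumour_meningioma", "Tumour, meningioma", TRUE,
  "glioma", "tumour_glioma", "Tumour, glioma", TRUE,
  "metastatic deposit", "tumour_metastasis", "Tumour, metastasis", TRUE,
  "haemorrhagic transformation", "haemorrhagic_transformation",
  "Haemorrhagic transformation", FALSE
)

pick <- function(x, n = 1) x[sample.int(length(x), n)]

article_for <- function(word) {
  if (grepl("^[aeiouAEIOU]", word)) "an" else "a"
}

cap1 <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

# a sentence is: words (character vector joined by single spaces, final
# "." appended), ents (tibble: w_from, w_to, etype, negated, pair),
# rels (tibble: obs, mod, rtype -- local entity indices), labels
new_sentence <- function(words, ents = NULL, rels = NULL,
                         labels = character()) {
  list(
    words = words,
    ents = if (is.null(ents)) {
      tibble(
        w_from = integer(), w_to = integer(), etype = character(),
        negated = logical(), pair = integer()
      )
    } else {
      ents
    },
    rels = if (is.null(rels)) {
      tibble(obs = integer(), mod = integer(), rtype = character())
    } else {
      rels
    },
    labels = labels
  )
}

ent_row <- function(w_from, w_to, etype, negated = FALSE,
                    pair = NA_integer_) {
  tibble(
    w_from = w_from, w_to = w_to, etype = etype, negated = negated,
    pair = pair
  )
}

# label for a stroke observation given its resolved location/time values
stroke_label <- function(obs_type, loc, time) {
  if (obs_type == "stroke_unknown") {
    return("Stroke, underspecified")
  }
  if (obs_type == "ischaemic_stroke") {
    if (loc == "deep") {
      return(switch(time,
        recent = "Ischaemic stroke, deep, recent",
        "Ischaemic stroke, deep, old" # old, or assumed old when unstated
      ))
    }
    if (loc == "cortical") {
      return(switch(time,
        recent = "Ischaemic stroke, cortical, recent",
        old = "Ischaemic stroke, cortical, old",
        "Ischaemic stroke, underspecified"
      ))
    }
    return("Ischaemic stroke, underspecified")
  }
  # haemorrhagic: cortical surfaces label as "lobar"; no assumed-old default
  if (loc == "deep" && time == "recent") {
    return("Haemorrhagic stroke, deep, recent")
  }
  if (loc == "deep" && time == "old") {
    return("Haemorrhagic stroke, deep, old")
  }
  if (loc == "cortical" && time == "recent") {
    return("Haemorrhagic stroke, lobar, recent")
  }
  if (loc == "cortical" && time == "old") {
    return("Haemorrhagic stroke, lobar, old")
  }
  "Haemorrhagic stroke, underspecified"
}

# ---- sentence templates -------------------------------------------------

t_stroke_modified <- function(spec, obs_type) {
  surf <- pick(.surf[[obs_type]])
  has_loc <- stats::runif(1) < spec$p_loc
  has_time <- stats::runif(1) < spec$p_time
  loc_kind <- pick(c("deep", "cortical"))
  time_kind <- pick(c("old", "recent"))
  words <- character()
  ents <- NULL
  i <- 0L
  time_idx <- loc_idx <- NA_integer_
  if (has_time) {
    words <- c(words, pick(.surf[[paste0("time_", time_kind)]]))
    i <- i + 1L
    ents <- dplyr::bind_rows(ents, ent_row(i, i, paste0("time_", time_kind)))
    time_idx <- nrow(ents)
  }
  if (has_loc) {
    loc_surf <- pick(.surf[[paste0("loc_", loc_kind)]])
    words <- c(words, loc_surf)
    i <- i + 1L
    ents <- dplyr::bind_rows(ents, ent_row(i, i, paste0("loc_", loc_kind)))
    loc_idx <- nrow(ents)
  }
  words <- c(words, surf)
  i <- i + 1L
  ents <- dplyr::bind_rows(ents, ent_row(i, i, obs_type))
  obs_idx <- nrow(ents)
  words <- c(words, pick(c("noted", "seen", "demonstrated")))
  words[1] <- cap1(words[1])
  rels <- NULL
  if (has_time) {
    rels <- dplyr::bind_rows(
      rels, tibble(obs = obs_idx, mod = time_idx, rtype = "mod_time")
    )
  }
  if (has_loc) {
    rels <- dplyr::bind_rows(
      rels, tibble(obs = obs_idx, mod = loc_idx, rtype = "mod_loc")
    )
  }
  lab <- stroke_label(
    obs_type,
    if (has_loc) loc_kind else "none",
    if (has_time) time_kind else "none"
  )
  new_sentence(words, ents, rels, lab)
}

t_stroke_unknown <- function(spec) {
  if (stats::runif(1) < spec$p_time) {
    s <- pick(.surf$time_old)
    new_sentence(
      c(cap1(s), "stroke", "noted"),
      dplyr::bind_rows(ent_row(1L, 1L, "time_old"), ent_row(2L, 2L, "stroke_unknown")),
      tibble(obs = 2L, mod = 1L, rtype = "mod_time"),
      "Stroke, underspecified"
    )
  } else {
    new_sentence(
      c("Evidence", "of", "a", "stroke", "is", "seen"),
      ent_row(4L, 4L, "stroke_unknown"),
      NULL,
      "Stroke, underspecified"
    )
  }
}

t_neg_coord <- function(spec) {
  width <- sample.int(3L, 1L, prob = spec$coord_width_probs)
  has_time <- stats::runif(1) < spec$p_time
  obs1_type <- pick(c("ischaemic_stroke", "haemorrhagic_stroke"))
  words <- "No"
  ents <- NULL
  i <- 1L
  time_idx <- NA_integer_
  if (has_time) {
    tk <- pick(c("old", "recent"))
    words <- c(words, pick(.surf[[paste0("time_", tk)]]))
    i <- i + 1L
    ents <- dplyr::bind_rows(
      ents, ent_row(i, i, paste0("time_", tk), negated = TRUE)
    )
    time_idx <- nrow(ents)
  }
  words <- c(words, pick(.surf[[obs1_type]]))
  i <- i + 1L
  ents <- dplyr::bind_rows(ents, ent_row(i, i, obs1_type, negated = TRUE))
  obs1_idx <- nrow(ents)
  if (width > 1L) {
    others <- .simple_obs[pick(seq_len(nrow(.simple_obs)), width - 1L), ]
    for (k in seq_len(nrow(others))) {
      sep <- if (k == nrow(others)) "or" else NULL
      if (k < nrow(others)) {
        # comma attaches to the previous word
        words[length(words)] <- paste0(words[length(words)], ",")
      }
      words <- c(words, sep)
      i <- length(words)
      surf_words <- strsplit(others$surface[k], " ", fixed = TRUE)[[1]]
      words <- c(words, surf_words)
      ents <- dplyr::bind_rows(ents, ent_row(
        i + 1L, i + length(surf_words), others$etype[k],
        negated = TRUE
      ))
    }
  }
  words <- c(words, "seen")
  rels <- if (has_time) {
    tibble(obs = obs1_idx, mod = time_idx, rtype = "mod_time")
  } else {
    NULL
  }
  new_sentence(words, ents, rels, character())
}

t_hedge <- function(spec) {
  v <- sample.int(3L, 1L)
  if (v == 1L) {
    tk <- pick(.surf$time_recent)
    ik <- pick(.surf$ischaemic_stroke)
    new_sentence(
      c(
        "A", "small", "focus", "of", tk, ik,
        "cannot", "be", "completely", "excluded"
      ),
      dplyr::bind_rows(
        ent_row(5L, 5L, "time_recent", negated = TRUE),
        ent_row(6L, 6L, "ischaemic_stroke", negated = TRUE)
      ),
      tibble(obs = 2L, mod = 1L, rtype = "mod_time"),
      character()
    )
  } else if (v == 2L) {
    row <- .simple_obs[pick(seq_len(nrow(.simple_obs))), ]
    sw <- strsplit(row$surface, " ", fixed = TRUE)[[1]]
    new_sentence(
      c(cap1(sw[1]), sw[-1], "cannot", "be", "excluded"),
      ent_row(1L, length(sw), row$etype, negated = TRUE),
      NULL, character()
    )
  } else {
    row <- .simple_obs[pick(seq_len(nrow(.simple_obs))), ]
    sw <- strsplit(row$surface, " ", fixed = TRUE)[[1]]
    new_sentence(
      c("Cannot", "exclude", sw),
      ent_row(3L, 2L + length(sw), row$etype, negated = TRUE),
      NULL, character()
    )
  }
}

t_verbal_not <- function(spec) {
  tk <- pick(.surf$time_recent)
  ik <- pick(.surf$ischaemic_stroke)
  new_sentence(
    c("Very", tk, ik, "may", "not", "be", "visible", "on", "this", "scan"),
    dplyr::bind_rows(
      ent_row(2L, 2L, "time_recent", negated = TRUE),
      ent_row(3L, 3L, "ischaemic_stroke", negated = TRUE)
    ),
    tibble(obs = 2L, mod = 1L, rtype = "mod_time"),
    character()
  )
}

t_nested <- function(spec) {
  acro <- pick(c("POCI", "TACI", "PACI", "LACI"))
  loc_type <- if (acro == "LACI") "loc_deep" else "loc_cortical"
  loc_kind <- if (acro == "LACI") "deep" else "cortical"
  has_time <- stats::runif(1) < spec$p_time
  if (has_time) {
    tw <- pick(.surf$time_old)
    words <- c("Appearances", "suggest", article_for(tw), tw, acro)
    ents <- dplyr::bind_rows(
      ent_row(4L, 4L, "time_old"),
      ent_row(5L, 5L, "ischaemic_stroke", pair = 3L),
      ent_row(5L, 5L, loc_type, pair = 2L)
    )
    rels <- tibble(obs = 2L, mod = 1L, rtype = "mod_time")
    lab <- stroke_label("ischaemic_stroke", loc_kind, "old")
  } else {
    words <- c("Appearances", "suggest", "a", acro)
    ents <- dplyr::bind_rows(
      ent_row(4L, 4L, "ischaemic_stroke", pair = 2L),
      ent_row(4L, 4L, loc_type, pair = 1L)
    )
    rels <- NULL
    lab <- stroke_label("ischaemic_stroke", loc_kind, "none")
  }
  new_sentence(words, ents, rels, lab)
}

t_microbleed <- function(spec) {
  has_loc <- stats::runif(1) < spec$p_loc
  if (has_loc) {
    kind <- pick(c("deep", "cortical"))
    surf <- pick(.surf[[paste0("loc_", kind)]])
    new_sentence(
      c(cap1(surf), "microbleeds", "noted"),
      dplyr::bind_rows(
        ent_row(1L, 1L, paste0("loc_", kind)),
        ent_row(2L, 2L, "microbleed")
      ),
      tibble(obs = 2L, mod = 1L, rtype = "mod_loc"),
      if (kind == "deep") "Microbleed, deep" else "Microbleed, lobar"
    )
  } else {
    new_sentence(
      c("Microbleeds", "noted"),
      ent_row(1L, 1L, "microbleed"),
      NULL, "Microbleed, underspecified"
    )
  }
}

t_sah <- function(spec) {
  if (stats::runif(1) < 0.5) {
    new_sentence(
      c(
        "Subarachnoid", "haemorrhage", "from", "a", "ruptured",
        "aneurysm", "noted"
      ),
      ent_row(1L, 2L, "subarachnoid_haemorrhage"),
      NULL, "Subarachnoid haemorrhage, aneurysmal"
    )
  } else {
    new_sentence(
      c("Subarachnoid", "haemorrhage", "noted"),
      ent_row(1L, 2L, "subarachnoid_haemorrhage"),
      NULL, "Subarachnoid haemorrhage, other"
    )
  }
}

t_simple <- function(spec, etype) {
  rows <- .simple_obs[.simple_obs$etype == etype, ]
  row <- rows[pick(seq_len(nrow(rows))), ]
  sw <- strsplit(row$surface, " ", fixed = TRUE)[[1]]
  v <- sample.int(2L, 1L)
  if (v == 1L) {
    pre <- if (row$countable) {
      c("There", "is", article_for(sw[1]))
    } else {
      c("There", "is")
    }
    new_sentence(
      c(pre, sw),
      ent_row(length(pre) + 1L, length(pre) + length(sw), row$etype),
      NULL, row$label
    )
  } else {
    new_sentence(
      c(cap1(sw[1]), sw[-1], "is", "present"),
      ent_row(1L, length(sw), row$etype),
      NULL, row$label
    )
  }
}

draw_body_sentence <- function(spec) {
  u <- stats::runif(1)
  if (u < spec$p_negation) {
    return(t_neg_coord(spec))
  }
  if (u < spec$p_negation + spec$p_hedge) {
    return(t_hedge(spec))
  }
  if (u < spec$p_negation + spec$p_hedge + spec$p_verbal_not) {
    return(t_verbal_not(spec))
  }
  w <- spec$obs_weights[observation_types()]
  etype <- sample(observation_types(), 1, prob = w)
  switch(etype,
    ischaemic_stroke = if (stats::runif(1) < spec$p_nested) {
      t_nested(spec)
    } else {
      t_stroke_modified(spec, etype)
    },
    haemorrhagic_stroke = t_stroke_modified(spec, etype),
    stroke_unknown = t_stroke_unknown(spec),
    microbleed = t_microbleed(spec),
    subarachnoid_haemorrhage = t_sah(spec),
    t_simple(spec, etype)
  )
}

details_pool <- c(
  "Sudden onset right sided weakness.",
  "Collapse with reduced consciousness.",
  "Worsening confusion over two weeks.",
  "Severe headache of sudden onset.",
  "Dizziness and unsteadiness."
)

neutral_conclusions <- c(
  "Appearances are within normal limits for age.",
  "Stable appearances compared with the prior examination.",
  "Clinical correlation is advised."
)

# render one sentence into text with 0-based offsets starting at `at`
render_sentence <- function(sent, at) {
  words <- sent$words
  starts <- integer(length(words))
  pos <- at
  for (k in seq_along(words)) {
    starts[k] <- pos
    pos <- pos + nchar(words[k]) + 1L # joining space
  }
  ends <- starts + nchar(words)
  txt <- paste0(paste(words, collapse = " "), ".")
  ents <- sent$ents
  if (nrow(ents)) {
    ents$start <- starts[ents$w_from]
    # strip a trailing comma glued onto the last word of an entity
    last_w <- words[ents$w_to]
    ents$end <- ends[ents$w_to] - ifelse(grepl(",$", last_w), 1L, 0L)
  }
  list(text = txt, width = nchar(txt), ents = ents, rels = sent$rels,
    labels = sent$labels)
}

#' Generate synthetic reports with gold annotations
#'
#' A deterministic function of `seed`: builds `spec$n_reports` reports of
#' template sentences instantiated from the shipped lexicon surface forms,
#' together with complete gold `rad_document` annotations (entities with
#' negation, relations, labels) that pass [validate_document()].
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed for all randomness.
#' @return A tibble with columns `report_id`, `text`, `gold` (list of
#'   `rad_document`).
#' @examples
#' corp <- generate_reports(generator_spec(n_reports = 2), seed = 7)
#' corp$gold[[1]]
#' @export
generate_reports <- function(spec = generator_spec(), seed = 1) {
  stopifnot(inherits(spec, "rad_generator_spec"))
  if (spec$n_reports == 0L) {
    return(tibble(
      report_id = character(), text = character(), gold = list()
    ))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  out <- vector("list", spec$n_reports)
  for (r in seq_len(spec$n_reports)) {
    rid <- sprintf("synth-%03d", r)
    pieces <- character()
    cursor <- 0L
    ents <- list()
    rels <- list()
    labels <- character()
    sec_rows <- list()
    emit <- function(txt) {
      pieces[[length(pieces) + 1L]] <<- txt
      cursor <<- cursor + nchar(txt)
    }
    emit_sentence <- function(sent, section_kind) {
      rs <- render_sentence(sent, cursor)
      if (nrow(rs$ents)) {
        rs$ents$section_kind <- section_kind
        base <- sum(vapply(ents, nrow, integer(1)))
        rs$rels$obs <- rs$rels$obs + base
        rs$rels$mod <- rs$rels$mod + base
        rs$ents$pair <- rs$ents$pair + base
        ents[[length(ents) + 1L]] <<- rs$ents
        if (!is.null(rs$rels) && nrow(rs$rels)) {
          rels[[length(rels) + 1L]] <<- rs$rels
        }
      }
      labels <<- union(labels, rs$labels)
      emit(rs$text)
    }
    # clinical details
    sec_start <- cursor
    emit("Clinical details:\n")
    if (stats::runif(1) < spec$p_details_entity) {
      emit_sentence(
        new_sentence(
          c("Previous", "stroke"),
          dplyr::bind_rows(
            ent_row(1L, 1L, "time_old"),
            ent_row(2L, 2L, "stroke_unknown")
          ),
          tibble(obs = 2L, mod = 1L, rtype = "mod_time"),
          character()
        ),
        "clinical_details"
      )
    } else {
      emit(pick(details_pool))
    }
    emit("\n\n")
    sec_rows[[1]] <- tibble(
      kind = "clinical_details", start = sec_start, end = cursor
    )
    # findings body
    sec_start <- cursor
    emit("Report:\n")
    n_body <- pick(seq(spec$body_sentences[1], spec$body_sentences[2]))
    for (s in seq_len(n_body)) {
      emit_sentence(draw_body_sentence(spec), "report_body")
      if (s < n_body) emit(" ")
    }
    has_concl <- stats::runif(1) < spec$p_conclusion
    emit(if (has_concl) "\n\n" else "\n")
    sec_rows[[2]] <- tibble(
      kind = "report_body", start = sec_start, end = cursor
    )
    # conclusion
    if (has_concl) {
      sec_start <- cursor
      emit("Conclusion:\n")
      if (stats::runif(1) < 0.5) {
        emit_sentence(draw_body_sentence(spec), "conclusion")
      } else {
        emit(pick(neutral_conclusions))
      }
      emit("\n")
      sec_rows[[3]] <- tibble(
        kind = "conclusion", start = sec_start, end = cursor
      )
    }
    text <- paste(pieces, collapse = "")
    doc <- read_report(text, rid)
    sec <- dplyr::bind_rows(sec_rows)
    sec$section_id <- seq_len(nrow(sec))
    doc$sections <- sec[, names(empty_sections())]
    if (length(ents)) {
      en <- dplyr::bind_rows(ents)
      en$local <- seq_len(nrow(en))
      en <- en[order(en$start, en$end, en$etype), ]
      en$entity_id <- paste0("T", seq_len(nrow(en)))
      id_of <- en$entity_id[match(seq_len(nrow(en)), en$local)]
      en$nested_with <- ifelse(is.na(en$pair), NA_character_,
        id_of[en$pair]
      )
      en$category <- entity_category(en$etype)
      en$text <- span_text(text, en$start, en$end)
      en$sentence_id <- NA_integer_
      doc$entities <- en[, names(empty_entities())]
      if (length(rels)) {
        rl <- dplyr::bind_rows(rels)
        doc$relations <- tibble(
          relation_id = paste0("R", seq_len(nrow(rl))),
          rtype = rl$rtype,
          observation = id_of[rl$obs],
          modifier = id_of[rl$mod]
        )
      }
      # label evidence: all non-negated entities whose type family matches
      for (lab in labels) {
        k <- which(doc$labels$label == lab)
        doc$labels$selected[k] <- TRUE
        ev <- doc$entities$entity_id[!doc$entities$negated &
          doc$entities$section_kind %in% c("report_body", "conclusion")]
        doc$labels$evidence[[k]] <- ev
      }
    }
    out[[r]] <- tibble(report_id = rid, text = text, gold = list(doc))
  }
  dplyr::bind_rows(out)
}

#' Corrupt a gold document for scorer testing
#'
#' Applies counted single-unit perturbations to a copy of a gold document,
#' so that scorer count deltas are predictable: dropping a matching entity
#' turns one TP into one FN, shifting a span by one character produces one
#' FP and one FN, and so on.
#'
#' @param doc A `rad_document`.
#' @param ops Named list/vector of counts among `drop_entity`,
#'   `shift_span`, `flip_negation`, `retype`, `drop_relation`,
#'   `toggle_label`.
#' @param seed Integer seed controlling which units are perturbed.
#' @return The perturbed document.
#' @export
corrupt_document <- function(doc, ops, seed = 1) {
  stopifnot(inherits(doc, "rad_document"))
  ops <- as.list(ops)
  known <- c(
    "drop_entity", "shift_span", "flip_negation", "retype",
    "drop_relation", "toggle_label"
  )
  if (length(setdiff(names(ops), known))) {
    stop("unknown corruption op: ",
      paste(setdiff(names(ops), known), collapse = ", "),
      call. = FALSE
    )
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  n_of <- function(op) if (is.null(ops[[op]])) 0L else as.integer(ops[[op]])
  need <- function(op, avail) {
    k <- n_of(op)
    if (k > avail) {
      stop("corruption '", op, "': requested ", k, " but only ", avail,
        " unit(s) available",
        call. = FALSE
      )
    }
    k
  }

  # relation/label ops first: their availability is judged against the
  # uncorrupted document (entity drops cascade into relations)
  k <- need("drop_relation", nrow(doc$relations))
  if (k > 0L) {
    rows <- pick(seq_len(nrow(doc$relations)), k)
    doc$relations <- doc$relations[-rows, ]
  }

  k <- need("toggle_label", nrow(doc$labels))
  if (k > 0L) {
    rows <- pick(seq_len(nrow(doc$labels)), k)
    doc$labels$selected[rows] <- !doc$labels$selected[rows]
  }

  k <- need("drop_entity", nrow(doc$entities))
  if (k > 0L) {
    drop <- pick(doc$entities$entity_id, k)
    doc$relations <- doc$relations[
      !(doc$relations$observation %in% drop |
        doc$relations$modifier %in% drop),
    ]
    doc$entities$nested_with[doc$entities$nested_with %in% drop] <-
      NA_character_
    doc$entities <- doc$entities[!doc$entities$entity_id %in% drop, ]
  }

  k <- need("shift_span", nrow(doc$entities))
  if (k > 0L) {
    rows <- pick(seq_len(nrow(doc$entities)), k)
    for (i in rows) {
      d <- if (doc$entities$end[i] < nchar(doc$text)) 1L else -1L
      doc$entities$start[i] <- doc$entities$start[i] + d
      doc$entities$end[i] <- doc$entities$end[i] + d
      doc$entities$text[i] <- span_text(
        doc$text, doc$entities$start[i], doc$entities$end[i]
      )
    }
  }

  k <- need("flip_negation", nrow(doc$entities))
  if (k > 0L) {
    rows <- pick(seq_len(nrow(doc$entities)), k)
    doc$entities$negated[rows] <- !doc$entities$negated[rows]
  }

  k <- need("retype", nrow(doc$entities))
  if (k > 0L) {
    rows <- pick(seq_len(nrow(doc$entities)), k)
    for (i in rows) {
      pool <- if (doc$entities$category[i] == "observation") {
        observation_types()
      } else {
        modifier_types()
      }
      doc$entities$etype[i] <- pick(setdiff(pool, doc$entities$etype[i]))
    }
  }

  doc
}
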