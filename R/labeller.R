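# Report-level phenotype labelling: 24 labels derived from non-negated
# observation entities and their (non-negated) modifier context, restricted
# to the report body and conclusion sections. Rules are data, not code, so
# that clinical users can audit and adapt them.

#' Load the declarative label rule table
#'
#' Five tab-separated columns: `obs_type`, `loc`, `time`, `cue`, `label`;
#' `#` lines are comments. See the shipped `label_rules.tsv` for the
#' row semantics ("any", "none", "-").
#'
#' @param path Path to the rule TSV; defaults to the shipped table.
#' @return A tibble of rules, in file order.
#' @export
load_label_rules <- function(path = radlabel_resource("label_rules.tsv")) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  parts <- stringr::str_split_fixed(lines[keep], "\t", 5)
  tb <- tibble(
    obs_type = trimws(parts[, 1]),
    loc = trimws(parts[, 2]),
    time = trimws(parts[, 3]),
    cue = trimws(parts[, 4]),
    label = trimws(parts[, 5])
  )
  bad <- which(!tb$label %in% label_inventory())
  if (length(bad)) {
    stop("label rules line ", bad[1], ": unknown label '",
      tb$label[bad[1]], "'",
      call. = FALSE
    )
  }
  tb
}

dim_matches <- function(rule_val, value) {
  rule_val %in% c("any", "-") | rule_val == value
}

#' Assign the 24 report-level labels
#'
#' For every non-negated observation entity in a `report_body` or
#' `conclusion` section, resolves its location value (deep/cortical/none)
#' and time value (old/recent/none) from explicit relations whose modifier
#' is itself non-negated, or from a nested co-extensive modifier, and looks
#' the combination up in the rule table; the first matching rule selects
#' its label with the contributing entity and relation ids recorded as
#' evidence. Evidence from the clinical-details section never contributes.
#' A document whose every entity is negated selects no labels.
#'
#' @param doc A fully annotated `rad_document` (entities, negation,
#'   relations complete).
#' @param rules Rule table from [load_label_rules()].
#' @return The document with its `labels` tibble updated (`selected`,
#'   `evidence`).
#' @export
assign_labels <- function(doc, rules = load_label_rules()) {
  stopifnot(inherits(doc, "rad_document"))
  labs <- fresh_labels()
  en <- doc$entities
  rl <- doc$relations
  obs_rows <- which(en$category == "observation" &
    !en$negated &
    en$section_kind %in% c("report_body", "conclusion"))
  loc_value <- function(et) {
    if (et == "loc_deep") "deep" else "cortical"
  }
  time_value <- function(et) {
    if (et == "time_old") "old" else "recent"
  }
  for (i in obs_rows) {
    oid <- en$entity_id[i]
    # modifier context: explicit relations (non-negated modifiers) + nesting
    rel <- rl[rl$observation == oid, ]
    mod_ids <- rel$modifier
    mrows <- match(mod_ids, en$entity_id)
    ok <- !en$negated[mrows]
    rel <- rel[ok, ]
    mrows <- mrows[ok]
    nest <- if (!is.na(en$nested_with[i])) {
      which(en$entity_id == en$nested_with[i] & !en$negated)
    } else {
      integer()
    }
    loc_sources <- c(
      mrows[en$etype[mrows] %in% c("loc_deep", "loc_cortical")],
      nest[en$etype[nest] %in% c("loc_deep", "loc_cortical")]
    )
    time_sources <- c(
      mrows[en$etype[mrows] %in% c("time_old", "time_recent")],
      nest[en$etype[nest] %in% c("time_old", "time_recent")]
    )
    locs <- unique(vapply(en$etype[loc_sources], loc_value, character(1)))
    times <- unique(vapply(en$etype[time_sources], time_value, character(1)))
    if (length(locs) == 0L) locs <- "none"
    if (length(times) == 0L) times <- "none"
    # aneurysm context cue: lemma starting "aneurysm" in the same sentence
    sent_tk <- doc$tokens[doc$tokens$sentence_id == en$sentence_id[i], ]
    has_cue <- any(grepl("^aneurysm", sent_tk$lemma))
    for (lv in locs) {
      for (tv in times) {
        hit <- which(rules$obs_type == en$etype[i] &
          dim_matches(rules$loc, lv) &
          dim_matches(rules$time, tv) &
          (rules$cue %in% c("-", "any") |
            (rules$cue == "aneurysm" & has_cue)))
        if (length(hit) == 0L) next
        lab <- rules$label[hit[1]]
        k <- which(labs$label == lab)
        ev_mods <- unique(c(
          en$entity_id[loc_sources[en$etype[loc_sources] ==
            paste0("loc_", if (lv == "cortical") "cortical" else lv)]],
          en$entity_id[time_sources[en$etype[time_sources] ==
            paste0("time_", tv)]]
        ))
        ev_rel <- rel$relation_id[match(ev_mods, en$entity_id[mrows])]
        ev <- unique(c(oid, ev_mods, ev_rel[!is.na(ev_rel)]))
        labs$selected[k] <- TRUE
        labs$evidence[[k]] <- unique(c(labs$evidence[[k]], ev))
      }
    }
  }
  labs$evidence <- purrr::map(labs$evidence, ~ if (is.null(.x)) {
    character()
  } else {
    .x
  })
  doc$labels <- labs
  doc
}

#' Explain why a label was (or was not) selected
#'
#' Produces a human-readable evidence trace for one label: the entities and
#' relations that fired its rule, with character offsets, or a "no
#' evidence" trace for unselected labels.
#'
#' @param doc A labelled `rad_document`.
#' @param label One of the 24 inventory labels.
#' @return A character vector of trace lines, invisibly also printed.
#' @export
explain <- function(doc, label) {
  stopifnot(inherits(doc, "rad_document"))
  if (!label %in% label_inventory()) {
    stop("unknown label: '", label, "'", call. = FALSE)
  }
  row <- which(doc$labels$label == label)
  if (!doc$labels$selected[row]) {
    out <- paste0("[", doc$report_id, "] ", label, ": not selected - ",
      "no evidence")
    cat(out, sep = "\n")
    return(invisible(out))
  }
  ev <- doc$labels$evidence[[row]]
  en <- doc$entities[doc$entities$entity_id %in% ev, ]
  rl <- doc$relations[doc$relations$relation_id %in% ev, ]
  out <- c(
    paste0("[", doc$report_id, "] ", label, ": SELECTED"),
    sprintf(
      "  entity %s %s [%d,%d) \"%s\"%s",
      en$entity_id, en$etype, en$start, en$end, en$text,
      ifelse(en$negated, " (negated)", "")
    ),
    if (nrow(rl)) {
      sprintf(
        "  relation %s %s %s -> %s",
        rl$relation_id, rl$rtype, rl$observation, rl$modifier
      )
    }
  )
  cat(out, sep = "\n")
  invisible(out)
}
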