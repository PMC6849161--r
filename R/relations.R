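# Relation extraction: links stroke observations to location/time
# modifiers and microbleeds to location modifiers, within a sentence, by
# nearest type-compatible attachment (same noun group preferred). Verbal
# "not" negation lives here too: its rules resemble the relation rules but
# the result is a negation attribute, never a relation.

#' Verbal "not" negation
#'
#' A verb group containing the particle "not" ("may not be visible",
#' "is not a tumour") negates the entities in the neighbouring noun-group
#' chains on both sides of the verb group (the subject to its left and the
#' complement to its right), bounded by other verb groups. No relation
#' object is created; the result is the `negated` attribute on the
#' entities.
#'
#' @param doc A chunked `rad_document` with entities.
#' @return The document with entity `negated` flags updated.
#' @export
apply_verbal_negation <- function(doc) {
  stopifnot(inherits(doc, "rad_document"))
  if (nrow(doc$chunks) == 0L || nrow(doc$entities) == 0L) {
    return(doc)
  }
  scope <- integer()
  vgs <- which(doc$chunks$kind == "verb_group")
  for (j in vgs) {
    ch <- doc$chunks[j, ]
    tk <- doc$tokens[doc$tokens$token_id >= ch$token_start &
      doc$tokens$token_id <= ch$token_end, ]
    if (!any(tolower(tk$surface) %in% c("not", "n't"))) next
    scope <- c(scope, ng_chain(
      doc, ch$sentence_id, ch$token_start, ch$token_end
    ))
  }
  negate_in_chunks(doc, unique(scope))
}

#' Extract mod-loc and mod-time relations
#'
#' Each location modifier links to at most one stroke or microbleed
#' observation, and each time modifier to at most one stroke observation
#' (microbleeds take no time relation): the nearest type-compatible
#' observation in the same noun group, else the nearest in the same
#' sentence with ties broken to the left. Attachment across chunks is
#' blocked when the two endpoints disagree in negation polarity; inside one
#' chunk it is unconditional. Co-extensive nested pairs are never linked
#' explicitly (the nesting implies the relation). When one observation
#' would collect conflicting same-type modifier values (e.g. "old" and
#' "recent"), only the nearest is kept and a warning is emitted.
#'
#' @param doc A chunked, negation-marked `rad_document`.
#' @return The document with its `relations` tibble populated.
#' @export
extract_relations <- function(doc) {
  stopifnot(inherits(doc, "rad_document"))
  en <- doc$entities
  if (nrow(en) == 0L) {
    doc$relations <- empty_relations()
    return(doc)
  }
  rng <- entity_token_range(doc)
  chk <- entity_chunk(doc, rng)
  rows <- list()
  mods <- which(en$category == "modifier" & is.na(en$nested_with))
  for (i in mods) {
    is_loc <- en$etype[i] %in% c("loc_deep", "loc_cortical")
    rtype <- if (is_loc) "mod_loc" else "mod_time"
    compat <- if (is_loc) {
      loc_compatible_observations()
    } else {
      time_compatible_observations()
    }
    cand <- which(en$category == "observation" &
      en$sentence_id == en$sentence_id[i] &
      en$etype %in% compat)
    if (length(cand) == 0L) next
    gap <- vapply(cand, function(j) {
      if (rng$first[j] > rng$last[i]) {
        rng$first[j] - rng$last[i]
      } else {
        rng$first[i] - rng$last[j]
      }
    }, integer(1))
    same_chunk <- !is.na(chk[cand]) & !is.na(chk[i]) & chk[cand] == chk[i]
    # polarity boundary: cross-chunk attachment requires matching flags
    allowed <- same_chunk | (en$negated[cand] == en$negated[i])
    cand <- cand[allowed]
    if (length(cand) == 0L) next
    gap <- gap[allowed]
    same_chunk <- same_chunk[allowed]
    leftward <- rng$last[cand] < rng$first[i]
    ord <- order(!same_chunk, gap, !leftward, rng$first[cand])
    target <- cand[ord[1]]
    rows[[length(rows) + 1L]] <- tibble(
      rtype = rtype,
      observation = en$entity_id[target],
      modifier = en$entity_id[i],
      mod_row = i,
      gap = gap[ord[1]]
    )
  }
  if (length(rows) == 0L) {
    doc$relations <- empty_relations()
    return(doc)
  }
  rl <- dplyr::bind_rows(rows)
  # conflicting same-type modifier values on one observation: keep nearest
  keep <- rep(TRUE, nrow(rl))
  for (grp in split(
    seq_len(nrow(rl)),
    paste(rl$observation, rl$rtype)
  )) {
    vals <- en$etype[rl$mod_row[grp]]
    if (length(unique(vals)) > 1L) {
      nearest <- grp[order(rl$gap[grp], rl$mod_row[grp])][1]
      drop <- setdiff(grp, grp[vals == en$etype[rl$mod_row[nearest]]])
      keep[drop] <- FALSE
      warning("conflicting ", rl$rtype[grp[1]], " modifiers on ",
        rl$observation[grp[1]], " in report ", doc$report_id,
        "; keeping the nearest",
        call. = FALSE
      )
    }
  }
  rl <- rl[keep, ]
  rl <- rl[order(as.integer(sub("^T", "", rl$modifier))), ]
  doc$relations <- tibble(
    relation_id = paste0("R", seq_len(nrow(rl))),
    rtype = rl$rtype,
    observation = rl$observation,
    modifier = rl$modifier
  )
  doc
}
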