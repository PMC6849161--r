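# Scoring: per-type and micro-averaged precision/recall/F1 for entities,
# negation, relations and report labels. The same machinery scores
# system-vs-gold and annotator-vs-annotator agreement; swapping the two
# sides swaps precision and recall and leaves F1 unchanged.

#' Precision, recall and F1 from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`, on the 0-100
#' scale. Zero denominators yield `NaN` rather than an arbitrary 0 or 100,
#' so a type with no predictions and no gold stays visibly undefined. F1 is
#' computed from the unrounded precision and recall; rounding (base R
#' `round()`, which is what reproduces published two-decimal scores exactly)
#' is applied only for reporting.
#'
#' @param tp,fp,fn Non-negative integer counts (vectorised).
#' @param digits Decimal places for reporting; `NULL` returns unrounded
#'   values.
#' @return A tibble with columns `precision`, `recall`, `f1`.
#' @examples
#' compute_prf(453, 9, 2)
#' compute_prf(0, 0, 1) # NaN precision and F1
#' @export
compute_prf <- function(tp, fp, fn, digits = 2) {
  stopifnot(all(tp >= 0), all(fp >= 0), all(fn >= 0))
  p <- ifelse(tp + fp == 0, NaN, 100 * tp / (tp + fp))
  r <- ifelse(tp + fn == 0, NaN, 100 * tp / (tp + fn))
  f <- ifelse(is.nan(p) | is.nan(r) | p + r == 0, NaN,
    2 * p * r / (p + r)
  )
  out <- tibble(precision = p, recall = r, f1 = f)
  if (!is.null(digits)) {
    out <- dplyr::mutate(out, dplyr::across(
      dplyr::everything(), ~ round(.x, digits)
    ))
  }
  out
}

# ---- pairing and keys ---------------------------------------------------

as_doc_list <- function(x) {
  docs <- corpus_docs(x)
  ids <- vapply(docs, function(d) d$report_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate report_id in document set: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  stats::setNames(docs, ids)
}

pair_documents <- function(gold, pred) {
  g <- as_doc_list(gold)
  p <- as_doc_list(pred)
  missing_p <- setdiff(names(g), names(p))
  missing_g <- setdiff(names(p), names(g))
  if (length(missing_p) || length(missing_g)) {
    stop(
      "unpaired report ids: ",
      paste(c(
        if (length(missing_p)) {
          paste0("missing from pred: ", paste(missing_p, collapse = ", "))
        },
        if (length(missing_g)) {
          paste0("missing from gold: ", paste(missing_g, collapse = ", "))
        }
      ), collapse = "; "),
      call. = FALSE
    )
  }
  list(gold = g, pred = p[names(g)])
}

entity_keys <- function(docs, negated_only = FALSE) {
  purrr::map_dfr(docs, function(d) {
    en <- d$entities
    if (negated_only) en <- en[en$negated, ]
    tibble(
      report_id = rep(d$report_id, nrow(en)),
      etype = en$etype,
      key = paste(d$report_id, en$start, en$end, en$etype)
    )
  })
}

relation_keys <- function(docs) {
  purrr::map_dfr(docs, function(d) {
    rl <- d$relations
    if (nrow(rl) == 0L) {
      return(tibble(
        report_id = character(), rtype = character(),
        key = character(), ep1 = character(), ep2 = character()
      ))
    }
    en <- d$entities
    io <- match(rl$observation, en$entity_id)
    im <- match(rl$modifier, en$entity_id)
    ep1 <- paste(d$report_id, en$start[io], en$end[io], en$etype[io])
    ep2 <- paste(d$report_id, en$start[im], en$end[im], en$etype[im])
    tibble(
      report_id = d$report_id, rtype = rl$rtype,
      key = paste(rl$rtype, ep1, ep2), ep1 = ep1, ep2 = ep2
    )
  })
}

label_keys <- function(docs) {
  purrr::map_dfr(docs, function(d) {
    sel <- d$labels$label[d$labels$selected]
    tibble(
      report_id = rep(d$report_id, length(sel)),
      etype = sel,
      key = paste(d$report_id, sel)
    )
  })
}

# generic count table: TP by key intersection, FP/FN from the remainders,
# per type plus a TOTAL row over summed counts
count_slice <- function(gold_keys, pred_keys, category, all_types = NULL) {
  tp_keys <- intersect(gold_keys$key, pred_keys$key)
  types <- unique(c(all_types, gold_keys$etype, pred_keys$etype))
  per <- purrr::map_dfr(types, function(t) {
    g <- gold_keys$key[gold_keys$etype == t]
    p <- pred_keys$key[pred_keys$etype == t]
    tibble(
      category = category, type = t,
      tp = length(intersect(g, tp_keys)),
      fp = length(setdiff(p, tp_keys)),
      fn = length(setdiff(g, tp_keys))
    )
  })
  if (nrow(per) == 0L) {
    per <- tibble(
      category = character(), type = character(),
      tp = integer(), fp = integer(), fn = integer()
    )
  }
  tot <- tibble(
    category = category, type = "TOTAL",
    tp = sum(per$tp), fp = sum(per$fp), fn = sum(per$fn)
  )
  out <- dplyr::bind_rows(per, tot)
  dplyr::bind_cols(out, compute_prf(out$tp, out$fp, out$fn, digits = NULL))
}

new_rad_scores <- function(tb) {
  class(tb) <- c("rad_scores", class(tibble()))
  tb
}

#' Score predicted annotations against gold
#'
#' All four scoring operations pair documents by `report_id` (an unpaired
#' id on either side is an error) and count exact matches:
#' * `score_entities()`: an entity matches iff exact character span and
#'   exact type.
#' * `score_negation()`: restricted to negated entities; a TP is a
#'   gold-negated entity whose span/type match in pred is also negated.
#' * `score_relations()`: a match is the same relation type with matched
#'   endpoint entities. With `iaa_mode = TRUE` (the agreement convention),
#'   a relation enters the counts only when both of its endpoint entities
#'   are entity-matches between the two sides.
#' * `score_labels()`: each selected (report, label) pair is one unit.
#'
#' Micro totals (the `TOTAL` row of each category) are computed from the
#' summed TP/FP/FN counts, never by averaging per-type scores. Undefined
#' ratios are `NaN`.
#'
#' @param gold,pred `rad_document` lists or corpus tibbles with a `doc`
#'   column. In inter-annotator use, `gold` is annotator A (the reference
#'   order is arbitrary: swapping the sides swaps precision and recall and
#'   preserves F1).
#' @param iaa_mode See above; default `FALSE` counts all relations.
#' @return A `rad_scores` tibble: one row per type plus a `TOTAL` row, with
#'   columns `category`, `type`, `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1` (unrounded; the print method rounds to 2 decimals).
#' @examples
#' corp <- generate_reports(generator_spec(n_reports = 3), seed = 1)
#' gold <- corp$gold
#' score_entities(gold, gold)
#' @name scoring
NULL

#' @rdname scoring
#' @export
score_entities <- function(gold, pred) {
  pr <- pair_documents(gold, pred)
  new_rad_scores(count_slice(
    entity_keys(pr$gold), entity_keys(pr$pred), "entities"
  ))
}

#' @rdname scoring
#' @export
score_negation <- function(gold, pred) {
  pr <- pair_documents(gold, pred)
  new_rad_scores(count_slice(
    entity_keys(pr$gold, negated_only = TRUE),
    entity_keys(pr$pred, negated_only = TRUE),
    "negation"
  ))
}

#' @rdname scoring
#' @export
score_relations <- function(gold, pred, iaa_mode = FALSE) {
  pr <- pair_documents(gold, pred)
  gk <- relation_keys(pr$gold)
  pk <- relation_keys(pr$pred)
  if (iaa_mode) {
    ge <- entity_keys(pr$gold)$key
    pe <- entity_keys(pr$pred)$key
    agreed <- intersect(ge, pe)
    gk <- gk[gk$ep1 %in% agreed & gk$ep2 %in% agreed, ]
    pk <- pk[pk$ep1 %in% agreed & pk$ep2 %in% agreed, ]
  }
  gk$etype <- gk$rtype
  pk$etype <- pk$rtype
  new_rad_scores(count_slice(gk, pk, "relations",
    all_types = relation_types()
  ))
}

#' @rdname scoring
#' @export
score_labels <- function(gold, pred) {
  pr <- pair_documents(gold, pred)
  new_rad_scores(count_slice(
    label_keys(pr$gold), label_keys(pr$pred), "labels",
    all_types = label_inventory()
  ))
}

#' @rdname scoring
#' @param ... Passed on to the per-category scorers (`iaa_mode`).
#' @export
score_documents <- function(gold, pred, ...) {
  new_rad_scores(dplyr::bind_rows(
    score_entities(gold, pred),
    score_negation(gold, pred),
    score_relations(gold, pred, ...),
    score_labels(gold, pred)
  ))
}

#' @export
print.rad_scores <- function(x, ...) {
  shown <- dplyr::mutate(
    tibble::as_tibble(x),
    dplyr::across(c("precision", "recall", "f1"), ~ round(.x, 2))
  )
  cat("<rad_scores>\n")
  print(shown, n = nrow(shown))
  invisible(x)
}

#' @export
tidy.rad_scores <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.rad_scores <- function(x, ...) {
  tot <- x[x$type == "TOTAL", ]
  tidyr::pivot_wider(
    tot[, c("category", "precision", "recall", "f1")],
    names_from = "category",
    values_from = c("precision", "recall", "f1"),
    names_glue = "{category}_{.value}"
  )
}

#' Plot a score report
#'
#' Bar chart of precision, recall and F1 per type, faceted by category.
#' `NaN` (undefined) values are dropped from the plot.
#'
#' @param object A `rad_scores` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rad_scores <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("precision", "recall", "f1"),
    names_to = "measure", values_to = "value"
  )
  long <- long[!is.nan(long$value), ]
  long$measure <- factor(long$measure,
    levels = c("precision", "recall", "f1")
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$type, y = .data$value, fill = .data$measure
    )
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~category, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "score (0-100)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
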