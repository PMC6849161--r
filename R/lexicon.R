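# Lexicon loading. Entries are one per line in UTF-8 TSV:
#   surface<TAB>type[<TAB>mode]
# with "#" comment lines; mode is "lemma" (default) or "literal".
# Observation entries use the 13 observation type names, modifier entries
# the 4 modifier names; the legacy spelling "microhaemorrhage" is accepted
# as an alias for the microbleed observation type.

type_aliases <- c(
  "microhaemorrhage" = "microbleed",
  "stroke (unknown type)" = "stroke_unknown",
  "ischaemic stroke" = "ischaemic_stroke",
  "haemorrhagic stroke" = "haemorrhagic_stroke",
  "tumour:meningioma" = "tumour_meningioma",
  "tumour:metastasis" = "tumour_metastasis",
  "tumour:glioma" = "tumour_glioma",
  "subdural haematoma" = "subdural_haematoma",
  "small vessel disease" = "small_vessel_disease",
  "subarachnoid haemorrhage" = "subarachnoid_haemorrhage",
  "haemorrhagic transformation" = "haemorrhagic_transformation",
  "loc:deep" = "loc_deep",
  "loc:cortical" = "loc_cortical",
  "time:old" = "time_old",
  "time:recent" = "time_recent"
)

canonical_type <- function(x) {
  x <- trimws(x)
  out <- ifelse(is.na(type_aliases[x]), x, type_aliases[x])
  unname(out)
}

#' Paths of the shipped default resources
#'
#' The starter lexicons, negation/hedge cue list, section-header table and
#' label rule table shipped with the package. All are plain TSV and are
#' meant to be copied and replaced by site-specific versions.
#'
#' @param file File name under the package's `extdata` directory.
#' @return A file path.
#' @export
radlabel_resource <- function(file) {
  system.file("extdata", file, package = "radlabel", mustWork = TRUE)
}

read_lexicon_file <- function(path, allowed_types) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  rows <- list()
  for (i in which(keep)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) {
      stop("lexicon ", basename(path), " line ", i,
        ": expected surface<TAB>type[<TAB>mode]",
        call. = FALSE
      )
    }
    surface <- trimws(parts[1])
    etype <- canonical_type(parts[2])
    mode <- if (length(parts) >= 3L && nzchar(trimws(parts[3]))) {
      trimws(parts[3])
    } else {
      "lemma"
    }
    if (!etype %in% allowed_types) {
      stop("lexicon ", basename(path), " line ", i,
        ": unknown entity type '", trimws(parts[2]), "'",
        call. = FALSE
      )
    }
    if (!mode %in% c("lemma", "literal")) {
      stop("lexicon ", basename(path), " line ", i,
        ": unknown match mode '", mode, "'",
        call. = FALSE
      )
    }
    if (!nzchar(surface)) {
      stop("lexicon ", basename(path), " line ", i, ": empty surface",
        call. = FALSE
      )
    }
    rows[[length(rows) + 1L]] <- tibble(
      surface = surface, etype = etype, mode = mode
    )
  }
  if (length(rows) == 0L) {
    return(tibble(
      surface = character(), etype = character(), mode = character(),
      tokens = list()
    ))
  }
  tb <- dplyr::bind_rows(rows)
  tb <- dplyr::distinct(tb)
  # match sequences are token sequences; lemma-mode sequences are stored
  # lowercased (lookup is against lowercase lemmas)
  tb$tokens <- stringr::str_extract_all(
    ifelse(tb$mode == "lemma", tolower(tb$surface), tb$surface),
    token_pattern
  )
  # deterministic internal order regardless of file order
  tb[order(-lengths(tb$tokens), tb$surface, tb$etype), ]
}

#' Load observation and modifier lexicons
#'
#' @param observations_path,modifiers_path Paths to lexicon TSV files;
#'   default to the shipped starter lexicons, which contain the surface
#'   forms documented for this annotation scheme plus clearly marked common
#'   synonyms (see the files themselves).
#' @return A list with tibbles `observations` and `modifiers`, each with
#'   columns `surface`, `etype`, `mode` and tokenised `tokens`.
#' @examples
#' lex <- load_lexicons()
#' head(lex$modifiers[, 1:3])
#' @export
load_lexicons <- function(observations_path = radlabel_resource("observations.tsv"),
                          modifiers_path = radlabel_resource("modifiers.tsv")) {
  key <- paste(observations_path, modifiers_path, sep = "|")
  cached <- .lexicon_cache[[key]]
  if (!is.null(cached)) {
    return(cached)
  }
  out <- list(
    observations = read_lexicon_file(observations_path, observation_types()),
    modifiers = read_lexicon_file(modifiers_path, modifier_types())
  )
  .lexicon_cache[[key]] <- out
  out
}

.lexicon_cache <- new.env(parent = emptyenv())

#' Load the negation and hedge cue list
#'
#' Same TSV dialect as the lexicons with type column values `negation`
#' (negative determiners/prepositions scoping over their noun group) or
#' `hedge` (non-exclusion constructions such as "cannot be excluded", which
#' the scheme treats as negative).
#'
#' @param path Path to the cue TSV; defaults to the shipped list.
#' @return A tibble with columns `surface`, `cue_type`, `tokens`.
#' @export
load_cues <- function(path = radlabel_resource("negation_cues.tsv")) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  parts <- stringr::str_split_fixed(lines[keep], "\t", 2)
  tb <- tibble(
    surface = trimws(parts[, 1]),
    cue_type = trimws(parts[, 2])
  )
  bad <- which(!tb$cue_type %in% c("negation", "hedge"))
  if (length(bad)) {
    stop("cue file line ", bad[1], ": unknown cue type '",
      tb$cue_type[bad[1]], "'",
      call. = FALSE
    )
  }
  tb$tokens <- stringr::str_extract_all(tolower(tb$surface), token_pattern)
  tb[order(-lengths(tb$tokens), tb$surface), ]
}
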