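#' Closed vocabularies of the annotation scheme
#'
#' The scheme recognises 13 observation entity types (radiological findings),
#' 4 modifier entity types (location and recency qualifiers), 2 relation
#' types, and an inventory of 24 report-level phenotype labels.
#'
#' @return A character vector of the members of the vocabulary.
#' @examples
#' observation_types()
#' modifier_types()
#' label_inventory()
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
observation_types <- function() {
  c(
    "ischaemic_stroke", "haemorrhagic_stroke", "stroke_unknown",
    "tumour_meningioma", "tumour_metastasis", "tumour_glioma", "tumour",
    "subdural_haematoma", "small_vessel_disease", "atrophy", "microbleed",
    "subarachnoid_haemorrhage", "haemorrhagic_transformation"
  )
}

#' @rdname vocabularies
#' @export
modifier_types <- function() {
  c("loc_deep", "loc_cortical", "time_old", "time_recent")
}

#' @rdname vocabularies
#' @export
relation_types <- function() {
  c("mod_loc", "mod_time")
}

#' @rdname vocabularies
#' @export
section_kinds <- function() {
  c("clinical_details", "report_body", "conclusion", "other")
}

#' @rdname vocabularies
#' @export
label_inventory <- function() {
  c(
    "Ischaemic stroke, deep, recent",
    "Ischaemic stroke, deep, old",
    "Ischaemic stroke, cortical, recent",
    "Ischaemic stroke, cortical, old",
    "Ischaemic stroke, underspecified",
    "Haemorrhagic stroke, deep, recent",
    "Haemorrhagic stroke, deep, old",
    "Haemorrhagic stroke, lobar, recent",
    "Haemorrhagic stroke, lobar, old",
    "Haemorrhagic stroke, underspecified",
    "Stroke, underspecified",
    "Tumour, meningioma",
    "Tumour, metastasis",
    "Tumour, glioma",
    "Tumour, other",
    "Small vessel disease",
    "Atrophy",
    "Subdural haematoma",
    "Subarachnoid haemorrhage, aneurysmal",
    "Subarachnoid haemorrhage, other",
    "Microbleed, deep",
    "Microbleed, lobar",
    "Microbleed, underspecified",
    "Haemorrhagic transformation"
  )
}

# entity type category: observation or modifier
entity_category <- function(etype) {
  dplyr::case_when(
    etype %in% observation_types() ~ "observation",
    etype %in% modifier_types() ~ "modifier",
    TRUE ~ NA_character_
  )
}

# observation types eligible for mod_loc / mod_time relations
loc_compatible_observations <- function() {
  c("ischaemic_stroke", "haemorrhagic_stroke", "stroke_unknown", "microbleed")
}

time_compatible_observations <- function() {
  c("ischaemic_stroke", "haemorrhagic_stroke", "stroke_unknown")
}
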