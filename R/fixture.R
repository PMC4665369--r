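# Loader for the curated 64-variant table packaged with mthia.
#
# The table transcribes, per variant: the label in both numbering dialects,
# the canonical base-pair partner in the human structure, the bacterial
# equivalent residue with its partner, a peptide-exit-tunnel flag, and the
# five evidence fields consumed by the classification rubric. Printed quirks
# (stray leading bases in two m. labels, a '?' partner, unlettered bacterial
# cells in one row) are preserved verbatim and flagged in the `note` column.

parse_partner_pos <- function(x) {
  # "115C" -> 115 ; "582C & 583U" -> 582 (first listed) ; "?" / "" -> NA
  n <- suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1", x)))
  ifelse(is.na(x) | !grepl("^[0-9]", x), NA_integer_, n)
}

parse_bacterial_pos <- function(x) {
  # "G468" -> 468 ; "794" -> 794 ; "G997 & C998" -> 997 ; "" -> NA
  m <- regmatches(x, regexpr("[0-9]+", x))
  out <- rep(NA_integer_, length(x))
  has <- !is.na(x) & lengths(regmatches(x, gregexpr("[0-9]+", x))) > 0
  out[has] <- as.integer(sub("^[A-Za-z]*([0-9]+).*$", "\\1", x[has]))
  out
}

#' Load the packaged curated variant table for the human 16S mt-rRNA
#'
#' Returns the 64 rare variants with their residue equivalences across
#' structures and the evidence profile used by [classify_variants()]. Labels
#' are parsed into canonical machine columns while the printed labels are
#' kept verbatim in `label_rrna` / `label_mt`.
#'
#' @param path Path to a fixture TSV; defaults to the packaged table.
#' @param mapper Coordinate mapper used to cross-check/complete numbering.
#' @return A tibble with one row per variant: printed labels, parsed variant
#'   columns (`event`, `rrna_position`, `mt_position`, `ref_allele`,
#'   `alt_allele`), equivalence columns (`human_partner`,
#'   `bacterial_equivalent`, `bacterial_partner`, parsed `*_pos` variants,
#'   `tunnel_flag`), and the evidence profile columns.
#' @export
load_variant_fixture <- function(path = system.file("extdata",
                                                    "table1_variants.tsv",
                                                    package = "mthia"),
                                 mapper = new_mapper()) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character())
  parsed <- parse_variant_label(raw$label_rrna, mapper = mapper)
  tibble(
    category = raw$category,
    label_rrna = raw$label_rrna,
    label_mt = raw$label_mt,
    event = parsed$event,
    rrna_position = parsed$rrna_position,
    mt_position = parsed$mt_position,
    ref_allele = parsed$ref_allele,
    alt_allele = parsed$alt_allele,
    human_partner = raw$human_partner,
    human_partner_pos = parse_partner_pos(raw$human_partner),
    bacterial_equivalent = raw$bacterial_equivalent,
    bacterial_equivalent_pos = parse_bacterial_pos(raw$bacterial_equivalent),
    bacterial_partner = raw$bacterial_partner,
    bacterial_partner_pos = parse_bacterial_pos(raw$bacterial_partner),
    tunnel_flag = raw$tunnel == "Y",
    placeable_on_structure = as.logical(raw$placeable_on_structure),
    heterologous_data_exists = as.logical(raw$heterologous_data_exists),
    direct_heterologous = raw$direct_heterologous,
    indirect_heterologous = raw$indirect_heterologous,
    direct_mito_biochemical = as.logical(raw$direct_mito_biochemical),
    note = raw$note
  )
}

#' Cross-check the mt. labels of a fixture against its rRNA labels
#'
#' Parses both label columns independently and verifies that their positions
#' agree under the calibrated offset. Used in tests; exported because it is
#' the natural sanity check for user-supplied fixtures.
#'
#' @param fixture A tibble from [load_variant_fixture()].
#' @param mapper Coordinate mapper.
#' @return Invisibly `TRUE`; errors if any row disagrees.
#' @export
check_fixture_numbering <- function(fixture, mapper = new_mapper()) {
  mt_parsed <- parse_variant_label(fixture$label_mt, mapper = mapper)
  bad <- which(mt_parsed$mt_position != fixture$mt_position |
                 mt_parsed$rrna_position != fixture$rrna_position)
  if (length(bad)) {
    abort(sprintf("numbering mismatch in rows: %s",
                  paste(fixture$label_rrna[bad], collapse = ", ")),
          class = "mthia_calibration_error")
  }
  invisible(TRUE)
}
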