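# The disruptive-power rubric.
#
# Seven categories describe how strongly the available evidence argues that a
# variant disrupts mitoribosomal function:
#   P   proven             — direct biochemical evidence in the mitochondrial
#                            system itself (e.g. cybrid studies)
#   und undetermined       — the site cannot be placed on the high-resolution
#                            structure, or no heterologous data exist /
#                            structural differences are too large
#   E   expectedly disruptive — direct heterologous mutagenesis at the residue
#                            or its base-pairing partner supports disruption
#   N   certainly not disruptive — direct heterologous data support tolerance
#   L   likely disruptive  — only indirect heterologous data, favouring
#                            disruption
#   U   unlikely disruptive — only indirect heterologous data, favouring
#                            tolerance
#   NEE not enough evidence — nothing argues either way
#
# The decision is a fixed priority cascade: P beats everything (direct
# homologous biochemistry outranks any inference), then placeability /
# existence of heterologous data, then direct over indirect evidence.

.hia_categories <- c("NEE", "U", "und", "L", "E", "P", "N")
.evidence_levels <- c("none", "supports_disruption", "supports_tolerance")

#' Classify an evidence profile into a disruptive-potential category
#'
#' Vectorised over the profile columns. The priority cascade is:
#' `direct_mito_biochemical` → P; not placeable on the structure or no
#' heterologous data → und; direct heterologous disruption support → E;
#' direct tolerance support → N; indirect disruption support → L; indirect
#' tolerance support → U; otherwise NEE.
#'
#' @param profile Data frame with logical columns `placeable_on_structure`,
#'   `heterologous_data_exists`, `direct_mito_biochemical` and character
#'   columns `direct_heterologous`, `indirect_heterologous` (each one of
#'   `"none"`, `"supports_disruption"`, `"supports_tolerance"`).
#' @return Character vector of category codes, one per row.
#' @export
#' @examples
#' classify_evidence(tibble::tibble(
#'   placeable_on_structure = TRUE, heterologous_data_exists = TRUE,
#'   direct_heterologous = "none", indirect_heterologous = "supports_disruption",
#'   direct_mito_biochemical = FALSE))  # "L"
classify_evidence <- function(profile) {
  needed <- c("placeable_on_structure", "heterologous_data_exists",
              "direct_heterologous", "indirect_heterologous",
              "direct_mito_biochemical")
  missing <- setdiff(needed, names(profile))
  if (length(missing)) {
    abort(sprintf("profile lacks columns: %s", paste(missing, collapse = ", ")),
          class = "mthia_input_error")
  }
  bad_lvl <- !profile$direct_heterologous %in% .evidence_levels |
    !profile$indirect_heterologous %in% .evidence_levels
  if (any(bad_lvl)) {
    abort("evidence fields must be one of none/supports_disruption/supports_tolerance",
          class = "mthia_input_error")
  }
  # invariant: direct heterologous evidence implies heterologous data exist
  viol <- profile$direct_heterologous != "none" & !profile$heterologous_data_exists
  if (any(viol)) {
    abort("direct heterologous evidence recorded but heterologous_data_exists is FALSE",
          class = "mthia_input_error")
  }
  dplyr::case_when(
    profile$direct_mito_biochemical ~ "P",
    !profile$placeable_on_structure | !profile$heterologous_data_exists ~ "und",
    profile$direct_heterologous == "supports_disruption" ~ "E",
    profile$direct_heterologous == "supports_tolerance" ~ "N",
    profile$indirect_heterologous == "supports_disruption" ~ "L",
    profile$indirect_heterologous == "supports_tolerance" ~ "U",
    TRUE ~ "NEE"
  )
}

#' Classify every variant of a fixture and tally the categories
#'
#' @param fixture Tibble with the evidence-profile columns (e.g. from
#'   [load_variant_fixture()]).
#' @return The input with a `code` column appended, of class
#'   `hia_classification`; the category histogram is available via
#'   [category_histogram()] or `glance()`.
#' @export
classify_variants <- function(fixture) {
  out <- dplyr::mutate(fixture, code = classify_evidence(fixture))
  class(out) <- c("hia_classification", class(out))
  out
}

#' Category histogram of a classification
#'
#' @param classified Output of [classify_variants()].
#' @return Named integer vector over all seven codes (zeros kept).
#' @export
category_histogram <- function(classified) {
  stopifnot("code" %in% names(classified))
  tab <- table(factor(classified$code, levels = .hia_categories))
  setNames(as.integer(tab), names(tab))
}

#' @export
glance.hia_classification <- function(x, ...) {
  h <- category_histogram(x)
  tibble(!!!as.list(h), total = nrow(x))
}

#' @importFrom generics glance
#' @export
generics::glance

#' Bar chart of disruptive-potential categories
#'
#' @param object Output of [classify_variants()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hia_classification <- function(object, ...) {
  h <- category_histogram(object)
  df <- tibble(code = factor(names(h), levels = .hia_categories), n = h)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$code, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "disruptive-potential category", y = "variants") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
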