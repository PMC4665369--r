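# Report assembly: the classified-variant table grouped by category in the
# conventional presentation order, plus the category histogram, serialized
# as byte-stable TSV.

.category_order <- c(NEE = "NEE", U = "Unlikely", und = "Undetermined",
                     L = "Likely", E = "Expectedly", P = "Proven",
                     N = "Certainly not")

#' Assemble the classified-variant report
#'
#' Rows are grouped by category in the presentation order NEE, Unlikely,
#' Undetermined, Likely, Expectedly, Proven (then Certainly-not, when
#' present) and ordered by rRNA position within each group. The category
#' histogram is attached as attribute `"histogram"` and equals
#' [category_histogram()] of the input.
#'
#' @param classified Output of [classify_variants()] (non-empty).
#' @return A `hia_report` tibble.
#' @export
build_report <- function(classified) {
  if (!nrow(classified)) {
    abort("nothing to report: empty classification", class = "mthia_input_error")
  }
  hist <- category_histogram(classified)
  cols <- intersect(
    c("category_label", "label_rrna", "label_mt", "event",
      "rrna_position", "mt_position", "human_partner",
      "bacterial_equivalent", "bacterial_partner", "tunnel_flag",
      "conservation_code", "cv", "note", "code"),
    c(names(classified), "category_label"))
  out <- classified |>
    dplyr::mutate(category_label = unname(.category_order[.data$code])) |>
    dplyr::arrange(factor(.data$code, levels = names(.category_order)),
                   .data$rrna_position) |>
    dplyr::select(dplyr::all_of(cols))
  out <- tibble::as_tibble(out)
  attr(out, "histogram") <- hist
  class(out) <- c("hia_report", class(out))
  out
}

#' Write a report as byte-stable TSV
#'
#' Fixed column order, tab separators, LF line endings, empty strings for
#' missing cells; two runs on the same report produce identical bytes, and
#' [read_report()] round-trips the table.
#'
#' @param report A `hia_report` (or any tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  df <- as.data.frame(report)
  readr::write_tsv(df, path, na = "", eol = "\n")
  invisible(path)
}

#' Read back a TSV report
#'
#' @param path Path written by [write_report()].
#' @return Tibble with the same columns and types as the written report.
#' @export
read_report <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    rrna_position = "i", mt_position = "i", tunnel_flag = "l",
    .default = "c"), na = character())
  if ("cv" %in% names(out)) out$cv <- as.numeric(out$cv)
  out
}

#' Summarise a report as JSON
#'
#' Writes the category histogram and row count; requires the jsonlite
#' package.
#'
#' @param report A `hia_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("jsonlite is required for JSON summaries", class = "mthia_input_error")
  }
  hist <- attr(report, "histogram")
  jsonlite::write_json(list(histogram = as.list(hist), total = nrow(report)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
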