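# Variant representation, label parsing and rCRS <-> rRNA coordinate mapping.
#
# Two numbering systems coexist in the mt-rRNA literature: "m." coordinates on
# the revised Cambridge Reference Sequence (rCRS, NC_012920.1) and 1-based
# residue indices within the 16S (MT-RNR2) rRNA itself. The two differ by a
# single constant offset over the gene span, which calibrate_mapper() derives
# from any table carrying both numberings.

#' Create a coordinate mapper between rRNA residue and rCRS numbering
#'
#' @param offset Integer, `mt_position - rrna_position`. The default (1670)
#'   corresponds to the annotated rCRS 16S gene.
#' @param gene_span Inclusive 1-based rCRS interval of the 16S gene.
#' @return An object of class `mt_mapper`.
#' @export
#' @examples
#' m <- new_mapper()
#' rrna_to_mtdna(173, m)  # 1843
new_mapper <- function(offset = 1670L, gene_span = c(1671L, 3229L)) {
  offset <- as.integer(offset)
  gene_span <- as.integer(gene_span)
  stopifnot(length(offset) == 1L, length(gene_span) == 2L,
            gene_span[1] <= gene_span[2])
  structure(list(offset = offset, gene_span = gene_span),
            class = "mt_mapper")
}

#' @export
print.mt_mapper <- function(x, ...) {
  cat(sprintf("<mt_mapper> offset %d, gene span m.%d-%d (rRNA 1-%d)\n",
              x$offset, x$gene_span[1], x$gene_span[2],
              x$gene_span[2] - x$offset))
  invisible(x)
}

#' Calibrate the coordinate offset from a double-numbered variant table
#'
#' Derives the single constant offset `mt_position - rrna_position` from every
#' row of `fixture` that carries both numberings, and fails loudly if any two
#' rows disagree.
#'
#' @param fixture Data frame with numeric columns `rrna_position` and
#'   `mt_position` (rows with either missing are ignored).
#' @param gene_span Passed to [new_mapper()].
#' @return An `mt_mapper`.
#' @export
calibrate_mapper <- function(fixture, gene_span = c(1671L, 3229L)) {
  stopifnot(is.data.frame(fixture),
            all(c("rrna_position", "mt_position") %in% names(fixture)))
  rows <- fixture[!is.na(fixture$rrna_position) & !is.na(fixture$mt_position), ]
  if (nrow(rows) < 2L) {
    abort("calibration needs at least 2 rows with both numberings",
          class = "mthia_calibration_error")
  }
  offsets <- rows$mt_position - rows$rrna_position
  if (length(unique(offsets)) != 1L) {
    bad <- rows[offsets != offsets[1], ]
    abort(sprintf(
      "inconsistent offsets: %s",
      paste(sprintf("rRNA %d vs m.%d (offset %d)",
                    bad$rrna_position, bad$mt_position,
                    bad$mt_position - bad$rrna_position),
            collapse = "; ")),
      class = "mthia_calibration_error")
  }
  new_mapper(offset = offsets[1], gene_span = gene_span)
}

span_check <- function(pos, mapper, numbering = c("mt", "rrna")) {
  numbering <- match.arg(numbering)
  lo <- mapper$gene_span[1]; hi <- mapper$gene_span[2]
  if (numbering == "rrna") { lo <- lo - mapper$offset; hi <- hi - mapper$offset }
  bad <- !is.na(pos) & (pos < lo | pos > hi)
  if (any(bad)) {
    abort(sprintf("position %s outside the 16S gene span [%d, %d] (%s numbering)",
                  paste(pos[bad], collapse = ", "), lo, hi, numbering),
          class = "mthia_range_error")
  }
  invisible(pos)
}

#' Convert between rRNA residue numbering and rCRS (m.) coordinates
#'
#' The mapping is a bijection on the 16S gene span; positions outside it are
#' an error.
#'
#' @param pos Integer vector of positions.
#' @param mapper An [new_mapper()] object.
#' @return Integer vector of converted positions.
#' @export
rrna_to_mtdna <- function(pos, mapper = new_mapper()) {
  pos <- as.integer(pos)
  span_check(pos, mapper, "rrna")
  pos + mapper$offset
}

#' @rdname rrna_to_mtdna
#' @export
mtdna_to_rrna <- function(pos, mapper = new_mapper()) {
  pos <- as.integer(pos)
  span_check(pos, mapper, "mt")
  pos - mapper$offset
}

# ---------------------------------------------------------------------------
# Label parsing

rna_of <- function(x) gsub("T", "U", toupper(x))
dna_of <- function(x) gsub("U", "T", toupper(x))

normalise_label <- function(label) {
  x <- trimws(label)
  x <- gsub("–|—", "-", x)   # en/em dash -> hyphen
  x <- gsub("≥", ">", x)          # ">=" glyph used in running text
  x <- gsub("\\s*>\\s*", ">", x)
  x
}

variant_row <- function(label, dialect, event, pos, ref, alt,
                        run_base = NA_character_,
                        run_before = NA_integer_, run_after = NA_integer_,
                        mapper) {
  if (dialect == "mt") {
    mt <- pos
    rrna <- if (!is.null(mapper)) mtdna_to_rrna(pos, mapper) else NA_integer_
  } else {
    rrna <- pos
    mt <- if (!is.null(mapper)) rrna_to_mtdna(pos, mapper) else NA_integer_
  }
  tibble(
    label = label, dialect = dialect, event = event,
    rrna_position = as.integer(rrna), mt_position = as.integer(mt),
    ref_allele = rna_of(ref), alt_allele = rna_of(alt),
    run_base = if (is.na(run_base)) run_base else rna_of(run_base),
    run_before = run_before, run_after = run_after
  )
}

parse_one_label <- function(label, mapper) {
  x <- normalise_label(label)
  dialect <- if (grepl("^m\\.", x)) "mt" else "rrna"
  body <- sub("^m\\.", "", x)

  B <- "[ACGTUacgtu]"
  m <- regmatches(body, regexec(
    sprintf("^(\\d+)\\s*-\\s*(\\d+)\\s*[Dd][Uu][Pp](%s+)$", B), body))[[1]]
  if (length(m)) {
    start <- as.integer(m[2]); end <- as.integer(m[3]); unit <- m[4]
    if (end - start + 1L != nchar(unit)) {
      abort(sprintf("duplication span %d-%d does not match unit '%s'",
                    start, end, unit), class = "mthia_parse_error")
    }
    return(variant_row(label, dialect, "duplication", start,
                       ref = unit, alt = paste0(unit, unit), mapper = mapper))
  }

  m <- regmatches(body, regexec(
    sprintf("^(\\d+)\\s*[Dd][Ee][Ll](%s+)$", B), body))[[1]]
  if (length(m)) {
    return(variant_row(label, dialect, "deletion", as.integer(m[2]),
                       ref = m[3], alt = "", mapper = mapper))
  }

  m <- regmatches(body, regexec(
    sprintf("^(\\d+)\\s*[Ii][Nn][Ss](%s+)$", B), body))[[1]]
  if (length(m)) {
    return(variant_row(label, dialect, "insertion", as.integer(m[2]),
                       ref = "", alt = m[3], mapper = mapper))
  }

  # homopolymer run-length change: "449 3T>4T"
  m <- regmatches(body, regexec(
    sprintf("^(\\d+)\\s+(\\d+)(%s)>(\\d+)(%s)$", B, B), body))[[1]]
  if (length(m)) {
    if (rna_of(m[4]) != rna_of(m[6])) {
      abort(sprintf("homopolymer label '%s' changes base identity", label),
            class = "mthia_parse_error")
    }
    n0 <- as.integer(m[3]); n1 <- as.integer(m[5]); base <- m[4]
    return(variant_row(label, dialect, "homopolymer_length_change",
                       as.integer(m[2]),
                       ref = strrep(base, n0), alt = strrep(base, n1),
                       run_base = base, run_before = n0, run_after = n1,
                       mapper = mapper))
  }

  # substitution, tolerating a stray leading base letter ("m.C1905C>A")
  m <- regmatches(body, regexec(
    sprintf("^(%s?)(\\d+)(%s)>(%s)$", B, B, B), body))[[1]]
  if (length(m)) {
    ref <- m[4]; alt <- m[5]
    if (rna_of(ref) == rna_of(alt)) {
      abort(sprintf("substitution '%s' has identical ref and alt", label),
            class = "mthia_parse_error")
    }
    return(variant_row(label, dialect, "substitution", as.integer(m[3]),
                       ref = ref, alt = alt, mapper = mapper))
  }

  bad <- regmatches(body, regexpr("[^0-9ACGTUacgtu> .-]+|^[A-Za-z]+", body))
  abort(sprintf("cannot parse variant label '%s'%s", label,
                if (length(bad) && nzchar(bad)) sprintf(" (offending token '%s')", bad)
                else ""),
        class = "mthia_parse_error")
}

#' Parse variant labels in the field's mixed dialects
#'
#' Understands the label styles used for mt-rRNA variants: substitutions
#' (`"1010U > C"`, `"m.2680T > C"`, tolerating a stray leading reference base
#' as in `"m.C1905C > A"`), deletions (`"404delA"`), insertions
#' (`"1328 InsU"`), duplications (`"478-479 dupAG"`, en-dash or hyphen) and
#' homopolymer run-length changes (`"449 3T > 4T"`). Alleles are stored in
#' the RNA alphabet (T is converted to U on ingest); the original dialect
#' ("rrna" or "mt") is recorded.
#'
#' @param label Character vector of labels.
#' @param mapper An [new_mapper()]; used to fill in the other numbering.
#'   Pass `NULL` to skip mapping (positions outside the default gene span).
#' @return A tibble with one row per label: `label`, `dialect`, `event`,
#'   `rrna_position`, `mt_position`, `ref_allele`, `alt_allele`, `run_base`,
#'   `run_before`, `run_after`.
#' @export
#' @examples
#' parse_variant_label(c("m.2680T > C", "404delA", "449 3T > 4T"))
parse_variant_label <- function(label, mapper = new_mapper()) {
  map_dfr(label, parse_one_label, mapper = mapper)
}

#' Format a parsed variant back to a canonical label
#'
#' The canonical form round-trips: parsing the formatted label reproduces an
#' equal variant row.
#'
#' @param variant One-or-more-row tibble as returned by
#'   [parse_variant_label()].
#' @param dialect `"rrna"` (RNA alphabet, residue numbering) or `"mt"`
#'   (DNA alphabet, m. numbering); defaults to each row's original dialect.
#' @return Character vector of labels.
#' @export
format_variant_label <- function(variant, dialect = NULL) {
  stopifnot(is.data.frame(variant))
  map_chr(seq_len(nrow(variant)), function(i) {
    v <- variant[i, ]
    d <- dialect %||% v$dialect
    pos <- if (d == "mt") v$mt_position else v$rrna_position
    conv <- if (d == "mt") dna_of else rna_of
    prefix <- if (d == "mt") "m." else ""
    switch(v$event,
      substitution = sprintf("%s%d%s>%s", prefix, pos,
                             conv(v$ref_allele), conv(v$alt_allele)),
      deletion = sprintf("%s%ddel%s", prefix, pos, conv(v$ref_allele)),
      insertion = sprintf("%s%dins%s", prefix, pos, conv(v$alt_allele)),
      duplication = sprintf("%s%d-%ddup%s", prefix, pos,
                            pos + nchar(v$ref_allele) - 1L, conv(v$ref_allele)),
      homopolymer_length_change = sprintf("%s%d %d%s>%d%s", prefix, pos,
                                          v$run_before, conv(v$run_base),
                                          v$run_after, conv(v$run_base)),
      abort(sprintf("unknown event '%s'", v$event))
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
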