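# Population-frequency rarity filter.
#
# Candidate variants are kept for structural analysis only when they are
# genuinely rare: at most `threshold` appearances in the combined population,
# and none of those appearances outside the sources that reported the
# variant as potentially pathogenic ("novel" appearances). Each population
# sequence is globally aligned to the reference, variants are extracted with
# indels left-normalized, and appearances are tallied per distinct variant.

check_alphabet <- function(seq, what) {
  if (!nzchar(seq)) {
    abort(sprintf("%s sequence is empty", what), class = "mthia_input_error")
  }
  bad <- gsub("[ACGTNacgtn]", "", seq)
  if (nzchar(bad)) {
    abort(sprintf("%s sequence contains unsupported symbols: %s",
                  what, paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")),
          class = "mthia_input_error")
  }
  invisible(TRUE)
}

#' Globally align a sequence to the reference
#'
#' Needleman-Wunsch global alignment with affine gaps (match +1, mismatch
#' -1, gap open -5, gap extend -1 by default), as provided by Biostrings.
#' Deterministic under fixed parameters; indel placement within repeats is
#' normalized downstream by [call_variants()].
#'
#' @param seq,reference DNA strings over A/C/G/T/N.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (penalties
#'   given as positive numbers).
#' @return List with aligned strings `seq` and `ref` (equal length, `-` for
#'   gaps) and `score`.
#' @export
align_to_reference <- function(seq, reference, match = 1, mismatch = -1,
                               gap_open = 5, gap_extend = 1) {
  check_alphabet(seq, "query"); check_alphabet(reference, "reference")
  al <- Biostrings::pairwiseAlignment(
    toupper(seq), toupper(reference), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE),
    gapOpening = gap_open, gapExtension = gap_extend)
  list(seq = as.character(Biostrings::pattern(al)),
       ref = as.character(Biostrings::subject(al)),
       score = Biostrings::score(al))
}

left_normalize <- function(pos, allele, ref_chars) {
  # VCF-style left shift of an indel: while the base before the event equals
  # the event's last base, move one step left
  allele_c <- strsplit(allele, "")[[1]]
  while (pos > 1 && ref_chars[pos - 1] == allele_c[length(allele_c)]) {
    allele_c <- c(ref_chars[pos - 1], allele_c[-length(allele_c)])
    pos <- pos - 1
  }
  list(pos = pos, allele = paste(allele_c, collapse = ""))
}

#' Extract variants from a pairwise alignment
#'
#' Walks the alignment columns, emitting substitutions and run-merged
#' indels in reference coordinates. Indels are left-normalized (shifted to
#' the leftmost equivalent position within a repeat). Columns involving `N`
#' in either sequence call nothing.
#'
#' @param alignment Output of [align_to_reference()].
#' @param mapper Optional [new_mapper()]; when given, an `mt_position`
#'   column (reference coordinate mapped into m. numbering) is added.
#' @return Tibble with `pos` (1-based reference coordinate; for insertions
#'   the base after which the insertion occurs), `event`, `ref_allele`,
#'   `alt_allele`, `key` (canonical label).
#' @export
call_variants <- function(alignment, mapper = NULL) {
  s <- strsplit(alignment$seq, "")[[1]]
  r <- strsplit(alignment$ref, "")[[1]]
  stopifnot(length(s) == length(r))
  ref_chars <- r[r != "-"]
  refpos <- cumsum(r != "-")   # reference coordinate at each column

  vars <- list()
  i <- 1; L <- length(s)
  while (i <= L) {
    if (r[i] != "-" && s[i] != "-") {
      if (s[i] != r[i] && s[i] != "N" && r[i] != "N") {
        vars[[length(vars) + 1L]] <- tibble(
          pos = refpos[i], event = "substitution",
          ref_allele = r[i], alt_allele = s[i])
      }
      i <- i + 1
    } else if (s[i] == "-") {        # deletion (run)
      j <- i
      while (j <= L && s[j] == "-") j <- j + 1
      del <- paste(r[i:(j - 1)], collapse = "")
      if (!grepl("N", del)) {
        nl <- left_normalize(refpos[i], del, ref_chars)
        vars[[length(vars) + 1L]] <- tibble(
          pos = nl$pos, event = "deletion",
          ref_allele = nl$allele, alt_allele = "")
      }
      i <- j
    } else {                          # insertion (run), r[i] == "-"
      j <- i
      while (j <= L && r[j] == "-") j <- j + 1
      ins <- paste(s[i:(j - 1)], collapse = "")
      if (!grepl("N", ins)) {
        anchor <- refpos[i]           # base after which the insertion sits
        nl <- left_normalize(anchor + 1L, ins, ref_chars)
        vars[[length(vars) + 1L]] <- tibble(
          pos = nl$pos - 1L, event = "insertion",
          ref_allele = "", alt_allele = nl$allele)
      }
      i <- j
    }
  }
  out <- if (length(vars)) dplyr::bind_rows(vars) else {
    tibble(pos = integer(), event = character(),
           ref_allele = character(), alt_allele = character())
  }
  out <- dplyr::mutate(out, key = dplyr::case_when(
    event == "substitution" ~ sprintf("%d%s>%s", pos, ref_allele, alt_allele),
    event == "deletion" ~ sprintf("%ddel%s", pos, ref_allele),
    event == "insertion" ~ sprintf("%dins%s", pos, alt_allele)))
  if (!is.null(mapper)) {
    out <- dplyr::mutate(out, mt_position = rrna_to_mtdna(pos, mapper))
  }
  out
}

#' Count appearances of every variant across a population
#'
#' Aligns each population sequence to the reference, calls variants and
#' tallies appearances. Appearances in sequences whose provenance tag is
#' `"known_reporting_source"` are not counted as novel.
#'
#' @param population A `population_set` (see [gen_population()] /
#'   [read_population_fasta()]).
#' @param mapper Optional coordinate mapper, passed to [call_variants()].
#' @param ... Alignment parameters passed to [align_to_reference()].
#' @return Tibble with one row per distinct variant: `key`, `pos`, `event`,
#'   `ref_allele`, `alt_allele`, `total`, `novel`.
#' @export
count_appearances <- function(population, mapper = NULL, ...) {
  ids <- population$sequences$id
  if (anyDuplicated(ids)) {
    abort("duplicate sequence ids in population", class = "mthia_input_error")
  }
  tags <- population$provenance$tag[match(ids, population$provenance$id)]
  per_seq <- purrr::map(seq_along(ids), function(i) {
    al <- align_to_reference(population$sequences$seq[i],
                             population$reference$seq, ...)
    v <- call_variants(al, mapper = mapper)
    if (nrow(v)) v$novel_hit <- tags[i] != "known_reporting_source"
    v
  })
  all_v <- dplyr::bind_rows(per_seq)
  if (!nrow(all_v)) {
    return(tibble(key = character(), pos = integer(), event = character(),
                  ref_allele = character(), alt_allele = character(),
                  total = integer(), novel = integer()))
  }
  all_v |>
    dplyr::group_by(.data$key, .data$pos, .data$event, .data$ref_allele,
                    .data$alt_allele) |>
    dplyr::summarise(total = dplyr::n(), novel = sum(.data$novel_hit),
                     .groups = "drop") |>
    dplyr::arrange(.data$pos, .data$key)
}

#' Apply the rarity filter to variant counts
#'
#' A variant is retained iff its total appearance count is at most
#' `threshold` and it has no novel appearances (appearances outside known
#' reporting sources).
#'
#' @param counts Tibble from [count_appearances()].
#' @param threshold Maximum allowed total appearances (default 15).
#' @return The input with `retained` and `reason` columns
#'   (`above_threshold` / `novel_appearances` / `retained`).
#' @export
apply_rarity_filter <- function(counts, threshold = 15L) {
  stopifnot(threshold >= 0)
  dplyr::mutate(counts,
    retained = .data$total <= threshold & .data$novel == 0L,
    reason = dplyr::case_when(
      .data$total > threshold ~ "above_threshold",
      .data$novel > 0 ~ "novel_appearances",
      TRUE ~ "retained"))
}
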