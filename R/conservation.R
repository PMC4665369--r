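# Conservation index over multiple-alignment columns, and the interaction
# conservation code strings used to annotate tertiary contacts.
#
# The index lives on a 0-2 scale: 2.000 for a gap-free, single-base column
# (universal conservation), decreasing with column entropy, and discounted by
# the fraction of gapped rows. With base-2 logarithms a gap-free 50/50
# two-base column scores exactly 1, and a uniform four-base column 0.

.aln_symbols <- c("A", "C", "G", "U", "-")

#' Symbol frequencies of an alignment column
#'
#' @param column Character vector over `A,C,G,U` plus `-` (gap); `T` is
#'   accepted and read as `U`.
#' @return A one-row tibble with columns `A`, `C`, `G`, `U` (frequencies over
#'   the non-gap rows; all zero if the column is fully gapped), `gap_fraction`
#'   and `n`.
#' @export
column_frequencies <- function(column) {
  stopifnot(length(column) >= 1)
  column <- gsub("T", "U", toupper(column))
  bad <- setdiff(unique(column), .aln_symbols)
  if (length(bad)) {
    abort(sprintf("unknown alignment symbol(s): %s", paste(bad, collapse = ", ")),
          class = "mthia_input_error")
  }
  n <- length(column)
  gaps <- sum(column == "-")
  bases <- column[column != "-"]
  freq <- if (length(bases)) {
    as.numeric(table(factor(bases, levels = c("A", "C", "G", "U")))) / length(bases)
  } else rep(0, 4)
  tibble(A = freq[1], C = freq[2], G = freq[3], U = freq[4],
         gap_fraction = gaps / n, n = n)
}

shannon_cv <- function(freqs, gap_fraction) {
  p <- freqs[freqs > 0]
  h <- if (length(p)) -sum(p * log2(p)) else 0
  if (sum(freqs) == 0) return(0)   # fully gapped column
  (2 - h) * (1 - gap_fraction)
}

#' Conservation index of an alignment column
#'
#' Computes `cv = (2 - H) * (1 - gap_fraction)` where `H` is the Shannon
#' entropy (bits) of the non-gap base frequencies; a fully gapped column
#' scores 0. The scoring function is pluggable: pass any
#' `function(freqs, gap_fraction)` to use a different definition on the same
#' 0-2 scale.
#'
#' @param column Character vector as for [column_frequencies()].
#' @param method Scoring function; default is the entropy-based index.
#' @return A one-row tibble with `cv` and `gap_fraction`.
#' @export
#' @examples
#' conservation_index(rep("U", 100))$cv        # 2
#' conservation_index(rep(c("A", "G"), 50))$cv # 1
conservation_index <- function(column, method = shannon_cv) {
  f <- column_frequencies(column)
  cv <- method(c(f$A, f$C, f$G, f$U), f$gap_fraction)
  tibble(cv = cv, gap_fraction = f$gap_fraction)
}

# ---------------------------------------------------------------------------
# Interaction-conservation code strings

.code_sources <- c(b = "bacterial", e = "eukaryotic", a = "archaeal",
                   m = "mammalian_mito", M = "yeast_mito")
.code_statuses <- c("observed", "unmodelled_partners_present",
                    "partner_absent", "not_observed")

#' Render an interaction-conservation code string
#'
#' An interaction observed across ribosomes is annotated with a `C` followed
#' by one letter per source in the fixed order bacterial (`b`), eukaryotic
#' (`e`), archaeal (`a`), mammalian mitochondrial (`m`), yeast mitochondrial
#' (`M`). A source where the interaction is not modelled but all partners
#' are present renders as `+`; a source missing one partner as `-`; a source
#' where the interaction is absent despite present partners as `?`. If no
#' source shows the interaction, the leading `C` is dropped.
#'
#' @param statuses Character vector of length 5, in source order b,e,a,m,M;
#'   each one of `"observed"`, `"unmodelled_partners_present"`,
#'   `"partner_absent"`, `"not_observed"`.
#' @return The rendered code string.
#' @export
#' @examples
#' conservation_code(rep("observed", 5))                       # "CbeamM"
#' conservation_code(c(rep("observed", 4), "partner_absent"))  # "Cbeam-"
conservation_code <- function(statuses) {
  if (length(statuses) != 5) {
    abort("exactly five source statuses required (order b, e, a, m, M)",
          class = "mthia_input_error")
  }
  bad <- setdiff(statuses, .code_statuses)
  if (length(bad)) {
    abort(sprintf("unknown status token(s): %s", paste(bad, collapse = ", ")),
          class = "mthia_input_error")
  }
  glyphs <- ifelse(statuses == "observed", names(.code_sources),
            ifelse(statuses == "unmodelled_partners_present", "+",
            ifelse(statuses == "partner_absent", "-", "?")))
  prefix <- if (any(statuses == "observed")) "C" else ""
  paste0(prefix, paste(glyphs, collapse = ""))
}
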