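# Atomic-coordinate I/O.
#
# A structure is an ordinary tibble of atoms — one row per atom with columns
# chain, resno, resname, atom, x, y, z, element — so every geometric
# operation downstream is a data-frame verb. Parsing of the standard formats
# is delegated to bio3d (read.pdb / read.cif); the writers here are minimal,
# byte-stable serializers used for synthetic models and round-trip tests.

#' Construct/validate a structure tibble
#'
#' @param df Data frame with columns `chain`, `resno`, `resname`, `atom`,
#'   `x`, `y`, `z` and optionally `element` (derived from the atom name when
#'   absent).
#' @return A validated structure tibble.
#' @export
as_structure <- function(df) {
  needed <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    abort(sprintf("structure lacks columns: %s", paste(missing, collapse = ", ")),
          class = "mthia_input_error")
  }
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    abort("non-finite coordinates in structure", class = "mthia_input_error")
  }
  if (!"element" %in% names(df)) {
    df$element <- substr(gsub("[^A-Za-z].*$", "", df$atom), 1, 1)
  }
  dup <- duplicated(df[, c("chain", "resno", "atom")])
  if (any(dup)) {
    abort("duplicated atom address (chain/resno/atom) in structure",
          class = "mthia_input_error")
  }
  tibble::as_tibble(df[, c(needed, "element")])
}

validate_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM|HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      abort(sprintf("malformed ATOM/HETATM record at line %d (too short)", i),
            class = "mthia_parse_error")
    }
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(coords))))) {
      abort(sprintf("malformed coordinates in ATOM/HETATM record at line %d", i),
            class = "mthia_parse_error")
    }
  }
  invisible(TRUE)
}

#' Read a structure from PDB or mmCIF
#'
#' Loads ATOM and HETATM records of the first model; residue numbering is
#' preserved verbatim. Alternate locations are resolved to the highest
#' occupancy (ties: first listed).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return A structure tibble (see [as_structure()]).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  if (format == "pdb") {
    validate_pdb_lines(readLines(path, warn = FALSE))
    pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  } else {
    pdb <- bio3d::read.cif(path, multi = FALSE, verbose = FALSE)
  }
  a <- pdb$atom
  df <- tibble(
    chain = as.character(a$chain),
    resno = as.integer(a$resno),
    resname = trimws(as.character(a$resid)),
    atom = gsub('^"|"$', "", trimws(as.character(a$elety))),
    x = a$x, y = a$y, z = a$z,
    element = trimws(as.character(a$elesy %||% substr(a$elety, 1, 1))),
    alt = as.character(a$alt),
    o = as.numeric(a$o)
  )
  df$element[is.na(df$element) | df$element == ""] <-
    substr(df$atom[is.na(df$element) | df$element == ""], 1, 1)
  # altloc: keep highest occupancy per atom address, ties first listed
  df$o[is.na(df$o)] <- 1
  df <- df |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::group_by(.data$chain, .data$resno, .data$atom) |>
    dplyr::arrange(dplyr::desc(.data$o), .data$.ord, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select(-".ord", -"alt", -"o")
  as_structure(df)
}

fmt_pdb_atom_name <- function(atom, element) {
  # standard PDB alignment: element right-justified in cols 13-14
  ifelse(nchar(element) == 1 & nchar(atom) < 4,
         sprintf(" %-3s", atom), sprintf("%-4s", atom))
}

#' Write a structure as a minimal PDB file
#'
#' Deterministic fixed-width ATOM records with LF line endings; suitable for
#' round-tripping synthetic models.
#'
#' @param model Structure tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  model <- as_structure(model)
  lines <- sprintf(
    "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(model)),
    fmt_pdb_atom_name(model$atom, model$element),
    model$resname, model$chain, model$resno,
    model$x, model$y, model$z, 1, 0,
    model$element)
  writeLines(c(lines, "END"), path, sep = "\n")
  invisible(path)
}

#' Write a structure as a minimal mmCIF file
#'
#' @inheritParams write_structure_pdb
#' @export
write_structure_cif <- function(model, path) {
  model <- as_structure(model)
  header <- c(
    "data_mthia",
    "#",
    "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
             "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
             "auth_comp_id", "auth_asym_id", "auth_atom_id",
             "pdbx_PDB_model_num")))
  aname <- ifelse(grepl("'", model$atom), sprintf("\"%s\"", model$atom),
                  model$atom)
  rows <- sprintf(
    "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
    seq_len(nrow(model)), model$element, aname, model$resname,
    model$chain, model$resno, model$x, model$y, model$z,
    model$resno, model$resname, model$chain, aname)
  writeLines(c(header, rows, "#"), path, sep = "\n")
  invisible(path)
}

#' Extract one chain's nucleotide sequence from a structure
#'
#' @param model Structure tibble.
#' @param chain Chain identifier.
#' @return Named character vector of one-letter residue codes (names are
#'   residue numbers), in residue order.
#' @export
chain_sequence <- function(model, chain) {
  res <- model |>
    dplyr::filter(.data$chain == !!chain) |>
    dplyr::distinct(.data$resno, .data$resname) |>
    dplyr::arrange(.data$resno)
  if (!nrow(res)) {
    abort(sprintf("no residues in chain '%s'", chain), class = "mthia_lookup_error")
  }
  code <- toupper(sub("^R?([ACGUT])$", "\\1", res$resname))
  setNames(code, res$resno)
}
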