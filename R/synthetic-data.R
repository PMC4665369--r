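# Synthetic ground-truth generators for every pipeline stage: sequence
# populations with planted variants, idealized A-form RNA duplexes with
# canonical (and optionally wobble) base-pair geometry, alignment columns of
# exact composition, and the exhaustive evidence-profile space.
#
# Base atoms are placed from the standard base reference frame used in
# nucleic-acid geometry (bases planar in z = 0; a Watson-Crick partner is the
# complementary base rotated 180 degrees about the x axis). These template
# coordinates are the single source of truth shared by the generator and the
# tests, so detector thresholds and generated geometry cannot drift apart.

.base_frames <- list(
  A = rbind(
    N9 = c(-1.291, 4.498, 0), C8 = c(0.024, 4.897, 0), N7 = c(0.877, 3.902, 0),
    C5 = c(0.071, 2.771, 0), C6 = c(0.369, 1.398, 0), N6 = c(1.611, 0.909, 0),
    N1 = c(-0.668, 0.532, 0), C2 = c(-1.912, 1.023, 0), N3 = c(-2.320, 2.290, 0),
    C4 = c(-1.267, 3.124, 0), `C1'` = c(-2.479, 5.346, 0)),
  G = rbind(
    N9 = c(-1.289, 4.551, 0), C8 = c(0.023, 4.962, 0), N7 = c(0.870, 3.969, 0),
    C5 = c(0.071, 2.833, 0), C6 = c(0.424, 1.460, 0), O6 = c(1.554, 0.955, 0),
    N1 = c(-0.700, 0.641, 0), C2 = c(-1.999, 1.087, 0), N2 = c(-2.949, 0.139, 0),
    N3 = c(-2.342, 2.364, 0), C4 = c(-1.265, 3.177, 0), `C1'` = c(-2.477, 5.399, 0)),
  C = rbind(
    N1 = c(-1.285, 4.542, 0), C2 = c(-1.472, 3.158, 0), O2 = c(-2.628, 2.709, 0),
    N3 = c(-0.391, 2.344, 0), C4 = c(0.837, 2.868, 0), N4 = c(1.875, 2.027, 0),
    C5 = c(1.056, 4.275, 0), C6 = c(-0.023, 5.068, 0), `C1'` = c(-2.477, 5.402, 0)),
  U = rbind(
    N1 = c(-1.284, 4.500, 0), C2 = c(-1.462, 3.131, 0), O2 = c(-2.563, 2.608, 0),
    N3 = c(-0.302, 2.397, 0), C4 = c(0.989, 2.884, 0), O4 = c(1.935, 2.094, 0),
    C5 = c(1.089, 4.311, 0), C6 = c(-0.024, 5.053, 0), `C1'` = c(-2.481, 5.354, 0))
)

.complement <- c(A = "U", U = "A", G = "C", C = "G")

rot_z <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), -sin(r), 0, sin(r), cos(r), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}
flip_x <- diag(c(1, -1, -1))

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# place atom D given chain A-B-C, bond |CD|, angle B-C-D and torsion
# D-C-B-A (natural extension reference frame)
place_atom <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  angle <- angle_deg * pi / 180; tors <- -dihedral_deg * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(tors),
          bond * sin(angle) * sin(tors))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

glycosidic_atoms <- function(code) {
  if (code %in% c("A", "G")) c(n = "N9", ref = "C4") else c(n = "N1", ref = "C2")
}

# template residue: base frame + O4' placed to realize the requested chi
residue_template <- function(code, chi = -160) {
  M <- .base_frames[[code]]
  g <- glycosidic_atoms(code)
  o4 <- place_atom(M[g["ref"], ], M[g["n"], ], M["C1'", ],
                   bond = 1.414, angle_deg = 108, dihedral_deg = chi)
  rbind(M, `O4'` = o4)
}

matrix_to_residue <- function(M, chain, resno, code) {
  tibble(chain = chain, resno = as.integer(resno), resname = code,
         atom = rownames(M), x = M[, 1], y = M[, 2], z = M[, 3],
         element = substr(rownames(M), 1, 1))
}

# in-plane wobble shift of the pyrimidine partner (derived so that the
# G O6-U N3 and G N1-U O2 donor-acceptor distances fall at ~2.8-2.9 A)
.wobble_shift <- c(0.9, 0.62, 0)

#' Generate an idealized base pair as a two-residue structure
#'
#' Builds coordinates realizing the requested geometry: `watson_crick`
#' (A:U/G:C, flip construction from the standard frame), `wobble` (G:U),
#' `reverse_hoogsteen` (A:U, the pyrimidine's Watson-Crick edge against the
#' purine's Hoogsteen edge, trans orientation) or `sheared` (G:A, sugar edge
#' against Hoogsteen edge).
#'
#' @param base_a,base_b One-letter codes (chain A residue 1, chain B
#'   residue 1).
#' @param geometry Pair geometry.
#' @param chi Glycosidic torsion applied to both residues (deg).
#' @return Structure tibble with chains "A" and "B".
#' @export
gen_base_pair <- function(base_a, base_b,
                          geometry = c("watson_crick", "wobble",
                                       "reverse_hoogsteen", "sheared"),
                          chi = -160) {
  geometry <- match.arg(geometry)
  Ma <- residue_template(base_a, chi)
  Mb <- residue_template(base_b, chi)
  if (geometry == "watson_crick") {
    if (.complement[[base_a]] != base_b) {
      abort(sprintf("%s:%s is not a complementary pair", base_a, base_b),
            class = "mthia_spec_error")
    }
    Mb <- Mb %*% t(flip_x)
  } else if (geometry == "wobble") {
    if (!setequal(c(base_a, base_b), c("G", "U"))) {
      abort("wobble generation supports G:U", class = "mthia_spec_error")
    }
    Mb <- Mb %*% t(flip_x)
    if (base_b == "U") {
      Mb <- sweep(Mb, 2, .wobble_shift, "+")
    } else {
      # G on strand B: shift the A-strand U instead, mirrored
      Ma <- sweep(Ma, 2, .wobble_shift * c(1, -1, 1), "+")
    }
  } else if (geometry == "reverse_hoogsteen") {
    if (!(base_a == "A" && base_b == "U")) {
      abort("reverse_hoogsteen generation supports A (chain A) : U (chain B)",
            class = "mthia_spec_error")
    }
    Mb <- fit_partner_by_hbonds(
      Ma, Mb, anchors_a = c("N7", "N6"), anchors_b = c("N3", "O2"),
      init_rot = rot_z(180), target = 2.9)
  } else {  # sheared G:A
    if (!(base_a == "G" && base_b == "A")) {
      abort("sheared generation supports G (chain A) : A (chain B)",
            class = "mthia_spec_error")
    }
    Mb <- fit_partner_by_hbonds(
      Ma, Mb, anchors_a = c("N3", "N2"), anchors_b = c("N6", "N7"),
      init_rot = rot_z(180), target = 2.9)
  }
  dplyr::bind_rows(matrix_to_residue(Ma, "A", 1, base_a),
                   matrix_to_residue(Mb, "B", 1, base_b))
}

# place partner base (in-plane rigid motion) so the two anchor atom pairs
# sit at the target hydrogen-bond distance; tiny deterministic least squares
fit_partner_by_hbonds <- function(Ma, Mb, anchors_a, anchors_b, init_rot,
                                  target = 2.9) {
  pa <- Ma[anchors_a, 1:2, drop = FALSE]
  ctr_a <- colMeans(Ma[, 1:2])
  out_dir <- colMeans(pa) - ctr_a
  out_dir <- out_dir / sqrt(sum(out_dir^2))
  Mb0 <- Mb %*% t(init_rot)
  # initial translation: put partner anchors beyond the donor edge
  t0 <- colMeans(pa) + out_dir * target - colMeans(Mb0[anchors_b, 1:2, drop = FALSE])
  obj <- function(par) {
    R <- rot_z(par[1])[1:2, 1:2]
    Bp <- sweep(Mb0[anchors_b, 1:2, drop = FALSE] %*% t(R), 2,
                par[2:3] + t0, "+")
    sum((sqrt(rowSums((Bp - pa)^2)) - target)^2)
  }
  fit <- stats::optim(c(0, 0, 0), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  R <- rot_z(fit$par[1])[1:2, 1:2]
  Bxy <- sweep(Mb0[, 1:2] %*% t(R), 2, fit$par[2:3] + t0, "+")
  cbind(Bxy, Mb0[, 3])
}

#' Generate an idealized A-form RNA duplex
#'
#' Stacks Watson-Crick pairs along the z axis with the given helical twist
#' and rise; complementary positions get canonical pair geometry, and listed
#' positions can instead carry a planted G:U wobble. Chain A runs 1..n;
#' chain B is its reverse complement, numbered 1..n in its own 5'-3'
#' direction so residue i of chain A pairs residue n-i+1 of chain B.
#'
#' @param sequence RNA string (chain A, length >= 4); positions listed in
#'   `wobble_positions` must carry G or U, their partner is generated as the
#'   wobble counterpart.
#' @param twist Helical twist per residue (deg, in (0, 45]).
#' @param rise Helical rise per residue (A).
#' @param wobble_positions Integer positions of chain A to generate as G:U
#'   wobble pairs.
#' @param chi Glycosidic torsion for every residue (deg; A-form is anti).
#' @return Structure tibble with attribute `"pairs"`: a ground-truth tibble
#'   of the planted pairs and their geometry class.
#' @export
gen_duplex <- function(sequence, twist = 32.7, rise = 2.81,
                       wobble_positions = integer(), chi = -160) {
  bases <- strsplit(gsub("T", "U", toupper(sequence)), "")[[1]]
  n <- length(bases)
  if (n < 4) abort("duplex needs >= 4 nt", class = "mthia_spec_error")
  if (!(twist > 0 && twist <= 45)) {
    abort("twist must lie in (0, 45] degrees", class = "mthia_spec_error")
  }
  if (!all(bases %in% names(.complement))) {
    abort("sequence must be over A/C/G/U", class = "mthia_spec_error")
  }
  bad <- setdiff(wobble_positions, seq_len(n))
  if (length(bad)) {
    abort("wobble positions outside the sequence", class = "mthia_spec_error")
  }
  res <- list(); truth <- list()
  for (i in seq_len(n)) {
    wob <- i %in% wobble_positions
    partner <- if (wob) {
      if (!bases[i] %in% c("G", "U")) {
        abort(sprintf("position %d is %s; wobble needs G or U", i, bases[i]),
              class = "mthia_spec_error")
      }
      if (bases[i] == "G") "U" else "G"
    } else .complement[[bases[i]]]
    pair <- gen_base_pair(bases[i], partner,
                          geometry = if (wob) "wobble" else "watson_crick",
                          chi = chi)
    Rz <- rot_z((i - 1) * twist)
    xyz <- as.matrix(pair[, c("x", "y", "z")]) %*% t(Rz)
    xyz[, 3] <- xyz[, 3] + (i - 1) * rise
    pair$x <- xyz[, 1]; pair$y <- xyz[, 2]; pair$z <- xyz[, 3]
    pair$resno <- ifelse(pair$chain == "A", i, n - i + 1L)
    res[[i]] <- pair
    truth[[i]] <- tibble(
      chain_i = "A", resno_i = i, base_i = bases[i],
      chain_j = "B", resno_j = n - i + 1L, base_j = partner,
      geometry_class = if (wob) "wobble" else "cis_watson_crick")
  }
  out <- as_structure(dplyr::bind_rows(res))
  attr(out, "pairs") <- dplyr::bind_rows(truth)
  out
}

#' Rigidly transform and optionally noise a structure
#'
#' Applies `rotation` then `translation`, then adds i.i.d. Gaussian noise of
#' standard deviation `noise_sigma` to every coordinate. Deterministic under
#' `seed`.
#'
#' @param model Structure tibble.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 vector.
#' @param noise_sigma Per-coordinate noise sd (A).
#' @param seed Optional integer seed.
#' @return The perturbed structure tibble.
#' @export
perturb_structure <- function(model, rotation = diag(3),
                              translation = c(0, 0, 0),
                              noise_sigma = 0, seed = NULL) {
  stopifnot(noise_sigma >= 0, nrow(model) > 0)
  xyz <- transform_xyz(as.matrix(model[, c("x", "y", "z")]),
                       rotation, translation)
  if (noise_sigma > 0) {
    xyz <- xyz + with_local_seed(seed,
      matrix(rnorm(length(xyz), sd = noise_sigma), ncol = 3))
  }
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}

#' Generate a random rotation matrix
#'
#' Uniform over SO(3) (QR of a Gaussian matrix, sign-corrected to
#' determinant +1). Deterministic under `seed`.
#'
#' @param seed Optional integer seed.
#' @return 3x3 proper rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  with_local_seed(seed, {
    q <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    R
  })
}

# ---------------------------------------------------------------------------
# Sequence population generator

apply_variant_to_seq <- function(seq_chars, pos, event, ref, alt) {
  ref <- strsplit(ref, "")[[1]]; alt_c <- strsplit(alt, "")[[1]]
  if (event != "insertion" &&
      !identical(seq_chars[pos:(pos + length(ref) - 1)], ref)) {
    abort(sprintf("reference mismatch at %d when planting variant", pos),
          class = "mthia_spec_error")
  }
  switch(event,
    substitution = { seq_chars[pos] <- alt_c; seq_chars },
    deletion = seq_chars[-(pos:(pos + length(ref) - 1))],
    insertion = append(seq_chars, alt_c, after = pos),
    abort(sprintf("unsupported planted event '%s'", event),
          class = "mthia_spec_error"))
}

#' Generate a sequence population with planted variants
#'
#' Emulates a reference-anchored genome collection: `n_sequences` copies of
#' a (random or supplied) reference, with each requested variant planted in
#' exactly `count` distinct sequences. All randomness is governed by `seed`.
#'
#' @param n_sequences Number of population sequences.
#' @param reference Reference DNA string, or `NULL` to draw a random one.
#' @param ref_length Length of the random reference when `reference` is NULL.
#' @param variants Tibble with columns `pos`, `event` (substitution /
#'   deletion / insertion), `ref`, `alt`, `count`, and optionally `source`
#'   (`"population"` default or `"known_reporting_source"`).
#' @param seed Integer seed.
#' @return A list of class `population_set`: `sequences` (tibble id/seq),
#'   `reference` (list id/seq), `provenance` (tibble id/tag), and attribute
#'   `"truth"` recording which sequences carry which variant.
#' @export
gen_population <- function(n_sequences = 100, reference = NULL,
                           ref_length = 2000, variants = NULL, seed = 1) {
  with_local_seed(seed, {
    if (is.null(reference)) {
      reference <- paste(sample(c("A", "C", "G", "T"), ref_length,
                                replace = TRUE), collapse = "")
    }
    ref_chars <- strsplit(reference, "")[[1]]
    if (is.null(variants)) {
      variants <- tibble(pos = integer(), event = character(),
                         ref = character(), alt = character(),
                         count = integer(), source = character())
    }
    if (!"source" %in% names(variants)) variants$source <- "population"
    if (any(variants$count > n_sequences)) {
      abort("planted count exceeds n_sequences", class = "mthia_spec_error")
    }
    if (any(variants$pos < 1 | variants$pos > length(ref_chars))) {
      abort("planted position outside the reference", class = "mthia_spec_error")
    }
    ids <- sprintf("seq_%04d", seq_len(n_sequences))
    carriers <- purrr::map(seq_len(nrow(variants)),
                           ~sort(sample(n_sequences, variants$count[.x])))
    # conflicting events at one position within one sequence are an error
    if (nrow(variants) > 1) {
      for (i in seq_len(nrow(variants) - 1)) {
        for (j in seq(i + 1, nrow(variants))) {
          if (variants$pos[i] == variants$pos[j] &&
              length(intersect(carriers[[i]], carriers[[j]]))) {
            abort(sprintf("conflicting variants at position %d in one sequence",
                          variants$pos[i]), class = "mthia_spec_error")
          }
        }
      }
    }
    seqs <- character(n_sequences)
    tags <- rep("population", n_sequences)
    for (s in seq_len(n_sequences)) {
      mine <- which(purrr::map_lgl(carriers, ~s %in% .x))
      chars <- ref_chars
      if (length(mine)) {
        # apply right-to-left so earlier coordinates stay valid
        for (v in mine[order(variants$pos[mine], decreasing = TRUE)]) {
          chars <- apply_variant_to_seq(chars, variants$pos[v],
                                        variants$event[v], variants$ref[v],
                                        variants$alt[v])
        }
        if (any(variants$source[mine] == "known_reporting_source")) {
          tags[s] <- "known_reporting_source"
        }
      }
      seqs[s] <- paste(chars, collapse = "")
    }
    out <- structure(list(
      sequences = tibble(id = ids, seq = seqs),
      reference = list(id = "reference", seq = reference),
      provenance = tibble(id = ids, tag = tags)
    ), class = "population_set")
    attr(out, "truth") <- dplyr::mutate(
      variants, carriers = purrr::map(carriers, ~ids[.x]))
    out
  })
}

#' Write a population set as FASTA (+ provenance TSV)
#'
#' @param population A `population_set`.
#' @param fasta_path Output FASTA for the population sequences.
#' @param ref_path Optional output FASTA for the reference.
#' @param provenance_path Optional output TSV (id, tag).
#' @return `fasta_path`, invisibly.
#' @export
write_population_fasta <- function(population, fasta_path, ref_path = NULL,
                                   provenance_path = NULL) {
  x <- Biostrings::DNAStringSet(setNames(population$sequences$seq,
                                         population$sequences$id))
  Biostrings::writeXStringSet(x, fasta_path)
  if (!is.null(ref_path)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(population$reference$seq,
                                        population$reference$id)), ref_path)
  }
  if (!is.null(provenance_path)) {
    readr::write_tsv(population$provenance, provenance_path)
  }
  invisible(fasta_path)
}

#' Read a population set from FASTA (+ provenance TSV)
#'
#' @param fasta_path Population FASTA.
#' @param ref_path Reference FASTA (single record).
#' @param provenance_path Optional TSV (id, tag); sequences without an entry
#'   are tagged "population".
#' @return A `population_set`.
#' @export
read_population_fasta <- function(fasta_path, ref_path,
                                  provenance_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ref <- Biostrings::readDNAStringSet(ref_path)
  ids <- names(seqs)
  prov <- tibble(id = ids, tag = "population")
  if (!is.null(provenance_path)) {
    given <- readr::read_tsv(provenance_path, col_types = "cc")
    prov$tag[match(given$id, prov$id)] <- given$tag
  }
  structure(list(
    sequences = tibble(id = ids, seq = unname(as.character(seqs))),
    reference = list(id = names(ref)[1], seq = as.character(ref[[1]])),
    provenance = prov
  ), class = "population_set")
}

# ---------------------------------------------------------------------------
# Alignment columns and evidence profiles

#' Generate an alignment column of exact composition
#'
#' Counts are realized by largest-remainder rounding of the requested
#' fractions, so the output composition is exact and deterministic.
#'
#' @param composition Named numeric vector over `A`, `C`, `G`, `U`, `-`
#'   (gap); fractions must sum to 1.
#' @param n Column depth.
#' @return Character vector of length `n`.
#' @export
#' @examples
#' gen_column(c(U = 1), 200)
#' gen_column(c(A = .5, G = .5), 100)
gen_column <- function(composition, n) {
  if (abs(sum(composition) - 1) > 1e-9) {
    abort("composition fractions must sum to 1", class = "mthia_spec_error")
  }
  if (!all(names(composition) %in% c("A", "C", "G", "U", "T", "-"))) {
    abort("composition symbols must be A/C/G/U/-", class = "mthia_spec_error")
  }
  raw <- composition * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  rep(names(composition), times = counts)
}

#' Enumerate the full evidence-profile space
#'
#' Every combination of the five rubric fields that satisfies the profile
#' invariant (direct heterologous evidence implies heterologous data exist).
#' Used for exhaustive rubric testing.
#'
#' @return Tibble of profiles.
#' @export
gen_evidence_profiles <- function() {
  grid <- tidyr::expand_grid(
    placeable_on_structure = c(TRUE, FALSE),
    heterologous_data_exists = c(TRUE, FALSE),
    direct_heterologous = .evidence_levels,
    indirect_heterologous = .evidence_levels,
    direct_mito_biochemical = c(TRUE, FALSE))
  dplyr::filter(grid, .data$direct_heterologous == "none" |
                  .data$heterologous_data_exists)
}
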