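# Geometric structural analysis: atomic contacts, hydrogen-bond inference,
# base-pair detection and classification, and glycosidic (syn/anti)
# conformation.
#
# Base-pair detection is purely geometric, in the style of standard RNA
# annotation tools: candidate hydrogen bonds are donor-acceptor heavy-atom
# pairs at 2.4-3.4 A, paired bases must be roughly coplanar (plane-normal
# angle < 35 deg) and unstaggered (< 2 A separation along the mean normal),
# and canonical/wobble pairs must additionally show >= 2 hydrogen bonds and
# a C1'-C1' distance in the helical 8.0-11.5 A window.

# polar base atoms with hydrogen-bonding roles (d = donor, a = acceptor)
.base_polar <- list(
  A = c(N1 = "a", N3 = "a", N6 = "d", N7 = "a"),
  G = c(N1 = "d", N2 = "d", N3 = "a", O6 = "a", N7 = "a"),
  C = c(O2 = "a", N3 = "a", N4 = "d"),
  U = c(O2 = "a", N3 = "d", O4 = "a")
)

.backbone_atoms <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'",
                     "O3'", "C2'", "O2'", "C1'")

base_code <- function(resname) toupper(sub("^R?([ACGUT])$", "\\1", resname))

#' Default geometric criteria for base-pair detection
#'
#' @param hbond_min,hbond_max Donor-acceptor heavy-atom distance window (A).
#' @param plane_angle_max Maximum angle between base-plane normals (deg).
#' @param stagger_max Maximum separation along the mean base normal (A).
#' @param c1_min,c1_max C1'-C1' window required for Watson-Crick and wobble
#'   geometry (A).
#' @param min_hbonds_canonical Minimum hydrogen bonds for Watson-Crick and
#'   wobble pairs.
#' @return A named list of criteria.
#' @export
pair_criteria <- function(hbond_min = 2.4, hbond_max = 3.4,
                          plane_angle_max = 35, stagger_max = 2.0,
                          c1_min = 8.0, c1_max = 11.5,
                          min_hbonds_canonical = 2L) {
  list(hbond_min = hbond_min, hbond_max = hbond_max,
       plane_angle_max = plane_angle_max, stagger_max = stagger_max,
       c1_min = c1_min, c1_max = c1_max,
       min_hbonds_canonical = min_hbonds_canonical)
}

residue_atoms <- function(model, chain, resno) {
  r <- model[model$chain == chain & model$resno == resno, ]
  if (!nrow(r)) {
    abort(sprintf("residue %s:%s not found", chain, resno),
          class = "mthia_lookup_error")
  }
  r
}

atom_xyz <- function(res, name) {
  i <- match(name, res$atom)
  if (is.na(i)) return(NULL)
  c(res$x[i], res$y[i], res$z[i])
}

parse_residue_address <- function(address) {
  if (is.list(address)) return(address)
  m <- regmatches(address, regexec("^([^:]+):(-?\\d+)$", address))[[1]]
  if (!length(m)) {
    abort(sprintf("residue address '%s' is not of the form chain:resno", address),
          class = "mthia_lookup_error")
  }
  list(chain = m[2], resno = as.integer(m[3]))
}

#' Atomic contacts of one residue against the rest of a model
#'
#' Reports all heavy-atom pairs between the residue and every other residue
#' at a distance strictly below `cutoff`, excluding intra-residue pairs and
#' the covalent backbone link between sequence-adjacent residues
#' (O3'(i)-P(i+1)). Results are sorted by distance.
#'
#' @param model Structure tibble.
#' @param residue Residue address, `"chain:resno"` or
#'   `list(chain =, resno =)`.
#' @param cutoff Distance cutoff in Angstrom (strict `<`).
#' @return Tibble with the two atom addresses and `distance`.
#' @export
find_contacts <- function(model, residue, cutoff = 3.0) {
  stopifnot(cutoff > 0)
  addr <- parse_residue_address(residue)
  res <- residue_atoms(model, addr$chain, addr$resno)
  res <- res[res$element != "H", ]
  rest <- model[!(model$chain == addr$chain & model$resno == addr$resno) &
                  model$element != "H", ]
  if (!nrow(rest) || !nrow(res)) {
    return(tibble(chain_a = character(), resno_a = integer(),
                  atom_a = character(), chain_b = character(),
                  resno_b = integer(), atom_b = character(),
                  distance = double()))
  }
  d <- sqrt(outer(res$x, rest$x, "-")^2 +
              outer(res$y, rest$y, "-")^2 +
              outer(res$z, rest$z, "-")^2)
  hit <- which(d < cutoff, arr.ind = TRUE)
  out <- tibble(
    chain_a = addr$chain, resno_a = addr$resno, atom_a = res$atom[hit[, 1]],
    chain_b = rest$chain[hit[, 2]], resno_b = rest$resno[hit[, 2]],
    atom_b = rest$atom[hit[, 2]],
    distance = d[hit]
  )
  # covalent backbone link between sequence neighbours
  covalent <- out$chain_b == addr$chain &
    ((out$resno_b == addr$resno + 1L & out$atom_a == "O3'" & out$atom_b == "P") |
     (out$resno_b == addr$resno - 1L & out$atom_a == "P" & out$atom_b == "O3'"))
  out <- out[!covalent, ]
  dplyr::arrange(out, .data$distance)
}

base_ring_atoms <- function(code) {
  switch(code,
         A = , G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
         C = , U = c("N1", "C2", "N3", "C4", "C5", "C6"),
         abort(sprintf("not a nucleotide code: '%s'", code)))
}

base_plane <- function(res, code) {
  ring <- res[res$atom %in% base_ring_atoms(code), c("x", "y", "z")]
  if (nrow(ring) < 3) return(NULL)
  m <- as.matrix(ring)
  ctr <- colMeans(m)
  sv <- svd(sweep(m, 2, ctr))
  list(center = ctr, normal = sv$v[, 3])
}

hbonds_between <- function(res_i, code_i, res_j, code_j, criteria) {
  pol_i <- .base_polar[[code_i]]; pol_j <- .base_polar[[code_j]]
  ai <- res_i[res_i$atom %in% names(pol_i), ]
  aj <- res_j[res_j$atom %in% names(pol_j), ]
  if (!nrow(ai) || !nrow(aj)) return(NULL)
  d <- sqrt(outer(ai$x, aj$x, "-")^2 + outer(ai$y, aj$y, "-")^2 +
              outer(ai$z, aj$z, "-")^2)
  hit <- which(d >= criteria$hbond_min & d <= criteria$hbond_max,
               arr.ind = TRUE)
  if (!nrow(hit)) return(NULL)
  roles_i <- pol_i[ai$atom[hit[, 1]]]
  roles_j <- pol_j[aj$atom[hit[, 2]]]
  ok <- roles_i != roles_j   # donor-acceptor complementarity
  if (!any(ok)) return(NULL)
  tibble(atom_i = ai$atom[hit[ok, 1]], atom_j = aj$atom[hit[ok, 2]],
         distance = d[hit[ok, , drop = FALSE]])
}

base_edge <- function(code, atoms) {
  purine <- code %in% c("A", "G")
  if (purine && any(atoms == "N7")) return("hoogsteen")
  if (any(atoms == "O2'")) return("sugar")
  if (purine && any(atoms == "N3")) return("sugar")
  "watson_crick"
}

glycosidic_vector <- function(res, code) {
  n <- if (code %in% c("A", "G")) "N9" else "N1"
  c1 <- atom_xyz(res, "C1'"); gn <- atom_xyz(res, n)
  if (is.null(c1) || is.null(gn)) return(NULL)
  gn - c1
}

pair_orientation <- function(res_i, code_i, res_j, code_j) {
  vi <- glycosidic_vector(res_i, code_i)
  vj <- glycosidic_vector(res_j, code_j)
  if (is.null(vi) || is.null(vj)) return(NA_character_)
  if (sum(vi * vj) > 0) "cis" else "trans"
}

canonical_wc <- function(code_i, code_j) {
  paste(sort(c(code_i, code_j)), collapse = "") %in% c("AU", "CG")
}

wobble_combo <- function(code_i, code_j) {
  paste(sort(c(code_i, code_j)), collapse = "") %in% c("GU", "AC")
}

#' Classify the geometry of a candidate base pair
#'
#' Assigns one of `cis_watson_crick`, `wobble`, `reverse_hoogsteen`,
#' `sheared`, `other_noncanonical` from which base edges donate the
#' hydrogen-bonded atoms and the relative glycosidic orientation.
#'
#' @param model Structure tibble.
#' @param residue_i,residue_j Residue addresses (`"chain:resno"`).
#' @param criteria Geometric thresholds from [pair_criteria()].
#' @return A one-row tibble: addresses, `geometry_class`, `n_hbonds`,
#'   `orientation`.
#' @export
classify_pair_geometry <- function(model, residue_i, residue_j,
                                   criteria = pair_criteria()) {
  ai <- parse_residue_address(residue_i); aj <- parse_residue_address(residue_j)
  res_i <- residue_atoms(model, ai$chain, ai$resno)
  res_j <- residue_atoms(model, aj$chain, aj$resno)
  code_i <- base_code(res_i$resname[1]); code_j <- base_code(res_j$resname[1])
  hb <- hbonds_between(res_i, code_i, res_j, code_j, criteria)
  # include ribose 2'-OH to base contacts for the sugar-edge classes
  ribose_hb <- ribose_base_hbonds(res_i, code_i, res_j, code_j, criteria)
  all_hb <- dplyr::bind_rows(hb, ribose_hb)
  if (is.null(all_hb) || !nrow(all_hb)) {
    abort("no hydrogen bond between the two residues; not a pair",
          class = "mthia_input_error")
  }
  edge_i <- base_edge(code_i, all_hb$atom_i)
  edge_j <- base_edge(code_j, all_hb$atom_j)
  orientation <- pair_orientation(res_i, code_i, res_j, code_j)
  base_hb_n <- if (is.null(hb)) 0L else nrow(hb)
  cls <- classify_from_edges(code_i, code_j, edge_i, edge_j, orientation,
                             base_hb_n, criteria)
  tibble(chain_i = ai$chain, resno_i = ai$resno, base_i = code_i,
         chain_j = aj$chain, resno_j = aj$resno, base_j = code_j,
         geometry_class = cls, n_hbonds = nrow(all_hb),
         orientation = orientation)
}

ribose_base_hbonds <- function(res_i, code_i, res_j, code_j, criteria) {
  out <- NULL
  o2i <- atom_xyz(res_i, "O2'")
  if (!is.null(o2i)) {
    pol_j <- .base_polar[[code_j]]
    aj <- res_j[res_j$atom %in% names(pol_j), ]
    if (nrow(aj)) {
      d <- sqrt((aj$x - o2i[1])^2 + (aj$y - o2i[2])^2 + (aj$z - o2i[3])^2)
      k <- d >= criteria$hbond_min & d <= criteria$hbond_max
      if (any(k)) out <- tibble(atom_i = "O2'", atom_j = aj$atom[k],
                                distance = d[k])
    }
  }
  o2j <- atom_xyz(res_j, "O2'")
  if (!is.null(o2j)) {
    pol_i <- .base_polar[[code_i]]
    ai <- res_i[res_i$atom %in% names(pol_i), ]
    if (nrow(ai)) {
      d <- sqrt((ai$x - o2j[1])^2 + (ai$y - o2j[2])^2 + (ai$z - o2j[3])^2)
      k <- d >= criteria$hbond_min & d <= criteria$hbond_max
      if (any(k)) out <- dplyr::bind_rows(
        out, tibble(atom_i = ai$atom[k], atom_j = "O2'", distance = d[k]))
    }
  }
  out
}

classify_from_edges <- function(code_i, code_j, edge_i, edge_j, orientation,
                                n_base_hbonds, criteria) {
  both_wc <- edge_i == "watson_crick" && edge_j == "watson_crick"
  if (both_wc && n_base_hbonds >= criteria$min_hbonds_canonical &&
      identical(orientation, "cis")) {
    if (canonical_wc(code_i, code_j)) return("cis_watson_crick")
    if (wobble_combo(code_i, code_j)) return("wobble")
  }
  wc_hoogsteen <- (edge_i == "watson_crick" && edge_j == "hoogsteen") ||
    (edge_i == "hoogsteen" && edge_j == "watson_crick")
  if (wc_hoogsteen && identical(orientation, "trans")) {
    return("reverse_hoogsteen")
  }
  sugar_hoogsteen <- (edge_i == "sugar" && edge_j == "hoogsteen") ||
    (edge_i == "hoogsteen" && edge_j == "sugar")
  if (sugar_hoogsteen) return("sheared")
  "other_noncanonical"
}

#' Detect base pairs in a structure
#'
#' Scans residue pairs for hydrogen-bonded, coplanar, unstaggered base-base
#' interactions and classifies each detected pair. Canonical (Watson-Crick)
#' and wobble assignments additionally require the C1'-C1' distance window
#' and at least `min_hbonds_canonical` hydrogen bonds.
#'
#' @param model Structure tibble.
#' @param chain Optional chain id; when given, only pairs with both residues
#'   in that chain are reported.
#' @param criteria Geometric thresholds from [pair_criteria()].
#' @return Tibble of pairs (`chain_i`, `resno_i`, `base_i`, `chain_j`,
#'   `resno_j`, `base_j`, `geometry_class`, `n_hbonds`), each pair reported
#'   once with (chain_i, resno_i) ordered before (chain_j, resno_j).
#' @export
detect_base_pairs <- function(model, chain = NULL, criteria = pair_criteria()) {
  model <- as_structure(model)
  if (!is.null(chain)) model <- model[model$chain %in% chain, ]
  res <- model |>
    dplyr::distinct(.data$chain, .data$resno, .data$resname) |>
    dplyr::filter(base_code(.data$resname) %in% c("A", "C", "G", "U"))
  n <- nrow(res)
  empty <- tibble(chain_i = character(), resno_i = integer(),
                  base_i = character(), chain_j = character(),
                  resno_j = integer(), base_j = character(),
                  geometry_class = character(), n_hbonds = integer())
  if (n < 2) return(empty)

  info <- purrr::map(seq_len(n), function(k) {
    r <- residue_atoms(model, res$chain[k], res$resno[k])
    code <- base_code(res$resname[k])
    list(res = r, code = code, plane = base_plane(r, code),
         c1 = atom_xyz(r, "C1'"))
  })

  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ri <- info[[i]]; rj <- info[[j]]
      if (is.null(ri$plane) || is.null(rj$plane)) next
      sep <- rj$plane$center - ri$plane$center
      if (sqrt(sum(sep^2)) > 15) next
      hb <- hbonds_between(ri$res, ri$code, rj$res, rj$code, criteria)
      if (is.null(hb)) next
      cosang <- abs(sum(ri$plane$normal * rj$plane$normal))
      angle <- acos(pmin(1, cosang)) * 180 / pi
      if (angle > criteria$plane_angle_max) next
      flip <- sign(sum(ri$plane$normal * rj$plane$normal))
      mean_normal <- ri$plane$normal + rj$plane$normal * flip
      stagger <- abs(sum(sep * mean_normal / sqrt(sum(mean_normal^2))))
      if (stagger > criteria$stagger_max) next
      edge_i <- base_edge(ri$code, hb$atom_i)
      edge_j <- base_edge(rj$code, hb$atom_j)
      orientation <- pair_orientation(ri$res, ri$code, rj$res, rj$code)
      cls <- classify_from_edges(ri$code, rj$code, edge_i, edge_j,
                                 orientation, nrow(hb), criteria)
      if (cls %in% c("cis_watson_crick", "wobble")) {
        if (is.null(ri$c1) || is.null(rj$c1)) {
          cls <- "other_noncanonical"
        } else {
          dc1 <- sqrt(sum((ri$c1 - rj$c1)^2))
          if (dc1 < criteria$c1_min || dc1 > criteria$c1_max) {
            cls <- "other_noncanonical"
          }
        }
      }
      out[[length(out) + 1L]] <- tibble(
        chain_i = res$chain[i], resno_i = res$resno[i], base_i = ri$code,
        chain_j = res$chain[j], resno_j = res$resno[j], base_j = rj$code,
        geometry_class = cls, n_hbonds = nrow(hb))
    }
  }
  if (!length(out)) return(empty)
  dplyr::bind_rows(out)
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Glycosidic (chi) conformation of a nucleotide
#'
#' Computes the chi torsion (O4'-C1'-N9-C4 for purines, O4'-C1'-N1-C2 for
#' pyrimidines) and labels the residue `syn` when chi lies in [-90, +90]
#' degrees, `anti` otherwise.
#'
#' @param model Structure tibble.
#' @param residue Residue address (`"chain:resno"`).
#' @return One-row tibble with `chi_deg` and `conformation` (`"syn"`,
#'   `"anti"` or `"undetermined_conformation"` when atoms are missing).
#' @export
glycosidic_conformation <- function(model, residue) {
  addr <- parse_residue_address(residue)
  res <- residue_atoms(model, addr$chain, addr$resno)
  code <- base_code(res$resname[1])
  atoms <- if (code %in% c("A", "G")) c("O4'", "C1'", "N9", "C4")
           else c("O4'", "C1'", "N1", "C2")
  xyz <- purrr::map(atoms, ~atom_xyz(res, .x))
  if (any(purrr::map_lgl(xyz, is.null))) {
    return(tibble(chain = addr$chain, resno = addr$resno,
                  chi_deg = NA_real_,
                  conformation = "undetermined_conformation"))
  }
  chi <- dihedral_angle(xyz[[1]], xyz[[2]], xyz[[3]], xyz[[4]])
  tibble(chain = addr$chain, resno = addr$resno, chi_deg = chi,
         conformation = if (abs(chi) <= 90) "syn" else "anti")
}
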