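# Least-squares (Kabsch) superposition with iterative outlier pruning, and
# cross-structure residue equivalence by proximity after superposition.
#
# The fit-prune loop mirrors the behaviour of interactive structure-viewer
# superposition: fit all paired atoms, discard pairs whose post-fit distance
# exceeds a cutoff, refit, and stop when no pair is removed. The rotation is
# always proper (determinant +1).

kabsch_fit <- function(P, Q) {
  # returns rotation R and translation t minimizing ||P %*% t(R) + t - Q||
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cq - as.vector(R %*% cp)
  list(rotation = R, translation = t_vec)
}

transform_xyz <- function(M, rotation, translation) {
  sweep(M %*% t(rotation), 2, translation, "+")
}

pair_coords <- function(model, pairing, side) {
  ch <- pairing[[paste0("chain_", side)]]
  rn <- pairing[[paste0("resno_", side)]]
  at <- pairing[[paste0("atom_", side)]]
  idx <- match(paste(ch, rn, at), paste(model$chain, model$resno, model$atom))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    abort(sprintf("paired atom %s:%s %s not found in the %s model",
                  ch[bad], rn[bad], at[bad],
                  if (side == "m") "mobile" else "target"),
          class = "mthia_lookup_error")
  }
  as.matrix(model[idx, c("x", "y", "z")])
}

#' Derive an atom pairing from the chain sequences of two structures
#'
#' Globally aligns the nucleotide sequences of one chain from each model and
#' pairs the C1' atoms of aligned (non-gap) columns.
#'
#' @param mobile,target Structure tibbles.
#' @param chain_mobile,chain_target Chain ids.
#' @param atom Atom name to pair (default C1').
#' @return Pairing tibble usable by [superpose_structures()].
#' @export
pairing_from_sequences <- function(mobile, target, chain_mobile, chain_target,
                                   atom = "C1'") {
  sm <- chain_sequence(mobile, chain_mobile)
  st <- chain_sequence(target, chain_target)
  al <- Biostrings::pairwiseAlignment(
    paste(gsub("U", "T", sm), collapse = ""),
    paste(gsub("U", "T", st), collapse = ""),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 1)
  pm <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
  pt <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
  im <- cumsum(pm != "-"); it <- cumsum(pt != "-")
  keep <- pm != "-" & pt != "-"
  tibble(
    chain_m = chain_mobile, resno_m = as.integer(names(sm)[im[keep]]),
    atom_m = atom,
    chain_t = chain_target, resno_t = as.integer(names(st)[it[keep]]),
    atom_t = atom)
}

#' Superpose one structure onto another with iterative pruning
#'
#' Least-squares (Kabsch) fit of the paired atoms, iteratively removing
#' pairs whose post-fit distance exceeds `prune_cutoff` and refitting until
#' no pair is removed.
#'
#' @param mobile,target Structure tibbles.
#' @param pairing Tibble of atom pairs with columns `chain_m`, `resno_m`,
#'   `atom_m`, `chain_t`, `resno_t`, `atom_t` (e.g. from
#'   [pairing_from_sequences()]).
#' @param prune_cutoff Post-fit distance above which a pair is dropped (A).
#' @param max_iter Safety bound on fit-prune iterations.
#' @return An object of class `rna_superposition`: rotation (3x3, proper),
#'   translation, `rmsd` over retained pairs, `retained_pairs`,
#'   `initial_pairs`, and the per-pair table (see `tidy()`).
#' @export
superpose_structures <- function(mobile, target, pairing, prune_cutoff = 2.0,
                                 max_iter = 100L) {
  stopifnot(prune_cutoff > 0)
  P_all <- pair_coords(mobile, pairing, "m")
  Q_all <- pair_coords(target, pairing, "t")
  n0 <- nrow(P_all)
  if (n0 < 3) {
    abort("superposition needs at least 3 atom pairs",
          class = "mthia_degeneracy_error")
  }
  keep <- rep(TRUE, n0)
  fit <- NULL; dist <- rep(NA_real_, n0)
  for (iter in seq_len(max_iter)) {
    if (sum(keep) < 3) {
      abort("fewer than 3 atom pairs retained during pruning",
            class = "mthia_degeneracy_error")
    }
    fit <- kabsch_fit(P_all[keep, , drop = FALSE], Q_all[keep, , drop = FALSE])
    moved <- transform_xyz(P_all, fit$rotation, fit$translation)
    dist <- sqrt(rowSums((moved - Q_all)^2))
    drop <- keep & dist > prune_cutoff
    if (!any(drop)) break
    keep <- keep & !drop
  }
  rmsd <- sqrt(mean(dist[keep]^2))
  structure(list(
    rotation = fit$rotation, translation = fit$translation,
    rmsd = rmsd, retained_pairs = sum(keep), initial_pairs = n0,
    pairs = dplyr::mutate(pairing, distance = dist, retained = keep)
  ), class = "rna_superposition")
}

#' @export
print.rna_superposition <- function(x, ...) {
  cat(sprintf("<rna_superposition> rmsd %.3f A over %d/%d atom pairs\n",
              x$rmsd, x$retained_pairs, x$initial_pairs))
  invisible(x)
}

#' @export
tidy.rna_superposition <- function(x, ...) x$pairs

#' @export
glance.rna_superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, retained_pairs = x$retained_pairs,
         initial_pairs = x$initial_pairs,
         rotation_det = det(x$rotation))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Apply a superposition to a structure
#'
#' @param model Structure tibble (typically the mobile model).
#' @param superposition An `rna_superposition`.
#' @return The transformed structure tibble.
#' @export
apply_superposition <- function(model, superposition) {
  xyz <- transform_xyz(as.matrix(model[, c("x", "y", "z")]),
                       superposition$rotation, superposition$translation)
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}

#' Map a residue to its spatial equivalent in another structure
#'
#' Transforms the query residue's C1' atom with the given superposition and
#' returns the other model's nucleotide whose C1' is nearest, or an unmapped
#' row when the nearest C1' is farther than `max_dist`.
#'
#' @param query_residue Residue address in `query_model` (`"chain:resno"`).
#' @param query_model,other_model Structure tibbles.
#' @param superposition `rna_superposition` taking `query_model` onto
#'   `other_model`'s frame.
#' @param max_dist Mapping radius (A).
#' @return One-row tibble: query address, equivalent `chain`/`resno`/
#'   `resname` (NA when unmapped), `distance`, `mapped`.
#' @export
map_equivalent_residue <- function(query_residue, query_model, other_model,
                                   superposition, max_dist = 4.0) {
  addr <- parse_residue_address(query_residue)
  res <- residue_atoms(query_model, addr$chain, addr$resno)
  c1 <- atom_xyz(res, "C1'")
  if (is.null(c1)) {
    abort(sprintf("residue %s:%d lacks a C1' atom", addr$chain, addr$resno),
          class = "mthia_lookup_error")
  }
  moved <- as.vector(superposition$rotation %*% c1) + superposition$translation
  cand <- other_model[other_model$atom == "C1'", ]
  if (!nrow(cand)) {
    abort("other model has no C1' atoms", class = "mthia_lookup_error")
  }
  d <- sqrt((cand$x - moved[1])^2 + (cand$y - moved[2])^2 +
              (cand$z - moved[3])^2)
  i <- which.min(d)
  mapped <- d[i] <= max_dist
  tibble(query_chain = addr$chain, query_resno = addr$resno,
         chain = ifelse(mapped, cand$chain[i], NA_character_),
         resno = ifelse(mapped, cand$resno[i], NA_integer_),
         resname = ifelse(mapped, cand$resname[i], NA_character_),
         distance = d[i], mapped = mapped)
}
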