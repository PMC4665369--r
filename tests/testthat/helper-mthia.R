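# Shared helpers: identity pairings, random duplex specs, and a brute-force
# hydrogen-bond counter kept independent of the package's detector internals.

identity_pairing <- function(model) {
  tibble::tibble(chain_m = model$chain, resno_m = model$resno,
                 atom_m = model$atom,
                 chain_t = model$chain, resno_t = model$resno,
                 atom_t = model$atom)
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# independent brute-force count of donor-acceptor heavy-atom pairs at
# 2.4-3.4 A between the bases of two residues
brute_force_hbonds <- function(model, chain_i, resno_i, chain_j, resno_j) {
  roles <- list(
    A = c(N1 = "a", N3 = "a", N6 = "d", N7 = "a"),
    G = c(N1 = "d", N2 = "d", N3 = "a", O6 = "a", N7 = "a"),
    C = c(O2 = "a", N3 = "a", N4 = "d"),
    U = c(O2 = "a", N3 = "d", O4 = "a"))
  ri <- model[model$chain == chain_i & model$resno == resno_i, ]
  rj <- model[model$chain == chain_j & model$resno == resno_j, ]
  pi_ <- roles[[ri$resname[1]]]; pj_ <- roles[[rj$resname[1]]]
  n <- 0
  for (ai in intersect(ri$atom, names(pi_))) {
    for (aj in intersect(rj$atom, names(pj_))) {
      if (pi_[[ai]] == pj_[[aj]]) next
      p <- unlist(ri[ri$atom == ai, c("x", "y", "z")])
      q <- unlist(rj[rj$atom == aj, c("x", "y", "z")])
      d <- sqrt(sum((p - q)^2))
      if (d >= 2.4 && d <= 3.4) n <- n + 1
    }
  }
  n
}

# deterministic mutation of a reference string at given 1-based position
mutate_base <- function(seq, pos, alt) {
  paste0(substr(seq, 1, pos - 1), alt, substr(seq, pos + 1, nchar(seq)))
}
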