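test_that("structure files round-trip identically through PDB and mmCIF", {
  d <- gen_duplex("GGCAUGCC")
  expect_equal(dplyr::n_distinct(paste(d$chain, d$resno)), 16L)

  pdb <- withr::local_tempfile(fileext = ".pdb")
  cif <- withr::local_tempfile(fileext = ".cif")
  write_structure_pdb(d, pdb)
  write_structure_cif(d, cif)
  a <- read_structure(pdb)
  b <- suppressWarnings(read_structure(cif))
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_equal(a$x, d$x, tolerance = 1e-3)

  # truncated ATOM record is a parse error with a line number
  lines <- readLines(pdb)
  lines[3] <- substr(lines[3], 1, 40)
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, bad)
  expect_error(read_structure(bad), "line 3", class = "mthia_parse_error")
})

test_that("contacts honour the strict cutoff and covalent exclusions", {
  toy <- as_structure(tibble::tibble(
    chain = "A", resno = c(1L, 2L, 3L, 4L), resname = "U",
    atom = c("O4", "N3", "N3", "O4"),
    x = c(0, 2.9, 3.0, 10), y = 0, z = 0,
    element = c("O", "N", "N", "O")))
  ct <- find_contacts(toy, "A:1", cutoff = 3.0)
  expect_equal(nrow(ct), 1L)             # 3.0 A excluded: strictly below
  expect_equal(ct$resno_b, 2L)
  expect_equal(ct$distance, 2.9)

  # covalent O3'(i)-P(i+1) backbone pair is not a contact
  bb <- as_structure(tibble::tibble(
    chain = "A", resno = c(1L, 2L), resname = "U",
    atom = c("O3'", "P"), x = c(0, 1.6), y = 0, z = 0,
    element = c("O", "P")))
  expect_equal(nrow(find_contacts(bb, "A:1", 3.0)), 0L)
  expect_error(find_contacts(toy, "A:99"), class = "mthia_lookup_error")

  # symmetry: the same pair appears viewed from either residue
  ct2 <- find_contacts(toy, "A:2", cutoff = 3.0)
  expect_true(any(ct2$resno_b == 1L & ct2$distance == 2.9))
})

test_that("ideal duplexes yield exactly the planted pairs", {
  d <- gen_duplex("GGCAUGCC")
  bp <- detect_base_pairs(d)
  truth <- attr(d, "pairs")
  expect_equal(nrow(bp), 8L)
  expect_setequal(paste(bp$resno_i, bp$resno_j),
                  paste(truth$resno_i, truth$resno_j))
  expect_true(all(bp$geometry_class == "cis_watson_crick"))
  # every detected pair has >= 2 h-bonds per an independent brute-force count
  for (k in seq_len(nrow(bp))) {
    expect_gte(brute_force_hbonds(d, bp$chain_i[k], bp$resno_i[k],
                                  bp$chain_j[k], bp$resno_j[k]), 2)
  }
})

test_that("planted wobble pairs are detected and classified as wobble", {
  d <- gen_duplex("GGCAUGCC", wobble_positions = c(2, 5))
  bp <- detect_base_pairs(d)
  expect_equal(nrow(bp), 8L)
  wob <- bp[bp$resno_i %in% c(2, 5) & bp$chain_i == "A", ]
  expect_true(all(wob$geometry_class == "wobble"))
  expect_true(all(bp$geometry_class[!bp$resno_i %in% c(2, 5)] ==
                    "cis_watson_crick"))
})

test_that("pair geometry classes follow edge and orientation rules", {
  wc <- gen_base_pair("A", "U", "watson_crick")
  expect_equal(classify_pair_geometry(wc, "A:1", "B:1")$geometry_class,
               "cis_watson_crick")

  gu <- gen_base_pair("G", "U", "wobble")
  expect_equal(classify_pair_geometry(gu, "A:1", "B:1")$geometry_class,
               "wobble")

  rh <- gen_base_pair("A", "U", "reverse_hoogsteen")
  cl <- classify_pair_geometry(rh, "A:1", "B:1")
  expect_equal(cl$geometry_class, "reverse_hoogsteen")
  expect_equal(cl$orientation, "trans")

  sh <- gen_base_pair("G", "A", "sheared")
  expect_equal(classify_pair_geometry(sh, "A:1", "B:1")$geometry_class,
               "sheared")

  # a lone ribose-to-base contact is other_noncanonical
  lone <- as_structure(tibble::tibble(
    chain = c("A", "A", "A", "A", "B", "B"),
    resno = c(1L, 1L, 1L, 1L, 1L, 1L),
    resname = c("U", "U", "U", "U", "A", "A"),
    atom = c("N1", "C2", "N3", "O2'", "N1", "C2"),
    x = c(-1.284, -1.462, -0.302, 2.0, 4.9, 6.1),
    y = c(4.5, 3.131, 2.397, 1.0, 1.0, 1.6),
    z = 0, element = c("N", "C", "N", "O", "N", "C")))
  expect_equal(classify_pair_geometry(lone, "A:1", "B:1")$geometry_class,
               "other_noncanonical")
  # residues without any hydrogen bond are not a pair at all
  expect_error(
    classify_pair_geometry(gen_duplex("GGCAUGCC"), "A:1", "A:5"),
    class = "mthia_input_error")
})

test_that("glycosidic conformation distinguishes syn from anti", {
  d <- gen_duplex("GGCAUGCC")
  g <- glycosidic_conformation(d, "A:1")
  expect_equal(g$conformation, "anti")
  expect_equal(g$chi_deg, -160, tolerance = 1e-6)

  syn <- gen_duplex("GGCAUGCC", chi = 30)
  gs <- glycosidic_conformation(syn, "A:1")
  expect_equal(gs$conformation, "syn")
  expect_equal(gs$chi_deg, 30, tolerance = 1e-6)

  # boundary convention: |chi| <= 90 is syn
  expect_equal(glycosidic_conformation(gen_duplex("GGCAUGCC", chi = 90),
                                       "A:1")$conformation, "syn")
  expect_equal(glycosidic_conformation(gen_duplex("GGCAUGCC", chi = -91),
                                       "A:1")$conformation, "anti")

  noatom <- d[!(d$atom == "O4'" & d$resno == 1 & d$chain == "A"), ]
  expect_equal(glycosidic_conformation(noatom, "A:1")$conformation,
               "undetermined_conformation")
})

test_that("conservation code strings render the published notation", {
  expect_equal(conservation_code(rep("observed", 5)), "CbeamM")
  expect_equal(conservation_code(c(rep("observed", 4), "partner_absent")),
               "Cbeam-")
  expect_equal(conservation_code(c(rep("observed", 4), "not_observed")),
               "Cbeam?")
  expect_equal(conservation_code(c("observed", "observed", "observed",
                                   "unmodelled_partners_present",
                                   "observed")), "Cbea+M")
  # no observed source: no leading C
  expect_equal(conservation_code(rep("not_observed", 5)), "?????")
  expect_error(conservation_code(rep("observed", 4)),
               class = "mthia_input_error")
  expect_error(conservation_code(c(rep("observed", 4), "maybe")),
               class = "mthia_input_error")
})
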