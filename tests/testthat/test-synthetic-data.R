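test_that("population generation is deterministic and exact", {
  vars <- function(ref) {
    refc <- strsplit(ref, "")[[1]]
    tibble::tibble(pos = 100L, event = "substitution", ref = refc[100],
                   alt = setdiff(c("A", "C", "G", "T"), refc[100])[1],
                   count = 3L, source = "population")
  }
  p0 <- gen_population(n_sequences = 5, ref_length = 500, seed = 2)
  pop1 <- gen_population(100, reference = p0$reference$seq,
                         variants = vars(p0$reference$seq), seed = 4)
  pop2 <- gen_population(100, reference = p0$reference$seq,
                         variants = vars(p0$reference$seq), seed = 4)
  expect_identical(pop1$sequences, pop2$sequences)
  truth <- attr(pop1, "truth")
  expect_equal(lengths(truth$carriers), 3L)
  # planted count recovered by the counting pipeline
  cts <- count_appearances(pop1)
  expect_equal(cts$total, 3L)

  expect_error(gen_population(10, variants = tibble::tibble(
    pos = 1L, event = "substitution", ref = "A", alt = "C", count = 11L),
    seed = 1), class = "mthia_spec_error")
})

test_that("conflicting planted variants at one site are rejected", {
  p0 <- gen_population(n_sequences = 5, ref_length = 200, seed = 3)
  refc <- strsplit(p0$reference$seq, "")[[1]]
  alts <- setdiff(c("A", "C", "G", "T"), refc[50])
  clash <- tibble::tibble(
    pos = c(50L, 50L), event = "substitution", ref = refc[50],
    alt = alts[1:2], count = c(40L, 40L), source = "population")
  expect_error(gen_population(50, reference = p0$reference$seq,
                              variants = clash, seed = 5),
               class = "mthia_spec_error")
})

test_that("population FASTA round-trips with provenance", {
  p0 <- gen_population(n_sequences = 8, ref_length = 300, seed = 12)
  fa <- withr::local_tempfile(fileext = ".fa")
  ref <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_population_fasta(p0, fa, ref, tsv)
  # same seed writes identical bytes
  fa2 <- withr::local_tempfile(fileext = ".fa")
  write_population_fasta(gen_population(n_sequences = 8, ref_length = 300,
                                        seed = 12), fa2)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fa2, "raw", file.size(fa2)))
  back <- read_population_fasta(fa, ref, tsv)
  expect_equal(back$sequences, p0$sequences)
  expect_equal(back$provenance, p0$provenance)
})

test_that("generated duplexes respect their spec", {
  expect_error(gen_duplex("GCA"), class = "mthia_spec_error")
  expect_error(gen_duplex("GGCAUGCC", twist = 60), class = "mthia_spec_error")
  expect_error(gen_duplex("GGCXUGCC"), class = "mthia_spec_error")
  expect_error(gen_duplex("GGCAUGCC", wobble_positions = 4),
               class = "mthia_spec_error")  # A cannot take a G:U wobble

  d <- gen_duplex("GGCAUGCC")
  # all residues anti in canonical A-form
  confs <- purrr::map_chr(1:8, function(i) {
    glycosidic_conformation(d, paste0("A:", i))$conformation
  })
  expect_true(all(confs == "anti"))
  truth <- attr(d, "pairs")
  expect_equal(nrow(truth), 8L)
})

test_that("structure perturbation is deterministic under seed", {
  d <- gen_duplex("GGCAUGCC")
  a <- perturb_structure(d, noise_sigma = 0.4, seed = 9)
  b <- perturb_structure(d, noise_sigma = 0.4, seed = 9)
  expect_identical(a, b)
  c_ <- perturb_structure(d, noise_sigma = 0.4, seed = 10)
  expect_false(identical(a, c_))
  # sigma = 0 is the pure rigid transform
  R <- random_rotation(seed = 2)
  expect_equal(as.matrix(perturb_structure(d, R, c(1, 2, 3))[, c("x", "y", "z")]),
               sweep(as.matrix(d[, c("x", "y", "z")]) %*% t(R), 2,
                     c(1, 2, 3), "+"), ignore_attr = TRUE)
})

test_that("generated columns realize exact compositions", {
  expect_equal(gen_column(c(U = 1), 200), rep("U", 200))
  col <- gen_column(c(A = .25, C = .25, G = .25, U = .25), 400)
  expect_equal(unname(table(col)["A"]), 100L, ignore_attr = TRUE)
  col <- gen_column(c(A = .5, G = .5), 100)
  expect_equal(sum(col == "A"), 50L)
  # largest remainder closes the count at awkward fractions
  col <- gen_column(c(A = 1 / 3, C = 1 / 3, G = 1 / 3), 100)
  expect_equal(length(col), 100L)
  expect_error(gen_column(c(A = .6, C = .6), 10), class = "mthia_spec_error")
  expect_error(gen_column(c(Z = 1), 10), class = "mthia_spec_error")
})
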