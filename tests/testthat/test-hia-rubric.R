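# Independent oracle for the rubric: a literal transcription of the category
# definitions applied case by case, kept separate from the package's
# vectorised cascade.
rubric_oracle <- function(p) {
  if (p$direct_mito_biochemical) return("P")
  if (!p$placeable_on_structure) return("und")
  if (!p$heterologous_data_exists) return("und")
  if (p$direct_heterologous == "supports_disruption") return("E")
  if (p$direct_heterologous == "supports_tolerance") return("N")
  if (p$indirect_heterologous == "supports_disruption") return("L")
  if (p$indirect_heterologous == "supports_tolerance") return("U")
  "NEE"
}

test_that("narrative evidence profiles map to the published categories", {
  profile <- function(placeable = TRUE, het = TRUE, direct = "none",
                      indirect = "none", mito = FALSE) {
    tibble::tibble(placeable_on_structure = placeable,
                   heterologous_data_exists = het,
                   direct_heterologous = direct,
                   indirect_heterologous = indirect,
                   direct_mito_biochemical = mito)
  }
  # direct cybrid biochemistry (e.g. the 173U>C case)
  expect_equal(classify_evidence(profile(mito = TRUE,
                                         indirect = "supports_disruption")), "P")
  # no structural placement (e.g. 399U>G)
  expect_equal(classify_evidence(profile(placeable = FALSE, het = FALSE)), "und")
  # direct heterologous dominant-lethal data at the equivalent (e.g. 1145G>A)
  expect_equal(classify_evidence(profile(direct = "supports_disruption")), "E")
  # indirect evidence only (e.g. 629U>A)
  expect_equal(classify_evidence(profile(indirect = "supports_disruption")), "L")
  expect_equal(classify_evidence(profile(indirect = "supports_tolerance")), "U")
  expect_equal(classify_evidence(profile(direct = "supports_tolerance")), "N")
  # evidence-free placeable profile
  expect_equal(classify_evidence(profile()), "NEE")
})

test_that("the rubric is total and deterministic over the whole profile space", {
  grid <- gen_evidence_profiles()
  # 2*2*3*3*2 = 72 combinations minus the 24 invariant-violating ones
  # (direct evidence recorded while heterologous_data_exists is FALSE)
  expect_equal(nrow(grid), 48L)
  got <- classify_evidence(grid)
  expect_true(all(got %in% c("N", "U", "NEE", "L", "E", "und", "P")))
  want <- purrr::map_chr(seq_len(nrow(grid)), ~rubric_oracle(grid[.x, ]))
  expect_equal(got, want)
  # P dominates every other flag combination
  expect_true(all(got[grid$direct_mito_biochemical] == "P"))
})

test_that("profile validation rejects malformed input", {
  bad <- tibble::tibble(placeable_on_structure = TRUE,
                        heterologous_data_exists = FALSE,
                        direct_heterologous = "supports_disruption",
                        indirect_heterologous = "none",
                        direct_mito_biochemical = FALSE)
  expect_error(classify_evidence(bad), class = "mthia_input_error")
  bad2 <- dplyr::mutate(bad, heterologous_data_exists = TRUE,
                        direct_heterologous = "yes")
  expect_error(classify_evidence(bad2), class = "mthia_input_error")
  expect_error(classify_evidence(tibble::tibble(a = 1)),
               class = "mthia_input_error")
})

test_that("classification histograms partition the input", {
  f <- load_variant_fixture()
  cl <- classify_variants(f)
  h <- category_histogram(cl)
  expect_equal(sum(h), nrow(f))
  expect_equal(unname(h["P"]), 1L)

  single <- classify_variants(f[f$category == "Proven", ])
  expect_equal(unname(category_histogram(single)["P"]), 1L)
  expect_equal(sum(category_histogram(single)), 1L)

  empty <- classify_variants(f[0, ])
  expect_equal(sum(category_histogram(empty)), 0L)

  g <- glance(cl)
  expect_equal(g$total, 64L)
  expect_equal(g$NEE, unname(h["NEE"]))
})
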