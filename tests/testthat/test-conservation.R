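# An N-terminal-style toy alignment (30 columns): tyrosine at reference
# position 7 flanked by acidic residues, a serine at 27 flanked by lysines,
# and class-structured variation (one cartilaginous species lacking Tyr-7).
nterm_fixture <- function() {
  template <- "MGKAENYELYQVAAAAAAAAAAAAKASKKA"
  swap <- function(s, pos, res) {
    substr(s, pos, pos) <- res
    s
  }
  seqs <- c(
    homo_sapiens = template,
    mus_musculus = swap(template, 10, "H"),
    monodelphis_domestica = template,
    macropus_eugenii = template,
    anolis_carolinensis = template,
    xenopus_laevis = swap(template, 27, "-"),
    danio_rerio = swap(swap(template, 10, "F"), 27, "A"),
    dasyatis_sabina = swap(template, 7, "F"),
    callorhinchus_milii = template
  )
  groups <- c(
    homo_sapiens = "placental", mus_musculus = "placental",
    monodelphis_domestica = "marsupial", macropus_eugenii = "marsupial",
    anolis_carolinensis = "reptile", xenopus_laevis = "amphibian",
    danio_rerio = "bony_fish",
    dasyatis_sabina = "cartilaginous", callorhinchus_milii = "cartilaginous"
  )
  list(aln = toy_alignment(seqs), groups = groups)
}

test_that("map_reference_positions skips reference gap columns", {
  aln <- toy_alignment(c(homo_sapiens = "M-AK", danio_rerio = "MKAK"))
  map <- map_reference_positions(aln, "homo_sapiens")
  expect_equal(as.integer(map), c(1L, NA, 2L, 3L))
  # ungapped reference: identity map
  map2 <- map_reference_positions(aln, "danio_rerio")
  expect_equal(as.integer(map2), 1:4)
  expect_error(map_reference_positions(aln, "mus_musculus"), "not in")
  allgap <- toy_alignment(c(homo_sapiens = "----", danio_rerio = "MKAK"))
  expect_error(map_reference_positions(allgap, "homo_sapiens"), "all gaps")
})

test_that("conservation_profile reports modal fractions and group structure", {
  fx <- nterm_fixture()
  prof <- conservation_profile(fx$aln, "homo_sapiens", fx$groups)
  expect_equal(nrow(prof), 30L)
  expect_equal(prof$position, 1:30)
  # position 1: methionine in everyone
  expect_equal(prof$conservation[prof$position == 1], 1.0)
  # position 7: tyrosine in 8 of 9 species
  p7 <- prof[prof$position == 7, ]
  expect_equal(p7$modal_residue, "Y")
  expect_equal(p7$conservation, 8 / 9)
  # conserved within every class except cartilaginous fish
  grp_cols <- grep("^grp_", names(prof), value = TRUE)
  expect_equal(unname(p7[[
    "grp_cartilaginous"]]), 0.5)
  others <- setdiff(grp_cols, "grp_cartilaginous")
  expect_true(all(unlist(p7[others]) == 1.0))
  # position 27: the gapped species leaves the denominator
  p27 <- prof[prof$position == 27, ]
  expect_equal(p27$n_nongap, 8L)
  expect_equal(p27$n_gap, 1L)
  expect_equal(p27$conservation, 7 / 8)
})

test_that("conservation fractions are invariant to species order", {
  fx <- nterm_fixture()
  prof1 <- conservation_profile(fx$aln, "homo_sapiens", fx$groups)
  shuffled <- validate_alignment(make_records(rev(fx$aln$seqs)))
  prof2 <- conservation_profile(shuffled, "homo_sapiens", fx$groups)
  expect_equal(prof1$conservation, prof2$conservation)
  expect_equal(prof1$modal_residue, prof2$modal_residue)
})

test_that("find_conserved thresholds correctly and is monotone", {
  fx <- nterm_fixture()
  prof <- conservation_profile(fx$aln, "homo_sapiens")
  strict <- find_conserved(prof, 1.0)
  expect_true(1 %in% strict)
  expect_false(7 %in% strict)    # 8/9 < 1
  loose <- find_conserved(prof, 0.85)
  expect_true(7 %in% loose)
  # monotone: raising the threshold never adds positions
  thresholds <- c(0.5, 0.7, 0.9, 1.0)
  sets <- lapply(thresholds, find_conserved, p = prof)
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
  expect_error(find_conserved(prof, 0), "threshold > 0")
})

test_that("kinase_context tags Src-style tyrosine context", {
  fx <- nterm_fixture()
  ctx <- kinase_context(fx$aln, 7, "homo_sapiens")
  expect_equal(attr(ctx, "window_size"), 3L)
  hs <- ctx[ctx$species == "homo_sapiens", ]
  expect_equal(hs$residue, "Y")
  expect_equal(hs$acidic, 2L)       # E at reference 5 and 8
  expect_equal(hs$verdict, "src-context")
  expect_false(hs$truncated)
  # the species lacking the tyrosine is not tagged
  ds <- ctx[ctx$species == "dasyatis_sabina", ]
  expect_equal(ds$residue, "F")
  expect_equal(ds$verdict, "none")
  summ <- attr(ctx, "summary")
  expect_equal(unname(summ[["src-context"]]), 8 / 9)
})

test_that("kinase_context tags PKC-style serine context and gaps", {
  fx <- nterm_fixture()
  ctx <- kinase_context(fx$aln, 27, "homo_sapiens")
  expect_equal(attr(ctx, "window_size"), 5L)
  hs <- ctx[ctx$species == "homo_sapiens", ]
  expect_equal(hs$residue, "S")
  expect_equal(hs$basic, 3L)        # K at 25, 28, 29
  expect_equal(hs$verdict, "pkc-context")
  expect_true(hs$truncated)         # window reaches the C-terminal end
  expect_equal(ctx$verdict[ctx$species == "xenopus_laevis"], "gap")
  expect_equal(ctx$verdict[ctx$species == "danio_rerio"], "none")
  expect_error(kinase_context(fx$aln, 99, "homo_sapiens"), "not mapped")
})

test_that("kinase_context windows use species-own ungapped coordinates", {
  # the second species has a gap inside the window: its own neighbours,
  # not the alignment columns, must be counted
  aln <- toy_alignment(c(
    homo_sapiens = "MAEAYAAKAA",
    mus_musculus = "MAE-YEAKAA"
  ))
  ctx <- kinase_context(aln, 5, "homo_sapiens", window_size = 2)
  hs <- ctx[ctx$species == "homo_sapiens", ]
  mm <- ctx[ctx$species == "mus_musculus", ]
  expect_equal(hs$window, "EA[Y]AA")
  expect_equal(mm$window, "AE[Y]EA")  # gap skipped, window slides inward
  expect_equal(mm$acidic, 2L)
  expect_equal(mm$verdict, "src-context")
  # a tyrosine with no acidic neighbour gets no tag
  aln2 <- toy_alignment(c(homo_sapiens = "MAKAYAAKAA",
                          mus_musculus = "MAKAYAAKAA"))
  ctx2 <- kinase_context(aln2, 5, "homo_sapiens", window_size = 2)
  expect_true(all(ctx2$verdict == "none"))
})

test_that("group assignments can come from a YAML file", {
  fx <- nterm_fixture()
  yml <- tempfile(fileext = ".yaml")
  writeLines(vapply(names(fx$groups), function(s) {
    paste0(s, ": ", fx$groups[[s]])
  }, ""), yml)
  prof_file <- conservation_profile(fx$aln, "homo_sapiens", yml)
  prof_vec <- conservation_profile(fx$aln, "homo_sapiens", fx$groups)
  expect_equal(prof_file, prof_vec, ignore_attr = TRUE)
})
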