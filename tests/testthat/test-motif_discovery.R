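toy_alignment <- function() {
  rows <- c(a1 = "AC", a2 = "AC", b1 = "AG", b2 = "AG")
  grouped_alignment(rows, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
}

test_that("column_profiles computes per-group modal residues and gap frequencies", {
  p <- column_profiles(toy_alignment())
  expect_length(p, 2L)
  expect_equal(p[[1]]$groups$modal, c("A", "A"))
  expect_equal(p[[1]]$groups$modal_freq, c(1, 1))
  expect_equal(p[[2]]$groups$modal, c("C", "G"))

  # all-gap column in one group: modal undefined, gap frequency 1
  aln <- grouped_alignment(c(a1 = "A-", b1 = "AC", b2 = "AC"),
                           c(a1 = "A", b1 = "B", b2 = "B"))
  p2 <- column_profiles(aln)
  expect_true(is.na(p2[[2]]$groups$modal[1]))
  expect_equal(p2[[2]]$groups$gap_freq[1], 1)

  # profiles are invariant under row shuffling
  rows <- c(a1 = "ACD", a2 = "AVD", b1 = "GCW", b2 = "GMW")
  grp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  perm <- c(3, 1, 4, 2)
  p_fwd <- column_profiles(grouped_alignment(rows, grp))
  p_shuf <- column_profiles(grouped_alignment(rows[perm], grp[perm]))
  expect_equal(p_fwd, p_shuf)

  expect_error(column_profiles(grouped_alignment(c(a = "AA"), c(a = "A"))),
               ">= 2 groups")
})

test_that("group_consensus recovers the published FN3 subtype motifs from a rotation-filled alignment", {
  aln <- generate_grouped_alignment(FN3_MOTIFS, n_per_group = 20,
                                    wildcard_policy = "rotation",
                                    max_freq = 0.25, seed = 1)
  cons <- group_consensus(column_profiles(aln), tau = 0.8, gamma = 0.5)
  expect_equal(cons[["InsR1"]], FN3_MOTIFS[["InsR1"]])
  expect_equal(cons[["InsR2"]], FN3_MOTIFS[["InsR2"]])
  expect_equal(cons[["InsR3"]], FN3_MOTIFS[["InsR3"]])
})

test_that("group_consensus threshold and degenerate-input contracts", {
  # one divergent sequence at a column defeats tau = 1
  rows <- c(a1 = "AAAA", a2 = "AACA", b1 = "GGGG", b2 = "GGGG")
  grp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  profs <- column_profiles(grouped_alignment(rows, grp))
  cons <- group_consensus(profs, tau = 1.0)
  expect_equal(cons[["A"]], "AAxA")
  expect_equal(cons[["B"]], "GGGG")

  # single-sequence groups reproduce each sequence verbatim
  profs1 <- column_profiles(grouped_alignment(c(x = "MKWY", y = "MDWC"),
                                              c(x = "X", y = "Y")))
  cons1 <- group_consensus(profs1, tau = 1.0)
  expect_equal(unname(cons1), c("MKWY", "MDWC"), ignore_attr = TRUE)

  # columns gapped beyond gamma in ALL groups are dropped from all strings
  rows2 <- c(a1 = "A-C", a2 = "A-C", b1 = "G-T", b2 = "G-T")
  cons2 <- group_consensus(column_profiles(grouped_alignment(rows2, grp)),
                           tau = 0.8, gamma = 0.5)
  expect_equal(unname(nchar(cons2)), c(2L, 2L))
  expect_equal(attr(cons2, "columns"), c(1L, 3L))
})

test_that("discovery round-trip recovers random motif sets exactly (property)", {
  withr::with_seed(99, {
    for (trial in 1:10) {
      k <- sample(2:4, 1)
      L <- sample(5:30, 1)
      motifs <- vapply(seq_len(k), function(i) {
        chars <- sample(c(AA20, "x"), L, replace = TRUE, prob = c(rep(1, 20), 10))
        paste0(chars, collapse = "")
      }, character(1))
      names(motifs) <- paste0("g", seq_len(k))
      aln <- generate_grouped_alignment(motifs, n_per_group = 12,
                                        wildcard_policy = "rotation",
                                        max_freq = 0.25, seed = trial)
      cons <- group_consensus(column_profiles(aln), tau = 0.8, gamma = 0.5)
      expect_equal(unname(cons[names(motifs)]), unname(motifs))
    }
  })
})

test_that("lowering tau never turns a fixed consensus position into a wildcard", {
  aln <- generate_grouped_alignment(FN3_MOTIFS, n_per_group = 10,
                                    wildcard_policy = "background", seed = 5)
  profs <- column_profiles(aln)
  hi <- group_consensus(profs, tau = 0.95)
  lo <- group_consensus(profs, tau = 0.6)
  for (g in names(hi)) {
    fixed_hi <- which(strsplit(hi[[g]], "")[[1]] != "x")
    lo_chars <- strsplit(lo[[g]], "")[[1]]
    expect_false(any(lo_chars[fixed_hi] == "x"))
  }
})

test_that("universal_positions finds columns fixed and identical across groups", {
  uni <- universal_positions(FN3_MOTIFS)
  expect_equal(as.integer(uni), c(2L, 3L, 6L, 20L))
  expect_equal(attr(uni, "residues"), c("Y", "A", "V", "S"))

  expect_equal(as.integer(universal_positions(c(a = "MKW", b = "MKW"))), 1:3)
  expect_length(universal_positions(c(a = "Ax", b = "xA")), 0L)
  expect_error(universal_positions(c(a = "AA", b = "A")), "unequal")

  # universal positions are a subset of every group's fixed positions
  aln <- generate_grouped_alignment(FN3_MOTIFS, n_per_group = 8, seed = 2)
  cons <- group_consensus(column_profiles(aln))
  uni2 <- as.integer(universal_positions(cons))
  for (g in names(cons)) {
    fixed <- which(strsplit(cons[[g]], "")[[1]] != "x")
    expect_true(all(uni2 %in% fixed))
  }
})

test_that("diagnostic_positions recovers planted discriminative quartet columns", {
  # 3 groups seeded with K/R/Q at one column and E/D/R at another, a shared A
  # column, and rotation-filled wildcards (emulates the subtype-diagnostic
  # peptide-binding columns)
  motifs <- c(g1 = "xAxKxEx", g2 = "xAxRxDx", g3 = "xAxQxRx")
  aln <- generate_grouped_alignment(motifs, n_per_group = 10, seed = 31)
  diag <- diagnostic_positions(column_profiles(aln), tau = 0.8)
  expect_equal(diag$column, c(2L, 4L, 6L))
  expect_equal(diag$kind, c("universal", "discriminative", "discriminative"))
  expect_equal(unname(unlist(diag[diag$column == 4L, c("g1", "g2", "g3")])),
               c("K", "R", "Q"))
  expect_equal(unname(unlist(diag[diag$column == 6L, c("g1", "g2", "g3")])),
               c("E", "D", "R"))

  # below-threshold column excluded
  rows <- c(a1 = "KA", a2 = "RA", b1 = "QA", b2 = "QA")
  grp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  diag2 <- diagnostic_positions(column_profiles(grouped_alignment(rows, grp)),
                                tau = 0.8)
  expect_equal(diag2$column, 2L)
  expect_equal(diag2$kind, "universal")

  # all-identical alignment: every column universal
  rows3 <- c(a = "MKW", b = "MKW")
  diag3 <- diagnostic_positions(column_profiles(
    grouped_alignment(rows3, c(a = "A", b = "B"))), tau = 0.8)
  expect_equal(diag3$kind, rep("universal", 3))
})

test_that("residue_proportions columns sum to one and honour gap exclusion", {
  aln <- grouped_alignment(c(a = "AC-", b = "CC-"), c(a = "A", b = "B"))
  props <- residue_proportions(aln)
  expect_equal(unname(rowSums(props)), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(props[1, c("A", "C")]), c(0.5, 0.5))
  expect_equal(unname(props[3, "-"]), 1)

  nog <- residue_proportions(aln, exclude_gaps = TRUE)
  expect_equal(unname(rowSums(nog)[1:2]), c(1, 1))
  expect_equal(unname(rowSums(nog)[3]), 0)   # all-gap column: zero row

  # row-shuffle invariance
  aln2 <- grouped_alignment(c(b = "CC-", a = "AC-"), c(a = "A", b = "B"))
  expect_equal(residue_proportions(aln2), residue_proportions(aln))

  # single sequence: unit mass at its residue
  one <- grouped_alignment(c(a = "MW", b = "MW"), c(a = "A", b = "B"))
  expect_equal(unname(residue_proportions(one)[1, "M"]), 1)
})
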