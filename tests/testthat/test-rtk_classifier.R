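test_that("noise-free synthetic sequences of every subtype are recovered at tier full", {
  for (k in seq_along(ALL_SUBTYPES)) {
    cl <- ALL_SUBTYPES[[k]][1]
    st <- ALL_SUBTYPES[[k]][2]
    g <- generate_sequence(synthetic_spec(cl, st, seed = 7), library = MOTIF_LIB)
    res <- classify(g$record, library = MOTIF_LIB)
    expect_equal(res$rtk_class, cl)
    expect_equal(res$subtype, st)
    expect_equal(res$tier, "full")
    expect_true(length(res$evidence) >= 1L)
  }
})

test_that("a truncated InsR retaining only the FN3 region is called at tier partial", {
  spec <- synthetic_spec("InsR", "InsR1", truncation = "c_terminal",
                         retained = 0.6, nterm_len = c(100L, 140L), seed = 3)
  g <- generate_sequence(spec, library = MOTIF_LIB)
  expect_true("cassette" %in% g$truth$evidence_lost)  # kinase domain gone
  res <- classify(g$record, library = MOTIF_LIB)
  expect_equal(res$rtk_class, "InsR")
  expect_equal(res$subtype, "InsR1")
  expect_equal(res$tier, "partial")
})

test_that("truncated FGFR/PVR keep the class call; fully-stripped sequences are unknown", {
  # the FGFR/PVR subtype motifs are kinase-internal, so a sequence keeping the
  # kinase cassette keeps both class and subtype
  spec <- synthetic_spec("PVR", "PVR1", truncation = "n_terminal",
                         retained = 0.5, seed = 9)
  g <- generate_sequence(spec, library = MOTIF_LIB)
  res <- classify(g$record, library = MOTIF_LIB)
  expect_equal(res$rtk_class, "PVR")

  # truncation that removes all planted evidence yields unknown
  spec2 <- synthetic_spec("FGFR", "FGFR1", truncation = "c_terminal",
                          retained = 0.3, nterm_len = c(300L, 400L), seed = 10)
  g2 <- generate_sequence(spec2, library = MOTIF_LIB)
  expect_true("cassette" %in% g2$truth$evidence_lost)
  expect_equal(classify(g2$record, library = MOTIF_LIB)$rtk_class, "unknown")
})

test_that("the PVR catalytic-loop G->R variant is recovered with relaxed_catloop", {
  g <- generate_sequence(synthetic_spec("PVR", "PVR2A", seed = 12),
                         library = MOTIF_LIB)
  res0 <- classify(g$record, library = MOTIF_LIB)
  expect_equal(res0$rtk_class, "PVR")

  # swap HGDLA -> HRDLA inside the planted cassette (the Lv-VEGFR2 exception)
  cas <- g$truth$offsets$cassette
  res_chars <- strsplit(g$record$residues, "")[[1]]
  catloop_at <- cas[["start"]] + 17L  # HGDLA starts at cassette position 17
  expect_equal(paste0(res_chars[catloop_at + 0:4], collapse = ""), "HGDLA")
  res_chars[catloop_at + 1L] <- "R"
  variant <- seq_record(g$record$id, paste0(res_chars, collapse = ""))

  relaxed <- classify(variant, library = MOTIF_LIB,
                      params = classifier_params(relaxed_catloop = TRUE))
  expect_equal(relaxed$rtk_class, "PVR")
  expect_equal(relaxed$subtype, "PVR2A")
  kinds <- vapply(relaxed$evidence, `[[`, character(1), "kind")
  expect_true("variant" %in% kinds)

  # without relaxation the class call survives on motif score, but the
  # HGDLA-anchored region evidence is absent
  strict <- classify(variant, library = MOTIF_LIB)
  expect_equal(strict$rtk_class, "PVR")
  strict_kinds <- vapply(strict$evidence, `[[`, character(1), "kind")
  expect_false("anchored_region" %in% strict_kinds)
})

test_that("a perfect InsR catalytic 10-mer is never called FGFR or PVR", {
  # graft a perfect VHRDLAARNC into an otherwise perfect FGFR1 sequence
  g <- generate_sequence(synthetic_spec("FGFR", "FGFR1", seed = 13),
                         library = MOTIF_LIB)
  res_chars <- strsplit(g$record$residues, "")[[1]]
  res_chars[5:14] <- strsplit("VHRDLAARNC", "")[[1]]
  hybrid <- seq_record("hybrid", paste0(res_chars, collapse = ""))
  res <- classify(hybrid, library = MOTIF_LIB)
  expect_equal(res$rtk_class, "InsR")
})

test_that("classification is deterministic and robust to out-of-motif truncation", {
  g <- generate_sequence(synthetic_spec("FGFR", "FGFR3", seed = 14),
                         library = MOTIF_LIB)
  r1 <- classify(g$record, library = MOTIF_LIB)
  r2 <- classify(g$record, library = MOTIF_LIB)
  expect_identical(r1[c("rtk_class", "subtype", "tier", "best_score")],
                   r2[c("rtk_class", "subtype", "tier", "best_score")])

  # removing residues outside all planted motif regions keeps the call
  off <- g$truth$offsets
  first_motif_start <- min(vapply(off, `[`, numeric(1), "start"))
  trimmed <- substr(g$record$residues, max(1L, first_motif_start - 10L),
                    nchar(g$record$residues))
  r3 <- classify(seq_record("trimmed", trimmed), library = MOTIF_LIB)
  expect_equal(r3$rtk_class, r1$rtk_class)
  expect_equal(r3$subtype, r1$subtype)
})

test_that("classify_batch summarises, keeps input order, and handles empty input", {
  ds <- generate_dataset(subtype_specs(n = 2, seed0 = 40), library = MOTIF_LIB)
  b <- classify_batch(ds$records, library = MOTIF_LIB)
  expect_equal(b$table$seq_id, ds$truth$id)
  expect_equal(sum(b$summary$n), 20L)
  cm <- confusion_matrix(b, ds$truth)
  expect_true(all(cm[cbind(rownames(cm), rownames(cm))] == 2L))

  e <- classify_batch(list(), library = MOTIF_LIB)
  expect_equal(nrow(e$table), 0L)
  expect_equal(nrow(e$summary), 0L)
})

test_that("subtype accuracy does not increase with the substitution rate", {
  rates <- c(0, 0.02, 0.05, 0.1)
  acc <- vapply(rates, function(r) subtype_accuracy(25, r, seed0 = 700),
                numeric(1))
  expect_equal(acc[1], 1)
  # finite-n slack of 0.05 on pairwise monotonicity
  expect_true(all(diff(acc) <= 0.05))
  expect_lt(acc[4], acc[1])
})

test_that("architecture_class reproduces the published domain-organisation rules", {
  arch <- function(domains) {
    data.frame(domain = domains,
               start = seq(1, by = 100, length.out = length(domains)),
               end = seq(90, by = 100, length.out = length(domains)))
  }
  expect_equal(architecture_class(arch(c("RECEPTOR_L", "FURIN_LIKE",
                                         "RECEPTOR_L", "FN3", "FN3",
                                         "TM", "TK"))), "InsR")
  expect_equal(architecture_class(arch(c(rep("IG_LIKE", 4), "TK"))), "PVR")
  expect_equal(architecture_class(arch(c("CADHERIN", "TK"))), "FGFR")
  expect_equal(architecture_class(arch(c("RECEPTOR_L", "FURIN_LIKE",
                                         "RECEPTOR_L", "GF_IV", "TK"))), "EGFR")
  # 2-3 immunoglobulin domains satisfy both growth-factor receptor signatures
  expect_setequal(architecture_class(arch(c(rep("IG_LIKE", 3), "TK"))),
                  c("FGFR", "PVR"))
  expect_length(architecture_class(arch(c("TM"))), 0L)
})

test_that("architecture evidence demotes conflicting calls and rescues unknowns", {
  g <- generate_sequence(synthetic_spec("FGFR", "FGFR1", seed = 15),
                         library = MOTIF_LIB)
  pvr_arch <- data.frame(domain = c(rep("IG_LIKE", 5), "TK"),
                         start = seq(1, by = 100, length.out = 6),
                         end = seq(90, by = 100, length.out = 6))
  res <- classify(g$record, library = MOTIF_LIB, domains = pvr_arch)
  expect_equal(res$rtk_class, "FGFR")      # motif evidence wins
  expect_equal(res$tier, "ambiguous")      # but the conflict demotes the tier
  kinds <- vapply(res$evidence, `[[`, character(1), "kind")
  expect_true("architecture_conflict" %in% kinds)

  # motif-free sequence with an unambiguous architecture: architecture_only
  insr_arch <- data.frame(domain = c("RECEPTOR_L", "FURIN_LIKE", "RECEPTOR_L",
                                     "FN3", "FN3"),
                          start = seq(1, by = 100, length.out = 5),
                          end = seq(90, by = 100, length.out = 5))
  res2 <- classify(seq_record("bare", random_protein(300, seed = 16)),
                   library = MOTIF_LIB, domains = insr_arch)
  expect_equal(res2$rtk_class, "InsR")
  expect_equal(res2$tier, "architecture_only")
  expect_equal(res2$subtype, "unassigned")
})
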