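# Shared fixtures and independent oracles, all built in code.

ALL_SUBTYPES <- list(
  c("InsR", "InsR1"), c("InsR", "InsR2"), c("InsR", "InsR3"),
  c("EGFR", "EGFR1"),
  c("FGFR", "FGFR1"), c("FGFR", "FGFR2"), c("FGFR", "FGFR3"),
  c("PVR", "PVR1"), c("PVR", "PVR2A"), c("PVR", "PVR2B"))

MOTIF_LIB <- load_motif_library()

# the three published InsR FN3 subtype 20-mers (worked-example inputs)
FN3_MOTIFS <- c(InsR1 = "RYAVYVETDTVADADIGARS",
                InsR2 = "RYAVxVKxxSLxSSxxGAQS",
                InsR3 = "xYAxYVxxYYTDxxKxxSRS")

random_protein <- function(n, seed = NULL) {
  draw <- function() paste0(sample(AA20, n, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# independent brute-force oracle: per-window recomputation of scan_motif,
# character by character, no shared code with the scanner
oracle_scan <- function(residues, consensus, min_score) {
  pat <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  sub <- strsplit(residues, "", fixed = TRUE)[[1L]]
  L <- length(pat)
  fixed_idx <- which(pat != "x")
  out <- data.frame(start = integer(0), score = numeric(0))
  if (length(sub) < L) return(out)
  for (off in 0:(length(sub) - L)) {
    hits <- 0L
    for (j in fixed_idx) if (sub[off + j] == pat[j]) hits <- hits + 1L
    score <- hits / length(fixed_idx)
    if (score >= min_score) {
      out <- rbind(out, data.frame(start = off, score = score))
    }
  }
  out[order(-out$score, out$start), , drop = FALSE]
}

# spec batch for every subtype at the given noise level
subtype_specs <- function(n, rate = 0, seed0 = 1L, ...) {
  lapply(seq_along(ALL_SUBTYPES), function(k) {
    synthetic_spec(ALL_SUBTYPES[[k]][1], ALL_SUBTYPES[[k]][2], n = n,
                   p_fix = rate, p_bg = rate, seed = seed0 + k, ...)
  })
}

subtype_accuracy <- function(n, rate, seed0, params = classifier_params()) {
  ds <- generate_dataset(subtype_specs(n, rate, seed0), library = MOTIF_LIB)
  b <- classify_batch(ds$records, library = MOTIF_LIB, params = params)
  mean(b$table$subtype == ds$truth$subtype)
}

write_tmp_fasta <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "seqs.fasta")
  writeLines(lines, path)
  path
}
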