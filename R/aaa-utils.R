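# Shared constants and small helpers.
#
# Internal coordinates are 0-based half-open throughout; anything written to a
# file or printed for a biologist is converted to 1-based inclusive at the I/O
# boundary.

#' The twenty standard amino acids (one-letter codes)
#'
#' @format Character vector of length 20, alphabetical.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# residues legal in an unaligned sequence: 20 amino acids plus ambiguity X
.seq_alphabet <- c(AA20, "X")
# residues legal in an alignment row: adds the gap character
.aln_alphabet <- c(.seq_alphabet, "-")

# controlled vocabulary for domain-architecture annotations
.domain_vocab <- c("RECEPTOR_L", "FURIN_LIKE", "FN3", "TM", "TK",
                   "IG_LIKE", "CADHERIN", "GF_IV")

.rtk_classes  <- c("InsR", "EGFR", "FGFR", "PVR")
.rtk_subtypes <- list(
  InsR = c("InsR1", "InsR2", "InsR3"),
  EGFR = "EGFR1",
  FGFR = c("FGFR1", "FGFR2", "FGFR3"),
  PVR  = c("PVR1", "PVR2A", "PVR2B")
)

# split a sequence (seq_record or character scalar) into a character vector
as_residues <- function(x) {
  if (inherits(x, "seq_record")) x <- x$residues
  stopifnot(is.character(x), length(x) == 1L)
  strsplit(x, "", fixed = TRUE)[[1L]]
}

seq_length <- function(x) {
  if (inherits(x, "seq_record")) nchar(x$residues) else nchar(x)
}

seq_id <- function(x) {
  if (inherits(x, "seq_record")) x$id else "<sequence>"
}

# derive a per-item RNG seed from a base seed, kept below 2^31
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
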