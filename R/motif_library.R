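# The packaged motif library.
#
# Shipped as a versioned TSV fixture (inst/extdata/motif_library.tsv) and
# compiled to degenerate motifs at load time.  Roles:
#   catalytic       - the InsR catalytic-loop 10-mer VHRDLAARNC (class marker)
#   fn3             - the InsR subtype 20-mers near the first FN3 domain
#   kinase_subtype  - FGFR/PVR catalytic-domain subtype motifs (class +
#                     subtype markers; the FGFR strings exist in a "verbatim"
#                     aligned variant with the single published '-' column and
#                     a gap-stripped "scan" variant used for matching)
#   egfr_context    - an artifact-derived (synthetic) EGFR catalytic-context
#                     string; NOT a published motif.

#' Load the packaged motif library
#'
#' @param path Path to a motif-library TSV (columns `name`, `rtk_class`,
#'   `subtype`, `role`, `variant`, `consensus`, `bold`, `source`).  Defaults to
#'   the fixture shipped with the package.
#' @param variant Which consensus variant to compile: `"scan"` (gap-stripped,
#'   used by the classifier) or `"verbatim"` (as printed, aligned).
#' @return A `motif_library`: list of [compile_motif()] objects plus a `table`
#'   attribute holding the raw TSV.
#' @export
load_motif_library <- function(path = NULL, variant = c("scan", "verbatim")) {
  variant <- match.arg(variant)
  if (is.null(path)) {
    path <- system.file("extdata", "motif_library.tsv", package = "rtkclass",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  sel <- tab[tab$variant == variant, , drop = FALSE]
  if (variant == "verbatim") {
    # motifs with no aligned twin fall back to their scan row
    covered <- sub("_aln$", "", sel$name)
    extra <- tab[tab$variant == "scan" & !tab$name %in% covered, , drop = FALSE]
    sel <- rbind(sel, extra)
  }
  motifs <- lapply(seq_len(nrow(sel)), function(i) {
    row <- sel[i, ]
    bold <- if (is.na(row$bold) || !nzchar(row$bold)) integer(0) else
      as.integer(strsplit(row$bold, ",", fixed = TRUE)[[1L]])
    consensus <- row$consensus
    if (variant == "verbatim" && grepl("-", consensus, fixed = TRUE)) {
      # aligned variant: keep verbatim string in `source` note, compile the
      # gap-stripped pattern (gaps are alignment bookkeeping, not residues)
      stripped <- gsub("-", "", consensus, fixed = TRUE)
      keepcols <- which(strsplit(consensus, "")[[1L]] != "-")
      bold <- sort(stats::na.omit(match(bold, keepcols)))
      consensus <- stripped
    }
    compile_motif(consensus, bold_positions = bold, name = row$name,
                  rtk_class = row$rtk_class, subtype = row$subtype,
                  source = row$source)
  })
  names(motifs) <- sel$name
  for (i in seq_along(motifs)) motifs[[i]]$role <- sel$role[i]
  structure(motifs, table = tab, class = "motif_library")
}

#' @export
print.motif_library <- function(x, ...) {
  cat(sprintf("<motif_library> %d motifs:\n", length(x)))
  for (m in x) {
    cat(sprintf("  %-18s %-5s %-6s %-15s len %3d\n", m$name,
                m$rtk_class %||% "", m$subtype %||% "", m$role, m$length))
  }
  invisible(x)
}

# helpers used by the classifier -------------------------------------------

library_motifs <- function(library, rtk_class = NULL, role = NULL) {
  sel <- library
  if (!is.null(rtk_class)) {
    sel <- Filter(function(m) identical(m$rtk_class, rtk_class), sel)
  }
  if (!is.null(role)) sel <- Filter(function(m) identical(m$role, role), sel)
  sel
}
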