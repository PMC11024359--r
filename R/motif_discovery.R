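# Supervised group-conservation motif discovery.
#
# Re-implements the discovery stage the study ran with a supervised
# grouped-alignment tool: per-column residue profiles within and across
# groups, per-group degenerate consensus strings, universally conserved
# columns, subtype-diagnostic columns, and the per-column residue-proportion
# table behind sequence-logo rendering.
#
# Conventions: X is a 21st residue category that can never become a consensus
# residue; gaps are counted separately from residues.  Modal-residue ties are
# broken alphabetically (and a tied column can never satisfy tau > 0.5, so the
# tie-break never invents a fixed consensus position).

.profile_categories <- c(AA20, "X", "-")

# alignment as a character matrix (rows = sequences)
.aln_matrix <- function(aln) {
  stopifnot(inherits(aln, "grouped_alignment"))
  do.call(rbind, strsplit(unname(aln$rows), "", fixed = TRUE))
}

#' Per-column residue profiles of a grouped alignment
#'
#' @param aln A [grouped_alignment()] with at least two groups, each non-empty.
#' @return List (one element per column) of `column_profile` objects:
#'   `column` (1-based), `counts` (named counts over residues, `X` and gap),
#'   and `groups`, a data frame with per-group `modal` residue (`NA` when the
#'   group has no residue in the column), `modal_freq` and `gap_freq`
#'   (frequencies over the group's row count).
#' @export
column_profiles <- function(aln) {
  if (length(aln$groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  sizes <- table(aln$group_of)
  if (any(sizes == 0L)) stop("empty group", call. = FALSE)
  mat <- .aln_matrix(aln)
  groups <- aln$groups
  grp_rows <- lapply(groups, function(g) which(unname(aln$group_of) == g))
  lapply(seq_len(aln$ncol), function(j) {
    col <- mat[, j]
    counts <- table(factor(col, levels = .profile_categories))
    per_group <- do.call(rbind, lapply(seq_along(groups), function(k) {
      sub <- col[grp_rows[[k]]]
      n <- length(sub)
      res <- sub[sub %in% AA20]         # X and gap excluded from modal choice
      if (length(res)) {
        tab <- sort(table(res), decreasing = TRUE)
        top <- max(tab)
        modal <- sort(names(tab)[tab == top])[1L]  # alphabetical tie-break
        modal_freq <- top / n
      } else {
        modal <- NA_character_
        modal_freq <- 0
      }
      data.frame(group = groups[k], modal = modal, modal_freq = modal_freq,
                 gap_freq = sum(sub == "-") / n, stringsAsFactors = FALSE)
    }))
    rownames(per_group) <- NULL
    structure(list(column = j, counts = c(unclass(counts)), groups = per_group),
              class = "column_profile")
  })
}

#' Per-group degenerate consensus strings
#'
#' A column contributes the group's modal residue when its within-group
#' frequency is at least `tau` and the group's gap frequency is at most
#' `gamma`; otherwise it contributes the wildcard `x`.  Columns whose gap
#' frequency exceeds `gamma` in every group are dropped from all consensuses,
#' keeping the strings equal length.
#'
#' @param profiles Output of [column_profiles()].
#' @param tau Within-group conservation threshold, in `(0.5, 1]`.
#' @param gamma Maximum tolerated within-group gap frequency, in `[0, 1]`.
#' @return Named character vector: one consensus string per group, with a
#'   `"columns"` attribute giving the retained 1-based alignment columns.
#' @export
group_consensus <- function(profiles, tau = 0.8, gamma = 0.5) {
  stopifnot(tau > 0.5, tau <= 1, gamma >= 0, gamma <= 1)
  groups <- profiles[[1L]]$groups$group
  keep <- vapply(profiles, function(p) any(p$groups$gap_freq <= gamma), logical(1))
  kept <- profiles[keep]
  out <- vapply(groups, function(g) {
    chars <- vapply(kept, function(p) {
      row <- p$groups[p$groups$group == g, ]
      if (!is.na(row$modal) && row$modal_freq >= tau && row$gap_freq <= gamma) {
        row$modal
      } else "x"
    }, character(1))
    paste0(chars, collapse = "")
  }, character(1))
  names(out) <- groups
  attr(out, "columns") <- which(keep)
  out
}

#' Universally conserved positions across group consensuses
#'
#' @param consensuses Named character vector of equal-length consensus strings
#'   (as from [group_consensus()]).
#' @return Integer vector of 1-based positions where every group carries the
#'   same fixed (non-`x`) residue, with a `"residues"` attribute naming them.
#' @export
universal_positions <- function(consensuses) {
  if (length(unique(nchar(consensuses))) > 1L) {
    stop("consensus strings have unequal lengths", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(unname(consensuses), "", fixed = TRUE))
  idx <- which(apply(mat, 2L, function(col) {
    length(unique(col)) == 1L && col[1L] != "x"
  }))
  structure(idx, residues = if (length(idx)) mat[1L, idx] else character(0))
}

#' Subtype-diagnostic alignment positions
#'
#' A position is reported when every group is fixed there (modal frequency at
#' least `tau` and gap frequency at most `gamma`).  It is `universal` when all
#' groups share the residue, `discriminative` when at least two groups differ
#' (the published class-diagnostic quartets, e.g. the FGFR1/2/3 K/R/Q
#' peptide-binding column, are of the latter kind).
#'
#' @inheritParams group_consensus
#' @return Data frame with columns `column` (1-based), `kind`, and one residue
#'   column per group.
#' @export
diagnostic_positions <- function(profiles, tau = 0.8, gamma = 0.5) {
  stopifnot(tau > 0.5, tau <= 1)
  groups <- profiles[[1L]]$groups$group
  rows <- lapply(profiles, function(p) {
    g <- p$groups
    fixed <- !is.na(g$modal) & g$modal_freq >= tau & g$gap_freq <= gamma
    if (!all(fixed)) return(NULL)
    kind <- if (length(unique(g$modal)) == 1L) "universal" else "discriminative"
    out <- data.frame(column = p$column, kind = kind, stringsAsFactors = FALSE)
    for (k in seq_along(groups)) out[[groups[k]]] <- g$modal[k]
    out
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    out <- data.frame(column = integer(0), kind = character(0))
    for (g in groups) out[[g]] <- character(0)
    return(out)
  }
  do.call(rbind, rows)
}

#' Per-column residue proportions (logo table)
#'
#' @param aln A [grouped_alignment()] (group labels are ignored; any alignment
#'   with at least one row works).
#' @param exclude_gaps When `TRUE`, proportions are renormalised over residues
#'   only (columns that are all gap become all-zero rows).
#' @return Numeric matrix, one row per alignment position, columns the 20
#'   residues plus `X` and `-`; each row sums to 1 (gap-included mode).
#' @export
residue_proportions <- function(aln, exclude_gaps = FALSE) {
  mat <- .aln_matrix(aln)
  n <- nrow(mat)
  props <- t(apply(mat, 2L, function(col) {
    table(factor(col, levels = .profile_categories)) / n
  }))
  dimnames(props) <- list(position = seq_len(ncol(mat)),
                          residue = .profile_categories)
  if (exclude_gaps) {
    res <- props[, c(AA20, "X"), drop = FALSE]
    tot <- rowSums(res)
    res <- sweep(res, 1L, pmax(tot, .Machine$double.eps), "/")
    res[tot == 0, ] <- 0
    return(res)
  }
  props
}

#' Write discovery output tables
#'
#' `write_consensus_tsv` writes one row per group (group, consensus,
#' comma-separated universal positions); `write_proportions_tsv` writes the
#' wide logo table (rows = positions, columns = residues) for external logo
#' renderers.
#'
#' @param consensuses Output of [group_consensus()].
#' @param proportions Output of [residue_proportions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consensus_tsv <- function(consensuses, path) {
  uni <- universal_positions(consensuses)
  tab <- data.frame(group = names(consensuses),
                    consensus = unname(consensuses),
                    universal_positions = paste(uni, collapse = ","),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_consensus_tsv
#' @export
write_proportions_tsv <- function(proportions, path) {
  tab <- data.frame(position = seq_len(nrow(proportions)), proportions,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
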